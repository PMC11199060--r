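# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_idsn <- function(...) stop(sprintf(...), call. = FALSE)

# Polynomial rolling hash over a character string, exact in double precision
# (modulus < 2^26 keeps every intermediate below 2^53). Used both for
# fingerprint bit hashing and for config hashes; NOT cryptographic.
.str_hash <- function(x, mod = 67108859) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% mod
  h
}

#' Deterministic hash of a configuration object
#'
#' Serialises the object with `deparse()` in a locale-independent way and
#' hashes the result. Identical configurations always map to the same
#' 8-hex-digit tag, which is recorded in every output file header so that
#' artefacts can be traced back to the settings that produced them.
#'
#' @param x Any R object (typically a [pipeline_config()] list).
#' @return A character scalar, eight lowercase hex digits.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  sprintf("%08x", as.integer(.str_hash(txt, mod = 2147483629)))
}

# Derive an independent substream seed from a master seed. Keeps results
# reproducible while letting different random components (prototypes, chem
# noise, pharm noise, label contamination) consume separate streams.
.substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

.assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_idsn("'%s' must be a single positive integer (got %s)", name,
              paste(format(x), collapse = ","))
  invisible(as.integer(x))
}

# Amino-acid alphabet accepted in target sequences (20 standard + X).
AA_ALPHABET20X <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                    "F","P","S","T","W","Y","V","X")

.check_aa_sequence <- function(seq, where = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET20X)
  if (nchar(seq) == 0L)
    stop_idsn("empty amino-acid %s", where)
  if (length(bad))
    stop_idsn("invalid amino-acid character(s) %s in %s",
              paste(bad, collapse = ","), where)
  invisible(TRUE)
}

# Deterministic number formatting for file output (byte-identical reruns).
.fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  gsub(" ", "", out, fixed = TRUE)
}
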
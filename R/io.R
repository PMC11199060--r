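#' Read a drug table (CSV or TSV)
#'
#' The table must contain at least `drug_id` and `structure` columns; an
#' optional `pathway` column supplies the downstream-pathway annotation.
#' `structure` is either a SMILES string or a precomputed fingerprint
#' bitstring (a string over 0/1); a cohort uses exactly one form. The
#' delimiter (comma vs tab) is auto-detected from the header line.
#'
#' @param path Path to the file.
#' @return A list of drug profiles (class `drug_cohort`). Each profile is a
#'   list with `drug_id`, `structure`, `fingerprint` (NULL until
#'   [structural_fingerprint()] runs), `targets` (list of
#'   `list(target_id, sequence)`), `pathway` (NA if absent), and
#'   `extra_annotations`.
#' @export
read_drug_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop_idsn("empty drug table: %s", path)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          na.strings = character())
  for (col in c("drug_id", "structure"))
    if (!col %in% names(df))
      stop_idsn("drug table is missing required column '%s'", col)
  dup <- unique(df$drug_id[duplicated(df$drug_id)])
  if (length(dup))
    stop_idsn("duplicate drug_id(s) in drug table: %s",
              paste(dup, collapse = ","))
  if (any(!nzchar(df$drug_id))) stop_idsn("empty drug_id in drug table")
  has_pw <- "pathway" %in% names(df)
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    pw <- if (has_pw && nzchar(df$pathway[i])) df$pathway[i] else NA_character_
    list(drug_id = df$drug_id[i], structure = df$structure[i],
         fingerprint = NULL, targets = list(), pathway = pw,
         extra_annotations = list())
  })
  names(profiles) <- df$drug_id
  class(profiles) <- "drug_cohort"
  profiles
}

#' Attach target protein sequences from a FASTA file
#'
#' FASTA headers must have the form `>drug_id|target_id`. Each record is
#' appended to the matching profile's target list. Drugs absent from the
#' FASTA keep empty target lists; their count is reported with a warning.
#' Sequences are validated against the 20-letter amino-acid alphabet plus X.
#'
#' @param path Path to the FASTA file.
#' @param profiles A `drug_cohort` from [read_drug_table()].
#' @return The updated `drug_cohort`.
#' @export
read_target_fasta <- function(path, profiles) {
  lines <- readLines(path)
  # manual parse so malformed headers can be reported with a line number
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L && any(nzchar(trimws(lines))))
    stop_idsn("no FASTA records found in %s", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (r in seq_along(hdr_idx)) {
    ln <- hdr_idx[r]
    header <- sub("^>", "", lines[ln])
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || any(!nzchar(parts)))
      stop_idsn("line %d: FASTA header '>%s' does not match 'drug_id|target_id'",
                ln, header)
    drug_id <- parts[[1]]; target_id <- parts[[2]]
    if (!drug_id %in% names(profiles))
      stop_idsn("line %d: drug '%s' in FASTA is not in the cohort", ln, drug_id)
    seq <- toupper(paste(trimws(lines[(ln + 1L):(bounds[r + 1L] - 1L)]),
                         collapse = ""))
    .check_aa_sequence(seq, where = sprintf("target %s of drug %s",
                                            target_id, drug_id))
    profiles[[drug_id]]$targets <-
      c(profiles[[drug_id]]$targets,
        list(list(target_id = target_id, sequence = seq)))
  }
  n_missing <- sum(vapply(profiles, function(p) length(p$targets) == 0L,
                          logical(1)))
  if (n_missing > 0L)
    warning(sprintf("%d drug(s) have no target sequences and will be excluded from pharm-DSN and fusion",
                    n_missing), call. = FALSE)
  profiles
}

#' Read a two-column annotation table (drug_id, label)
#'
#' @param path Path to a CSV/TSV with columns `drug_id` and a label column
#'   (any name; the second column is used).
#' @param scheme Name of the annotation scheme (e.g. `"pathway"`).
#' @return An `annotation_table`: list with `scheme`, `mapping` (named
#'   character vector drug_id -> label) and `categories`.
#' @export
read_annotation_table <- function(path, scheme) {
  lines <- readLines(path)
  if (length(lines) <= 1L && all(!nzchar(trimws(lines))) || length(lines) == 0L) {
    return(annotation_table(scheme, character(0)))
  }
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", comment.char = "",
                          check.names = FALSE)
  if (ncol(df) < 2L) stop_idsn("annotation table needs two columns")
  mapping <- stats::setNames(df[[2L]], df[[1L]])
  annotation_table(scheme, mapping)
}

#' Construct an annotation table from a named vector
#'
#' @param scheme Scheme name.
#' @param mapping Named character vector, names are drug ids.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(scheme, mapping) {
  dup <- unique(names(mapping)[duplicated(names(mapping))])
  if (length(dup))
    stop_idsn("duplicate drug_id(s) in annotation '%s': %s", scheme,
              paste(dup, collapse = ","))
  structure(list(scheme = scheme, mapping = mapping,
                 categories = sort(unique(unname(mapping)))),
            class = "annotation_table")
}

#' Write / read a similarity network as annotated TSV
#'
#' The format is a human-inspectable TSV: `#`-prefixed metadata header
#' (format version, source, scale, config hash, seed), then an id header row
#' and one id-prefixed row per drug. `read_network(write_network(net))` is an
#' entrywise identity to 1e-12 with identical id order.
#'
#' @param net A [similarity_network()].
#' @param path Output path.
#' @return `write_network`: `path`, invisibly. `read_network`: the network.
#' @export
write_network <- function(net, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# idsn-network v1",
    sprintf("# source: %s", net$source),
    sprintf("# scale: %s", net$scale),
    sprintf("# seed: %s", net$meta$seed %||% "NA"),
    sprintf("# config: %s", net$meta$config_hash %||% "NA")
  ), con)
  writeLines(paste(c("drug_id", net$ids), collapse = "\t"), con)
  for (i in seq_along(net$ids))
    writeLines(paste(c(net$ids[i], .fmt_num(net$matrix[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_field <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", m[[1]]))
  }
  source <- get_field("source"); scale <- get_field("scale")
  if (is.null(source)) stop_idsn("network file %s: missing 'source' header", path)
  if (is.null(scale)) stop_idsn("network file %s: missing 'scale' header", path)
  ids <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]][-1]
  n <- length(ids)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[[i + 1L]], "\t", fixed = TRUE)[[1]]
    m[i, ] <- as.numeric(parts[-1])
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-10)
    stop_idsn("network file %s: matrix asymmetric, max |Mij-Mji| = %g",
              path, asym)
  meta <- list()
  sd <- get_field("seed"); ch <- get_field("config")
  if (!is.null(sd) && sd != "NA") meta$seed <- as.integer(sd)
  if (!is.null(ch) && ch != "NA") meta$config_hash <- ch
  similarity_network((m + t(m)) / 2, ids = ids, source = source,
                     scale = scale, meta = meta)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (unique gene/target ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop_idsn("malformed GMT line (need name, description, >=1 gene): %s",
                substr(ln, 1, 60))
    sets[[parts[[1]]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Write cluster labels as TSV
#'
#' @param result A `clustering_result` from [spectral_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(result, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# idsn-labels v1",
               sprintf("# k: %d", result$k),
               sprintf("# seed: %s", result$seed %||% "NA")), con)
  writeLines("drug_id\tcluster", con)
  for (id in names(result$labels))
    writeLines(paste(id, result$labels[[id]], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_labels
#' @param path Path to a labels TSV written by [write_labels()].
#' @return `read_labels`: named integer vector drug_id -> cluster.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", colClasses = c("character",
                                                             "integer"))
  stats::setNames(df$cluster, df$drug_id)
}
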
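# Chemical structure vectorisation: hashed circular substructure
# fingerprints over a molecular graph parsed from SMILES, plus the two
# vector-space similarity metrics used on them.

# --- minimal SMILES reader ---------------------------------------------------
# Supports the organic subset (B C N O P S F Cl Br I), aromatic lowercase
# forms, bracket atoms [..], bonds - = # : /\\ (slashes treated as single),
# branches (), and ring closures 1-9 and %nn. This is deliberately a graph
# reader, not a chemistry engine: no valence or implicit-hydrogen model. It
# is sufficient to derive deterministic topological circular substructures.
.parse_smiles <- function(smiles, drug_id = "?") {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)
  elems <- character(0); arom <- logical(0)
  bonds <- list()          # list of c(i, j, order)
  stack <- integer(0)      # branch stack
  prev <- 0L               # previous atom index, 0 = none
  ring <- list()           # ring-closure digit -> c(atom, order)
  pend_bond <- 1           # bond order to apply to next attachment
  add_atom <- function(el, ar) {
    elems[[length(elems) + 1L]] <<- el
    arom[[length(arom) + 1L]] <<- ar
    idx <- length(elems)
    if (prev > 0L)
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, pend_bond)
    pend_bond <<- 1
    prev <<- idx
    idx
  }
  i <- 1L
  while (i <= n_ch) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i
      while (j <= n_ch && chars[[j]] != "]") j <- j + 1L
      if (j > n_ch)
        stop_idsn("unparseable SMILES for drug %s: unclosed '[' at position %d",
                  drug_id, i)
      token <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      core <- gsub("[0-9@+H-]", "", token)   # strip isotope/chirality/charge/H
      if (!nzchar(core))
        stop_idsn("unparseable SMILES for drug %s: empty bracket atom '[%s]'",
                  drug_id, token)
      ar <- core == tolower(core) && nchar(core) <= 2
      add_atom(toupper(core), ar && core %in% c("b","c","n","o","p","s","se","as"))
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      # two-letter organic-subset elements
      two <- if (i < n_ch) paste0(ch, chars[[i + 1L]]) else ""
      if (two %in% c("Cl", "Br")) { add_atom(two, FALSE); i <- i + 2L }
      else { add_atom(ch, FALSE); i <- i + 1L }
    } else if (ch %in% c("c", "b", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop_idsn("unparseable SMILES for drug %s: unmatched ')' at %d",
                  drug_id, i)
      prev <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-" || ch == "/" || ch == "\\") {
      pend_bond <- 1; i <- i + 1L
    } else if (ch == "=") {
      pend_bond <- 2; i <- i + 1L
    } else if (ch == "#") {
      pend_bond <- 3; i <- i + 1L
    } else if (ch == ":") {
      pend_bond <- 1.5; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n_ch)
          stop_idsn("unparseable SMILES for drug %s: truncated %% ring id",
                    drug_id)
        key <- paste(chars[(i + 1L):(i + 2L)], collapse = ""); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (prev == 0L)
        stop_idsn("unparseable SMILES for drug %s: ring closure before any atom",
                  drug_id)
      if (is.null(ring[[key]])) {
        ring[[key]] <- c(prev, pend_bond); pend_bond <- 1
      } else {
        bonds[[length(bonds) + 1L]] <- c(ring[[key]][[1]], prev,
                                         max(ring[[key]][[2]], pend_bond))
        ring[[key]] <- NULL; pend_bond <- 1
      }
    } else if (ch == ".") {
      prev <- 0L; i <- i + 1L
    } else {
      stop_idsn("unparseable SMILES for drug %s: unexpected character '%s' at position %d",
                drug_id, ch, i)
    }
  }
  if (length(elems) == 0L)
    stop_idsn("unparseable SMILES for drug %s: no atoms", drug_id)
  if (length(ring))
    stop_idsn("unparseable SMILES for drug %s: unclosed ring closure(s)", drug_id)
  if (length(stack))
    stop_idsn("unparseable SMILES for drug %s: unclosed branch '('", drug_id)
  list(elements = elems, aromatic = arom, bonds = bonds)
}

# Hash an integer vector into [0, mod) deterministically.
.vec_hash <- function(v, mod = 67108859) {
  h <- 0
  for (x in v) h <- (h * 131 + (x %% mod)) %% mod
  h
}

# --- circular fingerprint ----------------------------------------------------

#' Structural fingerprint of a drug
#'
#' Vectorises a chemical structure into a fixed-length binary vector. Two
#' input forms are accepted: a bitstring of exactly `L` characters over 0/1
#' (passed through unchanged, for cohorts that ship precomputed
#' fingerprints), or a SMILES string, which is converted to hashed circular
#' substructures: every atom-centred neighbourhood of radius 0..`r` is
#' canonically hashed and sets one bit in a length-`L` vector (an ECFP-style
#' construction; radius 2, L = 2048 are the field defaults).
#'
#' @param structure SMILES string or 0/1 bitstring of length `L`.
#' @param L Fingerprint length (positive integer).
#' @param r Circular substructure radius (non-negative integer).
#' @param drug_id Optional id used in error messages.
#' @return A `fingerprint`: list with `bits` (integer 0/1 vector of length
#'   `L`), `L`, `r`.
#' @export
structural_fingerprint <- function(structure, L = 2048L, r = 2L,
                                   drug_id = "?") {
  .assert_count(L, "L")
  if (r < 0 || r != floor(r)) stop_idsn("'r' must be a non-negative integer")
  if (grepl("^[01]+$", structure)) {
    if (nchar(structure) != L)
      stop_idsn("drug %s: bitstring length %d != fingerprint length L = %d",
                drug_id, nchar(structure), L)
    bits <- as.integer(strsplit(structure, "", fixed = TRUE)[[1]])
  } else {
    mol <- .parse_smiles(structure, drug_id)
    n <- length(mol$elements)
    adj <- vector("list", n)
    bond_ord <- vector("list", n)
    for (b in mol$bonds) {
      adj[[b[[1]]]] <- c(adj[[b[[1]]]], b[[2]])
      adj[[b[[2]]]] <- c(adj[[b[[2]]]], b[[1]])
      bond_ord[[b[[1]]]] <- c(bond_ord[[b[[1]]]], b[[3]])
      bond_ord[[b[[2]]]] <- c(bond_ord[[b[[2]]]], b[[3]])
    }
    # initial invariants: element, aromaticity, degree
    inv <- vapply(seq_len(n), function(i)
      .vec_hash(c(utf8ToInt(mol$elements[[i]]), as.integer(mol$aromatic[[i]]),
                  length(adj[[i]]))), numeric(1))
    feats <- inv
    if (r >= 1) for (round in seq_len(r)) {
      inv_new <- vapply(seq_len(n), function(i) {
        if (length(adj[[i]]) == 0L) return(.vec_hash(c(round, inv[[i]])))
        nb <- order(inv[adj[[i]]] * 10 + bond_ord[[i]])
        .vec_hash(c(round, inv[[i]],
                    as.vector(rbind(bond_ord[[i]][nb] * 2,
                                    inv[adj[[i]]][nb]))))
      }, numeric(1))
      inv <- inv_new
      feats <- c(feats, inv)
    }
    bits <- integer(L)
    bits[(unique(feats) %% L) + 1L] <- 1L
  }
  if (sum(bits) == 0L)
    stop_idsn("drug %s: fingerprint has no set bits", drug_id)
  fp <- list(bits = bits, L = as.integer(L), r = as.integer(r))
  class(fp) <- "fingerprint"   # avoid base::structure(): arg shadows it
  fp
}

#' Fingerprint every drug in a cohort
#'
#' @param profiles A `drug_cohort`.
#' @param L,r Fingerprint length and radius, see [structural_fingerprint()].
#' @return The cohort with `$fingerprint` filled on every profile.
#' @export
fingerprint_cohort <- function(profiles, L = 2048L, r = 2L) {
  for (id in names(profiles))
    profiles[[id]]$fingerprint <-
      structural_fingerprint(profiles[[id]]$structure, L = L, r = r,
                             drug_id = id)
  profiles
}

# --- metrics -----------------------------------------------------------------

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (||u|| * ||v||)`; for binary fingerprints the value lies in
#' \[0, 1\]. This is the vector-space-model similarity used for the chem-DSN.
#'
#' @param u,v Numeric vectors of equal length, each with at least one
#'   non-zero entry.
#' @param name_u,name_v Optional names for error messages.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(u, v, name_u = "u", name_v = "v") {
  if (length(u) != length(v)) stop_idsn("cosine: length mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0) stop_idsn("cosine: zero vector for %s", name_u)
  if (nv == 0) stop_idsn("cosine: zero vector for %s", name_v)
  sum(u * v) / (nu * nv)
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits. Alternative chem metric, selectable
#' in the pipeline configuration.
#'
#' @param a,b `fingerprint` objects (or 0/1 vectors) of equal length.
#' @return Tanimoto similarity in \[0, 1\].
#' @export
tanimoto_similarity <- function(a, b) {
  ba <- if (inherits(a, "fingerprint")) a$bits else a
  bb <- if (inherits(b, "fingerprint")) b$bits else b
  if (length(ba) != length(bb)) stop_idsn("tanimoto: fingerprint length mismatch")
  inter <- sum(ba & bb); uni <- sum(ba | bb)
  if (uni == 0) stop_idsn("tanimoto: both fingerprints empty")
  inter / uni
}
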
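## chemio: molecule parsing, fingerprints, similarity, diversity,
## clustering, substructure filtering and delimited-text I/O.

#' Morgan fingerprints for a vector of SMILES
#'
#' Circular substructure (Morgan/ECFP-like) fingerprints, radius 2 and
#' 1024 bits by default, no chirality, no counts.  Hashing follows RDKit's
#' default and is pinned by the packaged fixture
#' `extdata/fingerprint_pins.tsv` so cross-version drift is caught by the
#' test suite.
#'
#' @param smiles character vector of SMILES.
#' @param radius Morgan radius (default 2).
#' @param nbits fingerprint length (default 1024).
#' @param strict error on unparsable SMILES (default TRUE); otherwise the
#'   offending rows are dropped with a warning.
#' @return 0/1 integer matrix with one row per (valid) SMILES; rownames
#'   are the input SMILES.
#' @examples \dontrun{morganFingerprints(c("CCO", "c1ccccc1"))}
#' @export
morganFingerprints <- function(smiles, radius = 2L, nbits = 1024L,
                               strict = TRUE) {
  recs <- chem_process(smiles, radius = radius, nbits = nbits)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) {
    bad <- smiles[!ok]
    if (strict)
      stopf("unparsable SMILES: %s", paste(head(bad, 5), collapse = ", "))
    warning(sprintf("dropping %d unparsable SMILES", length(bad)))
  }
  fp <- matrix(0L, nrow = sum(ok), ncol = nbits)
  rownames(fp) <- smiles[ok]
  kept <- which(ok)
  for (i in seq_along(kept))
    fp[i, recs[[kept[i]]]$bits] <- 1L
  fp
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`.  By convention a pair of all-zero
#' (featureless) fingerprints has similarity 1.0.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("fingerprint length mismatch")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1.0)
  inter / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param A 0/1 matrix, one fingerprint per row.
#' @param B optional second matrix (defaults to `A`).
#' @return `nrow(A)` x `nrow(B)` similarity matrix.
#' @export
tanimotoMatrix <- function(A, B = A) {
  if (ncol(A) != ncol(B)) stopf("fingerprint length mismatch")
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  inter <- A %*% t(B)
  pa <- rowSums(A)
  pb <- rowSums(B)
  uni <- outer(pa, pb, "+") - inter
  s <- ifelse(uni == 0, 1.0, inter / pmax(uni, .Machine$double.eps))
  s
}

#' Set diversity: one minus the mean pairwise Tanimoto similarity
#'
#' For large sets the mean is estimated over `pair_cap` uniformly sampled
#' unordered pairs (seeded); with `pair_cap` at least the number of pairs
#' the exhaustive mean is used.
#'
#' @param fps 0/1 fingerprint matrix (>= 2 rows).
#' @param pair_cap maximum number of pairs to average over (default 50000).
#' @param seed RNG seed for pair sampling.
#' @return diversity D in `[0, 1]`.
#' @export
setDiversity <- function(fps, pair_cap = 50000L, seed = 1L) {
  n <- nrow(fps)
  if (is.null(n) || n < 2) stopf("set diversity needs at least 2 fingerprints")
  npairs <- n * (n - 1) / 2
  if (npairs <= pair_cap) {
    S <- tanimotoMatrix(fps)
    return(1 - mean(S[upper.tri(S)]))
  }
  with_seed(child_seed(seed, "setDiversity"), {
    i <- sample.int(n, pair_cap, replace = TRUE)
    j <- sample.int(n - 1L, pair_cap, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered distinct pairs
    sims <- vapply(seq_len(pair_cap),
                   function(k) tanimoto(fps[i[k], ], fps[j[k], ]),
                   numeric(1))
    1 - mean(sims)
  })
}

#' Diversity of a candidate against a set
#'
#' One minus the average Tanimoto similarity between the candidate and
#' each of the other candidates; used as a GA objective.
#'
#' @param fp candidate fingerprint (0/1 vector).
#' @param others 0/1 matrix of the other candidates (>= 1 row).
#' @return value in `[0, 1]`.
#' @export
candidateDiversity <- function(fp, others) {
  if (is.null(nrow(others)) || nrow(others) < 1)
    stopf("candidateDiversity needs a nonempty comparison set")
  sims <- tanimotoMatrix(matrix(fp, nrow = 1), others)
  1 - mean(sims)
}

#' k-medoids clustering of fingerprints under Tanimoto distance
#'
#' Partitioning around medoids (via \pkg{cluster}::\code{pam}) on the
#' `1 - Tanimoto` distance.  PAM's build + swap phases are deterministic,
#' so the result does not depend on `seed`; the argument is kept for
#' interface stability.
#'
#' @param fps 0/1 fingerprint matrix.
#' @param k number of clusters (`k <= nrow(fps)`).
#' @param seed unused; retained for call-site compatibility.
#' @return list with `labels` (1-based cluster index per row) and
#'   `medoids` (row indices of the medoid of each cluster).
#' @export
clusterKmedoids <- function(fps, k, seed = 1L) {
  n <- nrow(fps)
  if (k > n) stopf("k = %d exceeds number of fingerprints (%d)", k, n)
  if (k == n) return(list(labels = seq_len(n), medoids = seq_len(n)))
  D <- 1 - tanimotoMatrix(fps)
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                      keep.diss = FALSE, keep.data = FALSE)
  list(labels = as.integer(fit$clustering),
       medoids = as.integer(fit$id.med))
}

#' Load a named SMARTS pattern catalog
#'
#' Tab-separated file with columns `name<TAB>smarts`; lines starting with
#' `#` are ignored.  Patterns are validated at load time.
#'
#' @param path file path.
#' @return named character vector of SMARTS.
#' @export
loadSmartsCatalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stopf("malformed SMARTS catalog line")
  pat <- vapply(parts, `[`, character(1), 2)
  names(pat) <- vapply(parts, `[`, character(1), 1)
  ok <- chem_validate_smarts(pat)
  if (!all(ok))
    stopf("invalid SMARTS in catalog: %s", paste(names(pat)[!ok], collapse = ", "))
  pat
}

#' The packaged default substructure filter catalog
#'
#' A curated set of PAINS-type frequent-hitter patterns, common reactive
#' groups that an automated liquid-handling platform cannot test safely,
#' and the hydroxamate moiety (`-C(=O)N-O`) that dominates known HDAC
#' inhibitors and is deliberately excluded from generation.
#'
#' @return named character vector of SMARTS patterns.
#' @export
defaultFilterCatalog <- function() {
  loadSmartsCatalog(system.file("extdata", "filters_default.smarts",
                                package = "mfbo", mustWork = TRUE))
}

#' Filter molecules by substructure patterns
#'
#' Substructure (not exact) matching of each molecule against a named
#' SMARTS catalog.  Returns a partition of the input into kept and
#' removed molecules, the latter annotated with the first matching
#' pattern name.
#'
#' @param ids molecule identifiers.
#' @param smiles SMILES parallel to `ids`.
#' @param patterns named character vector of SMARTS (default: the
#'   packaged catalog, see [defaultFilterCatalog()]).
#' @return list with `kept` (character ids) and `removed`
#'   (data.frame id, pattern).
#' @export
filterSubstructures <- function(ids, smiles,
                                patterns = defaultFilterCatalog()) {
  stopifnot(length(ids) == length(smiles))
  if (!length(ids))
    return(list(kept = character(0),
                removed = data.frame(id = character(0),
                                     pattern = character(0),
                                     stringsAsFactors = FALSE)))
  hits <- chem_match(smiles, unname(patterns))
  first <- apply(hits, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  removed_idx <- which(!is.na(first))
  list(kept = ids[is.na(first)],
       removed = data.frame(id = ids[removed_idx],
                            pattern = names(patterns)[first[removed_idx]],
                            stringsAsFactors = FALSE))
}

## ---- library file I/O ---------------------------------------------------

#' Parse a molecular library from delimited text
#'
#' Reads a comma- or tab-separated file with a header, one molecule per
#' row.  SMILES are canonicalized and fingerprinted; assay columns are
#' converted to canonical orientation (higher = better).
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (".csv" = comma, otherwise tab) unless `sep` is given.
#' @param columns named list mapping roles to column names:
#'   `id`, `smiles`, `low`, `medium`, `high` (low/medium/high optional).
#' @param low_higher_better is the low-fidelity column already oriented
#'   higher-is-better?  Default FALSE (docking-like scores are negated).
#' @param high_format "pic50" (default), "ic50_nM" or "ic50_M"; IC50s are
#'   converted to pIC50.
#' @param strict error on unparsable SMILES (default FALSE: drop row with
#'   a warning).
#' @param sep optional field separator override.
#' @param fpRadius,fpBits fingerprint parameters.
#' @return a [LibraryDataset-class].
#' @export
parseLibrary <- function(path,
                         columns = list(id = "id", smiles = "smiles",
                                        low = "low", medium = "medium",
                                        high = "high"),
                         low_higher_better = FALSE,
                         high_format = c("pic50", "ic50_nM", "ic50_M"),
                         strict = FALSE, sep = NULL,
                         fpRadius = 2L, fpBits = 1024L) {
  if (!file.exists(path)) stopf("library file not found: %s", path)
  high_format <- match.arg(high_format)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!columns$smiles %in% names(df))
    stopf("SMILES column '%s' not found in %s", columns$smiles, path)
  n <- nrow(df)
  if (n == 0)
    return(makeLibraryDataset(character(0), character(0),
                              matrix(0L, 0, fpBits), numeric(0), numeric(0),
                              numeric(0), provenance = "file",
                              fpRadius = fpRadius, fpBits = fpBits))
  ids <- if (!is.null(columns$id) && columns$id %in% names(df))
    as.character(df[[columns$id]]) else sprintf("mol%05d", seq_len(n))
  if (anyDuplicated(ids))
    stopf("duplicate molecule ids in %s", path)
  smiles <- as.character(df[[columns$smiles]])
  recs <- chem_process(smiles)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) {
    if (strict)
      stopf("unparsable SMILES at row(s) %s of %s",
            paste(head(which(!ok), 5), collapse = ", "), path)
    warning(sprintf("dropping %d row(s) with unparsable SMILES", sum(!ok)))
  }
  keep <- which(ok)
  getcol <- function(role, default = NA_real_) {
    cn <- columns[[role]]
    if (!is.null(cn) && cn %in% names(df)) as.numeric(df[[cn]])[keep]
    else rep(default, length(keep))
  }
  low <- getcol("low")
  if (!low_higher_better) low <- -low
  medium <- getcol("medium")
  high <- getcol("high")
  high <- switch(high_format,
                 pic50 = high,
                 ic50_nM = -log10(high * 1e-9),
                 ic50_M = -log10(high))
  fp <- matrix(0L, nrow = length(keep), ncol = fpBits)
  for (i in seq_along(keep)) fp[i, recs[[keep[i]]]$bits] <- 1L
  makeLibraryDataset(ids[keep],
                     vapply(recs[keep], `[[`, character(1), "canonical"),
                     fp, low, medium, high, provenance = "file",
                     fpRadius = fpRadius, fpBits = fpBits)
}

makeLibraryDataset <- function(ids, smiles, fp, low, medium, high,
                               decoy = rep(FALSE, length(ids)),
                               provenance = "file",
                               fpRadius = 2L, fpBits = 1024L) {
  dimnames(fp) <- NULL
  new("LibraryDataset", ids = ids, smiles = smiles, fingerprints = fp,
      low = as.numeric(low), medium = as.numeric(medium),
      high = as.numeric(high), decoy = decoy, provenance = provenance,
      fpRadius = as.integer(fpRadius), fpBits = as.integer(fpBits))
}

#' Write a LibraryDataset to delimited text
#'
#' The inverse of [parseLibrary()]: the low column is written in
#' docking-like orientation (negated back) and the high column as pIC50,
#' so `parseLibrary(writeLibrary(x))` round-trips.
#'
#' @param x a [LibraryDataset-class].
#' @param path output path (".csv" = comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = x@ids, smiles = x@smiles, low = -x@low,
                   medium = x@medium, high = x@high, decoy = x@decoy,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
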
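## Bridge to the bundled RDKit helper (inst/python/chemtool.py).
##
## All chemistry primitives -- SMILES parsing, Morgan fingerprints, SMARTS
## substructure matching, molecular weight/QED, reaction-template
## application -- go through one batched subprocess call.  Results for
## (smiles, radius, nbits) fingerprints are memoised per session.

.bridge_env <- new.env(parent = emptyenv())

chem_python <- function() {
  cached <- .bridge_env$python
  if (!is.null(cached)) return(cached)
  cand <- Sys.getenv("MFBO_PYTHON", "")
  cand <- c(cand, Sys.which("python"), Sys.which("python3"))
  cand <- cand[nzchar(cand)]
  for (p in cand) {
    ok <- tryCatch(
      system2(p, c("-c", shQuote("import rdkit")),
              stdout = FALSE, stderr = FALSE) == 0,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (isTRUE(ok)) {
      .bridge_env$python <- p
      return(p)
    }
  }
  stopf("no python interpreter with rdkit found (looked at: %s); set MFBO_PYTHON",
        paste(cand, collapse = ", "))
}

chem_tool_path <- function() {
  p <- system.file("python", "chemtool.py", package = "mfbo")
  if (!nzchar(p)) p <- file.path("inst", "python", "chemtool.py")
  if (!file.exists(p)) stopf("chemtool.py helper not found")
  p
}

chem_call <- function(request) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(chem_python(), c(shQuote(chem_tool_path()),
                                     shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile))
    stopf("chemistry helper failed (exit status %s)", status)
  reply <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  if (!is.null(reply$error)) stopf("chemistry helper error: %s", reply$error)
  reply
}

## Batched molecule processing with per-session memoisation.
## Returns a list parallel to `smiles` with elements
## list(ok, canonical, bits (integer, 1-based), mw, qed).
chem_process <- function(smiles, radius = 2L, nbits = 1024L,
                         want = c("fp", "mw", "qed")) {
  key <- function(s) paste0(radius, "|", nbits, "|", s)
  cache <- .bridge_env$cache %||% new.env(parent = emptyenv())
  .bridge_env$cache <- cache
  res <- vector("list", length(smiles))
  missing_idx <- integer(0)
  for (i in seq_along(smiles)) {
    hit <- cache[[key(smiles[i])]]
    if (is.null(hit)) missing_idx <- c(missing_idx, i) else res[[i]] <- hit
  }
  if (length(missing_idx)) {
    uniq <- unique(smiles[missing_idx])
    reply <- chem_call(list(op = "process", smiles = as.list(unname(uniq)),
                            radius = radius, nbits = nbits,
                            want = as.list(c("fp", "mw", "qed"))))
    recs <- reply$records
    for (j in seq_along(uniq)) {
      r <- recs[[j]]
      rec <- if (isTRUE(r$ok)) {
        list(ok = TRUE, canonical = r$canonical,
             bits = sort(as.integer(unlist(r$bits))) + 1L,
             mw = as.numeric(r$mw %||% NA_real_),
             qed = as.numeric(r$qed %||% NA_real_))
      } else list(ok = FALSE, canonical = NA_character_,
                  bits = integer(0), mw = NA_real_, qed = NA_real_)
      cache[[key(uniq[j])]] <- rec
    }
    for (i in missing_idx) res[[i]] <- cache[[key(smiles[i])]]
  }
  res
}

chem_match <- function(smiles, smarts) {
  if (!length(smiles) || !length(smarts))
    return(matrix(FALSE, length(smiles), length(smarts)))
  reply <- chem_call(list(op = "match", smiles = as.list(unname(smiles)),
                          smarts = as.list(unname(smarts))))
  if (!all(unlist(reply$ok_smarts)))
    stopf("invalid SMARTS pattern(s): %s",
          paste(smarts[!unlist(reply$ok_smarts)], collapse = ", "))
  hits <- do.call(rbind, lapply(reply$hits, function(r) as.integer(unlist(r))))
  matrix(hits == 1L, nrow = length(smiles), ncol = length(smarts))
}

chem_react <- function(jobs) {
  reply <- chem_call(list(op = "react", jobs = lapply(jobs, function(j)
    list(smarts = j$smarts, reactants = as.list(j$reactants)))))
  reply$results
}

chem_validate_smarts <- function(smarts) {
  if (!length(smarts)) return(logical(0))
  unlist(chem_call(list(op = "validate_smarts",
                        smarts = as.list(unname(smarts))))$ok)
}
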
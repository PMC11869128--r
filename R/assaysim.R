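## assaysim: Hill-equation conversion between IC50 and single-point
## percent inhibition, the retrospective measurement oracle, and decoy
## injection.

#' Hill-equation percent inhibition from an IC50
#'
#' Noncooperative (Hill coefficient 1) by default:
#' `inhibition = 100 / (1 + (IC50 / conc)^hill)`.  At `conc = IC50` the
#' inhibition is exactly 50%.
#'
#' @param ic50 IC50 in molar (> 0); vectorized.
#' @param conc ligand concentration in molar (> 0).
#' @param hill Hill coefficient (> 0, default 1).
#' @return percent inhibition in (0, 100).
#' @export
hillInhibition <- function(ic50, conc, hill = 1) {
  if (any(ic50 <= 0) || any(conc <= 0) || any(hill <= 0))
    stopf("ic50, conc and hill must all be positive")
  100 / (1 + (ic50 / conc)^hill)
}

#' Invert a single-point percent inhibition to an IC50
#'
#' Exact inverse of [hillInhibition()]:
#' `IC50 = conc * (100/percent - 1)^(1/hill)`.
#'
#' @param percent percent inhibition, strictly inside (0, 100).
#' @param conc ligand concentration in molar.
#' @param hill Hill coefficient.
#' @return IC50 in molar.
#' @export
ic50FromInhibition <- function(percent, conc, hill = 1) {
  if (any(percent <= 0) || any(percent >= 100))
    stopf("percent inhibition must lie strictly inside (0, 100)")
  if (any(conc <= 0) || any(hill <= 0)) stopf("conc and hill must be positive")
  conc * (100 / percent - 1)^(1 / hill)
}

#' Build a retrospective assay oracle for a dataset
#'
#' The oracle answers (molecule, fidelity) queries from the dataset's
#' ground truth: level 1 returns the stored (canonical) docking-like
#' score plus Gaussian noise, level 2 the Hill-equation percent
#' inhibition of the molecule's IC50 at the screen concentration plus
#' Gaussian noise truncated to [0, 100], level 3 the pIC50 plus Gaussian
#' noise.  Every (id, fidelity) pair draws its noise from its own hashed
#' substream, so repeated queries return identical values and results do
#' not depend on query order.
#'
#' @param dataset a [LibraryDataset-class] with low and high ground truth.
#' @param screen_conc screen concentration in molar for the single-point
#'   assay (default 2e-5, i.e. a 20 uM screen).
#' @param noise list with per-fidelity noise SDs: `low` (canonical score
#'   units; default 10% of the low-score range), `medium` (percentage
#'   points, default 5), `high` (pIC50 units, default 0.1).
#' @param hill Hill coefficient (default 1, noncooperative).
#' @param seed base seed for the noise substreams.
#' @return an [AssayOracle-class].
#' @export
makeOracle <- function(dataset, screen_conc = 2e-5,
                       noise = list(low = NULL, medium = 5, high = 0.1),
                       hill = 1, seed = 1L) {
  noise <- modifyList(list(low = NULL, medium = 5, high = 0.1), noise)
  if (is.null(noise$low)) {
    rng <- diff(range(dataset@low))
    noise$low <- 0.1 * if (rng > 0) rng else 1
  }
  new("AssayOracle", ids = dataset@ids, truthLow = dataset@low,
      truthHigh = dataset@high, screenConc = screen_conc,
      hill = as.numeric(hill),
      noiseSD = as.numeric(c(noise$low, noise$medium, noise$high)),
      seed = as.integer(seed), memo = new.env(parent = emptyenv()))
}

#' Query the oracle at (molecule, fidelity) pairs
#'
#' @param oracle an [AssayOracle-class].
#' @param ids molecule identifiers.
#' @param fidelities 1-based fidelity level indices (1 = low, 2 = medium,
#'   3 = high), recycled against `ids`.
#' @return numeric measurement vector in canonical orientation.
#' @export
queryOracle <- function(oracle, ids, fidelities) {
  k <- max(length(ids), length(fidelities))
  ids <- rep_len(ids, k); fidelities <- rep_len(fidelities, k)
  idx <- match(ids, oracle@ids)
  if (anyNA(idx))
    stopf("unknown molecule(s): %s",
          paste(head(ids[is.na(idx)], 3), collapse = ", "))
  vapply(seq_len(k), function(j) {
    key <- paste0(ids[j], "|", fidelities[j])
    hit <- oracle@memo[[key]]
    if (!is.null(hit)) return(hit)
    f <- fidelities[j]; i <- idx[j]
    noise <- with_seed(hash32(oracle@seed, ids[j], f), rnorm(1))
    val <- if (f == 1) {
      oracle@truthLow[i] + oracle@noiseSD[1] * noise
    } else if (f == 2) {
      ic50 <- 10^(-oracle@truthHigh[i])
      v <- hillInhibition(ic50, oracle@screenConc, oracle@hill) +
        oracle@noiseSD[2] * noise
      min(100, max(0, v))
    } else if (f == 3) {
      oracle@truthHigh[i] + oracle@noiseSD[3] * noise
    } else stopf("fidelity index must be 1, 2 or 3")
    oracle@memo[[key]] <- val
    val
  }, numeric(1))
}

#' Inject decoy molecules into a dataset
#'
#' Adds presumed-inactive decoys so that they make up `fraction` of the
#' final library.  Decoys receive plausible docking-like scores (sampled
#' with replacement from the actives' low-fidelity distribution -- a
#' docking score is still calculated for a decoy) and negligible activity
#' (pIC50 fixed at the inactive sentinel, 3.0 = 1 mM by default), so they
#' never enter the top-N% label set.
#'
#' @param dataset a [LibraryDataset-class] of actives.
#' @param decoySmiles character vector of candidate decoy SMILES.
#' @param fraction decoy fraction of the final library, in [0, 1).
#' @param seed RNG seed.
#' @param sentinel inactive pIC50 sentinel (default 3.0).
#' @return a [LibraryDataset-class] with decoys appended and flagged.
#' @export
injectDecoys <- function(dataset, decoySmiles, fraction, seed = 1L,
                         sentinel = 3.0) {
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  if (fraction == 0) return(dataset)
  n_act <- nMolecules(dataset)
  n_dec <- round(fraction * n_act / (1 - fraction))
  recs <- chem_process(decoySmiles)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  canon <- vapply(recs, function(r)
    if (isTRUE(r$ok)) r$canonical else NA_character_, character(1))
  keep <- which(ok & !duplicated(canon) & !(canon %in% dataset@smiles))
  if (length(keep) < n_dec)
    stopf("need %d decoys but only %d valid unique decoy SMILES supplied",
          n_dec, length(keep))
  pick <- with_seed(child_seed(seed, "injectDecoys"),
                    sample(keep, n_dec))
  fp <- matrix(0L, n_dec, dataset@fpBits)
  for (i in seq_len(n_dec)) fp[i, recs[[pick[i]]]$bits] <- 1L
  low_dec <- with_seed(child_seed(seed, "decoyLow"),
                       sample(dataset@low, n_dec, replace = TRUE))
  makeLibraryDataset(
    ids = c(dataset@ids, sprintf("decoy%04d", seq_len(n_dec))),
    smiles = c(dataset@smiles, canon[pick]),
    fp = rbind(dataset@fingerprints, fp),
    low = c(dataset@low, low_dec),
    medium = c(dataset@medium, rep(NA_real_, n_dec)),
    high = c(dataset@high, rep(sentinel, n_dec)),
    decoy = c(dataset@decoy, rep(TRUE, n_dec)),
    provenance = dataset@provenance,
    fpRadius = dataset@fpRadius, fpBits = dataset@fpBits)
}
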
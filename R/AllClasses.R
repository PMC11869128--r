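## Core S4 containers.
##
## Values held in a LibraryDataset are always in canonical orientation:
## higher = better for every fidelity (docking-like scores are negated at
## parse time, IC50s are converted to pIC50).  File readers/writers handle
## the assay-native orientations.

#' FidelitySchedule: named experiment tiers, relative costs and a budget
#'
#' Describes the tiers of experiments available in a campaign, ordered from
#' lowest to highest fidelity.  Costs are dimensionless relative costs with
#' the highest fidelity normalized to 1.0 (e.g. docking 0.01, single-point
#' inhibition 0.2, dose-response 1.0); `budget` is the per-iteration
#' spending allowance in the same units.
#'
#' @slot levels character vector of fidelity names, lowest first.
#' @slot costs numeric vector of strictly increasing relative costs, last
#'   element 1.0.
#' @slot budget positive per-iteration budget.
#' @export
setClass("FidelitySchedule",
  representation(levels = "character", costs = "numeric", budget = "numeric"))

setValidity("FidelitySchedule", function(object) {
  msg <- character(0)
  if (length(object@levels) != length(object@costs))
    msg <- c(msg, "levels and costs must have equal length")
  if (length(object@costs) >= 1) {
    if (any(diff(object@costs) <= 0))
      msg <- c(msg, "costs must be strictly increasing with fidelity")
    if (abs(object@costs[length(object@costs)] - 1) > 1e-12)
      msg <- c(msg, "highest-fidelity cost must be normalized to 1.0")
    if (any(object@costs <= 0)) msg <- c(msg, "costs must be positive")
  }
  if (length(object@budget) != 1 || !is.finite(object@budget) ||
      object@budget < 0)
    msg <- c(msg, "budget must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Construct a FidelitySchedule
#'
#' @param levels fidelity names, lowest first.
#' @param costs strictly increasing relative costs; highest must be 1.0.
#' @param budget per-iteration budget (same units as costs).
#' @return A [FidelitySchedule-class] object.
#' @examples
#' fidelitySchedule()  # docking / single-point / dose-response at 0.01/0.2/1
#' @export
fidelitySchedule <- function(levels = c("low", "medium", "high"),
                             costs = c(0.01, 0.2, 1.0),
                             budget = 10.0) {
  new("FidelitySchedule", levels = levels, costs = as.numeric(costs),
      budget = as.numeric(budget))
}

#' LibraryDataset: a discrete molecular search space with ground truth
#'
#' Molecules (id, SMILES, Morgan fingerprint) plus per-fidelity ground
#' truth in canonical orientation (higher = better): `low` is a
#' docking-like score after negation, `medium` an optional percent
#' inhibition, `high` a pIC50.  `decoy` flags molecules injected as
#' presumed inactives.
#'
#' @slot ids unique molecule identifiers.
#' @slot smiles canonical SMILES, parallel to ids.
#' @slot fingerprints 0/1 integer matrix, one row per molecule.
#' @slot low,medium,high numeric ground-truth vectors (canonical
#'   orientation); `medium` may be all-NA (derived on demand).
#' @slot decoy logical flag per molecule.
#' @slot provenance "file", "synthetic" or "subset".
#' @slot fpRadius,fpBits fingerprint parameters.
#' @export
setClass("LibraryDataset",
  representation(ids = "character", smiles = "character",
                 fingerprints = "matrix",
                 low = "numeric", medium = "numeric", high = "numeric",
                 decoy = "logical", provenance = "character",
                 fpRadius = "integer", fpBits = "integer"))

setValidity("LibraryDataset", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (anyDuplicated(object@ids)) msg <- c(msg, "molecule ids must be unique")
  if (length(object@smiles) != n) msg <- c(msg, "smiles length mismatch")
  if (nrow(object@fingerprints) != n)
    msg <- c(msg, "fingerprint rows must match molecule count")
  for (s in c("low", "medium", "high"))
    if (length(slot(object, s)) != n) msg <- c(msg, paste(s, "length mismatch"))
  if (length(object@decoy) != n) msg <- c(msg, "decoy length mismatch")
  if (n && any(!is.finite(object@low))) msg <- c(msg, "low values must be finite")
  if (n && any(!is.finite(object@high))) msg <- c(msg, "high values must be finite")
  if (length(msg)) msg else TRUE
})

#' BatchPlan: the molecule-fidelity pairs selected for one iteration
#'
#' @slot pairs data.frame with columns id, fidelity (1-based level index),
#'   score (acquisition value at selection time) and cost.
#' @slot totalCost total charged cost, never exceeding the budget.
#' @slot budget the budget the plan was selected under.
#' @slot seed RNG seed used for selection.
#' @export
setClass("BatchPlan",
  representation(pairs = "data.frame", totalCost = "numeric",
                 budget = "numeric", seed = "integer"))

setValidity("BatchPlan", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (!all(c("id", "fidelity", "score", "cost") %in% names(p)))
    msg <- c(msg, "pairs must have columns id, fidelity, score, cost")
  if (nrow(p) && anyDuplicated(paste(p$id, p$fidelity)))
    msg <- c(msg, "duplicate (molecule, fidelity) pair in plan")
  if (object@totalCost > object@budget + 1e-9)
    msg <- c(msg, "total cost exceeds budget")
  if (length(msg)) msg else TRUE
})

#' AssayOracle: retrospective measurement simulator
#'
#' Answers (molecule, fidelity) queries from stored ground truth.  Low
#' fidelity returns the stored docking-like score plus Gaussian noise;
#' medium returns the Hill-equation percent inhibition at the screen
#' concentration plus truncated Gaussian noise; high returns the pIC50
#' plus Gaussian noise.  Each (id, fidelity) pair has its own noise
#' substream, so answers are memoized and independent of query order.
#'
#' @slot ids molecule identifiers with ground truth.
#' @slot truthLow,truthHigh canonical low score and pIC50 per molecule.
#' @slot screenConc screen concentration in molar for the single-point assay.
#' @slot hill Hill coefficient (1 = noncooperative).
#' @slot noiseSD per-fidelity noise standard deviations (low units,
#'   percentage points, pIC50 units).
#' @slot seed base RNG seed.
#' @slot memo environment cache of answered queries.
#' @export
setClass("AssayOracle",
  representation(ids = "character", truthLow = "numeric",
                 truthHigh = "numeric", screenConc = "numeric",
                 hill = "numeric", noiseSD = "numeric", seed = "integer",
                 memo = "environment"))

setValidity("AssayOracle", function(object) {
  msg <- character(0)
  if (object@screenConc <= 0) msg <- c(msg, "screen concentration must be > 0")
  if (any(object@noiseSD < 0)) msg <- c(msg, "noise SDs must be >= 0")
  if (length(object@noiseSD) != 3) msg <- c(msg, "noiseSD must have length 3")
  if (length(msg)) msg else TRUE
})

#' RecoveryCurve: cumulative top-N% rediscovery for one strategy run
#'
#' @slot recovery per-iteration cumulative fraction of top-N% molecules
#'   found under the campaign's counting rule; nondecreasing, in [0, 1].
#' @slot strategy strategy name.
#' @slot seed seed of the run.
#' @slot spend iterations x fidelities matrix of charged cost.
#' @export
setClass("RecoveryCurve",
  representation(recovery = "numeric", strategy = "character",
                 seed = "integer", spend = "matrix"))

setValidity("RecoveryCurve", function(object) {
  msg <- character(0)
  r <- object@recovery
  if (length(r) && (any(r < -1e-12) || any(r > 1 + 1e-12)))
    msg <- c(msg, "recovery must lie in [0, 1]")
  if (length(r) > 1 && any(diff(r) < -1e-12))
    msg <- c(msg, "recovery must be nondecreasing")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "FidelitySchedule", function(object) {
  cat("FidelitySchedule with", length(object@levels), "levels\n")
  for (i in seq_along(object@levels))
    cat(sprintf("  %-12s cost %.3g\n", object@levels[i], object@costs[i]))
  cat("  per-iteration budget:", object@budget, "\n")
})

setMethod("show", "LibraryDataset", function(object) {
  cat(sprintf("LibraryDataset: %d molecules (%s), %d decoys\n",
              length(object@ids), object@provenance, sum(object@decoy)))
  cat(sprintf("  fingerprints: radius %d, %d bits\n",
              object@fpRadius, object@fpBits))
  cat(sprintf("  high (pIC50) range: [%.2f, %.2f]\n",
              min(object@high), max(object@high)))
})

setMethod("show", "BatchPlan", function(object) {
  cat(sprintf("BatchPlan: %d pairs, cost %.3f of budget %.3f (seed %d)\n",
              nrow(object@pairs), object@totalCost, object@budget,
              object@seed))
  if (nrow(object@pairs)) {
    tab <- table(factor(object@pairs$fidelity))
    cat("  pairs per fidelity level:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  }
})

setMethod("show", "AssayOracle", function(object) {
  cat(sprintf("AssayOracle over %d molecules; screen %.3g M, Hill %.2g\n",
              length(object@ids), object@screenConc, object@hill))
  cat(sprintf("  noise SDs (low/medium/high): %s\n",
              paste(signif(object@noiseSD, 3), collapse = "/")))
})

setMethod("show", "RecoveryCurve", function(object) {
  cat(sprintf("RecoveryCurve [%s, seed %d]: %s\n", object@strategy,
              object@seed,
              paste(sprintf("%.2f", object@recovery), collapse = " ")))
})

## ---- accessors ----------------------------------------------------------

#' @describeIn LibraryDataset-class number of molecules.
#' @param x,object a LibraryDataset.
#' @export
nMolecules <- function(x) length(x@ids)

#' Accessors for LibraryDataset
#'
#' `moleculeIds`, `moleculeSmiles` and `fingerprintMatrix` return the
#' identity columns; `assayValues` returns the canonical-orientation
#' ground-truth table; `isDecoy` the decoy flags.
#'
#' @param x a [LibraryDataset-class].
#' @return vectors/matrix/data.frame parallel to the molecules.
#' @export
moleculeIds <- function(x) x@ids

#' @rdname moleculeIds
#' @export
moleculeSmiles <- function(x) x@smiles

#' @rdname moleculeIds
#' @export
fingerprintMatrix <- function(x) x@fingerprints

#' @rdname moleculeIds
#' @export
assayValues <- function(x)
  data.frame(id = x@ids, low = x@low, medium = x@medium, high = x@high,
             decoy = x@decoy, stringsAsFactors = FALSE)

#' @rdname moleculeIds
#' @export
isDecoy <- function(x) x@decoy

#' Accessors for FidelitySchedule
#'
#' @param x a [FidelitySchedule-class].
#' @export
fidelityNames <- function(x) x@levels

#' @rdname fidelityNames
#' @export
fidelityCosts <- function(x) x@costs

#' @rdname fidelityNames
#' @export
iterationBudget <- function(x) x@budget

#' @rdname fidelityNames
#' @export
nFidelities <- function(x) length(x@levels)

#' Accessors for BatchPlan
#'
#' @param x a [BatchPlan-class].
#' @export
planPairs <- function(x) x@pairs

#' @rdname planPairs
#' @export
planCost <- function(x) x@totalCost

#' Accessor for RecoveryCurve
#'
#' @param x a [RecoveryCurve-class].
#' @export
recoveryValues <- function(x) x@recovery

#' @rdname recoveryValues
#' @export
spendMatrix <- function(x) x@spend
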
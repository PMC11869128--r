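## Synthetic-library generator: a stand-in discrete search space that
## emulates the regimes a retrospective screen needs -- configurable size,
## set diversity D, and correlation between a cheap docking-like score
## and the latent potency.  Molecules are assembled from a packaged
## fragment vocabulary; potency is a smooth function of structure (a GP
## draw under the Tanimoto kernel), so structure-aware surrogates have
## signal to exploit.

## ~40 terminal/ring fragments; each can stand at either end of a
## fragment-linker-fragment assembly.
mfbo_fragments <- function() c(
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccoc1", "c1ccsc1",
  "c1cc[nH]c1", "c1cnc[nH]1", "c1cnccn1", "c1ccc2ccccc2c1",
  "Fc1ccccc1", "Clc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "CC(C)c1ccccc1",
  "C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCOC1", "C1CCSC1",
  "C1CCNC1", "C1CC1", "C1CCC1",
  "CC", "CCC", "CCCC", "CC(C)", "CC(C)C", "CCO", "CCOC", "CCN", "CCNC",
  "CC(C)O", "CCS", "CCCO", "CCCN", "CC=C", "CCC#C", "CC1CCCCC1"
)

## ~8 two-sided linkers (left-LINKER-right reads as one SMILES).
mfbo_linkers <- function() c(
  "C", "CC", "O", "N", "C(=O)", "C(=O)N", "S(=O)(=O)N", "OC(=O)", "C=C", "CN"
)

## Assemble up to n unique valid molecules from the first k fragments of a
## seeded vocabulary permutation.  Returns list(smiles, fps) or NULL when
## the restricted vocabulary cannot produce n unique molecules.
.assemble_library <- function(n, k, seed, fpBits = 1024L) {
  frags <- mfbo_fragments()
  links <- mfbo_linkers()
  perm <- with_seed(child_seed(seed, "vocabPerm"),
                    sample(seq_along(frags)))
  vocab <- frags[perm[seq_len(min(k, length(frags)))]]
  seen <- character(0)
  smiles <- character(0)
  attempts <- 0L
  with_seed(child_seed(seed, "assemble"), {
    while (length(smiles) < n && attempts < 40L * n) {
      todo <- min(4L * (n - length(smiles)), 4000L)
      li <- sample(vocab, todo, replace = TRUE)
      lk <- sample(links, todo, replace = TRUE)
      ri <- sample(vocab, todo, replace = TRUE)
      cand <- paste0(li, lk, ri)
      attempts <- attempts + todo
      recs <- chem_process(unique(cand))
      for (r in recs) {
        if (!isTRUE(r$ok)) next
        if (r$canonical %in% seen) next
        seen <- c(seen, r$canonical)
        smiles <- c(smiles, r$canonical)
        if (length(smiles) >= n) break
      }
    }
  })
  if (length(smiles) < n) return(NULL)
  smiles <- smiles[seq_len(n)]
  recs <- chem_process(smiles, nbits = fpBits)
  fp <- matrix(0L, n, fpBits)
  for (i in seq_len(n)) fp[i, recs[[i]]$bits] <- 1L
  list(smiles = smiles, fps = fp)
}

#' Generate a synthetic molecular library with controlled D and |rho|
#'
#' Builds a discrete search space of `n` unique valid molecules from a
#' packaged fragment vocabulary (fragment-linker-fragment assemblies):
#' the number of distinct fragments allowed is tuned by bisection until
#' the set diversity (one minus mean pairwise Tanimoto similarity) is
#' within `d_tol` of `target_D`.  A latent potency surface is drawn from
#' a noise-free GP with Tanimoto kernel over the fingerprints and mapped
#' to pIC50 in `pic50_range`; the high-fidelity truth is this latent
#' surface.  The docking-like low-fidelity truth is
#' `alpha * g + (1 - alpha) * h` with `h` an independent GP draw, `alpha`
#' tuned by bisection until `|cor(low, high)|` is within `rho_tol` of
#' `target_rho`.  Medium-fidelity values are derived on demand by the
#' assay oracle (Hill transform), not stored.  Deterministic given
#' `seed`.
#'
#' @param n library size (>= 50).
#' @param target_D target set diversity in [0, 1].
#' @param target_rho target `|cor(low, high)|` in [0, 1].
#' @param seed RNG seed.
#' @param config list of generator settings: `d_tol` (0.1), `rho_tol`
#'   (0.05), `pic50_range` (c(4, 9)), `pair_cap` (20000), `fpBits`
#'   (1024).
#' @return a [LibraryDataset-class] with a `manifest` attribute recording
#'   the seed, the targets and the achieved metrics.
#' @export
generateSyntheticLibrary <- function(n, target_D = 0.85, target_rho = 0.4,
                                     seed = 1L, config = list()) {
  if (n < 50) stopf("synthetic libraries need n >= 50")
  config <- modifyList(list(d_tol = 0.1, rho_tol = 0.05,
                            pic50_range = c(4, 9), pair_cap = 20000L,
                            fpBits = 1024L), config)
  kmax <- length(mfbo_fragments())

  diversity_of <- function(lib)
    setDiversity(lib$fps, pair_cap = config$pair_cap, seed = seed)

  ## bisection on vocabulary breadth k (diversity grows with breadth)
  lib_hi <- .assemble_library(n, kmax, seed, config$fpBits)
  if (is.null(lib_hi))
    stopf("cannot assemble %d unique molecules from the packaged vocabulary", n)
  d_hi <- diversity_of(lib_hi)
  klo <- 3L
  lib_lo <- .assemble_library(n, klo, seed, config$fpBits)
  d_lo <- if (is.null(lib_lo)) NA_real_ else diversity_of(lib_lo)
  if (target_D > d_hi + config$d_tol)
    stopf("target_D = %.2f unreachable; achievable up to ~%.2f",
          target_D, d_hi)
  if (!is.na(d_lo) && target_D < d_lo - config$d_tol)
    stopf("target_D = %.2f unreachable; achievable down to ~%.2f",
          target_D, d_lo)
  best <- list(lib = lib_hi, d = d_hi, k = kmax)
  if (abs(d_hi - target_D) > config$d_tol) {
    lo <- klo; hi <- kmax
    for (step in seq_len(8)) {
      mid <- as.integer((lo + hi) %/% 2)
      if (mid <= lo) break
      lib <- .assemble_library(n, mid, seed, config$fpBits)
      if (is.null(lib)) { lo <- mid; next }  # too narrow to fill n
      d <- diversity_of(lib)
      if (abs(d - target_D) < abs(best$d - target_D))
        best <- list(lib = lib, d = d, k = mid)
      if (abs(d - target_D) <= config$d_tol) break
      if (d > target_D) hi <- mid else lo <- mid
    }
  }
  if (abs(best$d - target_D) > config$d_tol)
    stopf("target_D = %.2f unreachable with the packaged vocabulary (got %.2f)",
          target_D, best$d)
  lib <- best$lib

  ## latent potency and docking-like score from GP draws
  S <- tanimotoMatrix(lib$fps)
  R <- chol(S + diag(1e-6, n))
  z <- with_seed(child_seed(seed, "latents"), matrix(rnorm(2L * n), n))
  g_raw <- as.numeric(t(R) %*% z[, 1])
  h_raw <- as.numeric(t(R) %*% z[, 2])
  g_std <- as.numeric(scale(g_raw))
  h_std <- as.numeric(scale(h_raw))
  lo_r <- config$pic50_range[1]; hi_r <- config$pic50_range[2]
  high <- lo_r + (hi_r - lo_r) * (g_raw - min(g_raw)) /
    max(max(g_raw) - min(g_raw), 1e-12)

  rho_of <- function(alpha)
    abs(cor(alpha * g_std + (1 - alpha) * h_std, high))
  r1 <- rho_of(1)
  alpha <- if (target_rho >= r1) 1 else {   # ceiling: low a copy of high
    aLo <- 0; aHi <- 1
    for (step in seq_len(40)) {
      aMid <- (aLo + aHi) / 2
      r <- rho_of(aMid)
      if (abs(r - target_rho) <= config$rho_tol / 2) { aLo <- aHi <- aMid; break }
      if (r > target_rho) aHi <- aMid else aLo <- aMid
    }
    (aLo + aHi) / 2
  }
  low <- alpha * g_std + (1 - alpha) * h_std
  achieved_rho <- abs(cor(low, high))
  if (abs(achieved_rho - target_rho) > config$rho_tol && target_rho < r1)
    stopf("target_rho = %.2f not achieved (got %.2f)", target_rho,
          achieved_rho)

  ds <- makeLibraryDataset(sprintf("syn%05d", seq_len(n)), lib$smiles,
                           lib$fps, low, rep(NA_real_, n), high,
                           provenance = "synthetic",
                           fpBits = config$fpBits)
  med_nf <- hillInhibition(10^(-high), 2e-5)
  attr(ds, "manifest") <- list(
    seed = as.integer(seed), n = n, target_D = target_D,
    target_rho = target_rho, achieved_D = best$d,
    achieved_rho = achieved_rho,
    achieved_multiple_rho = multipleCorrelation(low, med_nf, high),
    vocabulary_size = best$k, alpha = alpha)
  ds
}
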
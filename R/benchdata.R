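## benchdata: dataset-level metrics and structured-subset construction.

#' Absolute multiple correlation between fidelities
#'
#' The square root of the coefficient of determination from the
#' least-squares fit of the high-fidelity values on the lower-fidelity
#' values (with intercept).  With a single predictor this reduces to the
#' absolute Pearson correlation.  A lower-fidelity predictor that
#' duplicates another (or is constant) is dropped before fitting.
#'
#' @param low low-fidelity values.
#' @param medium optional medium-fidelity values (NULL or all-NA to use
#'   the single-predictor form).
#' @param high high-fidelity values.
#' @return `|rho|` in `[0, 1]`.
#' @export
multipleCorrelation <- function(low, medium = NULL, high) {
  if (!is.null(medium) && all(is.na(medium))) medium <- NULL
  n <- length(high)
  if (length(low) != n || (!is.null(medium) && length(medium) != n))
    stopf("fidelity value vectors must have equal length")
  if (n < 4) stopf("need at least 4 molecules to estimate |rho|")
  if (sd(high) <= 1e-12) stopf("high-fidelity values are constant")
  preds <- list(low = low)
  if (!is.null(medium)) preds$medium <- medium
  keep <- vapply(preds, function(p) sd(p) > 1e-12, logical(1))
  preds <- preds[keep]
  if (!length(preds)) stopf("all predictors are constant")
  if (length(preds) == 2 &&
      abs(abs(cor(preds[[1]], preds[[2]])) - 1) < 1e-12)
    preds <- preds[1]  # rank deficiency: drop the duplicate
  X <- do.call(cbind, preds)
  fit <- lm(high ~ X)
  ## R^2 from residuals directly (summary.lm warns on perfect fits)
  r2 <- 1 - sum(residuals(fit)^2) / sum((high - mean(high))^2)
  sqrt(min(max(r2, 0), 1))
}

#' Ids of the top-N% molecules by high-fidelity value
#'
#' The `ceiling(n * top_percent / 100)` molecules with highest pIC50;
#' ties are broken by id order (stable and documented).
#'
#' @param dataset a [LibraryDataset-class].
#' @param top_percent percentage in (0, 100].
#' @return character vector of ids.
#' @export
topFractionLabels <- function(dataset, top_percent = 2) {
  n <- nMolecules(dataset)
  if (n == 0) stopf("empty dataset")
  if (top_percent <= 0 || top_percent > 100)
    stopf("top_percent must be in (0, 100]")
  k <- ceiling(n * top_percent / 100)
  o <- order(-dataset@high, dataset@ids)
  dataset@ids[o[seq_len(k)]]
}

#' Subset a dataset by molecule indices
#'
#' @param dataset a [LibraryDataset-class].
#' @param idx integer indices or character ids.
#' @return a [LibraryDataset-class] with provenance "subset".
#' @export
subsetLibrary <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset@ids)
  makeLibraryDataset(dataset@ids[idx], dataset@smiles[idx],
                     dataset@fingerprints[idx, , drop = FALSE],
                     dataset@low[idx], dataset@medium[idx],
                     dataset@high[idx], decoy = dataset@decoy[idx],
                     provenance = "subset",
                     fpRadius = dataset@fpRadius, fpBits = dataset@fpBits)
}

## achieved low~high correlation of a candidate index set
.subset_rho <- function(dataset, idx)
  multipleCorrelation(dataset@low[idx], NULL, dataset@high[idx])

#' Build a subset with controlled diversity span and fidelity correlation
#'
#' Recreates the structured-subset protocol used to probe when
#' multifidelity search pays off: (1) cluster the pool fingerprints into
#' `n_clusters` k-medoids clusters; (2) restrict to a narrow span (the
#' fewest clusters, largest first, whose union covers `n` molecules) or
#' keep all clusters (diverse span); (3) regress the high-fidelity value
#' on the low-fidelity value over the restricted pool and take absolute
#' residuals; (4) draw `n` molecules without replacement with weights
#' `softmax(sign * beta * |resid|)`, where the sign moves the achieved
#' correlation toward `target_rho` and `beta` is tuned by bisection over
#' a deterministic re-draw loop until the achieved `|rho|` (low vs high)
#' is within `tol` or `max_steps` bisection steps have run.
#'
#' @param pool a [LibraryDataset-class].
#' @param n subset size.
#' @param n_clusters number of clusters (default 25).
#' @param cluster_span "narrow" or "diverse".
#' @param target_rho optional target `|rho|` in [0, 1]; NULL for a plain
#'   (stratified) draw.
#' @param seed RNG seed.
#' @param tol correlation tolerance (default 0.05).
#' @param max_steps maximum bisection steps (default 25).
#' @return a [LibraryDataset-class] with attributes `achieved_rho` and
#'   `target_missed` (TRUE when the target was unreachable and the
#'   best-achieved subset is returned with a warning).
#' @export
buildStructuredSubset <- function(pool, n, n_clusters = 25L,
                                  cluster_span = c("diverse", "narrow"),
                                  target_rho = NULL, seed = 1L,
                                  tol = 0.05, max_steps = 25L) {
  cluster_span <- match.arg(cluster_span)
  N <- nMolecules(pool)
  if (n > N) stopf("subset size n exceeds pool size")
  if (n_clusters > N) stopf("more clusters than molecules")
  cl <- clusterKmedoids(pool@fingerprints, n_clusters, seed = seed)

  restricted <- if (cluster_span == "narrow") {
    sizes <- sort(table(cl$labels), decreasing = TRUE)
    cum <- cumsum(sizes)
    use <- as.integer(names(sizes))[seq_len(which(cum >= n)[1])]
    which(cl$labels %in% use)
  } else seq_len(N)

  resid <- abs(residuals(lm(pool@high[restricted] ~ pool@low[restricted])))
  rs <- sd(resid)
  resid_std <- if (rs > 1e-12) resid / rs else rep(0, length(resid))

  draw <- function(beta_signed) {
    w <- exp(beta_signed * resid_std - max(beta_signed * resid_std))
    with_seed(child_seed(seed, "structuredDraw"),
              restricted[sample.int(length(restricted), n, prob = w)])
  }

  plain <- draw(0)
  if (is.null(target_rho))
    return(structure(subsetLibrary(pool, plain),
                     achieved_rho = .subset_rho(pool, plain),
                     target_missed = FALSE))

  rho_plain <- .subset_rho(pool, plain)
  s <- if (target_rho < rho_plain) 1 else -1  # +: favor large residuals
  lo <- 0; hi <- 12
  best_idx <- plain; best_rho <- rho_plain
  if (abs(rho_plain - target_rho) <= tol)
    return(structure(subsetLibrary(pool, plain), achieved_rho = rho_plain,
                     target_missed = FALSE))
  rho_hi <- .subset_rho(pool, draw(s * hi))
  bracket <- (min(rho_plain, rho_hi) - tol <= target_rho &&
              target_rho <= max(rho_plain, rho_hi) + tol)
  for (step in seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    idx <- draw(s * mid)
    rho <- .subset_rho(pool, idx)
    if (abs(rho - target_rho) < abs(best_rho - target_rho)) {
      best_idx <- idx; best_rho <- rho
    }
    if (abs(rho - target_rho) <= tol) break
    ## with s = +1, larger beta lowers the correlation
    toward_target <- if (s > 0) rho > target_rho else rho < target_rho
    if (toward_target) lo <- mid else hi <- mid
  }
  missed <- abs(best_rho - target_rho) > tol
  if (missed)
    warning(sprintf(
      "structured subset: target |rho| = %.2f unreachable (achieved %.2f)",
      target_rho, best_rho))
  structure(subsetLibrary(pool, best_idx), achieved_rho = best_rho,
            target_missed = missed)
}
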
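## surrogate: exact multi-fidelity Gaussian process over (molecule,
## fidelity) pairs.
##
## Kernel: K[(x,f),(x',f')] = amplitude * B[f,f'] * tanimoto(x, x'), an
## intrinsic-coregionalization model (ICM) -- the product of a Tanimoto
## input kernel on Morgan fingerprints and a learned F x F PSD matrix
## B = LL' + diag(d) (rank-2 factor plus diagonal), with per-fidelity
## Gaussian noise.  Training values are z-scored per fidelity inside the
## model; spatially varying effective correlation between assays emerges
## through posterior conditioning.

#' MFSurrogate: a fitted multi-fidelity GP surrogate
#'
#' @slot molIds ids of the distinct training molecules.
#' @slot fps fingerprints of the training molecules (0/1 matrix).
#' @slot simTrain cached Tanimoto similarity among training molecules.
#' @slot obs data.frame (id, molRow, fidelity, value, z) of training
#'   observations in canonical orientation.
#' @slot amplitude kernel amplitude a > 0.
#' @slot B F x F symmetric PSD coregionalization matrix.
#' @slot noise per-fidelity noise variances (standardized units).
#' @slot zmu,zsd per-fidelity standardization statistics.
#' @slot R upper Cholesky factor of the training covariance.
#' @slot alpha cached solve of the training system.
#' @slot nlev number of fidelity levels F.
#' @slot logLik log marginal likelihood at the fitted hyperparameters.
#' @slot config fit configuration list.
#' @export
setClass("MFSurrogate",
  representation(molIds = "character", fps = "matrix", simTrain = "matrix",
                 obs = "data.frame", amplitude = "numeric", B = "matrix",
                 noise = "numeric", zmu = "numeric", zsd = "numeric",
                 R = "matrix", alpha = "numeric", nlev = "integer",
                 logLik = "numeric", config = "list"))

setValidity("MFSurrogate", function(object) {
  msg <- character(0)
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  F <- object@nlev
  if (!all(dim(object@B) == c(F, F))) msg <- c(msg, "B must be F x F")
  ev <- eigen(object@B, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) msg <- c(msg, "B must be positive semidefinite")
  if (any(object@noise < 0)) msg <- c(msg, "noise variances must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MFSurrogate", function(object) {
  cat(sprintf("MFSurrogate: %d observations on %d molecules, %d fidelities\n",
              nrow(object@obs), length(object@molIds), object@nlev))
  cat(sprintf("  amplitude %.3g; log marginal likelihood %.2f\n",
              object@amplitude, object@logLik))
  cat("  coregionalization B:\n")
  print(signif(object@B, 3))
})

#' Multi-fidelity Tanimoto covariance matrix
#'
#' Covariance between two sets of (molecule, fidelity) pairs:
#' `K[(x,f),(x',f')] = amplitude * B[f,f'] * tanimoto(x, x')`.
#'
#' @param fpsA,fpsB 0/1 fingerprint matrices (one molecule per row).
#' @param fidelitiesA,fidelitiesB 1-based fidelity index per row.
#' @param amplitude kernel amplitude.
#' @param B F x F coregionalization matrix.
#' @return `nrow(fpsA)` x `nrow(fpsB)` covariance matrix.
#' @export
mfKernelMatrix <- function(fpsA, fidelitiesA, fpsB = fpsA,
                           fidelitiesB = fidelitiesA,
                           amplitude = 1, B = diag(max(fidelitiesA))) {
  if (nrow(fpsA) != length(fidelitiesA) || nrow(fpsB) != length(fidelitiesB))
    stopf("fingerprint rows and fidelity vector lengths differ")
  S <- tanimotoMatrix(fpsA, fpsB)
  amplitude * B[cbind(rep(fidelitiesA, times = length(fidelitiesB)),
                      rep(fidelitiesB, each = length(fidelitiesA)))] * S
}

## Assemble B from the packed parameter vector.
## theta layout: log_amplitude, L (F*rank, unconstrained), log_diag (F),
## log_noise (F).
unpack_theta <- function(theta, F, rank) {
  la <- theta[1]
  L <- matrix(theta[1 + seq_len(F * rank)], F, rank)
  ld <- theta[1 + F * rank + seq_len(F)]
  ln <- theta[1 + F * rank + F + seq_len(F)]
  list(amplitude = exp(la), B = tcrossprod(L) + diag(exp(ld), F),
       noise = exp(ln), L = L)
}

## Negative log marginal likelihood of the standardized observations.
## fid_idx is the precomputed m^2 x 2 index of B entries per K cell --
## constant across evaluations, so it is hoisted out of the optimizer loop.
mf_nll <- function(theta, simObs, fid, z, F, rank, noise_floor,
                   fid_idx = cbind(rep(fid, length(fid)),
                                   rep(fid, each = length(fid)))) {
  p <- unpack_theta(theta, F, rank)
  noise <- pmax(p$noise, noise_floor)
  K <- p$amplitude * p$B[fid_idx] * simObs
  diag(K) <- diag(K) + noise[fid]
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  alpha <- backsolve(R, backsolve(R, z, transpose = TRUE))
  0.5 * sum(z * alpha) + sum(log(diag(R))) + 0.5 * length(z) * log(2 * pi)
}

default_fit_config <- function() {
  list(rank = 2L, n_restarts = 5L, maxit = 60L, noise_floor = 1e-6,
       noise_cap = 0.25, max_fit_points = Inf)
}

#' Fit the multi-fidelity GP surrogate
#'
#' Hyperparameters (amplitude, coregionalization matrix B through a
#' rank-2-plus-diagonal factor, per-fidelity noise) maximize the log
#' marginal likelihood by seeded multi-start bounded quasi-Newton search
#' in log space.  Training values are z-scored per fidelity first.  When
#' `config$max_fit_points` is below the number of observations the
#' likelihood is optimized on a seeded subsample, and the returned state
#' conditions on all observations at the optimum (standard practice to
#' keep exact-GP refits tractable inside a campaign loop).
#'
#' @param observations data.frame with columns `id`, `fidelity` (1-based
#'   level index) and `value` (canonical orientation, higher = better).
#' @param fps 0/1 fingerprint matrix with rownames giving molecule ids
#'   for every id appearing in `observations`.
#' @param nlev number of fidelity levels F (default: max index observed).
#' @param config fit configuration; see Details.  Defaults: rank 2,
#'   5 restarts, 60 iterations, noise variance bounded to
#'   [1e-6, 0.25] in standardized units -- the cap encodes that assay
#'   noise is a minor share of the observed spread, and keeps the
#'   marginal-likelihood search away from the degenerate all-noise
#'   optimum on small training sets.
#' @param seed RNG seed for restarts and subsampling.
#' @return a fitted [MFSurrogate-class].
#' @export
fitSurrogate <- function(observations, fps, nlev = NULL, config = list(),
                         seed = 1L) {
  if (is.null(observations) || nrow(observations) == 0)
    stopf("fitSurrogate needs at least one observation")
  config <- modifyList(default_fit_config(), config)
  F <- as.integer(nlev %||% max(observations$fidelity))
  rank <- min(config$rank, F)
  if (is.null(rownames(fps))) stopf("fps must carry molecule ids as rownames")
  molIds <- unique(observations$id)
  missing_fp <- setdiff(molIds, rownames(fps))
  if (length(missing_fp))
    stopf("no fingerprint for observed molecule(s): %s",
          paste(head(missing_fp, 3), collapse = ", "))
  fps <- fps[molIds, , drop = FALSE]
  obs <- observations
  obs$molRow <- match(obs$id, molIds)
  stopifnot(all(obs$fidelity >= 1 & obs$fidelity <= F),
            all(is.finite(obs$value)))
  if (anyDuplicated(paste(obs$id, obs$fidelity)))
    stopf("duplicate (molecule, fidelity) observations")

  ## per-fidelity standardization
  zmu <- zsd <- numeric(F)
  for (f in seq_len(F)) {
    v <- obs$value[obs$fidelity == f]
    zmu[f] <- if (length(v)) mean(v) else 0
    s <- if (length(v) > 1) sd(v) else 0
    zsd[f] <- if (is.finite(s) && s > 1e-12) s else 1
  }
  obs$z <- (obs$value - zmu[obs$fidelity]) / zsd[obs$fidelity]

  simTrain <- tanimotoMatrix(fps)

  ## subsample for hyperparameter search if requested
  fit_idx <- seq_len(nrow(obs))
  if (nrow(obs) > config$max_fit_points) {
    fit_idx <- with_seed(child_seed(seed, "fit_subsample"), {
      ## always keep all highest-fidelity points; fill with a uniform draw
      hi <- which(obs$fidelity == F)
      rest <- setdiff(seq_len(nrow(obs)), hi)
      c(hi, sample(rest, max(0, config$max_fit_points - length(hi))))
    })
  }
  simObs <- simTrain[obs$molRow[fit_idx], obs$molRow[fit_idx], drop = FALSE]
  fid_fit <- obs$fidelity[fit_idx]
  z_fit <- obs$z[fit_idx]

  ## the noise cap keeps the optimizer away from the degenerate all-noise
  ## optimum: assay noise is a known small fraction of the signal range
  npar <- 1 + F * rank + 2 * F
  lower <- c(log(1e-3), rep(-3, F * rank), rep(log(1e-6), F),
             rep(log(config$noise_floor), F))
  upper <- c(log(1e3), rep(3, F * rank), rep(log(10), F),
             rep(log(config$noise_cap), F))
  init0 <- pmin(upper, pmax(lower, c(0, rep(0.5, F * rank),
                                     rep(log(0.1), F), rep(log(0.05), F))))

  ## parameters whose bounds coincide (e.g. pinned noise) are held fixed:
  ## L-BFGS-B cannot finite-difference a zero-width box
  free <- (upper - lower) > 1e-12
  embed <- function(th_free) { th <- init0; th[free] <- th_free; th }
  fid_idx <- cbind(rep(fid_fit, length(fid_fit)),
                   rep(fid_fit, each = length(fid_fit)))
  nll_free <- function(th_free)
    mf_nll(embed(th_free), simObs, fid_fit, z_fit, F, rank,
           config$noise_floor, fid_idx)
  best <- NULL
  starts <- with_seed(child_seed(seed, "fit_restarts"), {
    lapply(seq_len(config$n_restarts), function(i) {
      if (i == 1) init0 else pmin(upper, pmax(lower, init0 + rnorm(npar, 0, 0.7)))
    })
  })
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0[free], nll_free, method = "L-BFGS-B",
            lower = lower[free], upper = upper[free],
            control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stopf("surrogate hyperparameter optimization failed")
  ## never return a start worse than the untouched initial value
  nll0 <- mf_nll(init0, simObs, fid_fit, z_fit, F, rank, config$noise_floor)
  if (nll0 < best$value) best <- list(par = init0[free], value = nll0)
  p <- unpack_theta(embed(best$par), F, rank)
  noise <- pmax(p$noise, config$noise_floor)

  ## condition on ALL observations at the optimum
  K <- p$amplitude * p$B[cbind(rep(obs$fidelity, nrow(obs)),
                               rep(obs$fidelity, each = nrow(obs)))] *
    simTrain[obs$molRow, obs$molRow, drop = FALSE]
  diag(K) <- diag(K) + noise[obs$fidelity]
  R <- tryCatch(chol(K), error = function(e)
    stopf("training covariance is singular after the noise floor; %s",
          "check for duplicated (molecule, fidelity) observations"))
  alpha <- backsolve(R, backsolve(R, obs$z, transpose = TRUE))

  new("MFSurrogate", molIds = molIds, fps = fps, simTrain = simTrain,
      obs = obs[, c("id", "molRow", "fidelity", "value", "z")],
      amplitude = p$amplitude, B = p$B, noise = noise, zmu = zmu, zsd = zsd,
      R = R, alpha = as.numeric(alpha), nlev = F, logLik = -best$value,
      config = config)
}

#' Posterior prediction at (molecule, fidelity) pairs
#'
#' Standard GP posterior mean and variance in canonical assay units.  The
#' reported variance includes the fidelity's observation noise, so a
#' molecule with zero similarity to all training molecules gets
#' `amplitude * B[f,f] + noise[f]` (in standardized units) around the
#' prior mean.
#'
#' @param state a fitted [MFSurrogate-class].
#' @param fps 0/1 fingerprint matrix of query molecules.
#' @param fidelity single 1-based fidelity index for all queries, or a
#'   vector with one index per query row.
#' @return data.frame with columns `mean` and `var`.
#' @export
predictSurrogate <- function(state, fps, fidelity) {
  if (!is(state, "MFSurrogate")) stopf("state must be a fitted MFSurrogate")
  q <- nrow(fps)
  fidelity <- if (length(fidelity) == 1) rep(fidelity, q) else fidelity
  stopifnot(length(fidelity) == q)
  simQ <- tanimotoMatrix(fps, state@fps)          # q x u
  obs <- state@obs
  m <- nrow(obs)
  ## K_star (q x m)
  Kst <- simQ[, obs$molRow, drop = FALSE] *
    matrix(state@amplitude * state@B[cbind(rep(fidelity, m),
                                           rep(obs$fidelity, each = q))],
           q, m)
  mean_z <- as.numeric(Kst %*% state@alpha)
  V <- backsolve(state@R, t(Kst), transpose = TRUE)  # m x q
  prior <- state@amplitude * diag(state@B)[fidelity] + state@noise[fidelity]
  var_z <- pmax(prior - colSums(V^2), 0)
  data.frame(mean = mean_z * state@zsd[fidelity] + state@zmu[fidelity],
             var = var_z * state@zsd[fidelity]^2)
}

#' Pool-scaled predictions for cost-aware acquisition
#'
#' Predicts every (pool molecule, fidelity) pair and applies the scaling
#' the acquisition consumes: each fidelity's mean is min-max scaled over
#' the candidate pool to `[0, 1]` (clipped), and each variance is divided
#' by the squared pool range and by the relative cost of the fidelity, so
#' cheap fidelities carry inflated variance.  A degenerate pool
#' (max = min) gets scaled mean 0.5.
#'
#' @param state a fitted [MFSurrogate-class].
#' @param poolFps fingerprints of the candidate pool.
#' @param schedule a [FidelitySchedule-class].
#' @return list with `pred` (data.frame pool x fidelity rows: molecule
#'   row, fidelity, mean, var, scaled_mean, scaled_var) and `stats`
#'   (per-fidelity pool min/max used for the scaling).
#' @export
scaledPredictions <- function(state, poolFps, schedule) {
  F <- nFidelities(schedule)
  out <- vector("list", F)
  stats <- data.frame(fidelity = seq_len(F), min = NA_real_, max = NA_real_)
  for (f in seq_len(F)) {
    pr <- predictSurrogate(state, poolFps, f)
    mn <- min(pr$mean); mx <- max(pr$mean)
    stats$min[f] <- mn; stats$max[f] <- mx
    rng <- mx - mn
    if (rng <= 1e-12) {
      mfbo_log("degenerate pool at fidelity ", f, ": scaled mean set to 0.5")
      sm <- rep(0.5, nrow(pr)); rng <- 1
    } else sm <- clip01((pr$mean - mn) / rng)
    out[[f]] <- data.frame(molecule = seq_len(nrow(poolFps)), fidelity = f,
                           mean = pr$mean, var = pr$var, scaled_mean = sm,
                           scaled_var = pr$var / rng^2 / fidelityCosts(schedule)[f])
  }
  list(pred = do.call(rbind, out), stats = stats)
}

#' Serialize / restore a fitted surrogate
#'
#' Writes hyperparameters, standardization statistics, training
#' observations and training fingerprints (as on-bit indices) to a single
#' JSON manifest.  Reloading recomputes the Cholesky factorization from
#' the stored numbers, so predictions reproduce to full double precision
#' (differences bounded by the decimal round-trip of the JSON text,
#' below 1e-12).
#'
#' @param state a fitted [MFSurrogate-class].
#' @param path output JSON path.
#' @return `path` invisibly (`saveSurrogate`); an [MFSurrogate-class]
#'   (`loadSurrogate`).
#' @export
saveSurrogate <- function(state, path) {
  bits <- apply(state@fps, 1, function(r) which(r != 0), simplify = FALSE)
  payload <- list(
    format = "mfbo-surrogate-1",
    nlev = state@nlev, amplitude = state@amplitude, B = state@B,
    noise = state@noise, zmu = state@zmu, zsd = state@zsd,
    nbits = ncol(state@fps), molIds = state@molIds, fpBits = bits,
    obs = state@obs[, c("id", "fidelity", "value")],
    logLik = state@logLik, config = state@config[c("rank", "noise_floor")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSurrogate
#' @export
loadSurrogate <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "mfbo-surrogate-1"))
    stopf("not an mfbo surrogate manifest: %s", path)
  nbits <- as.integer(p$nbits)
  fps <- matrix(0L, length(p$molIds), nbits,
                dimnames = list(p$molIds, NULL))
  for (i in seq_along(p$fpBits)) fps[i, as.integer(p$fpBits[[i]])] <- 1L
  obs <- as.data.frame(p$obs)
  molIds <- p$molIds
  obs$molRow <- match(obs$id, molIds)
  zmu <- as.numeric(p$zmu); zsd <- as.numeric(p$zsd)
  obs$z <- (obs$value - zmu[obs$fidelity]) / zsd[obs$fidelity]
  simTrain <- tanimotoMatrix(fps)
  B <- matrix(as.numeric(p$B), p$nlev, p$nlev)
  noise <- as.numeric(p$noise)
  K <- p$amplitude * B[cbind(rep(obs$fidelity, nrow(obs)),
                             rep(obs$fidelity, each = nrow(obs)))] *
    simTrain[obs$molRow, obs$molRow, drop = FALSE]
  diag(K) <- diag(K) + noise[obs$fidelity]
  R <- chol(K)
  alpha <- backsolve(R, backsolve(R, obs$z, transpose = TRUE))
  new("MFSurrogate", molIds = molIds, fps = fps, simTrain = simTrain,
      obs = obs[, c("id", "molRow", "fidelity", "value", "z")],
      amplitude = as.numeric(p$amplitude), B = B, noise = noise,
      zmu = zmu, zsd = zsd, R = R, alpha = as.numeric(alpha),
      nlev = as.integer(p$nlev), logLik = as.numeric(p$logLik),
      config = modifyList(default_fit_config(), as.list(p$config)))
}
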
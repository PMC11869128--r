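## acquisition: cost-aware expected improvement over (molecule, fidelity)
## pairs and Monte-Carlo fantasy batch selection under a budget.
##
## Batch selection conditions fantasized observations into the GP
## posterior without refitting hyperparameters.  The conditioner below
## maintains V = R'^-1 K(train, pool) and the whitened data w = R'^-1 z,
## so adding one fantasy observation updates every pool pair's posterior
## mean and variance in O(m + P) per pair instead of refactorizing -- the
## standard low-rank Cholesky-update trick that makes batched Kriging
## believers affordable.

#' Closed-form expected improvement
#'
#' `EI = (mu - y*) Phi(z) + sigma phi(z)` with `z = (mu - y*)/sigma`; for
#' `sigma = 0` the deterministic improvement `max(mu - y*, 0)`.
#'
#' @param mean posterior mean(s).
#' @param sd posterior standard deviation(s), `>= 0`.
#' @param incumbent the incumbent best value y*.
#' @return EI value(s), always `>= 0`.
#' @export
expectedImprovement <- function(mean, sd, incumbent) {
  if (any(sd < 0)) stopf("negative standard deviation in expectedImprovement")
  d <- mean - incumbent
  out <- pmax(d, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- d[pos] / sd[pos]
    out[pos] <- d[pos] * pnorm(z) + sd[pos] * dnorm(z)
  }
  pmax(out, 0)
}

## ---- incremental pool conditioner --------------------------------------

## Build the conditioner environment for a fitted surrogate and a candidate
## pool.  Pool pairs are every (molecule, fidelity) combination; pairs that
## coincide with a training observation start out marked observed.
new_conditioner <- function(state, poolIds, poolFps, schedule) {
  F <- nFidelities(schedule)
  if (F != state@nlev)
    stopf("schedule has %d levels but surrogate was fitted with %d",
          F, state@nlev)
  n <- length(poolIds)
  P <- n * F
  pm <- rep(seq_len(n), times = F)        # pool molecule row per pair
  pf <- rep(seq_len(F), each = n)         # fidelity per pair
  costs <- fidelityCosts(schedule)

  simPool <- tanimotoMatrix(poolFps)                   # n x n
  simPoolTrain <- tanimotoMatrix(poolFps, state@fps)   # n x u

  obs <- state@obs
  m0 <- nrow(obs)
  amp <- state@amplitude; B <- state@B; noise <- state@noise
  ## K(train, pool): m0 x P
  Ktp <- t(simPoolTrain[pm, obs$molRow, drop = FALSE]) *
    matrix(amp * B[cbind(rep(obs$fidelity, P), rep(pf, each = m0))], m0, P)
  ## V and w are zero-padded to full capacity so per-depth updates never
  ## subset (and so never copy) the big fantasy matrix
  cap <- m0 + P
  V <- matrix(0, cap, P)
  V[seq_len(m0), ] <- backsolve(state@R, Ktp, transpose = TRUE)
  w <- numeric(cap)
  w[seq_len(m0)] <- backsolve(state@R, obs$z, transpose = TRUE)
  mu <- as.numeric(crossprod(V, w))
  prior <- amp * diag(B)[pf] + noise[pf]
  s2 <- pmax(prior - colSums(V^2), 1e-12)

  observed <- logical(P)
  hit <- match(paste(obs$id, obs$fidelity), paste(poolIds[pm], pf))
  observed[hit[!is.na(hit)]] <- TRUE

  ## fixed per-fidelity scaling statistics from the initial pool means
  zmu <- state@zmu; zsd <- state@zsd
  mean_can <- mu * zsd[pf] + zmu[pf]
  mn <- rng <- numeric(F)
  for (f in seq_len(F)) {
    v <- mean_can[pf == f]
    mn[f] <- min(v); r <- max(v) - mn[f]
    rng[f] <- if (r <= 1e-12) NA_real_ else r   # NA marks a degenerate pool
  }

  env <- new.env(parent = baseenv())
  env$state <- state; env$poolIds <- poolIds
  env$n <- n; env$P <- P; env$pm <- pm; env$pf <- pf
  env$costs <- costs; env$simPool <- simPool
  env$amp <- amp; env$B <- B; env$noise <- noise
  env$zmu <- zmu; env$zsd <- zsd; env$mn <- mn; env$rng <- rng
  env$m <- m0; env$V <- V; env$w <- w; env$mu <- mu; env$s2 <- s2
  env$observed <- observed
  env
}

cond_clone <- function(env) {
  e2 <- new.env(parent = baseenv())
  for (nm in ls(env)) assign(nm, get(nm, envir = env), envir = e2)
  e2
}

## canonical-unit posterior for every pool pair
cond_moments <- function(env) {
  list(mean = env$mu * env$zsd[env$pf] + env$zmu[env$pf],
       var = env$s2 * env$zsd[env$pf]^2)
}

## scaled mean / scaled variance per the TVR contract
cond_scaled <- function(env) {
  mo <- cond_moments(env)
  f <- env$pf
  rng <- env$rng[f]
  sm <- ifelse(is.na(rng), 0.5, clip01((mo$mean - env$mn[f]) / rng))
  rr <- ifelse(is.na(rng), 1, rng)
  sv <- mo$var / rr^2 / env$costs[f]
  list(scaled_mean = sm, scaled_var = pmax(sv, 0))
}

## condition one observation (canonical units) at pool pair index p
cond_add <- function(env, p, value_can) {
  f <- env$pf[p]
  z <- (value_can - env$zmu[f]) / env$zsd[f]
  m <- env$m
  r <- env$V[, p]                  # rows > m are zero by construction
  d <- sqrt(max(env$s2[p], 1e-12))
  kcross <- env$amp * env$B[f, env$pf] * env$simPool[env$pm[p], env$pm]
  vnew <- (kcross - as.numeric(crossprod(r, env$V))) / d
  wnew <- (z - sum(r * env$w)) / d
  ## in-place row write: evaluated inside env so the matrix binding keeps
  ## reference count 1 (a cloned branch shares V and copies on first write)
  env$.row <- m + 1L; env$.vnew <- vnew
  evalq(V[.row, ] <- .vnew, env)
  env$w[m + 1L] <- wnew
  env$m <- m + 1L
  env$mu <- env$mu + vnew * wnew
  env$s2 <- pmax(env$s2 - vnew^2, 1e-12)
  env$observed[p] <- TRUE
  invisible(env)
}

## ---- public scoring -----------------------------------------------------

#' Incumbent best on the scaled axis
#'
#' The best highest-fidelity observation of the surrogate, min-max scaled
#' with the given pool statistics and clipped to `[0, 1]`.  Before any
#' highest-fidelity observation exists the incumbent defaults to 0 (the
#' most optimistic feasible value on the scaled axis).
#'
#' @param state a fitted [MFSurrogate-class].
#' @param stats per-fidelity scaling statistics as returned in
#'   `scaledPredictions(...)$stats`.
#' @return scalar incumbent in `[0, 1]`.
#' @export
incumbentValue <- function(state, stats) {
  F <- state@nlev
  hi <- state@obs$value[state@obs$fidelity == F]
  if (!length(hi)) {
    mfbo_log("no highest-fidelity observation yet; incumbent defaults to 0")
    return(0)
  }
  rng <- stats$max[F] - stats$min[F]
  if (rng <= 1e-12) return(0.5)
  clip01((max(hi) - stats$min[F]) / rng)
}

#' Cost-aware EI scores for every (molecule, fidelity) pair of a pool
#'
#' Each pair is scored as the expected improvement of its pool-scaled
#' mean/variance over the incumbent best scaled highest-fidelity
#' observation; dividing variances by relative cost inflates the EI of
#' cheap fidelities (targeted variance reduction).
#'
#' @param state a fitted [MFSurrogate-class].
#' @param poolIds,poolFps candidate pool ids and fingerprints.
#' @param schedule a [FidelitySchedule-class].
#' @return data.frame (id, fidelity, mean, var, scaled_mean, scaled_var,
#'   score, observed, cost).
#' @export
scorePairs <- function(state, poolIds, poolFps, schedule) {
  env <- new_conditioner(state, poolIds, poolFps, schedule)
  sc <- cond_scaled(env)
  mo <- cond_moments(env)
  stats <- data.frame(fidelity = seq_len(nFidelities(schedule)),
                      min = env$mn,
                      max = env$mn + ifelse(is.na(env$rng), 0, env$rng))
  inc <- incumbentValue(state, stats)
  data.frame(id = env$poolIds[env$pm], fidelity = env$pf,
             mean = mo$mean, var = mo$var,
             scaled_mean = sc$scaled_mean, scaled_var = sc$scaled_var,
             score = expectedImprovement(sc$scaled_mean,
                                         sqrt(sc$scaled_var), inc),
             observed = env$observed, cost = env$costs[env$pf],
             stringsAsFactors = FALSE)
}

## ---- batch selection ----------------------------------------------------

pick_best_pair <- function(env, ei, affordable) {
  cand <- which(affordable & !env$observed)
  if (!length(cand)) return(NULL)
  e <- ei[cand]
  best <- max(e)
  tied <- cand[e >= best - 1e-15]
  if (length(tied) > 1) {
    o <- order(env$costs[env$pf[tied]], env$poolIds[env$pm[tied]])
    tied <- tied[o]
  }
  tied[1]
}

#' Select a batch of molecule-fidelity pairs under a budget
#'
#' Beam-style Monte-Carlo fantasy search.  At each depth every surviving
#' branch picks the affordable unobserved pair with maximum cost-aware EI,
#' draws `n_fantasies` outcomes from its posterior at that pair (a single
#' fantasy uses the posterior mean -- the classic Kriging believer),
#' conditions each outcome into a child branch without refitting
#' hyperparameters, and the `keep_branches` children with highest
#' cumulative EI survive.  A branch stops when no unobserved pair is
#' affordable; the final plan is the pair sequence of the finished branch
#' with the highest cumulative EI (ties: lower cost, then lexicographic
#' pair ids).  Deterministic given `seed`.
#'
#' @param state a fitted [MFSurrogate-class].
#' @param poolIds,poolFps candidate pool.
#' @param schedule a [FidelitySchedule-class]; its `budget` bounds the
#'   total cost of the plan.
#' @param mc list with `n_fantasies` (default 3) and `keep_branches`
#'   (default 5).
#' @param seed RNG seed.
#' @return a [BatchPlan-class].
#' @export
selectBatch <- function(state, poolIds, poolFps, schedule,
                        mc = list(n_fantasies = 3L, keep_branches = 5L),
                        seed = 1L) {
  if (!length(poolIds)) stopf("empty candidate pool")
  mc <- modifyList(list(n_fantasies = 3L, keep_branches = 5L), mc)
  nf <- max(1L, as.integer(mc$n_fantasies))
  kb <- max(1L, as.integer(mc$keep_branches))
  budget <- iterationBudget(schedule)
  costs <- fidelityCosts(schedule)
  F <- nFidelities(schedule)

  env0 <- new_conditioner(state, poolIds, poolFps, schedule)
  stats <- data.frame(fidelity = seq_len(F), min = env0$mn,
                      max = env0$mn + ifelse(is.na(env0$rng), 0, env0$rng))
  inc0 <- incumbentValue(state, stats)

  empty_plan <- function() {
    new("BatchPlan",
        pairs = data.frame(id = character(0), fidelity = integer(0),
                           score = numeric(0), cost = numeric(0),
                           stringsAsFactors = FALSE),
        totalCost = 0, budget = budget, seed = as.integer(seed))
  }
  if (budget < min(costs) - 1e-12) return(empty_plan())

  mk_branch <- function(env, cumEI, spent, rows, inc)
    list(env = env, cumEI = cumEI, spent = spent, rows = rows, inc = inc)

  res <- with_seed(child_seed(seed, "selectBatch"), {
    active <- list(mk_branch(env0, 0, 0, list(), inc0))
    finished <- list()
    greedy <- (nf == 1L && kb == 1L)
    while (length(active)) {
      children <- list()
      for (br in active) {
        env <- br$env
        sc <- cond_scaled(env)
        ei <- expectedImprovement(sc$scaled_mean, sqrt(sc$scaled_var), br$inc)
        affordable <- env$costs[env$pf] <= (budget - br$spent) + 1e-9
        p <- pick_best_pair(env, ei, affordable)
        if (is.null(p)) { finished[[length(finished) + 1L]] <- br; next }
        f <- env$pf[p]
        mo <- cond_moments(env)
        mean_p <- mo$mean[p]; sd_p <- sqrt(max(mo$var[p], 0))
        fan <- if (nf == 1L) mean_p else mean_p + sd_p * rnorm(nf)
        row <- data.frame(id = env$poolIds[env$pm[p]], fidelity = f,
                          score = ei[p], cost = env$costs[f],
                          stringsAsFactors = FALSE)
        for (y in fan) {
          cenv <- if (greedy) env else cond_clone(env)
          cond_add(cenv, p, y)
          inc <- br$inc
          if (f == F && !is.na(env$rng[F]))
            inc <- max(inc, clip01((y - env$mn[F]) / env$rng[F]))
          children[[length(children) + 1L]] <-
            mk_branch(cenv, br$cumEI + ei[p], br$spent + env$costs[f],
                      c(br$rows, list(row)), inc)
        }
      }
      if (length(children) > kb) {
        key <- order(-vapply(children, `[[`, numeric(1), "cumEI"),
                     vapply(children, `[[`, numeric(1), "spent"))
        children <- children[key[seq_len(kb)]]
      }
      active <- children
    }
    if (!length(finished)) empty_plan() else {
      sig <- vapply(finished, function(b)
        paste(vapply(b$rows, function(r) paste0(r$id, ":", r$fidelity),
                     character(1)), collapse = ","), character(1))
      o <- order(-vapply(finished, `[[`, numeric(1), "cumEI"),
                 vapply(finished, `[[`, numeric(1), "spent"), sig)
      win <- finished[[o[1]]]
      pairs <- if (length(win$rows)) do.call(rbind, win$rows) else
        data.frame(id = character(0), fidelity = integer(0),
                   score = numeric(0), cost = numeric(0))
      new("BatchPlan", pairs = pairs, totalCost = win$spent, budget = budget,
          seed = as.integer(seed))
    }
  })
  res
}

#' Per-fidelity budget breakdown of a batch plan
#'
#' Counts, cost and percent of budget per fidelity, with nearest-integer
#' percent rounding (e.g. 336 single-point experiments at relative cost
#' 0.2 against a budget of 100.0 are 67% of budget).
#'
#' @param plan a [BatchPlan-class].
#' @param schedule a [FidelitySchedule-class].
#' @return list with `table` (data.frame level, count, cost, percent) and
#'   `unspent` budget.
#' @export
budgetBreakdown <- function(plan, schedule) {
  F <- nFidelities(schedule)
  costs <- fidelityCosts(schedule)
  budget <- plan@budget
  counts <- tabulate(plan@pairs$fidelity, nbins = F)
  cost <- counts * costs
  data_tab <- data.frame(level = fidelityNames(schedule), count = counts,
                         cost = cost,
                         percent = round(100 * cost / budget),
                         stringsAsFactors = FALSE)
  list(table = data_tab, unspent = budget - sum(cost))
}

#' Serialize a batch plan to JSON
#'
#' @param plan a [BatchPlan-class].
#' @param schedule the schedule the plan was selected under.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBatchPlan <- function(plan, schedule, path) {
  bd <- budgetBreakdown(plan, schedule)
  payload <- list(seed = plan@seed, budget = plan@budget,
                  total_cost = plan@totalCost,
                  pairs = plan@pairs, breakdown = bd$table,
                  unspent = bd$unspent)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
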
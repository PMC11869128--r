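## campaign: the iterative discovery loop for five experiment-selection
## strategies (MF-BO, high-fidelity-only BO, experimental funnel,
## transfer-learning funnel, random), and the rediscovery metrics.

#' Campaign configuration
#'
#' @param strategy one of "mfbo", "bo_high", "funnel", "transfer",
#'   "random".
#' @param init_frac fraction of molecules measured at every fidelity at
#'   initialization (default 0.05), drawn from outside the top-N% set.
#' @param top_percent top-N% definition for rediscovery (default 2).
#' @param n_iterations number of search iterations (default 5).
#' @param budget_frac per-iteration budget as a fraction of the pool
#'   measured at the highest fidelity (default 0.02: each iteration can
#'   afford high-fidelity tests on 2% of the molecules).
#' @param seed base seed; iterations and the oracle derive substreams.
#' @param mc fantasy-search settings passed to [selectBatch()]; the
#'   campaign default is the single-branch Kriging believer
#'   (`n_fantasies = 1`, `keep_branches = 1`), which keeps a full
#'   retrospective benchmark tractable at desk scale.
#' @param funnel_alloc budget fractions spent at (low, medium, high) by
#'   the funnel-type strategies (default 0.2/0.4/0.4).
#' @param fit_config surrogate fit settings; the campaign default caps
#'   the likelihood-optimization subsample at 300 observations with 2
#'   restarts.
#' @param count_rule when does a top molecule count as found?  "medium"
#'   (default): once it has a physical inhibition measurement --
#'   single-point or dose-response; a docking score alone never counts.
#'   "high": only a dose-response measurement counts.  The default
#'   reflects how a multifidelity search actually confirms hits: most of
#'   its budget goes to cheap assays, and demanding a dose-response
#'   reading for credit would score the method's central behavior as
#'   zero.  For the single-fidelity baselines the rule is immaterial
#'   (all their spend is at the highest fidelity).
#' @param noise oracle noise settings (see [makeOracle()]).
#' @return a validated configuration list.
#' @export
campaignConfig <- function(strategy = c("mfbo", "bo_high", "funnel",
                                        "transfer", "random"),
                           init_frac = 0.05, top_percent = 2,
                           n_iterations = 5L, budget_frac = 0.02,
                           seed = 1L,
                           mc = list(n_fantasies = 1L, keep_branches = 1L),
                           funnel_alloc = c(0.2, 0.4, 0.4),
                           fit_config = list(max_fit_points = 300L,
                                             n_restarts = 2L, maxit = 40L),
                           count_rule = c("medium", "high"),
                           noise = list()) {
  strategy <- match.arg(strategy)
  count_rule <- match.arg(count_rule)
  stopifnot(init_frac >= 0, init_frac <= 1, top_percent > 0,
            top_percent <= 100, n_iterations >= 1, budget_frac >= 0,
            length(funnel_alloc) == 3, all(funnel_alloc >= 0),
            sum(funnel_alloc) <= 1 + 1e-9)
  list(strategy = strategy, init_frac = init_frac,
       top_percent = top_percent, n_iterations = as.integer(n_iterations),
       budget_frac = budget_frac, seed = as.integer(seed), mc = mc,
       funnel_alloc = funnel_alloc, fit_config = fit_config,
       count_rule = count_rule, noise = noise)
}

## observation bookkeeping helpers
.obs_has <- function(obs, ids, fidelity)
  ids %in% obs$id[obs$fidelity == fidelity]

.obs_value <- function(obs, ids, fidelity) {
  sub <- obs[obs$fidelity == fidelity, ]
  sub$value[match(ids, sub$id)]
}

#' Initialize a campaign state
#'
#' Draws `round(init_frac * N)` molecules uniformly (seeded) from outside
#' the top-N% label set and measures each at every fidelity through the
#' oracle; initialization cost is not charged against the iteration
#' budget.
#'
#' @param dataset a [LibraryDataset-class].
#' @param config a [campaignConfig()] list.
#' @param schedule a [FidelitySchedule-class]; NULL for the default
#'   0.01/0.2/1.0 schedule with budget `budget_frac * N`.
#' @param oracle an [AssayOracle-class]; NULL to build one from the
#'   dataset with the config's noise settings.
#' @return a campaign state list.
#' @export
initializeCampaign <- function(dataset, config, schedule = NULL,
                               oracle = NULL) {
  N <- nMolecules(dataset)
  if (is.null(schedule))
    schedule <- fidelitySchedule(budget = config$budget_frac * N * 1.0)
  if (is.null(oracle))
    oracle <- makeOracle(dataset, noise = config$noise,
                         seed = child_seed(config$seed, "oracle"))
  topIds <- topFractionLabels(dataset, config$top_percent)
  nonTop <- setdiff(dataset@ids, topIds)
  n_init <- round(config$init_frac * N)
  if (n_init > length(nonTop))
    stopf("initialization sample (%d) exceeds the non-top pool (%d)",
          n_init, length(nonTop))
  if (n_init == 0)
    warning("initialization fraction rounds to zero molecules")
  init_ids <- with_seed(child_seed(config$seed, "init"),
                        sample(nonTop, n_init))
  F <- nFidelities(schedule)
  obs <- if (n_init) {
    data.frame(id = rep(init_ids, each = F),
               fidelity = rep(seq_len(F), times = n_init),
               stringsAsFactors = FALSE)
  } else data.frame(id = character(0), fidelity = integer(0))
  obs$value <- if (nrow(obs)) queryOracle(oracle, obs$id, obs$fidelity)
               else numeric(0)
  list(dataset = dataset, schedule = schedule, oracle = oracle,
       config = config, obs = obs, topIds = topIds, init_ids = init_ids,
       spend = matrix(0, config$n_iterations, F,
                      dimnames = list(NULL, fidelityNames(schedule))),
       recovery = numeric(0), iter = 0L)
}

.recovery_of <- function(state) {
  rule_f <- if (state$config$count_rule == "medium") c(2L, 3L) else 3L
  found <- unique(state$obs$id[state$obs$fidelity %in% rule_f])
  mean(state$topIds %in% found)
}

#' Run a retrospective discovery campaign
#'
#' Each iteration the configured strategy proposes a [BatchPlan-class]
#' within the per-iteration budget, the oracle answers every pair, the
#' observations are appended (the surrogate is refit once per iteration
#' where the strategy uses one), and the cumulative top-N% recovery is
#' recorded.
#'
#' @inheritParams initializeCampaign
#' @return a [RecoveryCurve-class].
#' @export
runCampaign <- function(dataset, config, schedule = NULL, oracle = NULL) {
  state <- initializeCampaign(dataset, config, schedule, oracle)
  strat <- switch(config$strategy,
                  mfbo = strategyMFBO, bo_high = strategyBOHigh,
                  random = strategyRandom, funnel = strategyFunnel,
                  transfer = strategyTransfer)
  costs <- fidelityCosts(state$schedule)
  for (iter in seq_len(config$n_iterations)) {
    state$iter <- iter
    iter_seed <- child_seed(config$seed, paste0("iter", iter))
    plan <- strat(state, iter_seed)
    pairs <- planPairs(plan)
    if (nrow(pairs)) {
      already <- paste(pairs$id, pairs$fidelity) %in%
        paste(state$obs$id, state$obs$fidelity)
      if (any(already)) stopf("plan repeats an already-observed pair")
      vals <- queryOracle(state$oracle, pairs$id, pairs$fidelity)
      state$obs <- rbind(state$obs,
                         data.frame(id = pairs$id, fidelity = pairs$fidelity,
                                    value = vals, stringsAsFactors = FALSE))
      for (f in seq_along(costs))
        state$spend[iter, f] <- sum(pairs$fidelity == f) * costs[f]
    }
    state$recovery[iter] <- .recovery_of(state)
  }
  new("RecoveryCurve", recovery = state$recovery,
      strategy = config$strategy, seed = config$seed, spend = state$spend)
}

## ---- strategies ---------------------------------------------------------

#' Experiment-selection strategies
#'
#' Internal per-iteration planners; all return a [BatchPlan-class] within
#' the schedule budget and never repeat an observed pair.
#' `strategyMFBO` fits the multi-fidelity surrogate and runs cost-aware
#' fantasy batch selection over every (molecule, fidelity) pair.
#' `strategyBOHigh` is single-fidelity BO: a GP on high-fidelity data
#' only, spending the whole budget at cost 1.0.  `strategyRandom` draws
#' unmeasured molecules uniformly for high-fidelity testing.
#' `strategyFunnel` allocates fixed budget fractions to the three stages:
#' random unscreened molecules at low fidelity, the best low scorers at
#' medium, the best medium scorers at high.  `strategyTransfer` follows
#' the funnel flow but ranks the high-fidelity stage with a kernel-ridge
#' surrogate trained on high-fidelity values whose representation is the
#' fingerprint augmented with the molecule's observed lower-fidelity
#' measurements.
#'
#' @param state a campaign state (see [initializeCampaign()]).
#' @param seed per-iteration seed.
#' @return a [BatchPlan-class].
#' @name strategies
NULL

.make_plan <- function(ids, fids, scores, schedule, seed) {
  costs <- fidelityCosts(schedule)[fids]
  new("BatchPlan",
      pairs = data.frame(id = ids, fidelity = as.integer(fids),
                         score = scores, cost = costs,
                         stringsAsFactors = FALSE),
      totalCost = sum(costs), budget = iterationBudget(schedule),
      seed = as.integer(seed))
}

#' @rdname strategies
#' @export
strategyMFBO <- function(state, seed = 1L) {
  sur <- fitSurrogate(state$obs, .named_fps(state$dataset),
                      nlev = nFidelities(state$schedule),
                      config = state$config$fit_config, seed = seed)
  selectBatch(sur, moleculeIds(state$dataset),
              fingerprintMatrix(state$dataset), state$schedule,
              mc = state$config$mc, seed = seed)
}

.named_fps <- function(dataset) {
  fp <- dataset@fingerprints
  rownames(fp) <- dataset@ids
  fp
}

#' @rdname strategies
#' @export
strategyBOHigh <- function(state, seed = 1L) {
  F <- nFidelities(state$schedule)
  obs_hi <- state$obs[state$obs$fidelity == F, ]
  if (!nrow(obs_hi)) return(strategyRandom(state, seed))
  obs1 <- data.frame(id = obs_hi$id, fidelity = 1L, value = obs_hi$value,
                     stringsAsFactors = FALSE)
  sched1 <- fidelitySchedule(levels = fidelityNames(state$schedule)[F],
                             costs = 1.0,
                             budget = iterationBudget(state$schedule))
  sur <- fitSurrogate(obs1, .named_fps(state$dataset), nlev = 1L,
                      config = state$config$fit_config, seed = seed)
  plan1 <- selectBatch(sur, moleculeIds(state$dataset),
                       fingerprintMatrix(state$dataset), sched1,
                       mc = state$config$mc, seed = seed)
  p <- planPairs(plan1)
  .make_plan(p$id, rep(F, nrow(p)), p$score, state$schedule, seed)
}

#' @rdname strategies
#' @export
strategyRandom <- function(state, seed = 1L) {
  F <- nFidelities(state$schedule)
  budget <- iterationBudget(state$schedule)
  k <- floor(budget / fidelityCosts(state$schedule)[F] + 1e-9)
  cand <- state$dataset@ids[!.obs_has(state$obs, state$dataset@ids, F)]
  k <- min(k, length(cand))
  if (k == 0)
    return(.make_plan(character(0), integer(0), numeric(0),
                      state$schedule, seed))
  pick <- with_seed(child_seed(seed, "random"), sample(cand, k))
  .make_plan(pick, rep(F, k), rep(NA_real_, k), state$schedule, seed)
}

## stage-wise funnel core; rank_high is a function(state, cand_ids) giving
## a ranking score (higher first) for the high-fidelity stage
.funnel_plan <- function(state, seed, rank_high) {
  sched <- state$schedule
  F <- nFidelities(sched)
  stopifnot(F == 3)
  costs <- fidelityCosts(sched)
  budget <- iterationBudget(sched)
  alloc <- state$config$funnel_alloc
  obs <- state$obs
  oracle <- state$oracle
  ids <- state$dataset@ids
  plan_id <- character(0); plan_f <- integer(0)

  ## stage 1: random unscreened molecules at low fidelity
  n_low <- floor(alloc[1] * budget / costs[1] + 1e-9)
  cand <- ids[!.obs_has(obs, ids, 1L)]
  pick <- with_seed(child_seed(seed, "funnel_low"),
                    sample(cand, min(n_low, length(cand))))
  if (length(pick)) {
    vals <- queryOracle(oracle, pick, 1L)  # memoized: re-asked at execution
    obs <- rbind(obs, data.frame(id = pick, fidelity = 1L, value = vals,
                                 stringsAsFactors = FALSE))
    plan_id <- c(plan_id, pick); plan_f <- c(plan_f, rep(1L, length(pick)))
  }

  ## stage 2: best observed low scorers advance to the single-point assay
  n_med <- floor(alloc[2] * budget / costs[2] + 1e-9)
  cand <- ids[.obs_has(obs, ids, 1L) & !.obs_has(obs, ids, 2L)]
  if (length(cand) && n_med > 0) {
    o <- order(-.obs_value(obs, cand, 1L), cand)
    pick <- cand[o[seq_len(min(n_med, length(cand)))]]
    vals <- queryOracle(oracle, pick, 2L)
    obs <- rbind(obs, data.frame(id = pick, fidelity = 2L, value = vals,
                                 stringsAsFactors = FALSE))
    plan_id <- c(plan_id, pick); plan_f <- c(plan_f, rep(2L, length(pick)))
  }

  ## stage 3: best survivors advance to dose-response
  n_high <- floor(alloc[3] * budget / costs[3] + 1e-9)
  cand <- ids[.obs_has(obs, ids, 2L) & !.obs_has(obs, ids, 3L)]
  if (length(cand) && n_high > 0) {
    st2 <- state
    st2$obs <- obs
    score <- rank_high(st2, cand)
    o <- order(-score, cand)
    pick <- cand[o[seq_len(min(n_high, length(cand)))]]
    plan_id <- c(plan_id, pick); plan_f <- c(plan_f, rep(3L, length(pick)))
  }
  .make_plan(plan_id, plan_f, rep(NA_real_, length(plan_id)), sched, seed)
}

#' @rdname strategies
#' @export
strategyFunnel <- function(state, seed = 1L) {
  .funnel_plan(state, seed,
               function(st, cand) .obs_value(st$obs, cand, 2L))
}

## kernel-ridge score on fingerprint + observed lower-fidelity values
.transfer_rank <- function(st, cand) {
  obs <- st$obs
  train_ids <- unique(obs$id[obs$fidelity == 3L])
  if (!length(train_ids)) return(.obs_value(obs, cand, 2L))
  feat <- function(ids_) cbind(.obs_value(obs, ids_, 1L),
                               .obs_value(obs, ids_, 2L))
  Xtr <- feat(train_ids); Xte <- feat(cand)
  ## molecules missing a lower-fidelity reading fall back to the column mean
  for (j in 1:2) {
    mu <- mean(Xtr[, j], na.rm = TRUE)
    if (!is.finite(mu)) mu <- 0
    Xtr[is.na(Xtr[, j]), j] <- mu; Xte[is.na(Xte[, j]), j] <- mu
  }
  ctr <- colMeans(Xtr); sc <- pmax(apply(Xtr, 2, sd), 1e-9)
  Xtr <- sweep(sweep(Xtr, 2, ctr), 2, sc, "/")
  Xte <- sweep(sweep(Xte, 2, ctr), 2, sc, "/")
  fp <- .named_fps(st$dataset)
  Ttr <- tanimotoMatrix(fp[train_ids, , drop = FALSE])
  Tte <- tanimotoMatrix(fp[cand, , drop = FALSE],
                        fp[train_ids, , drop = FALSE])
  rbf <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * 1.0^2))
  }
  Ktr <- 0.5 * Ttr + 0.5 * rbf(Xtr, Xtr)
  Kte <- 0.5 * Tte + 0.5 * rbf(Xte, Xtr)
  y <- .obs_value(obs, train_ids, 3L)
  ym <- mean(y)
  as.numeric(Kte %*% solve(Ktr + diag(1e-2, nrow(Ktr)), y - ym)) + ym
}

#' @rdname strategies
#' @export
strategyTransfer <- function(state, seed = 1L) {
  .funnel_plan(state, seed, .transfer_rank)
}

## ---- metrics ------------------------------------------------------------

#' Fold improvement of one recovery curve over another
#'
#' The ratio of cumulative recoveries at a given iteration (default 5,
#' i.e. after spending the equivalent of 10% of the space at 2% per
#' iteration).  A zero denominator yields an undefined result (flagged),
#' not infinity.
#'
#' @param curve_a,curve_b [RecoveryCurve-class] objects or numeric
#'   vectors.
#' @param at_iteration iteration at which to compare.
#' @return list with `ratio` and `undefined`.
#' @export
foldImprovement <- function(curve_a, curve_b, at_iteration = 5L) {
  va <- if (is(curve_a, "RecoveryCurve")) curve_a@recovery else curve_a
  vb <- if (is(curve_b, "RecoveryCurve")) curve_b@recovery else curve_b
  if (length(va) < at_iteration || length(vb) < at_iteration)
    stopf("curves shorter than at_iteration = %d", at_iteration)
  if (vb[at_iteration] <= 0)
    return(list(ratio = NA_real_, undefined = TRUE))
  list(ratio = va[at_iteration] / vb[at_iteration], undefined = FALSE)
}

#' Per-iteration mean and SD over replicate curves
#'
#' @param curves list of [RecoveryCurve-class] objects or numeric
#'   vectors of equal length (>= 2 curves).
#' @return data.frame (iteration, mean, sd, n).
#' @export
summarizeReplicates <- function(curves) {
  vals <- lapply(curves, function(cv)
    if (is(cv, "RecoveryCurve")) cv@recovery else as.numeric(cv))
  if (length(vals) < 2) stopf("need at least 2 replicate curves")
  L <- unique(lengths(vals))
  if (length(L) != 1) stopf("replicate curves have ragged lengths")
  M <- do.call(rbind, vals)
  data.frame(iteration = seq_len(L), mean = colMeans(M),
             sd = apply(M, 2, sd), n = nrow(M))
}

#' Run several strategies over several seeds on one dataset
#'
#' @param dataset a [LibraryDataset-class].
#' @param strategies character vector of strategy names.
#' @param seeds integer vector of seeds (one campaign per seed).
#' @param ... further arguments to [campaignConfig()].
#' @return tidy data.frame (strategy, seed, iteration, recovery).
#' @export
benchmarkStrategies <- function(dataset, strategies, seeds, ...) {
  rows <- list()
  for (strat in strategies) {
    for (sd_ in seeds) {
      cfg <- campaignConfig(strategy = strat, seed = sd_, ...)
      cv <- runCampaign(dataset, cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = strat, seed = sd_,
                   iteration = seq_along(cv@recovery),
                   recovery = cv@recovery, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
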
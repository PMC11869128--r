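test_that("closed-form EI matches limits and a Monte-Carlo oracle", {
  expect_equal(expectedImprovement(1, 0, 1), 0)       # mu = y*, sigma = 0
  expect_equal(expectedImprovement(11, 0, 1), 10)     # deterministic gain
  expect_equal(expectedImprovement(0, 0, 1), 0)       # no negative EI
  expect_error(expectedImprovement(0, -1, 0), "negative")

  ## MC oracle over a (mu - y*, sigma) grid, including mu = y*, sigma = 1;
  ## antithetic draws remove the first-order error of the sample mean
  half <- mfbo:::with_seed(99, rnorm(5e5))
  draws <- c(half, -half)
  for (d in c(-1, -0.3, 0, 0.5, 2)) {
    for (s in c(0.3, 1, 2)) {
      mc <- mean(pmax(d + s * draws, 0))
      expect_equal(expectedImprovement(d, s, 0), mc, tolerance = 2e-3,
                   label = sprintf("EI(d=%g, s=%g)", d, s))
    }
  }
  ## the canonical point: EI(mu = y*, sigma = 1) = phi(0)
  expect_equal(expectedImprovement(0, 1, 0), dnorm(0), tolerance = 1e-12)
})

test_that("pair scores are cost-aware and handle degenerate pools", {
  fit <- tiny_surrogate(n_train = 5, seed = 13)
  ds <- fit$dataset
  sched <- fidelitySchedule()
  sp <- scorePairs(fit$surrogate, moleculeIds(ds), fingerprintMatrix(ds),
                   sched)
  expect_equal(nrow(sp), nMolecules(ds) * 3)
  expect_true(all(sp$score >= 0))
  ## the scaled variance of a cheap fidelity is inflated by 1/cost:
  ## with equal scaled means and raw variances, lower cost scores higher
  inc <- 0.6
  ei_cheap <- expectedImprovement(0.5, sqrt(0.04 / 0.01), inc)
  ei_dear <- expectedImprovement(0.5, sqrt(0.04 / 1.0), inc)
  expect_gt(ei_cheap, ei_dear)
  ## already-observed pairs carry near-zero scores unless still promising
  obs_pairs <- sp[sp$observed, ]
  expect_true(all(obs_pairs$var < max(sp$var[!sp$observed])))

  ## degenerate pool: identical molecules -> all scores equal per fidelity
  ds1 <- tiny_library(high = rep(6, 8))
  fp1 <- fingerprintMatrix(ds1)[rep(1, 4), ]
  obs1 <- data.frame(id = "p1", fidelity = 3L, value = 6)
  fps_named <- fp1; rownames(fps_named) <- paste0("p", 1:4)
  sur1 <- manual_surrogate(obs1, fps_named, 1, diag(3) + 0.5, rep(0.01, 3))
  sp1 <- scorePairs(sur1, paste0("p", 1:4), fp1, sched)
  for (f in 1:3) {
    expect_equal(length(unique(round(sp1$score[sp1$fidelity == f], 12))), 1)
    expect_true(all(sp1$scaled_mean[sp1$fidelity == f] == 0.5))
  }
})

test_that("batch plans respect the budget, affordability and determinism", {
  fit <- tiny_surrogate(n_train = 4, seed = 17)
  ds <- fit$dataset
  fp <- fingerprintMatrix(ds)
  ## budget affords exactly one lowest-fidelity experiment
  sched1 <- fidelitySchedule(budget = 0.015)
  plan1 <- selectBatch(fit$surrogate, moleculeIds(ds), fp, sched1, seed = 1)
  expect_equal(nrow(planPairs(plan1)), 1)
  expect_equal(planPairs(plan1)$fidelity, 1L)
  ## budget below the cheapest cost -> a valid empty plan
  sched0 <- fidelitySchedule(budget = 0.005)
  plan0 <- selectBatch(fit$surrogate, moleculeIds(ds), fp, sched0, seed = 1)
  expect_equal(nrow(planPairs(plan0)), 0)
  expect_error(selectBatch(fit$surrogate, character(0),
                           fp[0, , drop = FALSE], sched1), "empty")

  ## seeded contract sweep: never over budget, never a duplicate pair,
  ## never a repeat of an already-observed pair
  sched <- fidelitySchedule(budget = 1.0)
  observed <- paste(fit$obs$id, fit$obs$fidelity)
  for (s in 1:25) {
    pl <- selectBatch(fit$surrogate, moleculeIds(ds), fp, sched,
                      mc = list(n_fantasies = 2, keep_branches = 3),
                      seed = s)
    p <- planPairs(pl)
    expect_lte(planCost(pl), iterationBudget(sched) + 1e-9)
    expect_equal(anyDuplicated(paste(p$id, p$fidelity)), 0)
    expect_false(any(paste(p$id, p$fidelity) %in% observed))
  }
  ## determinism: identical seeds give identical plans
  a <- selectBatch(fit$surrogate, moleculeIds(ds), fp, sched, seed = 7)
  b <- selectBatch(fit$surrogate, moleculeIds(ds), fp, sched, seed = 7)
  expect_identical(planPairs(a), planPairs(b))
})

test_that("greedy selection equals an independent sequential-believer oracle", {
  ## independent oracle: a plain loop that rescores the full pool with
  ## dense GP algebra, picks the same argmax rule, conditions the
  ## posterior-mean fantasy by refactorizing from scratch, and repeats
  fit <- tiny_surrogate(n_train = 3, seed = 23)
  ds <- fit$dataset
  ids5 <- moleculeIds(ds)[1:5]
  fp5 <- fingerprintMatrix(ds)[1:5, ]
  sched <- fidelitySchedule(budget = 0.45)
  plan <- selectBatch(fit$surrogate, ids5, fp5, sched,
                      mc = list(n_fantasies = 1, keep_branches = 1),
                      seed = 31)

  sur <- fit$surrogate
  fps_named <- fp5; rownames(fps_named) <- ids5
  obs <- sur@obs[, c("id", "fidelity", "value")]
  costs <- fidelityCosts(sched)
  ## fixed scaling statistics from the initial state, as in the contract
  sc0 <- scaledPredictions(sur, fp5, sched)
  stats <- sc0$stats
  inc <- incumbentValue(sur, stats)
  spent <- 0
  oracle_pairs <- list()
  all_fps <- rbind(sur@fps[setdiff(rownames(sur@fps), ids5), , drop = FALSE],
                   fps_named)
  repeat {
    cand <- expand.grid(id = ids5, fidelity = 1:3, stringsAsFactors = FALSE)
    cand <- cand[!(paste(cand$id, cand$fidelity) %in%
                   paste(obs$id, obs$fidelity)), ]
    cand <- cand[costs[cand$fidelity] <= sched@budget - spent + 1e-9, ]
    if (!nrow(cand)) break
    ei <- numeric(nrow(cand))
    mom <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      mom[[i]] <- dense_gp_posterior(obs, all_fps, sur@amplitude, sur@B,
                                     sur@noise, cand$id[i], cand$fidelity[i],
                                     sur@zmu, sur@zsd)
      f <- cand$fidelity[i]
      rng <- stats$max[f] - stats$min[f]
      sm <- min(1, max(0, (mom[[i]]$mean - stats$min[f]) / rng))
      sv <- mom[[i]]$var / rng^2 / costs[f]
      ei[i] <- expectedImprovement(sm, sqrt(sv), inc)
    }
    o <- order(-ei, costs[cand$fidelity], cand$id)
    pick <- o[1]
    oracle_pairs[[length(oracle_pairs) + 1]] <-
      c(cand$id[pick], cand$fidelity[pick])
    spent <- spent + costs[cand$fidelity[pick]]
    ## believer: condition the posterior mean as a pseudo-observation
    obs <- rbind(obs, data.frame(id = cand$id[pick],
                                 fidelity = cand$fidelity[pick],
                                 value = mom[[pick]]$mean))
    if (cand$fidelity[pick] == 3) {
      rng <- stats$max[3] - stats$min[3]
      inc <- max(inc, min(1, max(0, (mom[[pick]]$mean - stats$min[3]) / rng)))
    }
  }
  got <- planPairs(plan)
  expect_equal(nrow(got), length(oracle_pairs))
  for (i in seq_along(oracle_pairs)) {
    expect_equal(got$id[i], oracle_pairs[[i]][1])
    expect_equal(got$fidelity[i], as.integer(oracle_pairs[[i]][2]))
  }
})

test_that("fresh surrogates spend mostly at the lowest fidelity", {
  ## exploration pressure: with costs 0.01/0.2/1.0 and only the
  ## initialization observed, the modal fidelity in the plan is the lowest
  ds <- generateSyntheticLibrary(60, target_D = 0.8, target_rho = 0.5,
                                 seed = 41)
  fp <- fingerprintMatrix(ds)
  rownames(fp) <- moleculeIds(ds)
  orc <- makeOracle(ds, seed = 41)
  sched <- fidelitySchedule(budget = 1.2)
  for (s in 1:6) {
    init <- mfbo:::with_seed(s, sample(moleculeIds(ds), 4))
    obs <- data.frame(id = rep(init, each = 3), fidelity = rep(1:3, 4))
    obs$value <- queryOracle(orc, obs$id, obs$fidelity)
    sur <- fitSurrogate(obs, fp, nlev = 3, seed = s,
                        config = list(n_restarts = 2, maxit = 30))
    pl <- selectBatch(sur, moleculeIds(ds), fp, sched, seed = s)
    counts <- tabulate(planPairs(pl)$fidelity, 3)
    expect_equal(which.max(counts), 1L,
                 label = sprintf("modal fidelity at seed %d", s))
  }
})

test_that("budget breakdown reproduces the printed worked examples", {
  sched <- fidelitySchedule(budget = 100.0)
  mk <- function(n, f) new("BatchPlan",
    pairs = data.frame(id = sprintf("m%04d", seq_len(n)),
                       fidelity = rep(as.integer(f), n),
                       score = rep(NA_real_, n),
                       cost = rep(fidelityCosts(sched)[f], n)),
    totalCost = n * fidelityCosts(sched)[f], budget = 100.0, seed = 1L)
  ## 336 single-point experiments at cost 0.2 of a 100.0 budget -> 67%
  bd1 <- budgetBreakdown(mk(336, 2), sched)
  expect_equal(bd1$table$percent[2], 67)
  ## 380 docking experiments at cost 0.01 -> 4%
  bd2 <- budgetBreakdown(mk(380, 1), sched)
  expect_equal(bd2$table$percent[1], 4)
  ## empty plan -> all zero
  bd0 <- budgetBreakdown(mk(0, 1), sched)
  expect_true(all(bd0$table$percent == 0))
  expect_equal(bd0$unspent, 100.0)

  ## serialized plan carries seed, pairs and breakdown
  path <- tempfile(fileext = ".json")
  writeBatchPlan(mk(3, 3), sched, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$total_cost, 3)
  expect_equal(nrow(back$pairs), 3)
})
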
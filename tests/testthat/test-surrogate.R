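test_that("the multifidelity kernel has the product structure and is PSD", {
  fps <- random_fps(4, bits = 32, seed = 1)
  B <- diag(2)
  ## single molecule, single fidelity, B[f,f] = 1 -> [amplitude]
  K1 <- mfKernelMatrix(fps[1, , drop = FALSE], 1L, amplitude = 2.5, B = B)
  expect_equal(K1, matrix(2.5, 1, 1))
  ## B = identity: zero covariance across fidelities
  K2 <- mfKernelMatrix(fps[1:2, ], c(1L, 2L), amplitude = 1, B = B)
  expect_equal(K2[1, 2], 0)
  ## PSD of a larger mixed-fidelity matrix
  fps20 <- random_fps(20, bits = 64, seed = 9)
  L <- matrix(c(1, 0.8, 0.9, 0, 0.3, 0.2), 3, 2)
  Bfull <- tcrossprod(L) + diag(0.1, 3)
  fid <- rep(1:3, length.out = 20)
  K3 <- mfKernelMatrix(fps20, fid, amplitude = 1.3, B = Bfull)
  expect_equal(K3, t(K3))
  expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("fitting improves the marginal likelihood and respects structure", {
  fit <- tiny_surrogate(n_train = 5, seed = 3)
  sur <- fit$surrogate
  expect_s4_class(sur, "MFSurrogate")
  expect_true(validObject(sur))
  ## optimizer contract: fitted nll <= nll at the untouched initial values
  cfg <- sur@config
  obs <- sur@obs
  sim <- sur@simTrain[obs$molRow, obs$molRow]
  init0 <- c(0, rep(0.5, 3 * cfg$rank), rep(log(0.1), 3), rep(log(0.05), 3))
  nll_init <- mfbo:::mf_nll(init0, sim, obs$fidelity, obs$z, 3L, cfg$rank,
                            cfg$noise_floor)
  expect_lte(-sur@logLik, nll_init + 1e-8)
  expect_error(fitSurrogate(data.frame(), fit$fps), "at least one")

  ## correlated-fidelity evidence: duplicate molecule observed at two
  ## fidelities with identical values favors B = all-ones over identity
  fps <- fit$fps
  obs2 <- data.frame(id = rep(c("t1", "t2", "t3"), each = 2),
                     fidelity = rep(1:2, 3),
                     value = rep(c(1, -0.5, 0.2), each = 2))
  obs2$z <- obs2$value
  sim2 <- tanimotoMatrix(fps[unique(obs2$id), , drop = FALSE])
  simObs <- sim2[match(obs2$id, unique(obs2$id)),
                 match(obs2$id, unique(obs2$id))]
  pack <- function(B) {
    ## theta for rank-0-like evaluation: encode via L and diag
    c(0, as.numeric(chol_fac <- t(chol(B + diag(1e-9, 2)))[, 1:2]),
      rep(log(1e-9), 2), rep(log(0.01), 2))
  }
  nll_ones <- mfbo:::mf_nll(pack(matrix(1, 2, 2)), simObs, obs2$fidelity,
                            obs2$z, 2L, 2L, 1e-9)
  nll_iden <- mfbo:::mf_nll(pack(diag(2)), simObs, obs2$fidelity,
                            obs2$z, 2L, 2L, 1e-9)
  expect_lt(nll_ones, nll_iden)
})

test_that("posterior predictions match an independent dense-solve oracle", {
  fps <- random_fps(6, bits = 48, seed = 21)
  storage.mode(fps) <- "integer"
  rownames(fps) <- paste0("m", 1:6)
  B <- matrix(c(1, 0.7, 0.5, 0.7, 1.2, 0.8, 0.5, 0.8, 1.5), 3, 3)
  noise <- c(0.05, 0.02, 0.01)
  obs <- data.frame(id = c("m1", "m1", "m2", "m3", "m4", "m4", "m5", "m2",
                           "m3", "m5"),
                    fidelity = c(1L, 2L, 1L, 2L, 3L, 1L, 3L, 3L, 1L, 2L),
                    value = c(0.3, 0.5, -0.2, 0.1, 0.9, 0.4, -0.5, 0.2,
                              0.0, 0.6))
  sur <- manual_surrogate(obs, fps, amplitude = 1.4, B = B, noise = noise)
  for (q in list(c("m6", 3L), c("m2", 2L), c("m1", 3L), c("m4", 2L))) {
    oracle <- dense_gp_posterior(obs, fps, 1.4, B, noise, q[[1]],
                                 as.integer(q[[2]]))
    got <- predictSurrogate(sur, fps[q[[1]], , drop = FALSE],
                            as.integer(q[[2]]))
    expect_equal(got$mean, oracle$mean, tolerance = 1e-8)
    expect_equal(got$var, oracle$var, tolerance = 1e-8)
    expect_gte(got$var, 0)
  }
})

test_that("a dissimilar molecule reverts to the prior", {
  fps <- rbind(c(rep(1L, 8), rep(0L, 8)),
               c(rep(0L, 8), rep(1L, 8)))
  rownames(fps) <- c("a", "b")
  obs <- data.frame(id = "a", fidelity = 1L, value = 2.0)
  B <- matrix(1.3, 1, 1)
  sur <- manual_surrogate(obs, fps, amplitude = 2.0, B = B, noise = 0.1,
                          zmu = 0, zsd = 1)
  pr <- predictSurrogate(sur, fps["b", , drop = FALSE], 1L)
  expect_equal(pr$mean, 0)                   # prior mean (z units)
  expect_equal(pr$var, 2.0 * 1.3 + 0.1)      # amplitude*B[f,f] + noise
})

test_that("noise-floored fits interpolate their training pairs", {
  fit <- tiny_surrogate(n_train = 5, seed = 5,
                        config = list(noise_floor = 1e-8, noise_cap = 1e-8,
                                      n_restarts = 2))
  sur <- fit$surrogate
  fp <- fit$fps
  for (i in seq_len(nrow(fit$obs))) {
    pr <- predictSurrogate(sur, fp[fit$obs$id[i], , drop = FALSE],
                           fit$obs$fidelity[i])
    expect_lt(abs(pr$mean - fit$obs$value[i]), 1e-3)
  }
})

test_that("information never decreases and correlated fidelities transfer", {
  fps <- random_fps(3, bits = 32, seed = 31)
  storage.mode(fps) <- "integer"
  rownames(fps) <- c("x", "y", "z")
  noise <- c(0.05, 0.05)
  obs1 <- data.frame(id = "y", fidelity = 2L, value = 0.4)
  obs2 <- rbind(obs1, data.frame(id = "x", fidelity = 1L, value = 0.7))

  ## monotone information: adding an observation at (x, 1) cannot raise
  ## the variance at (x, 1)
  B <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  s_before <- manual_surrogate(obs1, fps, 1, B, noise)
  s_after <- manual_surrogate(obs2, fps, 1, B, noise)
  v_before <- predictSurrogate(s_before, fps["x", , drop = FALSE], 1L)$var
  v_after <- predictSurrogate(s_after, fps["x", , drop = FALSE], 1L)$var
  expect_lte(v_after, v_before + 1e-12)

  ## cross-fidelity transfer: with B = all-ones a low observation at x
  ## shrinks the high variance at x strictly more than with B = identity
  ones <- matrix(1, 2, 2) + diag(1e-6, 2)
  iden <- diag(2)
  v_ones <- predictSurrogate(manual_surrogate(obs2, fps, 1, ones, noise),
                             fps["x", , drop = FALSE], 2L)$var
  v_iden <- predictSurrogate(manual_surrogate(obs2, fps, 1, iden, noise),
                             fps["x", , drop = FALSE], 2L)$var
  expect_lt(v_ones, v_iden)
})

test_that("pool scaling follows the inverse-cost contract", {
  fit <- tiny_surrogate(n_train = 5, seed = 7)
  ds <- fit$dataset
  sched <- fidelitySchedule()                 # costs 0.01 / 0.2 / 1.0
  sc <- scaledPredictions(fit$surrogate, fingerprintMatrix(ds), sched)
  pr <- sc$pred
  for (f in 1:3) {
    sub <- pr[pr$fidelity == f, ]
    expect_equal(max(sub$scaled_mean), 1.0)   # pool max maps to 1
    expect_equal(min(sub$scaled_mean), 0.0)
    rng <- sc$stats$max[f] - sc$stats$min[f]
    expect_equal(sub$scaled_var,
                 sub$var / rng^2 / fidelityCosts(sched)[f])
  }
  ## identical raw variance at costs 0.01 and 1.0 -> scaled ratio 100
  ## (after removing the per-fidelity range normalization)
  s1 <- pr[pr$fidelity == 1, ]; s3 <- pr[pr$fidelity == 3, ]
  r1 <- sc$stats$max[1] - sc$stats$min[1]
  r3 <- sc$stats$max[3] - sc$stats$min[3]
  expect_equal((s1$scaled_var[1] * r1^2 / s1$var[1]) /
               (s3$scaled_var[1] * r3^2 / s3$var[1]), 100)
})

test_that("surrogates serialize and reload to identical predictions", {
  fit <- tiny_surrogate(n_train = 4, seed = 11)
  path <- tempfile(fileext = ".json")
  saveSurrogate(fit$surrogate, path)
  back <- loadSurrogate(path)
  fp <- fit$fps
  for (f in 1:3) {
    a <- predictSurrogate(fit$surrogate, fp, f)
    b <- predictSurrogate(back, fp, f)
    expect_equal(a$mean, b$mean, tolerance = 1e-12)
    expect_equal(a$var, b$var, tolerance = 1e-12)
  }
})
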
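## Shared fixtures: tiny deterministic molecule sets and libraries built
## in code at test time.

## a handful of small, chemically distinct molecules
tiny_smiles <- function() c(
  m1 = "CCO", m2 = "c1ccccc1", m3 = "CC(=O)O", m4 = "CCN",
  m5 = "c1ccncc1", m6 = "CCCCCC", m7 = "COc1ccccc1", m8 = "CC(C)O")

## a small LibraryDataset with hand-set ground truth (canonical
## orientation; ids t1..t8)
tiny_library <- function(high = NULL) {
  smi <- unname(tiny_smiles())
  fp <- morganFingerprints(smi)
  n <- length(smi)
  if (is.null(high)) high <- seq(4.5, 8, length.out = n)
  mfbo:::makeLibraryDataset(
    ids = paste0("t", seq_len(n)), smiles = smi, fp = fp,
    low = 0.5 * high + 1, medium = rep(NA_real_, n), high = high,
    provenance = "file")
}

## deterministic pseudo-random binary fingerprints (no chemistry needed)
random_fps <- function(n, bits = 64, density = 0.25, seed = 1) {
  mfbo:::with_seed(seed, {
    m <- matrix(as.integer(runif(n * bits) < density), n, bits)
    ## ensure no all-zero rows
    for (i in seq_len(n)) if (sum(m[i, ]) == 0) m[i, sample(bits, 3)] <- 1L
    m
  })
}

## fit a small multi-fidelity surrogate on the tiny library via the oracle
tiny_surrogate <- function(n_train = 5, seed = 1, config = list()) {
  ds <- tiny_library()
  orc <- makeOracle(ds, seed = seed)
  ids <- moleculeIds(ds)[seq_len(n_train)]
  obs <- data.frame(id = rep(ids, each = 3), fidelity = rep(1:3, n_train))
  obs$value <- queryOracle(orc, obs$id, obs$fidelity)
  fp <- fingerprintMatrix(ds)
  rownames(fp) <- moleculeIds(ds)
  list(surrogate = fitSurrogate(obs, fp, nlev = 3, seed = seed,
                                config = config),
       dataset = ds, oracle = orc, obs = obs, fps = fp)
}

## construct an MFSurrogate directly from fixed hyperparameters (no fit);
## used by oracle tests that need full control of amplitude/B/noise
manual_surrogate <- function(obs, fps, amplitude, B, noise,
                             zmu = NULL, zsd = NULL) {
  F <- nrow(B)
  molIds <- unique(obs$id)
  fps <- fps[molIds, , drop = FALSE]
  obs$molRow <- match(obs$id, molIds)
  if (is.null(zmu)) zmu <- rep(0, F)
  if (is.null(zsd)) zsd <- rep(1, F)
  obs$z <- (obs$value - zmu[obs$fidelity]) / zsd[obs$fidelity]
  simTrain <- tanimotoMatrix(fps)
  m <- nrow(obs)
  K <- amplitude * B[cbind(rep(obs$fidelity, m), rep(obs$fidelity, each = m))] *
    simTrain[obs$molRow, obs$molRow, drop = FALSE]
  diag(K) <- diag(K) + noise[obs$fidelity]
  R <- chol(K)
  alpha <- backsolve(R, backsolve(R, obs$z, transpose = TRUE))
  methods::new("MFSurrogate", molIds = molIds, fps = fps,
               simTrain = simTrain,
               obs = obs[, c("id", "molRow", "fidelity", "value", "z")],
               amplitude = amplitude, B = B, noise = noise, zmu = zmu,
               zsd = zsd, R = R, alpha = as.numeric(alpha),
               nlev = as.integer(F), logLik = NA_real_,
               config = mfbo:::default_fit_config())
}

## brute-force dense GP posterior via explicit matrix inverse -- an
## independent oracle for predictSurrogate / the conditioner
dense_gp_posterior <- function(obs, fps, amplitude, B, noise,
                               query_id, query_fid,
                               zmu = rep(0, nrow(B)), zsd = rep(1, nrow(B))) {
  molIds <- unique(obs$id)
  S <- tanimotoMatrix(fps[molIds, , drop = FALSE])
  rowOf <- match(obs$id, molIds)
  m <- nrow(obs)
  K <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    K[i, j] <- amplitude * B[obs$fidelity[i], obs$fidelity[j]] *
      S[rowOf[i], rowOf[j]]
  diag(K) <- diag(K) + noise[obs$fidelity]
  z <- (obs$value - zmu[obs$fidelity]) / zsd[obs$fidelity]
  Kinv <- solve(K)
  sq <- tanimotoMatrix(fps[query_id, , drop = FALSE],
                       fps[molIds, , drop = FALSE])
  k <- vapply(seq_len(m), function(i)
    amplitude * B[query_fid, obs$fidelity[i]] * sq[1, rowOf[i]], numeric(1))
  prior <- amplitude * B[query_fid, query_fid] + noise[query_fid]
  mean_z <- sum(k * (Kinv %*% z))
  var_z <- prior - as.numeric(t(k) %*% Kinv %*% k)
  list(mean = mean_z * zsd[query_fid] + zmu[query_fid],
       var = var_z * zsd[query_fid]^2)
}
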
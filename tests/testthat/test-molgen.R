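test_that("non-dominated sorting equals the brute-force dominance oracle", {
  expect_equal(nonDominatedSort(matrix(1, 1, 1), "max"), 1L)
  two <- rbind(c(2, 2), c(1, 1))
  expect_equal(nonDominatedSort(two, c("max", "max")), c(1L, 2L))
  expect_equal(nonDominatedSort(two, c("min", "min")), c(2L, 1L))
  expect_error(nonDominatedSort(matrix(numeric(0), 0, 1), "max"), "empty")
  expect_error(nonDominatedSort(matrix(NA_real_, 1, 1), "max"), "finite")

  ## O(n^2 k) oracle: peel fronts by explicit pairwise dominance loops
  oracle_nds <- function(X) {
    n <- nrow(X)
    dominates <- function(i, j)
      all(X[i, ] >= X[j, ]) && any(X[i, ] > X[j, ])
    rank <- integer(n)
    left <- seq_len(n); r <- 0L
    while (length(left)) {
      r <- r + 1L
      nd <- left[vapply(left, function(j)
        !any(vapply(left, function(i) i != j && dominates(i, j),
                    logical(1))), logical(1))]
      rank[nd] <- r
      left <- setdiff(left, nd)
    }
    rank
  }
  for (s in 1:4) {
    X <- mfbo:::with_seed(s, matrix(rnorm(20 * 3), 20, 3))
    dirs <- c("max", "min", "max")
    Xn <- sweep(X, 2, c(1, -1, 1), "*")
    expect_equal(nonDominatedSort(X, dirs), oracle_nds(Xn))
  }
  ## larger instance, 4 objectives
  X <- mfbo:::with_seed(9, matrix(rnorm(50 * 4), 50, 4))
  expect_equal(nonDominatedSort(X, rep("max", 4)), oracle_nds(X))
})

test_that("stochastic universal sampling keeps counts within floor/ceil", {
  ## uniform fitness, n draws = n -> every index exactly once
  expect_setequal(stochasticUniversalSampling(rep(1, 7), 7, seed = 1), 1:7)
  ## fitness {3, 1}, 4 draws -> exact counts {3, 1}
  idx <- stochasticUniversalSampling(c(3, 1), 4, seed = 2)
  expect_equal(sum(idx == 1), 3)
  expect_equal(sum(idx == 2), 1)
  ## a single positive fitness takes every draw
  expect_equal(unique(stochasticUniversalSampling(c(0, 5, 0), 6, seed = 3)),
               2L)
  expect_error(stochasticUniversalSampling(c(0, 0), 2), "all-zero")
  expect_error(stochasticUniversalSampling(c(-1, 2), 2), "nonnegative")
  ## floor/ceil property over random fitness vectors
  for (s in 1:8) {
    f <- mfbo:::with_seed(s, runif(6))
    nd <- 11
    idx <- stochasticUniversalSampling(f, nd, seed = s)
    expected <- nd * f / sum(f)
    counts <- tabulate(idx, 6)
    expect_true(all(counts >= floor(expected) & counts <= ceiling(expected)))
  }
})

test_that("reaction templates apply, refuse mismatches, and undo exactly", {
  templates <- loadTemplates()
  expect_true(all(c("amide_coupling_acid", "sulfonamide_formation") %in%
                  templates$name))
  amide <- templates[templates$name == "amide_coupling_acid", ]
  ## acetic acid + methylamine -> N-methylacetamide (parser round-trip)
  prod <- applyTemplate(amide, "CC(=O)O", "CN")
  expect_equal(prod, "CNC(C)=O")
  ## molecule without the required group -> typed no-match error
  expect_error(applyTemplate(amide, "CCCC", "CN"), class = "mfbo_no_match")
  ## undo restores the precursor canonical SMILES
  cand <- newCandidate("CC(=O)O")
  cand$steps <- list(list(template = "amide_coupling_acid", partner = "CN",
                          product = prod))
  cand$smiles <- prod
  back <- undoTemplate(cand)
  expect_equal(back$smiles, "CC(=O)O")
  expect_length(back$steps, 0)
  expect_error(undoTemplate(back), "no route step")
})

test_that("operator choice follows the molecular-weight bands", {
  ops_at <- function(mw) vapply(1:40, function(s)
    chooseOperation(mw, seed = s, p_cross = 0.2), character(1))
  expect_false("remove" %in% ops_at(80))     # below 100 Da: never remove
  expect_false("apply" %in% ops_at(600))     # above 500 Da: never apply
  mid <- ops_at(300)                          # both present mid-band
  expect_true(all(c("apply", "remove") %in% mid))
  ## determinism per seed
  expect_identical(chooseOperation(250, seed = 7),
                   chooseOperation(250, seed = 7))
})

test_that("crossover swaps route suffixes at a shared template", {
  templates <- loadTemplates()
  mk <- function(seed_smiles, tpl, partner) {
    cand <- newCandidate(seed_smiles)
    prod <- applyTemplate(templates[templates$name == tpl, ], seed_smiles,
                          partner)
    cand$steps <- list(list(template = tpl, partner = partner,
                            product = prod))
    cand$smiles <- prod
    cand$mw <- mfbo:::chem_process(prod)[[1]]$mw
    cand
  }
  c1 <- mk("CC(=O)O", "amide_coupling_acid", "CN")
  c2 <- mk("CCC(=O)O", "amide_coupling_acid", "NCc1ccccc1")
  kids <- crossoverCandidates(c1, c2, templates)
  ## partner-swapped products after replay
  expect_equal(kids[[1]]$smiles,
               applyTemplate(templates[templates$name == "amide_coupling_acid", ],
                             "CC(=O)O", "NCc1ccccc1"))
  expect_equal(kids[[2]]$smiles,
               applyTemplate(templates[templates$name == "amide_coupling_acid", ],
                             "CCC(=O)O", "CN"))
  ## identical candidates -> children identical to parents
  same <- crossoverCandidates(c1, c1, templates)
  expect_equal(same[[1]]$smiles, c1$smiles)
  ## disjoint template sets -> typed error
  c3 <- mk("CCN", "sulfonamide_formation", "CS(=O)(=O)Cl")
  expect_error(crossoverCandidates(c1, c3, templates),
               class = "mfbo_no_common_template")
})

test_that("expensive scores are amortized over cluster medoids", {
  smi <- c("CCO", "CCCO", "c1ccccc1", "Cc1ccccc1")
  fps <- morganFingerprints(smi)
  calls <- new.env(); calls$n <- 0L; calls$molecules <- character(0)
  scorer <- function(s) {
    calls$n <- calls$n + 1L
    calls$molecules <- c(calls$molecules, s)
    nchar(s)
  }
  sc <- amortizeExpensiveScore(smi, fps, scorer, k = 2, seed = 1)
  expect_length(sc, 4)
  expect_equal(calls$n, 1L)                   # one batched invocation
  expect_length(calls$molecules, 2L)          # exactly k medoids scored
  ## duplicate groups share their medoid's score
  cl <- clusterKmedoids(fps, 2)
  for (g in unique(cl$labels))
    expect_length(unique(sc[cl$labels == g]), 1)
  ## k = n degenerates to scoring every candidate directly
  sc_all <- amortizeExpensiveScore(smi, fps, function(s) nchar(s), k = 4)
  expect_equal(sc_all, nchar(smi))
  expect_error(amortizeExpensiveScore(smi, fps, scorer, k = 9), "exceeds")
})

test_that("evolution preserves elites, size, filters and route replay", {
  templates <- loadTemplates()
  blocks <- loadBuildingBlocks()
  cfg <- generationConfig(
    population = 12,
    objectives = list(
      list(name = "mw_dev", direction = "min", scorer = scorerMWTarget(300)),
      list(name = "rnd", direction = "max", scorer = scorerRandom(5))),
    n_generations = 2, seed = 7)
  gen0 <- seedPopulation(blocks, templates, cfg$population, cfg, seed = 7)
  expect_length(gen0, 12)
  st <- evolveGeneration(gen0, blocks, templates, cfg, seed = 11)
  gen1 <- st$generation
  expect_length(gen1, 12)

  ## elitism: every rank-1 candidate of generation t is in generation t+1
  elite_smiles <- vapply(gen0[st$ranks == 1], `[[`, character(1), "smiles")
  next_smiles <- vapply(gen1, `[[`, character(1), "smiles")
  expect_true(all(elite_smiles %in% next_smiles))

  ## no survivor matches the filter catalog (hydroxamate impossible)
  hits <- mfbo:::chem_match(next_smiles, unname(cfg$filters))
  expect_equal(sum(hits), 0)

  ## route replay: every candidate reconstructs its SMILES from its route
  for (cand in gen1) {
    if (!length(cand$steps)) next
    expect_equal(mfbo:::replayRoute(cand, templates), cand$smiles)
    expect_equal(cand$steps[[length(cand$steps)]]$product, cand$smiles)
  }
  ## determinism
  st2 <- evolveGeneration(gen0, blocks, templates, cfg, seed = 11)
  expect_identical(vapply(st2$generation, `[[`, character(1), "smiles"),
                   next_smiles)
})

test_that("selection pressure moves weight toward the scorer optimum", {
  templates <- loadTemplates()
  blocks <- loadBuildingBlocks()
  shift <- numeric(6)
  for (s in 1:6) {
    cfg <- generationConfig(
      population = 14,
      objectives = list(list(name = "mw_dev", direction = "min",
                             scorer = scorerMWTarget(300))),
      n_generations = 5, seed = s)
    gen <- seedPopulation(blocks, templates, cfg$population, cfg, seed = s)
    dev0 <- median(abs(vapply(gen, `[[`, numeric(1), "mw") - 300))
    for (g in seq_len(cfg$n_generations))
      gen <- evolveGeneration(gen, blocks, templates, cfg,
                              seed = mfbo:::child_seed(s, paste0("g", g)))$generation
    dev5 <- median(abs(vapply(gen, `[[`, numeric(1), "mw") - 300))
    shift[s] <- dev0 - dev5
  }
  expect_gt(mean(shift), 0)                   # mean improvement over seeds
})

test_that("pooled multi-run fronts are nondominated and deduplicated", {
  templates <- loadTemplates()
  blocks <- loadBuildingBlocks()
  cfg <- generationConfig(
    population = 10,
    objectives = list(
      list(name = "mw_dev", direction = "min", scorer = scorerMWTarget(250)),
      list(name = "rnd", direction = "max", scorer = scorerRandom(2))),
    n_generations = 2, n_independent_runs = 2, seed = 13)
  res <- runGA(blocks, templates, cfg)
  expect_length(res$runs, 2)
  front_smiles <- vapply(res$front, `[[`, character(1), "smiles")
  expect_equal(anyDuplicated(front_smiles), 0)
  expect_equal(nrow(res$front_scores), length(res$front))
  ## front members are rank 1 within the pooled candidate set
  all_smiles <- unique(unlist(lapply(res$runs, function(g)
    vapply(g, `[[`, character(1), "smiles"))))
  expect_true(all(front_smiles %in% all_smiles))
})
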
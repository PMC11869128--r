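## molgen: reaction-template genetic algorithm with non-dominated sorting
## (NDS), elitism, stochastic universal sampling (SUS), molecular-weight
## guided operator choice, substructure filtering, and amortized
## expensive scoring.  Scorers are pluggable; mock scorers are packaged
## for testing without trained property models.

#' Load a reaction-template table
#'
#' Tab-separated with columns name, reaction SMARTS (molecule = first
#' reactant, partner building block = second), arity, a compatibility
#' SMARTS for the molecule (`react1`), a SMARTS a partner block must
#' match (`react2`), and a reversible flag.  Patterns are validated at
#' load time.
#'
#' @param path template file; default: the packaged robot-amenable set
#'   (amide coupling, sulfonamide formation, reductive amination,
#'   N-alkylation, ester/urea formation, SNAr amination, imine
#'   condensation, biaryl coupling, ether formation).
#' @return data.frame of templates.
#' @export
loadTemplates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "templates_default.tsv",
                        package = "mfbo", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 6)) stopf("malformed template line")
  df <- data.frame(name = vapply(parts, `[`, "", 1),
                   smarts = vapply(parts, `[`, "", 2),
                   arity = as.integer(vapply(parts, `[`, "", 3)),
                   react1 = vapply(parts, `[`, "", 4),
                   react2 = vapply(parts, `[`, "", 5),
                   reversible = vapply(parts, `[`, "", 6) == "1",
                   stringsAsFactors = FALSE)
  ok <- chem_validate_smarts(c(df$react1, df$react2))
  if (!all(ok)) stopf("invalid template compatibility SMARTS")
  df
}

#' Load building blocks (SMILES lines)
#'
#' @param path one SMILES per line; default: the packaged block library
#'   (amines, acids, aldehydes, sulfonyl chlorides, halides, alcohols,
#'   isocyanates, boronic acids).
#' @return character vector of valid canonical SMILES.
#' @export
loadBuildingBlocks <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "building_blocks.smi",
                        package = "mfbo", mustWork = TRUE)
  smi <- trimws(readLines(path, warn = FALSE))
  smi <- smi[nzchar(smi) & !startsWith(smi, "#")]
  recs <- chem_process(smi)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  if (any(!ok)) warning(sprintf("dropping %d invalid building blocks", sum(!ok)))
  unique(vapply(recs[ok], `[[`, character(1), "canonical"))
}

## ---- candidates ---------------------------------------------------------

#' Create a route-less candidate from a SMILES
#'
#' A candidate carries its SMILES, molecular weight and a synthesis
#' route: the seed building block plus an ordered list of template
#' applications, each recording the template name, the partner block and
#' the product, so routes replay and undo exactly.
#'
#' @param smiles a valid SMILES.
#' @return a candidate list.
#' @export
newCandidate <- function(smiles) {
  r <- chem_process(smiles)[[1]]
  if (!isTRUE(r$ok)) stopf("invalid SMILES: %s", smiles)
  list(smiles = r$canonical, mw = r$mw, seed_block = r$canonical,
       steps = list())
}

candidate_template_names <- function(cand)
  vapply(cand$steps, `[[`, character(1), "template")

#' Apply a reaction template to a molecule
#'
#' Runs the template's reaction SMARTS with the molecule as first
#' reactant (plus a partner for arity-2 templates).  When several
#' products arise (multiple match sites) the first in canonical SMILES
#' order is taken (documented, stable).  A molecule that does not carry
#' the required group raises a typed `mfbo_no_match` condition.
#'
#' @param template one row of [loadTemplates()] as a list or
#'   single-row data.frame.
#' @param molecule SMILES of the molecule to transform.
#' @param partner partner block SMILES (required iff arity 2).
#' @return product SMILES.
#' @export
applyTemplate <- function(template, molecule, partner = NULL) {
  template <- as.list(template)
  if (template$arity == 2 && is.null(partner))
    stopf("template '%s' needs a partner reactant", template$name)
  reactants <- if (template$arity == 2) c(molecule, partner) else molecule
  res <- chem_react(list(list(smarts = template$smarts,
                              reactants = reactants)))[[1]]
  if (identical(res$status, "nomatch"))
    stop(structure(class = c("mfbo_no_match", "error", "condition"),
                   list(message = sprintf("template '%s' does not match %s",
                                          template$name, molecule),
                        call = sys.call())))
  if (!identical(res$status, "ok"))
    stopf("template '%s' failed on %s: %s", template$name, molecule,
          res$message %||% res$status)
  unlist(res$products)[1]
}

#' Undo the last template application of a candidate
#'
#' Routes record every intermediate product, so removing a step restores
#' the precursor exactly (canonical SMILES equality).
#'
#' @param cand a candidate.
#' @return the candidate with its last step removed.
#' @export
undoTemplate <- function(cand) {
  k <- length(cand$steps)
  if (k == 0) stopf("candidate has no route step to undo")
  cand$steps <- cand$steps[-k]
  smiles <- if (k == 1) cand$seed_block else cand$steps[[k - 1]]$product
  r <- chem_process(smiles)[[1]]
  cand$smiles <- r$canonical
  cand$mw <- r$mw
  cand
}

## replay a candidate's route from its seed block; returns SMILES or NA
replayRoute <- function(cand, templates) {
  cur <- cand$seed_block
  for (st in cand$steps) {
    tpl <- templates[templates$name == st$template, , drop = FALSE]
    if (!nrow(tpl)) return(NA_character_)
    prod <- tryCatch(applyTemplate(tpl[1, ], cur, st$partner),
                     error = function(e) NA_character_)
    if (is.na(prod)) return(NA_character_)
    cur <- prod
  }
  cur
}

#' Crossover two candidates at a shared template
#'
#' Both routes must contain a common template name; at its first
#' occurrence in each route the suffixes are swapped and both children
#' replayed from their seed blocks.  Children whose replay fails are
#' returned as failures, not errors; routes with no shared template raise
#' a typed `mfbo_no_common_template` condition.
#'
#' @param c1,c2 candidates with routes.
#' @param templates template table.
#' @return list of two elements, each either a candidate or NULL (failed
#'   replay), with attribute `shared` naming the crossover template.
#' @export
crossoverCandidates <- function(c1, c2, templates) {
  t1 <- candidate_template_names(c1)
  t2 <- candidate_template_names(c2)
  shared <- intersect(t1, t2)
  if (!length(shared))
    stop(structure(class = c("mfbo_no_common_template", "error", "condition"),
                   list(message = "no common template between routes",
                        call = sys.call())))
  tpl <- shared[1]
  i1 <- which(t1 == tpl)[1]; i2 <- which(t2 == tpl)[1]
  mk <- function(base, steps) {
    child <- base
    child$steps <- steps
    smi <- replayRoute(child, templates)
    if (is.na(smi)) return(NULL)
    r <- chem_process(smi)[[1]]
    child$smiles <- r$canonical; child$mw <- r$mw
    ## refresh recorded products along the replayed route
    cur <- child$seed_block
    for (k in seq_along(child$steps)) {
      cur <- applyTemplate(
        templates[templates$name == child$steps[[k]]$template, ][1, ],
        cur, child$steps[[k]]$partner)
      child$steps[[k]]$product <- cur
    }
    child
  }
  ## the suffix starting at the shared step (including its partner) is
  ## exchanged, so single-step routes swap partners
  out <- list(mk(c1, c(c1$steps[seq_len(i1 - 1)],
                       c2$steps[seq(i2, length(c2$steps))])),
              mk(c2, c(c2$steps[seq_len(i2 - 1)],
                       c1$steps[seq(i1, length(c1$steps))])))
  attr(out, "shared") <- tpl
  out
}

## ---- GA algebra ---------------------------------------------------------

#' Non-dominated sorting
#'
#' Pareto ranks: rank 1 = nondominated; rank r = nondominated after all
#' ranks < r are removed.  Candidate j dominates i when it is no worse in
#' every objective and strictly better in at least one, after direction
#' normalization.
#'
#' @param scores n x k score matrix.
#' @param directions character vector of "max"/"min" per objective.
#' @return integer vector of positive ranks.
#' @export
nonDominatedSort <- function(scores, directions) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n == 0) stopf("empty score matrix")
  if (ncol(scores) != length(directions))
    stopf("one direction per objective required")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  X <- sweep(scores, 2, ifelse(directions == "max", 1, -1), "*")
  ranks <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    Xr <- X[remaining, , drop = FALSE]
    nd <- vapply(seq_along(remaining), function(i) {
      ge <- Xr >= matrix(Xr[i, ], nrow(Xr), ncol(Xr), byrow = TRUE)
      gt <- Xr > matrix(Xr[i, ], nrow(Xr), ncol(Xr), byrow = TRUE)
      !any(rowSums(ge) == ncol(Xr) & rowSums(gt) > 0)
    }, logical(1))
    ranks[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  ranks
}

#' Stochastic universal sampling
#'
#' Fitness-proportional selection with a single uniformly-offset comb of
#' evenly spaced pointers over the cumulative fitness, guaranteeing each
#' index is drawn between `floor` and `ceiling` of its expected count.
#'
#' @param fitness nonnegative fitness values, not all zero.
#' @param n_draws number of draws.
#' @param seed RNG seed.
#' @return integer vector of `n_draws` indices.
#' @export
stochasticUniversalSampling <- function(fitness, n_draws, seed = 1L) {
  if (any(fitness < 0)) stopf("fitness must be nonnegative")
  total <- sum(fitness)
  if (total <= 0) stopf("all-zero fitness")
  step <- total / n_draws
  start <- with_seed(child_seed(seed, "sus"), runif(1, 0, step))
  pointers <- start + (seq_len(n_draws) - 1) * step
  cum <- cumsum(fitness)
  findInterval(pointers, cum, left.open = TRUE) + 1L
}

#' Choose a genetic operation from molecular weight
#'
#' P(apply) is proportional to `clamp((500 - mw)/400, 0, 1)` and
#' P(remove) to `clamp((mw - 100)/400, 0, 1)` (renormalized to share
#' `1 - p_cross` with a fixed crossover probability), so molecules drift
#' into the 100-500 Da band: heavy molecules shed template steps, light
#' ones grow.
#'
#' @param mw molecular weight in Da (> 0).
#' @param seed RNG seed.
#' @param p_cross crossover probability (default 0.2).
#' @return one of "apply", "remove", "crossover".
#' @export
chooseOperation <- function(mw, seed = 1L, p_cross = 0.2) {
  stopifnot(mw > 0)
  pa <- min(1, max(0, (500 - mw) / 400))
  pr <- min(1, max(0, (mw - 100) / 400))
  if (pa + pr == 0) { pa <- 1 }
  probs <- c(apply = pa / (pa + pr) * (1 - p_cross),
             remove = pr / (pa + pr) * (1 - p_cross),
             crossover = p_cross)
  with_seed(child_seed(seed, "chooseOp"),
            sample(names(probs), 1, prob = probs))
}

#' Amortize an expensive scorer over cluster medoids
#'
#' Clusters the candidates' fingerprints into k k-medoids clusters,
#' scores only the k medoid molecules, and assigns each candidate its
#' medoid's score -- the standard trick for slow structure-based scorers
#' such as docking.  A failed medoid score (NA) marks its whole cluster.
#'
#' @param smiles candidate SMILES.
#' @param fps candidate fingerprints.
#' @param scorer function(smiles vector) -> numeric.
#' @param k number of clusters (scorer evaluations).
#' @param seed RNG seed (passed to clustering).
#' @return numeric scores, one per candidate.
#' @export
amortizeExpensiveScore <- function(smiles, fps, scorer, k, seed = 1L) {
  n <- length(smiles)
  if (k > n) stopf("k exceeds number of candidates")
  cl <- clusterKmedoids(fps, k, seed = seed)
  med_scores <- scorer(smiles[cl$medoids])
  if (length(med_scores) != k) stopf("scorer returned wrong length")
  if (any(is.na(med_scores)))
    mfbo_log("scorer failed on ", sum(is.na(med_scores)), " medoid(s)")
  ## cluster labels index medoids in order
  med_of <- match(cl$labels, sort(unique(cl$labels)))
  med_scores[med_of]
}

## ---- mock scorers -------------------------------------------------------

#' Packaged mock scorers
#'
#' Lightweight objectives usable without trained property models:
#' a molecular-weight target (absolute deviation from `target` Da,
#' minimize), a drug-likeness proxy (RDKit QED, maximize), within-batch
#' diversity (one minus mean Tanimoto similarity to the other candidates,
#' maximize) and a seeded pseudo-random score for null experiments.
#' External scorers plug in as any `function(smiles) -> numeric`.
#'
#' @param target target molecular weight in Da.
#' @param seed seed of the pseudo-random scorer.
#' @return a scorer function.
#' @name mockScorers
NULL

#' @rdname mockScorers
#' @export
scorerMWTarget <- function(target = 300) {
  function(smiles) {
    recs <- chem_process(smiles)
    abs(vapply(recs, function(r) r$mw %||% NA_real_, numeric(1)) - target)
  }
}

#' @rdname mockScorers
#' @export
scorerQED <- function() {
  function(smiles) {
    recs <- chem_process(smiles)
    vapply(recs, function(r) r$qed %||% NA_real_, numeric(1))
  }
}

#' @rdname mockScorers
#' @export
scorerDiversity <- function() {
  function(smiles) {
    fps <- morganFingerprints(smiles)
    n <- nrow(fps)
    if (n < 2) return(rep(1, length(smiles)))
    S <- tanimotoMatrix(fps)
    1 - (rowSums(S) - 1) / (n - 1)
  }
}

#' @rdname mockScorers
#' @export
scorerRandom <- function(seed = 1L) {
  function(smiles)
    vapply(smiles, function(s) hash32(seed, s) / 2147483646, numeric(1),
           USE.NAMES = FALSE)
}

## ---- evolution ----------------------------------------------------------

#' Generation configuration for the genetic generator
#'
#' @param population population size (>= 2).
#' @param objectives list of objectives, each
#'   `list(name =, direction = "max"|"min", scorer = function(smiles))`.
#' @param mw_band target molecular-weight band in Da (default 100-500).
#' @param filters named SMARTS catalog every survivor must avoid
#'   (default: [defaultFilterCatalog()]).
#' @param n_generations generations per run.
#' @param n_independent_runs GA restarts whose final fronts are pooled.
#' @param p_cross crossover probability in operator choice.
#' @param seed base seed.
#' @return a validated configuration list.
#' @export
generationConfig <- function(population = 30L, objectives,
                             mw_band = c(100, 500),
                             filters = NULL, n_generations = 5L,
                             n_independent_runs = 1L, p_cross = 0.2,
                             seed = 1L) {
  stopifnot(population >= 2, mw_band[1] < mw_band[2], length(objectives) >= 1)
  if (is.null(filters)) filters <- defaultFilterCatalog()
  list(population = as.integer(population), objectives = objectives,
       mw_band = mw_band, filters = filters,
       n_generations = as.integer(n_generations),
       n_independent_runs = as.integer(n_independent_runs),
       p_cross = p_cross, seed = as.integer(seed))
}

score_population <- function(smiles, objectives) {
  S <- vapply(objectives, function(o) as.numeric(o$scorer(smiles)),
              numeric(length(smiles)))
  if (length(smiles) == 1) S <- matrix(S, nrow = 1)
  colnames(S) <- vapply(objectives, `[[`, character(1), "name")
  S
}

## batched "apply" mutation: molecule x template compatibility and
## template x block compatibility are precomputed, jobs run in one call
.batch_apply <- function(parents, templates, blocks, block_match, seed) {
  smi <- vapply(parents, `[[`, character(1), "smiles")
  compat <- chem_match(smi, templates$react1)   # n x T
  jobs <- vector("list", length(parents))
  meta <- vector("list", length(parents))
  for (i in seq_along(parents)) {
    ts <- which(compat[i, ])
    if (!length(ts)) next
    pick <- with_seed(child_seed(seed, paste0("applyT", i)), {
      t_i <- ts[sample.int(length(ts), 1)]
      part <- NA_character_
      if (templates$arity[t_i] == 2) {
        bs <- which(block_match[, t_i])
        if (!length(bs)) t_i <- NA_integer_
        else part <- blocks[bs[sample.int(length(bs), 1)]]
      }
      list(t = t_i, partner = part)
    })
    if (is.na(pick$t)) next
    reactants <- if (is.na(pick$partner)) smi[i] else c(smi[i], pick$partner)
    jobs[[i]] <- list(smarts = templates$smarts[pick$t],
                      reactants = reactants)
    meta[[i]] <- list(template = templates$name[pick$t],
                      partner = pick$partner)
  }
  have <- !vapply(jobs, is.null, logical(1))
  products <- rep(NA_character_, length(parents))
  tname <- partner <- rep(NA_character_, length(parents))
  if (any(have)) {
    res <- chem_react(jobs[have])
    hi <- which(have)
    for (j in seq_along(hi)) {
      if (identical(res[[j]]$status, "ok")) {
        products[hi[j]] <- unlist(res[[j]]$products)[1]
        tname[hi[j]] <- meta[[hi[j]]]$template
        partner[hi[j]] <- meta[[hi[j]]]$partner
      }
    }
  }
  list(product = products, template = tname, partner = partner)
}

#' Evolve one generation
#'
#' Scores the population on every objective, ranks by non-dominated
#' sorting, carries every rank-1 candidate into the next generation
#' (elitism), fills the remainder by stochastic universal sampling with
#' fitness `1 / rank`, and mutates each sampled parent by an operation
#' chosen from its molecular weight: apply a compatible template with a
#' random partner block, remove the last route step, or cross over with
#' another sampled parent sharing a template.  Children that fail
#' chemistry, parse, or the substructure filters are replaced by their
#' (already clean) parent, so the population size is preserved; if every
#' candidate is filtered out an error advises reviewing templates and
#' filters.
#'
#' @param generation list of candidates.
#' @param blocks building-block SMILES.
#' @param templates template table.
#' @param config a [generationConfig()].
#' @param seed per-generation seed.
#' @return list with `generation` (next candidates), `ranks` and
#'   `scores` of the incoming generation.
#' @export
evolveGeneration <- function(generation, blocks, templates, config,
                             seed = 1L) {
  pop <- config$population
  smi <- vapply(generation, `[[`, character(1), "smiles")
  scores <- score_population(smi, config$objectives)
  dirs <- vapply(config$objectives, `[[`, character(1), "direction")
  ranks <- nonDominatedSort(scores, dirs)

  elites <- generation[ranks == 1L]
  if (length(elites) > pop) elites <- elites[seq_len(pop)]
  n_fill <- pop - length(elites)

  children <- list()
  if (n_fill > 0) {
    idx <- stochasticUniversalSampling(1 / ranks, n_fill,
                                       seed = child_seed(seed, "sus"))
    parents <- generation[idx]
    ops <- vapply(seq_along(parents), function(i)
      chooseOperation(parents[[i]]$mw, seed = child_seed(seed, paste0("op", i)),
                      p_cross = config$p_cross), character(1))

    ## crossover first (route surgery, no new chemistry unless replayed)
    children <- vector("list", n_fill)
    for (i in which(ops == "crossover")) {
      mates <- setdiff(seq_along(parents), i)
      t_i <- candidate_template_names(parents[[i]])
      ok_mate <- mates[vapply(mates, function(j)
        length(intersect(t_i, candidate_template_names(parents[[j]]))) > 0,
        logical(1))]
      if (!length(t_i) || !length(ok_mate)) { ops[i] <- "apply"; next }
      j <- ok_mate[with_seed(child_seed(seed, paste0("mate", i)),
                             sample.int(length(ok_mate), 1))]
      kids <- tryCatch(crossoverCandidates(parents[[i]], parents[[j]],
                                           templates),
                       error = function(e) NULL)
      kid <- if (!is.null(kids) && !is.null(kids[[1]])) kids[[1]] else NULL
      if (is.null(kid)) ops[i] <- "apply" else children[[i]] <- kid
    }
    for (i in which(ops == "remove")) {
      if (length(parents[[i]]$steps) == 0) { ops[i] <- "apply"; next }
      children[[i]] <- undoTemplate(parents[[i]])
    }
    ai <- which(ops == "apply" & vapply(children, is.null, logical(1)))
    if (length(ai)) {
      block_match <- chem_match(blocks, templates$react2)
      ba <- .batch_apply(parents[ai], templates, blocks, block_match,
                         child_seed(seed, "apply"))
      recs <- chem_process(ba$product[!is.na(ba$product)])
      ri <- 0L
      for (k in seq_along(ai)) {
        i <- ai[k]
        if (is.na(ba$product[k])) { children[[i]] <- parents[[i]]; next }
        ri <- ri + 1L
        r <- recs[[ri]]
        if (!isTRUE(r$ok)) { children[[i]] <- parents[[i]]; next }
        child <- parents[[i]]
        child$steps <- c(child$steps,
                         list(list(template = ba$template[k],
                                   partner = ba$partner[k],
                                   product = r$canonical)))
        child$smiles <- r$canonical
        child$mw <- r$mw
        children[[i]] <- child
      }
    }
    ## any slot still empty (e.g. apply fallback with no compatible
    ## template) keeps its parent
    for (i in seq_len(n_fill))
      if (is.null(children[[i]])) children[[i]] <- parents[[i]]

    ## substructure filter: dirty children are replaced by their parent
    csmi <- vapply(children, `[[`, character(1), "smiles")
    rep_flag <- rep(FALSE, n_fill)
    hits <- chem_match(csmi, unname(config$filters))
    for (i in which(rowSums(hits) > 0)) {
      children[[i]] <- parents[[i]]
      rep_flag[i] <- TRUE
    }
    ## a parent that itself fails the filter is dropped entirely
    psmi <- vapply(children, `[[`, character(1), "smiles")
    hits2 <- chem_match(psmi, unname(config$filters))
    children <- children[rowSums(hits2) == 0]
  }

  nxt <- c(elites, children)
  if (!length(nxt))
    stopf("population collapse: every candidate filtered; %s",
          "review the template set and filter catalog")
  list(generation = nxt, ranks = ranks, scores = scores)
}

#' Seed an initial population from building blocks
#'
#' Random blocks receive one random compatible template application with
#' a random partner; blocks with no compatible template enter as-is.
#'
#' @param blocks building-block SMILES.
#' @param templates template table.
#' @param population population size.
#' @param config a [generationConfig()] (for filters).
#' @param seed RNG seed.
#' @return list of candidates.
#' @export
seedPopulation <- function(blocks, templates, population, config,
                           seed = 1L) {
  seeds <- with_seed(child_seed(seed, "seeds"),
                     sample(blocks, population, replace = TRUE))
  parents <- lapply(seeds, newCandidate)
  block_match <- chem_match(blocks, templates$react2)
  ba <- .batch_apply(parents, templates, blocks, block_match,
                     child_seed(seed, "seedApply"))
  out <- vector("list", population)
  good <- which(!is.na(ba$product))
  recs <- if (length(good)) chem_process(ba$product[good]) else list()
  for (k in seq_along(good)) {
    i <- good[k]; r <- recs[[k]]
    if (!isTRUE(r$ok)) next
    cand <- parents[[i]]
    cand$steps <- list(list(template = ba$template[i],
                            partner = ba$partner[i], product = r$canonical))
    cand$smiles <- r$canonical; cand$mw <- r$mw
    out[[i]] <- cand
  }
  for (i in seq_len(population)) if (is.null(out[[i]])) out[[i]] <- parents[[i]]
  smi <- vapply(out, `[[`, character(1), "smiles")
  hits <- chem_match(smi, unname(config$filters))
  clean <- out[rowSums(hits) == 0]
  if (!length(clean))
    stopf("population collapse at seeding; review blocks and filters")
  ## refill to the requested size from the clean pool
  while (length(clean) < population)
    clean <- c(clean, clean[seq_len(min(length(clean),
                                        population - length(clean)))])
  clean[seq_len(population)]
}

#' Run the genetic generator
#'
#' Runs `n_independent_runs` GA instances with distinct derived seeds for
#' `n_generations` each and pools their final nondominated fronts --
#' multiple short runs uncover more local optima than one long run and
#' accumulate fewer undesirable functionalities.
#'
#' @param blocks building-block SMILES (default packaged set).
#' @param templates template table (default packaged set).
#' @param config a [generationConfig()].
#' @return list with `front` (pooled nondominated candidates, deduplicated
#'   by SMILES), `front_scores`, and `runs` (per-run final generations).
#' @export
runGA <- function(blocks = loadBuildingBlocks(),
                  templates = loadTemplates(), config) {
  runs <- vector("list", config$n_independent_runs)
  for (r in seq_len(config$n_independent_runs)) {
    rs <- child_seed(config$seed, paste0("run", r))
    gen <- seedPopulation(blocks, templates, config$population, config,
                          seed = rs)
    for (g in seq_len(config$n_generations)) {
      st <- evolveGeneration(gen, blocks, templates, config,
                             seed = child_seed(rs, paste0("gen", g)))
      gen <- st$generation
    }
    runs[[r]] <- gen
  }
  all_cand <- do.call(c, runs)
  smi <- vapply(all_cand, `[[`, character(1), "smiles")
  keep <- !duplicated(smi)
  all_cand <- all_cand[keep]; smi <- smi[keep]
  scores <- score_population(smi, config$objectives)
  dirs <- vapply(config$objectives, `[[`, character(1), "direction")
  ranks <- nonDominatedSort(scores, dirs)
  list(front = all_cand[ranks == 1L],
       front_scores = scores[ranks == 1L, , drop = FALSE],
       runs = runs)
}
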
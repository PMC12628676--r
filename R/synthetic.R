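#' Scenario configuration for synthetic communities
#'
#' Bundles the design of a simulated lake survey: a regional OTU pool on a
#' rooted tree with Brownian niche optima, a sampling design of ecosystems x
#' years x replicates, and one of five community assembly processes governing
#' how each sample is drawn from the pool.
#'
#' Defaults mirror the motivating survey design: 11 ecosystems sampled in 4
#' years with duplicate samples, a 300-OTU regional pool, and 7,690 reads per
#' sample (the rarefaction depth).
#'
#' @param process one of `"variable_selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"drift"`.
#' @param n_otus_pool regional pool size (tips of the simulated tree).
#' @param n_ecosystems,n_years,n_replicates design dimensions (all >= 1).
#' @param reads_per_sample sequencing depth of every sample.
#' @param selection_strength niche breadth sigma (> 0) in units of the
#'   standard deviation of the tip optima; smaller is stronger selection.
#' @param trait_rate Brownian-motion variance per unit branch length for the
#'   niche optima.
#' @param trait_conservatism early-burst decay of the trait's evolutionary
#'   rate over tree depth (0 = plain Brownian motion). Positive values
#'   concentrate trait divergence at deep splits, i.e. clade-level niche
#'   conservatism, strengthening the phylogenetic signal of the optima.
#' @param pool_evenness lognormal `sdlog` of the regional relative
#'   abundances; larger is a more uneven (dominance-structured) pool.
#' @param founder_sd for `dispersal_limitation`, standard deviation of the
#'   per-ecosystem lognormal founder effect applied to the pool weights —
#'   restricted colonization lets each ecosystem's community drift to its
#'   own dominance structure.
#' @param hs_env for `homogeneous_selection`, the common environment value
#'   (standardized trait units) imposed everywhere; off-centre values select
#'   a clade-coherent niche.
#' @param niche_truncation for `homogeneous_selection`, hard niche limit in
#'   multiples of `selection_strength`: taxa beyond it get zero weight.
#' @param niche_membership for `homogeneous_selection`, fraction of the
#'   niche's member taxa that establish in each ecosystem-year (a
#'   colonization lottery within the selected clade).
#' @param fitness_flattening for `homogeneous_selection`, exponent (< 1)
#'   applied to the within-niche weights: strong selection equalizes fitness
#'   among niche members, flattening regional dominance structure.
#' @param drift_bottleneck_frac,drift_cycles for `drift`, serial bottleneck
#'   size as a fraction of `reads_per_sample`, and number of
#'   bottleneck-regrowth cycles per ecosystem-year lineage.
#' @param habitat habitat label written into the sample frame (one habitat
#'   per generated dataset; generate twice for a two-habitat design).
#' @param seed master seed; identical config + seed gives identical output.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(process = c("variable_selection", "homogeneous_selection",
                                        "dispersal_limitation", "homogenizing_dispersal",
                                        "drift"),
                            n_otus_pool = 300L, n_ecosystems = 11L, n_years = 4L,
                            n_replicates = 2L, reads_per_sample = 7690L,
                            selection_strength = 0.5, trait_rate = 1,
                            trait_conservatism = 5,
                            pool_evenness = 2, founder_sd = 2,
                            hs_env = 1.2, niche_truncation = 2,
                            niche_membership = 0.5, fitness_flattening = 0.25,
                            drift_bottleneck_frac = 0.05, drift_cycles = 5L,
                            habitat = "water", seed = 1L) {
  process <- match.arg(process)
  for (nm in c("n_otus_pool", "n_ecosystems", "n_years", "n_replicates",
               "reads_per_sample")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm)
    if (v < 1) stop("'", nm, "' must be >= 1")
  }
  if (n_otus_pool < 2) stop("'n_otus_pool' must be >= 2")
  if (selection_strength <= 0) stop("'selection_strength' must be > 0")
  if (trait_rate <= 0) stop("'trait_rate' must be > 0")
  structure(list(process = process,
                 n_otus_pool = as.integer(n_otus_pool),
                 n_ecosystems = as.integer(n_ecosystems),
                 n_years = as.integer(n_years),
                 n_replicates = as.integer(n_replicates),
                 reads_per_sample = as.integer(reads_per_sample),
                 selection_strength = selection_strength,
                 trait_rate = trait_rate,
                 trait_conservatism = trait_conservatism,
                 pool_evenness = pool_evenness,
                 founder_sd = founder_sd,
                 hs_env = hs_env,
                 niche_truncation = niche_truncation,
                 niche_membership = niche_membership,
                 fitness_flattening = fitness_flattening,
                 drift_bottleneck_frac = drift_bottleneck_frac,
                 drift_cycles = as.integer(drift_cycles),
                 habitat = habitat,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a rooted pure-birth phylogeny
#'
#' Yule (pure-birth) tree with tips labelled `OTU1..OTUn`. Deterministic
#' given the seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] tree, rooted, with branch lengths.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  stop_if_not_scalar_number(n_tips, "n_tips")
  if (n_tips < 2) stop("'n_tips' must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(as.integer(n_tips), birth = 1, death = 0)
  tree$tip.label <- paste0("OTU", seq_len(n_tips))
  check_phylogeny(tree)
}

#' Evolve a niche optimum by Brownian motion
#'
#' One continuous trait evolved from a root value of 0 with variance `rate`
#' per unit branch length, so a tip at root-to-tip distance `d` has variance
#' `rate * d` and two tips covary by the rate times their shared path length.
#'
#' @param tree rooted tree with branch lengths.
#' @param rate Brownian variance per unit branch length (> 0).
#' @param seed integer seed.
#' @return named numeric vector of tip optima.
#' @export
evolve_trait_bm <- function(tree, rate = 1, seed = 1L) {
  # star phylogenies (basal polytomies) are legitimate here, so only the
  # branch-length invariants are enforced, not rootedness
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  stop_if_not_scalar_number(rate, "rate")
  if (rate <= 0) stop("'rate' must be > 0")
  set.seed(seed)
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate), root.value = 0)
}

## early-burst rescaling of branch lengths: the trait's evolutionary rate
## decays as exp(-decay * t / depth) along time t from the root, so most
## trait divergence happens at deep splits (clade-level niche conservatism)
earlyburst_lengths <- function(tree, decay) {
  if (decay <= 0) return(tree)
  nt <- ape::node.depth.edgelength(tree)
  a <- -decay / max(nt)
  t1 <- nt[tree$edge[, 1]]
  t2 <- nt[tree$edge[, 2]]
  tree$edge.length <- (exp(a * t2) - exp(a * t1)) / a
  tree
}

## regional pool: tree + (early-burst) BM optima + lognormal abundances
build_regional_pool <- function(config) {
  tree <- simulate_tree(config$n_otus_pool,
                        seed = substream_seed(config$seed, "tree"))
  trait_tree <- earlyburst_lengths(tree, config$trait_conservatism)
  optima <- evolve_trait_bm(trait_tree, rate = config$trait_rate,
                            seed = substream_seed(config$seed, "trait"))
  set.seed(substream_seed(config$seed, "pool"))
  ab <- stats::rlnorm(config$n_otus_pool, meanlog = 0, sdlog = config$pool_evenness)
  pool <- ab / sum(ab)
  names(pool) <- tree$tip.label
  list(tree = tree, optima = optima[tree$tip.label], pool_abundance = pool)
}

#' Assemble a synthetic dataset under one assembly process
#'
#' Generates the full bundle a survey would provide: an OTU count table,
#' a sample frame (ecosystem, year, habitat, replicate, coordinates, date),
#' the regional phylogeny, and a one-variable environment table. Per sample,
#' OTU sampling weights follow the configured process:
#'
#' * `variable_selection`: Gaussian niche filtering
#'   `w_i ~ pool_i * exp(-(opt_i - env)^2 / (2 sigma^2))` with the
#'   environment differing among ecosystems (an even gradient);
#' * `homogeneous_selection`: an identical environment everywhere (`hs_env`)
#'   imposing a hard-truncated niche (`niche_truncation`), with a
#'   colonization lottery over niche members per ecosystem-year
#'   (`niche_membership`) and flattened within-niche dominance
#'   (`fitness_flattening`);
#' * `dispersal_limitation`: restricted colonization — each ecosystem's
#'   weights are the pool under an independent lognormal founder effect
#'   (`founder_sd`), so dominance structures diverge between ecosystems
#'   while selection plays no role;
#' * `homogenizing_dispersal`: every sample is a multinomial draw from the
#'   common pool;
#' * `drift`: each ecosystem-year lineage undergoes serial
#'   bottleneck-and-regrowth multinomial resampling before sampling.
#'
#' Replicates share the ecosystem-year generative state and differ only by
#' multinomial sampling noise. Counts are `multinomial(reads_per_sample, w)`.
#' Niche optima are standardized to unit variance before filtering so the
#' niche breadth `selection_strength` is comparable across tree depths.
#'
#' @param config a [scenario_config()].
#' @return list with elements `table` ([community_table()]), `meta` (sample
#'   frame), `tree` ([ape::phylo]), `env` (data.frame, rownames = sample
#'   ids), `pool` (the regional pool), and `config`.
#' @export
assemble_dataset <- function(config) {
  if (!inherits(config, "scenario_config")) stop("'config' must be a scenario_config")
  pool <- build_regional_pool(config)
  E <- config$n_ecosystems; Y <- config$n_years; R <- config$n_replicates
  reads <- config$reads_per_sample
  years <- seq(2017L, by = 2L, length.out = Y)
  ecosystems <- paste0("L", seq_len(E))
  replicates <- LETTERS[seq_len(R)]

  z <- as.numeric(scale(pool$optima))      # standardized optima
  names(z) <- names(pool$optima)
  sigma <- config$selection_strength

  ## environment per ecosystem x year (standardized trait units)
  env_grid <- matrix(0, E, Y, dimnames = list(ecosystems, as.character(years)))
  if (config$process == "homogeneous_selection") env_grid[] <- config$hs_env
  if (config$process == "variable_selection") {
    gradient <- if (E == 1) 0 else seq(-1.5, 1.5, length.out = E)
    set.seed(substream_seed(config$seed, "env"))
    jitter_y <- matrix(stats::rnorm(E * Y, 0, 0.05), E, Y)
    env_grid <- matrix(gradient, E, Y) + jitter_y
    dimnames(env_grid) <- list(ecosystems, as.character(years))
  }

  ## founder effects for dispersal limitation (per-ecosystem, years share)
  if (config$process == "dispersal_limitation") {
    founder <- lapply(seq_len(E), function(e) {
      set.seed(substream_seed(config$seed, "founder", ecosystems[e]))
      exp(stats::rnorm(config$n_otus_pool, 0, config$founder_sd))
    })
    names(founder) <- ecosystems
  }

  eco_year_weights <- function(eco, year) {
    switch(config$process,
      variable_selection = {
        env <- env_grid[eco, as.character(year)]
        w <- pool$pool_abundance * exp(-(z - env)^2 / (2 * sigma^2))
        w / sum(w)
      },
      homogeneous_selection = {
        ## identical harsh filter everywhere: hard-truncated niche around
        ## hs_env, flattened fitness within it, and a per-ecosystem-year
        ## colonization lottery over which niche members establish
        w <- (pool$pool_abundance *
                exp(-(z - config$hs_env)^2 / (2 * sigma^2)))^config$fitness_flattening
        w[abs(z - config$hs_env) > config$niche_truncation * sigma] <- 0
        window <- which(w > 0)
        if (length(window) < 3) stop("homogeneous-selection niche is empty; widen it")
        set.seed(substream_seed(config$seed, "membership", eco, year))
        keep <- sample(window, max(3L, round(config$niche_membership * length(window))))
        w[setdiff(window, keep)] <- 0
        w / sum(w)
      },
      dispersal_limitation = {
        w <- pool$pool_abundance * founder[[eco]]
        w / sum(w)
      },
      homogenizing_dispersal = pool$pool_abundance,
      drift = {
        set.seed(substream_seed(config$seed, "drift", eco, year))
        w <- pool$pool_abundance
        n_b <- max(2L, round(config$drift_bottleneck_frac * reads))
        for (k in seq_len(config$drift_cycles)) {
          b <- stats::rmultinom(1, n_b, w)[, 1]
          w <- b / sum(b)
        }
        w
      })
  }

  ## coordinates: ecosystems on a small grid near the study region
  ncol_grid <- ceiling(sqrt(E))
  eco_lat <- -62.20 + ((seq_len(E) - 1) %/% ncol_grid) * 0.010
  eco_lon <- -58.95 + ((seq_len(E) - 1) %% ncol_grid) * 0.020

  n_samples <- E * Y * R
  counts <- matrix(0L, n_samples, config$n_otus_pool,
                   dimnames = list(NULL, pool$tree$tip.label))
  meta <- data.frame(sample_id = character(n_samples), ecosystem = "",
                     year = 0L, habitat = config$habitat, replicate = "",
                     latitude = 0, longitude = 0, date = as.Date(NA),
                     stringsAsFactors = FALSE)
  env_values <- numeric(n_samples)
  row <- 0L
  for (e in seq_len(E)) for (y in seq_len(Y)) {
    w <- eco_year_weights(ecosystems[e], years[y])
    for (r in seq_len(R)) {
      row <- row + 1L
      id <- sprintf("%s_%s_%d_%s", toupper(substr(config$habitat, 1, 1)),
                    ecosystems[e], years[y], replicates[r])
      set.seed(substream_seed(config$seed, "sample", id))
      counts[row, ] <- stats::rmultinom(1, reads, w)[, 1]
      meta$sample_id[row] <- id
      meta$ecosystem[row] <- ecosystems[e]
      meta$year[row] <- years[y]
      meta$replicate[row] <- replicates[r]
      meta$latitude[row] <- eco_lat[e]
      meta$longitude[row] <- eco_lon[e]
      meta$date[row] <- as.Date(sprintf("%d-01-15", years[y])) + (e - 1L)
      env_values[row] <- env_grid[e, y]
    }
  }
  rownames(counts) <- meta$sample_id
  env <- data.frame(env1 = env_values, row.names = meta$sample_id)
  list(table = community_table(counts), meta = validate_sample_metadata(meta),
       tree = pool$tree, env = env, pool = pool, config = config)
}
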
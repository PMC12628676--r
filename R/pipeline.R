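#' Run the full assembly-process pipeline
#'
#' Orchestrates the analysis end-to-end, independently per habitat:
#' validate -> rarefy -> alpha/beta diversity (PERMANOVA on ecosystem and
#' year, group dispersion, PCoA) -> distance-decay (geographic and temporal)
#' -> spatial/temporal cores -> phylogenetic-signal gate -> null models
#' (bNTI + RCbray) -> process classification -> contribution partitioning ->
#' permutation tests between subsets.
#'
#' The configuration is a named list (or a YAML file path) with one of a
#' `scenario` block (arguments to [scenario_config()]; the demo mode),
#' `inputs` (paths: `table`, `tree`, `metadata`, `environment`), or
#' `dataset` (an in-memory list with the same four elements), plus the
#' optional settings `habitats` (default: all in the metadata),
#' `rarefaction_depth` (default `NULL` = skip), `n_null` (default 999),
#' `n_perm` (default 999), `detection` (0.001), `prevalence` (0.75),
#' `abundance_filter` (0.01, for the optima), `seed` (1), `force` (FALSE;
#' run the null models even when the signal gate fails), and `output_dir`
#' (default `NULL` = nothing written).
#'
#' @param config named list or path to a YAML config file.
#' @return a run manifest: list with per-habitat results (`diversity`,
#'   `permanova`, `dispersion`, `pcoa`, `ddr`, `cores`, `signal`, `fit`,
#'   `contributions`, `subset_tests`) plus `config` and `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::yaml.load_file(config)
  }
  cfg <- utils::modifyList(
    list(habitats = NULL, rarefaction_depth = NULL, n_null = 999L,
         n_perm = 999L, detection = 0.001, prevalence = 0.75,
         abundance_filter = 0.01, seed = 1L, force = FALSE,
         output_dir = NULL),
    config)
  seed <- as.integer(cfg$seed)

  if (!is.null(cfg$scenario)) {
    sc <- do.call(scenario_config, utils::modifyList(cfg$scenario, list(seed = seed)))
    ds <- assemble_dataset(sc)
    table <- ds$table; tree <- ds$tree; meta <- ds$meta; env <- ds$env
  } else if (!is.null(cfg$dataset)) {
    table <- as_community_table(cfg$dataset$table)
    tree <- check_phylogeny(cfg$dataset$tree)
    meta <- validate_sample_metadata(cfg$dataset$meta)
    env <- cfg$dataset$env
  } else if (!is.null(cfg$inputs)) {
    table <- load_community_table(cfg$inputs$table)
    tree <- load_phylogeny(cfg$inputs$tree)
    meta <- load_sample_metadata(cfg$inputs$metadata)
    env <- if (!is.null(cfg$inputs$environment)) {
      load_environment_table(cfg$inputs$environment)
    } else NULL
  } else {
    stop("config needs a 'scenario' block, 'inputs' paths, or a 'dataset'")
  }

  validate_dataset(table, meta, tree, strict = TRUE)
  habitats <- cfg$habitats %||% unique(meta$habitat)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  for (hab in habitats) {
    hmeta <- meta[meta$habitat == hab, ]
    htab <- as_community_table(ct_matrix(table)[hmeta$sample_id, , drop = FALSE])
    if (!is.null(cfg$rarefaction_depth)) {
      htab <- rarefy(htab, cfg$rarefaction_depth,
                     seed = substream_seed(seed, "rarefy", hab))
      hmeta <- hmeta[hmeta$sample_id %in% rownames(htab), ]
    }
    htab <- as_community_table(
      ct_matrix(htab)[, colSums(ct_matrix(htab)) > 0, drop = FALSE])

    alpha <- alpha_diversity(htab)
    hel <- hellinger(htab)
    bc <- bray_curtis(hel)
    perma <- rbind(
      permanova(bc, hmeta$ecosystem, n_perm = cfg$n_perm,
                seed = substream_seed(seed, "permanova-eco", hab),
                factor_name = "ecosystem"),
      permanova(bc, factor(hmeta$year), n_perm = cfg$n_perm,
                seed = substream_seed(seed, "permanova-year", hab),
                factor_name = "year"))
    disp <- tryCatch(
      dispersion_homogeneity(bc, hmeta$ecosystem, n_perm = cfg$n_perm,
                             seed = substream_seed(seed, "disp", hab)),
      error = function(e) NULL)
    ord <- pcoa(bc)

    pairs_all <- categorize_pairs(hmeta, unordered_pairs(hmeta$sample_id))
    ddr <- list(
      geographic = distance_decay(bc, geographic_distance(hmeta),
                                  pairs = pairs_all[pairs_all$category ==
                                                      "inter_lake_same_year", ],
                                  n_perm = cfg$n_perm,
                                  seed = substream_seed(seed, "ddr-geo", hab)),
      temporal = distance_decay(bc, temporal_distance(hmeta),
                                pairs = pairs_all[pairs_all$category ==
                                                    "inter_year_same_lake", ],
                                n_perm = cfg$n_perm,
                                seed = substream_seed(seed, "ddr-time", hab)))

    cores <- list(
      overall = core_members(htab, cfg$prevalence, cfg$detection),
      spatial = lapply(sort(unique(hmeta$year)), function(y)
        spatial_core(htab, hmeta, y, cfg$prevalence, cfg$detection)),
      temporal = lapply(sort(unique(hmeta$ecosystem)), function(e)
        temporal_core(htab, hmeta, e, cfg$prevalence, cfg$detection)))

    signal <- NULL
    gate_ok <- TRUE
    if (!is.null(env)) {
      signal <- tryCatch({
        ab <- filter_abundant(htab, cfg$abundance_filter, mode = "any_sample")
        opt <- cca_optima(ab, env[rownames(ct_matrix(ab)), , drop = FALSE],
                          n_perm = cfg$n_perm,
                          seed = substream_seed(seed, "cca", hab))
        if (opt$status != "ok") {
          list(optima = opt, correlogram = NULL, gate = FALSE)
        } else {
          corr <- mantel_correlogram(opt, tree, n_perm = cfg$n_perm,
                                     seed = substream_seed(seed, "correlog", hab))
          list(optima = opt, correlogram = corr, gate = signal_gate(corr))
        }
      }, error = function(e) list(optima = NULL, correlogram = NULL,
                                  gate = FALSE, error = conditionMessage(e)))
      gate_ok <- isTRUE(signal$gate)
    }
    if (!gate_ok && !isTRUE(cfg$force)) {
      stop("phylogenetic-signal gate failed for habitat '", hab,
           "': no significant positive short-distance class; ",
           "rerun with force = TRUE to proceed regardless")
    }

    fit <- assembly_fit(htab, tree, meta = hmeta, n_null = cfg$n_null,
                        seed = substream_seed(seed, "fit", hab))
    contrib <- summary(fit)
    tests <- subset_tests(fit)

    if (!is.null(out_dir)) {
      write_habitat_outputs(out_dir, hab, alpha, perma, fit, contrib, tests)
    }
    results[[hab]] <- list(diversity = alpha, permanova = perma,
                           dispersion = disp, pcoa = ord, ddr = ddr,
                           cores = cores, signal = signal, fit = fit,
                           contributions = contrib, subset_tests = tests)
  }
  manifest <- list(habitats = results, seed = seed, config = cfg,
                   n_samples = nrow(table), n_otus = ncol(table))
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(seed = seed,
                              habitats = habitats,
                              n_samples = nrow(table), n_otus = ncol(table)),
                         file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(manifest)
}

## pairwise permutation tests of each process between comparison subsets
subset_tests <- function(fit, n_perm = 1000L) {
  subsets <- c("intra_lake", "inter_lake_same_year", "inter_year_same_lake")
  per_type <- lapply(subsets, function(s) {
    tryCatch(attr(contributions(fit$pairs, s), "per_type"),
             error = function(e) NULL)
  })
  names(per_type) <- subsets
  combos <- utils::combn(subsets, 2)
  out <- list()
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    if (is.null(per_type[[a]]) || is.null(per_type[[b]])) next
    for (proc in colnames(per_type[[a]])) {
      tst <- subset_permutation_test(per_type[[a]][, proc], per_type[[b]][, proc],
                                     n_perm = n_perm,
                                     seed = substream_seed(fit$seed, "subset-test",
                                                           a, b, proc))
      out[[length(out) + 1L]] <- data.frame(subset_a = a, subset_b = b,
                                            process = proc,
                                            statistic = tst$statistic,
                                            p_value = tst$p_value,
                                            exact = tst$exact,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

write_habitat_outputs <- function(out_dir, hab, alpha, perma, fit, contrib, tests) {
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(hab, "_", name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(alpha, "alpha_diversity")
  w(perma, "permanova")
  w(fit$pairs, "pairs")
  w(as.data.frame(unclass(contrib)), "contributions")
  if (!is.null(tests)) {
    jsonlite::write_json(tests, file.path(out_dir, paste0(hab, "_subset_tests.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
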
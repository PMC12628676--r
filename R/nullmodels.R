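## ---- beta MNTD / beta NTI ---------------------------------------------

## Core kernel: betaMNTD for all sample pairs given a relative-abundance
## matrix (samples x taxa, zeros for absent taxa, rows summing to 1) and a
## cophenetic distance matrix in the same taxon order.
##
## For pair (k, m):
##   betaMNTD = 1/2 [ sum_i f_ik min_{j in m} d_ij + sum_j f_jm min_{i in k} d_ij ]
## Computed via M[i, m] = min_{j present in m} d_ij, so the pair matrix is
## (F M + (F M)') / 2 with F the abundance matrix.
beta_mntd_kernel <- function(f, d) {
  n_taxa <- ncol(f)
  n_samp <- nrow(f)
  pres <- f > 0
  M <- matrix(0, n_taxa, n_samp)
  for (m in seq_len(n_samp)) {
    cols <- which(pres[m, ])
    v <- d[, cols[1L]]
    for (cc in cols[-1L]) v <- pmin(v, d[, cc])
    M[, m] <- v
  }
  A <- f %*% M
  bm <- 0.5 * (A + t(A))
  dimnames(bm) <- list(rownames(f), rownames(f))
  bm
}

## samples x taxa relative abundances (weighted) or 1/richness (unweighted)
relabund_matrix <- function(m, weighted) {
  if (weighted) {
    sweep(m, 1, rowSums(m), "/")
  } else {
    p <- (m > 0) * 1
    sweep(p, 1, rowSums(p), "/")
  }
}

#' Between-community mean nearest-taxon distance
#'
#' For each pair of samples, the abundance-weighted mean phylogenetic
#' (cophenetic) distance from every taxon in one community to its nearest
#' relative in the other, averaged over both directions. Taxa shared between
#' the two communities contribute a distance of zero. With
#' `weighted = FALSE`, taxa are weighted 1/richness instead of by relative
#' abundance.
#'
#' @param table a [community_table()].
#' @param tree rooted phylogeny whose tips cover all OTUs with nonzero
#'   counts.
#' @param weighted abundance-weighted (default) or presence-based weighting.
#' @return symmetric matrix of betaMNTD values (tree branch-length units).
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  table <- as_community_table(table)
  check_phylogeny(tree)
  m <- ct_matrix(table)
  if (any(rowSums(m) == 0)) {
    stop("empty communities: ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  used <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing)) stop("OTUs missing from tree: ", paste(missing, collapse = ", "))
  m <- m[, used, drop = FALSE]
  d <- stats::cophenetic(ape::keep.tip(tree, used))[used, used]
  beta_mntd_kernel(relabund_matrix(m, weighted), d)
}

#' Beta nearest-taxon index
#'
#' Standardized effect size of [beta_mntd()] against a taxa-shuffle null: in
#' each null replicate the taxa are reassigned uniformly at random to tip
#' positions of the phylogeny (one permutation per replicate, applied to all
#' pairs) and betaMNTD is recomputed. bNTI = (observed - null mean) / null
#' SD. Pairs with a null SD below `1e-12` (e.g. identical communities) are
#' flagged `degenerate` with `beta_nti = NA`.
#'
#' The taxon pool over which labels are shuffled is, by default, the full
#' set of tree tips (`null_pool = "tree"`): the tree defines the regional
#' species pool. When the tree was inferred from exactly the observed OTUs
#' the choice is immaterial; `null_pool = "table"` restricts the shuffle to
#' taxa observed in the table.
#'
#' @inheritParams beta_mntd
#' @param n_null number of null replicates (>= 99).
#' @param seed integer seed.
#' @param null_pool shuffle taxa across all tree tips (`"tree"`, default) or
#'   only across taxa present in the table (`"table"`).
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti`,
#'   `n_null`, `degenerate`.
#' @export
beta_nti <- function(table, tree, n_null = 999L, seed = 1L, weighted = TRUE,
                     null_pool = c("tree", "table")) {
  null_pool <- match.arg(null_pool)
  if (n_null < 99) stop("'n_null' must be >= 99")
  table <- as_community_table(table)
  check_phylogeny(tree)
  m <- ct_matrix(table)
  if (any(rowSums(m) == 0)) {
    stop("empty communities: ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  used <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing)) stop("OTUs missing from tree: ", paste(missing, collapse = ", "))
  m <- m[, used, drop = FALSE]
  f <- relabund_matrix(m, weighted)
  if (null_pool == "tree") {
    dfull <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
    idx_obs <- match(used, tree$tip.label)
    n_pool <- length(tree$tip.label)
  } else {
    dfull <- stats::cophenetic(ape::keep.tip(tree, used))[used, used]
    idx_obs <- seq_along(used)
    n_pool <- length(used)
  }
  obs <- beta_mntd_kernel(f, dfull[idx_obs, idx_obs])
  n_used <- length(used)
  sum1 <- matrix(0, nrow(m), nrow(m))
  sum2 <- matrix(0, nrow(m), nrow(m))
  set.seed(substream_seed(seed, "bnti"))
  for (r in seq_len(n_null)) {
    perm <- sample.int(n_pool, n_used)
    bm <- beta_mntd_kernel(f, dfull[perm, perm])
    sum1 <- sum1 + bm
    sum2 <- sum2 + bm^2
  }
  null_mean <- sum1 / n_null
  null_var <- pmax(sum2 / n_null - null_mean^2, 0) * n_null / (n_null - 1)
  null_sd <- sqrt(null_var)
  pairs <- unordered_pairs(rownames(m))
  pairs$beta_mntd_obs <- pairs_from_matrix(obs, pairs)
  pairs$null_mean <- pairs_from_matrix(null_mean, pairs)
  pairs$null_sd <- pairs_from_matrix(null_sd, pairs)
  pairs$degenerate <- pairs$null_sd < 1e-12
  pairs$beta_nti <- ifelse(pairs$degenerate, NA_real_,
                           (pairs$beta_mntd_obs - pairs$null_mean) / pairs$null_sd)
  pairs$n_null <- as.integer(n_null)
  pairs[, c("sample_i", "sample_j", "beta_mntd_obs", "null_mean", "null_sd",
            "beta_nti", "n_null", "degenerate")]
}

## ---- Raup-Crick (Bray-Curtis) -----------------------------------------

## One null community: draw `richness` taxa without replacement with
## probability proportional to occupancy, seed each with one read, then
## allocate the remaining reads multinomially by pooled relative abundance
## restricted to the drawn taxa.
null_community <- function(richness, reads, occupancy, pool_rel) {
  p <- length(occupancy)
  idx <- sample.int(p, richness, prob = occupancy)
  cnt <- numeric(p)
  cnt[idx] <- 1
  extra <- reads - richness
  if (extra > 0) {
    cnt[idx] <- cnt[idx] + stats::rmultinom(1, extra, pool_rel[idx])[, 1]
  }
  cnt
}

#' Raup-Crick dissimilarity with Bray-Curtis
#'
#' For each unordered sample pair, compares the observed Bray-Curtis
#' dissimilarity to a null distribution in which both communities are
#' reassembled from the regional pool: each null community draws the observed
#' richness of taxa without replacement with probability proportional to
#' occupancy (fraction of samples containing the taxon), seeds each drawn
#' taxon with one read, and allocates the remaining reads multinomially in
#' proportion to pooled relative abundance restricted to the drawn taxa.
#' With `RC_raw = (#\{null < obs\} + 0.5 #\{null = obs\}) / n_null` (ties
#' within `1e-12`), the index is `RCbray = 2 (RC_raw - 1/2)`, in [-1, 1].
#'
#' Null replicate streams are seeded per unordered pair from the sorted
#' sample ids, so results are order-independent and symmetric.
#'
#' @param table a [community_table()]; the pool (occupancy and pooled
#'   abundances) is computed over all its samples.
#' @param n_null null replicates per pair (>= 99).
#' @param seed master integer seed.
#' @param pairs optional data.frame (`sample_i`, `sample_j`) restricting
#'   computation to those pairs; default all unordered pairs.
#' @return data.frame with `sample_i`, `sample_j`, `bc_obs`, `rc_bray`,
#'   `n_null`.
#' @export
raup_crick_bray <- function(table, n_null = 999L, seed = 1L, pairs = NULL) {
  if (n_null < 99) stop("'n_null' must be >= 99")
  table <- as_community_table(table)
  m <- ct_matrix(table)
  if (any(rowSums(m) == 0)) {
    stop("empty communities: ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  occupancy <- colMeans(m > 0)
  pool_rel <- colSums(m) / sum(as.numeric(m))
  pool_size <- sum(occupancy > 0)
  richness <- rowSums(m > 0)
  reads <- rowSums(m)
  if (any(richness > pool_size)) stop("community richness exceeds pool size")
  if (is.null(pairs)) pairs <- unordered_pairs(rownames(m))
  bcm <- bray_curtis(m)
  out <- pairs
  out$bc_obs <- pairs_from_matrix(bcm, pairs)
  out$rc_bray <- rep(NA_real_, nrow(out))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$sample_i[k]; b <- pairs$sample_j[k]
    set.seed(pair_seed(seed, a, b))
    ## regenerate in sorted-id order so the draw is order-independent
    ids <- sort(c(a, b))
    nulls <- numeric(n_null)
    for (r in seq_len(n_null)) {
      c1 <- null_community(richness[ids[1]], reads[ids[1]], occupancy, pool_rel)
      c2 <- null_community(richness[ids[2]], reads[ids[2]], occupancy, pool_rel)
      nulls[r] <- bc_pair(c1, c2)
    }
    obs <- out$bc_obs[k]
    rc_raw <- (sum(nulls < obs - 1e-12) + 0.5 * sum(abs(nulls - obs) <= 1e-12)) / n_null
    out$rc_bray[k] <- 2 * (rc_raw - 0.5)
  }
  out$n_null <- rep(as.integer(n_null), nrow(out))
  out
}

## ---- process classification -------------------------------------------

#' Classify a sample pair into an assembly process
#'
#' Threshold rules of the two-step null-model framework, with strict
#' inequalities: `bNTI < -2` homogeneous selection; `bNTI > +2` variable
#' selection; otherwise `RCbray > +0.95` dispersal limitation,
#' `RCbray < -0.95` homogenizing dispersal, and anything in between
#' ecological drift. Degenerate bNTI (null SD = 0) yields `undetermined`.
#'
#' @param beta_nti numeric vector of bNTI values (`NA` = degenerate).
#' @param rc_bray numeric vector of RCbray values, aligned with `beta_nti`
#'   (may be `NA` where `|bNTI| > 2` since it is then unused).
#' @return factor with levels `variable_selection`, `homogeneous_selection`,
#'   `dispersal_limitation`, `homogenizing_dispersal`, `drift`,
#'   `undetermined`.
#' @export
classify_process <- function(beta_nti, rc_bray) {
  if (length(beta_nti) != length(rc_bray)) {
    stop("beta_nti and rc_bray must have the same length")
  }
  lev <- c("variable_selection", "homogeneous_selection", "dispersal_limitation",
           "homogenizing_dispersal", "drift", "undetermined")
  out <- rep("undetermined", length(beta_nti))
  sel_lo <- !is.na(beta_nti) & beta_nti < -2
  sel_hi <- !is.na(beta_nti) & beta_nti > 2
  stoch <- !is.na(beta_nti) & !sel_lo & !sel_hi
  out[sel_lo] <- "homogeneous_selection"
  out[sel_hi] <- "variable_selection"
  need_rc <- stoch & is.na(rc_bray)
  if (any(need_rc)) stop("RCbray missing for stochastic pair(s)")
  out[stoch & rc_bray > 0.95] <- "dispersal_limitation"
  out[stoch & rc_bray < -0.95] <- "homogenizing_dispersal"
  out[stoch & rc_bray >= -0.95 & rc_bray <= 0.95] <- "drift"
  factor(out, levels = lev)
}

#' Fit assembly processes to a community dataset
#'
#' The central estimator: runs the phylogenetic null model ([beta_nti()]) and
#' the taxonomic null model ([raup_crick_bray()]) over all unordered sample
#' pairs and classifies each pair into one of the five assembly processes
#' ([classify_process()]). When sample metadata are supplied, each pair is
#' also assigned its comparison category and replicate-combination type
#' ([categorize_pairs()]), enabling [summary.assembly_fit()] to partition
#' process contributions across spatial/temporal/replicate subsets.
#'
#' @param table a [community_table()] (one habitat; habitats are analyzed
#'   independently).
#' @param tree rooted phylogeny covering the table's OTUs.
#' @param meta optional sample metadata (see [validate_sample_metadata()]).
#' @param n_null null replicates for both null models (>= 99).
#' @param seed master integer seed.
#' @param weighted abundance-weighted betaMNTD (default) or presence-based.
#' @param rc_pairs `"needed"` computes RCbray only for pairs not already
#'   classified as selection by bNTI (labels are unchanged; faster);
#'   `"all"` computes it for every pair.
#' @param null_pool taxon pool for the betaMNTD null; see [beta_nti()].
#' @return object of class `assembly_fit`: a list with `pairs` (one row per
#'   unordered pair: ids, betaMNTD and null moments, bNTI, BC, RCbray,
#'   process, category, replicate combo), `n_null`, `seed`, `weighted`,
#'   `n_samples`, and the `call`.
#' @seealso [summary.assembly_fit()], [contributions()],
#'   [subset_permutation_test()]
#' @export
assembly_fit <- function(table, tree, meta = NULL, n_null = 999L, seed = 1L,
                         weighted = TRUE, rc_pairs = c("needed", "all"),
                         null_pool = c("tree", "table")) {
  rc_pairs <- match.arg(rc_pairs)
  table <- as_community_table(table)
  bn <- beta_nti(table, tree, n_null = n_null, seed = seed, weighted = weighted,
                 null_pool = match.arg(null_pool))
  stoch <- bn$degenerate == FALSE & abs(bn$beta_nti) <= 2
  rc_subset <- if (rc_pairs == "all") NULL else bn[stoch, c("sample_i", "sample_j")]
  rc <- raup_crick_bray(table, n_null = n_null, seed = seed, pairs = rc_subset)
  key <- function(df) paste(df$sample_i, df$sample_j, sep = "\r")
  idx <- match(key(bn), key(rc))
  bn$bc_obs <- rc$bc_obs[idx]
  bn$rc_bray <- rc$rc_bray[idx]
  if (rc_pairs == "needed") {
    ## BC itself is cheap and part of the record; fill it for all pairs
    bcm <- bray_curtis(table)
    bn$bc_obs <- pairs_from_matrix(bcm, bn)
  }
  rc_for_class <- ifelse(stoch, bn$rc_bray, 0)
  bn$process <- classify_process(ifelse(bn$degenerate, NA_real_, bn$beta_nti),
                                 ifelse(stoch, bn$rc_bray, rc_for_class))
  if (!is.null(meta)) {
    meta <- validate_sample_metadata(meta)
    cat_df <- categorize_pairs(meta, bn[, c("sample_i", "sample_j")])
    bn$category <- cat_df$category
    bn$replicate_combo <- cat_df$replicate_combo
  }
  structure(list(pairs = bn, n_null = as.integer(n_null), seed = as.integer(seed),
                 weighted = weighted, n_samples = nrow(table),
                 call = match.call()),
            class = "assembly_fit")
}

#' @export
print.assembly_fit <- function(x, ...) {
  cat("Community assembly process fit\n")
  cat(sprintf("  %d samples, %d pairs, %d null replicates (seed %d)\n",
              x$n_samples, nrow(x$pairs), x$n_null, x$seed))
  tab <- table(x$pairs$process)
  pct <- 100 * tab / sum(tab)
  for (nm in names(tab)) {
    if (tab[nm] > 0) cat(sprintf("  %-24s %5d pairs (%.1f%%)\n", nm, tab[nm], pct[nm]))
  }
  invisible(x)
}

#' Summarize an assembly fit by comparison subset
#'
#' Partitions the classified pairs into the four comparison subsets (all,
#' intra-lake, inter-lake same year, inter-year same lake) and computes the
#' relative contribution of each process per subset, averaged across
#' replicate-combination comparison types (see [contributions()]).
#'
#' @param object an [assembly_fit()] with metadata-annotated pairs.
#' @param subsets subsets to summarize.
#' @param ... unused.
#' @return data.frame of class `summary.assembly_fit` with columns `subset`,
#'   `process`, `mean_percent`, `sd_percent`, `ci95_halfwidth`, `n_types`,
#'   `n_pairs`.
#' @export
summary.assembly_fit <- function(object,
                                 subsets = c("all", "intra_lake",
                                             "inter_lake_same_year",
                                             "inter_year_same_lake"), ...) {
  if (is.null(object$pairs$category)) {
    stop("fit has no comparison categories; refit with sample metadata")
  }
  res <- do.call(rbind, lapply(subsets, function(s) {
    tryCatch(contributions(object$pairs, subset = s),
             error = function(e) NULL)
  }))
  class(res) <- c("summary.assembly_fit", class(res))
  res
}

#' @export
print.summary.assembly_fit <- function(x, ...) {
  cat("Assembly process contributions (mean % across comparison types)\n")
  for (s in unique(x$subset)) {
    cat("\n ", s, "\n")
    sub <- x[x$subset == s, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("   %-24s %6.1f%% (sd %5.1f, n_pairs %d)\n",
                  sub$process[i], sub$mean_percent[i], sub$sd_percent[i],
                  sub$n_pairs[i]))
    }
  }
  invisible(x)
}

#' Plot process contributions of an assembly fit
#'
#' Stacked bars of the mean relative contribution of each assembly process
#' per comparison subset.
#'
#' @param x an [assembly_fit()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.assembly_fit <- function(x, ...) {
  s <- summary(x)
  processes <- c("variable_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  subsets <- unique(s$subset)
  mat <- sapply(subsets, function(ss) {
    v <- s$mean_percent[match(processes, s$process[s$subset == ss])]
    v[is.na(v)] <- 0
    v
  })
  rownames(mat) <- processes
  graphics::barplot(mat, col = c("#d95f02", "#e6ab02", "#7570b3", "#1b9e77", "#666666"),
                    ylab = "mean contribution (%)", legend.text = processes,
                    args.legend = list(x = "topright", cex = 0.6, bty = "n"), ...)
  invisible(mat)
}
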
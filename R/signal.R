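#' Keep abundant OTUs
#'
#' Retains OTUs whose within-sample relative abundance exceeds `threshold`
#' (strict >) in at least one sample (`"any_sample"`, default) or in every
#' sample (`"every_sample"`).
#'
#' @param table a [community_table()].
#' @param threshold fraction in (0, 1), e.g. 0.01 for a 1% cut.
#' @param mode `"any_sample"` or `"every_sample"`.
#' @return filtered [community_table()].
#' @export
filter_abundant <- function(table, threshold = 0.01,
                            mode = c("any_sample", "every_sample")) {
  table <- as_community_table(table)
  mode <- match.arg(mode)
  stop_if_not_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  m <- ct_matrix(table)
  rel <- sweep(m, 1, pmax(rowSums(m), 1), "/")
  keep <- if (mode == "any_sample") {
    apply(rel, 2, max) > threshold
  } else {
    apply(rel, 2, min) > threshold
  }
  if (!any(keep)) {
    stop("no OTU passes the abundance filter; lower the threshold")
  }
  community_table(m[, keep, drop = FALSE])
}

#' Environmental optima of OTUs
#'
#' Estimates per-OTU niche optima either as OTU scores on the first
#' significant axis of a canonical correspondence analysis (CCA) constrained
#' by the environmental variables (`method = "cca_axis1"`), or as
#' abundance-weighted means of an environmental variable
#' (`method = "abundance_weighted_mean"`, a fallback when no CCA axis is
#' significant). Global and per-axis significance use permutation tests; the
#' first axis with p < `alpha` supplies the scores.
#'
#' @param table a [community_table()] (typically pre-filtered with
#'   [filter_abundant()]).
#' @param env data.frame of numeric environmental variables, rownames =
#'   sample ids covering the table's samples.
#' @param n_perm permutations for the CCA significance tests.
#' @param seed integer seed.
#' @param alpha significance level for axis selection.
#' @param method optimum estimator.
#' @return list of class `niche_optima` with `otu_ids`, `optima`, `method`,
#'   `axis` (CCA axis used or `NA`), `p_model`, `p_axis`, and `status`
#'   (`"ok"` or `"no_signal_basis"`, the latter with `optima = NULL` unless a
#'   fallback was computed).
#' @export
cca_optima <- function(table, env, n_perm = 999L, seed = 1L, alpha = 0.05,
                       method = c("cca_axis1", "abundance_weighted_mean")) {
  table <- as_community_table(table)
  method <- match.arg(method)
  m <- ct_matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 samples and 2 OTUs")
  env <- as.data.frame(env)[rownames(m), , drop = FALSE]
  if (any(is.na(env))) stop("environment table has missing values for the table's samples")
  const <- vapply(env, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    stop("constant environmental variable(s): ",
         paste(names(env)[const], collapse = ", "))
  }
  if (method == "abundance_weighted_mean") {
    rel <- sweep(m, 1, rowSums(m), "/")
    opt <- as.numeric(crossprod(rel, env[[1]]) / colSums(rel))
    return(structure(list(otu_ids = colnames(m), optima = stats::setNames(opt, colnames(m)),
                          method = method, axis = NA_integer_,
                          p_model = NA_real_, p_axis = NA_real_, status = "ok"),
                     class = "niche_optima"))
  }
  fit <- vegan::cca(m ~ ., data = env)
  if (any(is.na(fit$CCA$eig))) stop("rank-deficient constraints")
  set.seed(substream_seed(seed, "cca-global"))
  p_model <- stats::anova(fit, permutations = n_perm)$`Pr(>F)`[1]
  set.seed(substream_seed(seed, "cca-axis"))
  ax <- stats::anova(fit, by = "axis", permutations = n_perm)
  p_axis <- ax$`Pr(>F)`[seq_len(length(fit$CCA$eig))]
  sig <- which(p_axis < alpha)
  if (!length(sig)) {
    return(structure(list(otu_ids = colnames(m), optima = NULL,
                          method = method, axis = NA_integer_,
                          p_model = p_model, p_axis = p_axis,
                          status = "no_signal_basis"),
                     class = "niche_optima"))
  }
  axis <- sig[1]
  sc <- vegan::scores(fit, display = "species", choices = axis, scaling = "species")
  structure(list(otu_ids = colnames(m),
                 optima = stats::setNames(as.numeric(sc), colnames(m)),
                 method = method, axis = axis,
                 p_model = p_model, p_axis = p_axis, status = "ok"),
            class = "niche_optima")
}

#' Mantel correlogram of niche optima against phylogenetic distance
#'
#' Tests the phylogenetic-signal prerequisite of the null-model framework:
#' Pearson Mantel correlations between pairwise differences in environmental
#' optima (|opt_i - opt_j|) and cophenetic phylogenetic distances, in
#' equal-width distance classes (default 30), with permutation p-values and a
#' progressive Bonferroni correction applied in order of increasing distance.
#' A significant positive correlation in the shortest classes indicates that
#' closely related OTUs have similar optima.
#'
#' @param optima a `niche_optima` object (from [cca_optima()]) or a named
#'   numeric vector of per-OTU optima.
#' @param tree rooted tree whose tips include the optima's OTUs.
#' @param n_classes number of distance classes (>= 2).
#' @param n_perm permutations per class.
#' @param seed integer seed.
#' @return data.frame of class `mantel_correlogram` with one row per class:
#'   `class_index`, `class_midpoint`, `n_dist`, `mantel_r`, `p_raw`,
#'   `p_corrected`, `significant`.
#' @export
mantel_correlogram <- function(optima, tree, n_classes = 30L, n_perm = 999L,
                               seed = 1L) {
  if (inherits(optima, "niche_optima")) {
    if (is.null(optima$optima)) stop("optima carry no signal basis (no significant axis)")
    opt <- optima$optima
  } else {
    opt <- optima
  }
  if (is.null(names(opt))) stop("optima must be named by OTU id")
  if (length(opt) < 3) stop("need at least 3 OTUs")
  if (n_classes < 2) stop("'n_classes' must be >= 2")
  check_phylogeny(tree)
  missing <- setdiff(names(opt), tree$tip.label)
  if (length(missing)) {
    stop("optima OTUs missing from tree: ", paste(missing, collapse = ", "))
  }
  coph <- stats::cophenetic(ape::keep.tip(tree, names(opt)))[names(opt), names(opt)]
  d_opt <- stats::dist(opt)
  d_phy <- stats::as.dist(coph)
  if (stats::sd(d_opt) == 0) {
    # identical optima: the Mantel statistic is undefined in every class;
    # report untestable classes rather than crash
    breaks <- seq(min(d_phy), max(d_phy), length.out = n_classes + 1)
    mids <- (breaks[-1] + breaks[-(n_classes + 1)]) / 2
    out <- data.frame(class_index = seq_len(n_classes), class_midpoint = mids,
                      n_dist = as.integer(table(cut(d_phy, breaks,
                                                    include.lowest = TRUE))),
                      mantel_r = NA_real_, p_raw = NA_real_,
                      p_corrected = NA_real_, significant = FALSE)
    class(out) <- c("mantel_correlogram", class(out))
    return(out)
  }
  set.seed(seed)
  mc <- vegan::mantel.correlog(d_opt, D.geo = d_phy, n.class = n_classes,
                               cutoff = FALSE, r.type = "pearson",
                               nperm = n_perm, mult = "bonferroni",
                               progressive = TRUE)
  tab <- as.data.frame(mc$mantel.res)
  out <- data.frame(class_index = seq_len(nrow(tab)),
                    class_midpoint = tab$class.index,
                    n_dist = tab$n.dist,
                    mantel_r = tab$Mantel.cor,
                    p_raw = tab$`Pr(Mantel)`,
                    p_corrected = tab$`Pr(corrected)`,
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_corrected) & out$p_corrected < 0.05
  class(out) <- c("mantel_correlogram", class(out))
  out
}

#' Phylogenetic-signal gate
#'
#' The null-model stage should only run when closely related taxa have
#' similar niche optima. The gate passes when at least one of the
#' `n_short` shortest distance classes with a testable correlation is
#' significantly positive after progressive Bonferroni correction.
#'
#' @param correlogram a [mantel_correlogram()] result.
#' @param n_short how many of the shortest classes to inspect.
#' @return logical.
#' @export
signal_gate <- function(correlogram, n_short = 3L) {
  tested <- correlogram[!is.na(correlogram$mantel_r) & !is.na(correlogram$p_raw), ]
  if (!nrow(tested)) return(FALSE)
  short <- utils::head(tested[order(tested$class_midpoint), ], n_short)
  any(short$significant & short$mantel_r > 0)
}
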
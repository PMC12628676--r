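#' Alpha diversity per sample
#'
#' Richness (OTUs with count > 0) and Shannon entropy in natural-log units,
#' H = -sum p_i log p_i with p the within-sample relative abundances.
#'
#' @param table a [community_table()].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  m <- ct_matrix(as_community_table(table))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("zero-sum sample(s): ", paste(rownames(m)[totals == 0], collapse = ", "))
  }
  data.frame(sample_id = rownames(m),
             richness = as.integer(rowSums(m > 0)),
             shannon = as.numeric(vegan::diversity(m, index = "shannon")),
             stringsAsFactors = FALSE)
}

#' Hellinger transformation
#'
#' Square roots of within-sample relative abundances; each transformed row's
#' squared values sum to one.
#'
#' @param table a [community_table()] or non-negative matrix.
#' @return numeric matrix, samples x OTUs.
#' @export
hellinger <- function(table) {
  m <- if (inherits(table, "community_table")) ct_matrix(table) else as.matrix(table)
  if (any(rowSums(m) == 0)) {
    stop("zero-sum sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  vegan::decostand(m, method = "hellinger")
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = sum |a_i - b_i| / sum (a_i + b_i). Bray-Curtis is a semimetric:
#' values lie in [0, 1] but the triangle inequality is not guaranteed.
#'
#' @param m samples x OTUs matrix (counts or transformed abundances),
#'   non-negative rows, none all-zero.
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
bray_curtis <- function(m) {
  if (inherits(m, "community_table")) m <- ct_matrix(m)
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative abundances")
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Classical scaling (eigen-decomposition of the double-centred squared
#' distance matrix). Axes are ordered by decreasing eigenvalue; only axes
#' with positive eigenvalues carry coordinates, and proportions explained
#' are relative to the sum of positive eigenvalues (negative eigenvalues are
#' reported but truncated for ordination).
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @return list of class `pcoa_result` with `ids`, `coordinates`,
#'   `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  ## Bray-Curtis is a semimetric: negative eigenvalues are expected and
  ## reported, so cmdscale's axis-count warning is uninformative here
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = nrow(dm) - 1,
                                         eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > max(eig) * 1e-10 & eig > 0)
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(ids = rownames(dm),
                 coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = pmax(eig[pos], 0) / sum(pmax(eig, 0))),
            class = "pcoa_result")
}

#' PERMANOVA (single factor)
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix, one factor at a time. The permutation p-value counts the observed
#' statistic among the null values, so it is never zero.
#'
#' @param d dissimilarity matrix (or `dist`) over samples.
#' @param groups factor or character vector of group labels, aligned with the
#'   rows of `d`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param factor_name label recorded in the output's `factor` column.
#' @return data.frame with `factor`, `R2`, `F`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L,
                      factor_name = "groups") {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm)) stop("'groups' length must match the matrix")
  if (nlevels(droplevels(groups)) < 2) stop("PERMANOVA needs at least 2 groups")
  if (n_perm < 99) stop("'n_perm' must be >= 99")
  set.seed(seed)
  df <- data.frame(g = groups)
  fit <- vegan::adonis2(stats::as.dist(dm) ~ g, data = df, permutations = n_perm)
  data.frame(factor = factor_name,
             R2 = fit$R2[1], F = fit$F[1], p_value = fit$`Pr(>F)`[1],
             n_permutations = n_perm, stringsAsFactors = FALSE)
}

#' Homogeneity of multivariate dispersion
#'
#' Distances to group centroids in principal-coordinate space (with the
#' standard imaginary-axis correction for negative eigenvalues), followed by
#' a permutation test on dispersion differences.
#'
#' @inheritParams permanova
#' @return list with `group_dispersion` (named mean distance-to-centroid) and
#'   `p_value`.
#' @export
dispersion_homogeneity <- function(d, groups, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm)) stop("'groups' length must match the matrix")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(droplevels(groups)) < 2)) {
    stop("each group needs at least 2 samples for a dispersion test")
  }
  bd <- vegan::betadisper(stats::as.dist(dm), groups, type = "centroid")
  set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(group_dispersion = tapply(bd$distances, groups, mean),
       p_value = pt$tab$`Pr(>F)`[1])
}

#' Great-circle distances between samples
#'
#' Haversine distance on a sphere of radius 6371 km, from the latitude and
#' longitude columns of the sample frame.
#'
#' @param meta sample metadata with `sample_id`, `latitude`, `longitude`.
#' @return symmetric matrix of distances in km, dimnames = sample ids.
#' @export
geographic_distance <- function(meta) {
  if (any(is.na(meta$latitude) | is.na(meta$longitude))) {
    bad <- meta$sample_id[is.na(meta$latitude) | is.na(meta$longitude)]
    stop("missing coordinates for: ", paste(bad, collapse = ", "))
  }
  p <- cbind(meta$longitude, meta$latitude)
  d <- geosphere::distm(p, fun = function(x, y) geosphere::distHaversine(x, y, r = 6371))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

#' Temporal distances between samples
#'
#' Absolute days elapsed between sampling dates.
#'
#' @param meta sample metadata with `sample_id` and `date`.
#' @return symmetric matrix of day counts, dimnames = sample ids.
#' @export
temporal_distance <- function(meta) {
  if (any(is.na(meta$date))) {
    stop("missing dates for: ", paste(meta$sample_id[is.na(meta$date)], collapse = ", "))
  }
  d <- abs(outer(as.numeric(meta$date), as.numeric(meta$date), "-"))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

#' Distance-decay regression
#'
#' Ordinary least squares of community dissimilarity on a pairwise predictor
#' (geographic km or temporal days) over a selectable subset of pairs, with a
#' Mantel-style permutation p-value: sample identities are permuted jointly
#' in the dissimilarity matrix while the retained pair positions stay fixed,
#' which accounts for the non-independence of pairs sharing a sample. The
#' two-sided p compares |r| and includes the observed statistic.
#'
#' @param community_dist,predictor_dist square matrices with identical sample
#'   ids.
#' @param pairs optional data.frame (`sample_i`, `sample_j`) restricting the
#'   regression to those unordered pairs; default all pairs.
#' @param n_perm permutations for the Mantel test.
#' @param seed integer seed.
#' @return data.frame with `slope`, `intercept`, `R2`, `p_value`, `n_pairs`.
#' @export
distance_decay <- function(community_dist, predictor_dist, pairs = NULL,
                           n_perm = 999L, seed = 1L) {
  cd <- as.matrix(community_dist)
  pd <- as.matrix(predictor_dist)
  ids <- rownames(cd)
  if (!identical(sort(ids), sort(rownames(pd)))) {
    stop("community and predictor matrices must share sample ids")
  }
  pd <- pd[ids, ids]
  if (is.null(pairs)) pairs <- unordered_pairs(ids)
  if (nrow(pairs) < 3) stop("need at least 3 retained pairs")
  ii <- match(pairs$sample_i, ids)
  jj <- match(pairs$sample_j, ids)
  x <- pd[cbind(ii, jj)]
  y <- cd[cbind(ii, jj)]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  r2 <- if (stats::var(y) == 0 || stats::var(x) == 0) 0 else stats::cor(x, y)^2
  r_obs <- if (stats::var(y) == 0 || stats::var(x) == 0) 0 else stats::cor(x, y)
  set.seed(seed)
  n <- length(ids)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    yp <- cd[cbind(perm[ii], perm[jj])]
    rp <- suppressWarnings(stats::cor(x, yp))
    if (!is.finite(rp)) rp <- 0
    if (abs(rp) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  data.frame(slope = slope, intercept = intercept, R2 = r2,
             p_value = (hits + 1) / (n_perm + 1), n_pairs = nrow(pairs))
}
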
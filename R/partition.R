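## comparison-subset bookkeeping and contribution aggregation

#' Categorize sample pairs into comparison subsets
#'
#' Assigns each unordered pair one category: `intra_lake` (same ecosystem,
#' same year, different replicate), `inter_lake_same_year` (same year,
#' different ecosystem), `inter_year_same_lake` (same ecosystem, different
#' year) or `other` (different ecosystem and year; contributes only to the
#' `all` subset). Replicate pairs never enter the spatial or temporal
#' subsets. Pairs must lie within one habitat: habitats are analyzed
#' independently.
#'
#' The replicate combination (e.g. `A-B`) is canonicalized as unordered by
#' default; `ordered_combos = TRUE` keeps both orderings as distinct types
#' (the enumeration that yields four combinations for two replicates).
#'
#' @param meta sample metadata (see [validate_sample_metadata()]).
#' @param pairs data.frame with `sample_i`, `sample_j`.
#' @param ordered_combos treat `A-B` and `B-A` as distinct comparison types.
#' @return `pairs` with added `category` and `replicate_combo` columns.
#' @export
categorize_pairs <- function(meta, pairs, ordered_combos = FALSE) {
  meta <- validate_sample_metadata(meta)
  rownames(meta) <- meta$sample_id
  missing <- setdiff(c(pairs$sample_i, pairs$sample_j), meta$sample_id)
  if (length(missing)) stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  a <- meta[pairs$sample_i, ]
  b <- meta[pairs$sample_j, ]
  if (any(a$habitat != b$habitat)) {
    stop("cross-habitat pair(s); analyze habitats independently")
  }
  same_eco <- a$ecosystem == b$ecosystem
  same_year <- a$year == b$year
  category <- rep("other", nrow(pairs))
  category[same_eco & same_year] <- "intra_lake"
  category[!same_eco & same_year] <- "inter_lake_same_year"
  category[same_eco & !same_year] <- "inter_year_same_lake"
  ## a same-ecosystem, same-year pair with the same replicate label can only
  ## arise from duplicated design coordinates; flag it rather than miscount
  dup <- same_eco & same_year & a$replicate == b$replicate
  if (any(dup)) {
    stop("pairs with identical (ecosystem, year, replicate): ",
         paste(pairs$sample_i[dup], pairs$sample_j[dup], sep = "/", collapse = ", "))
  }
  combo <- if (ordered_combos) {
    paste(a$replicate, b$replicate, sep = "-")
  } else {
    paste(pmin(a$replicate, b$replicate), pmax(a$replicate, b$replicate), sep = "-")
  }
  pairs$category <- factor(category, levels = c("intra_lake", "inter_lake_same_year",
                                                "inter_year_same_lake", "other"))
  pairs$replicate_combo <- combo
  pairs
}

#' Process contributions per comparison subset
#'
#' Within a subset, classified pairs are grouped by replicate-combination
#' comparison type; per type, the occurrences of each process are converted
#' to percentages (summing to 100 within the type); the mean, SD and 95%
#' confidence half-width (1.96 SD / sqrt(n_types), from the standard error
#' across types) are then taken across types with equal weight.
#' Degenerate/undetermined pairs are excluded from the denominators.
#'
#' @param records data.frame of classified pairs (the `pairs` element of an
#'   [assembly_fit()]), with `process`, `category`, `replicate_combo`.
#' @param subset `"all"` or one of the comparison categories.
#' @return data.frame with `subset`, `process`, `mean_percent`, `sd_percent`,
#'   `ci95_halfwidth`, `n_types`, `n_pairs`, plus a `per_type` attribute
#'   (type x process percentage matrix).
#' @export
contributions <- function(records, subset = c("all", "intra_lake",
                                              "inter_lake_same_year",
                                              "inter_year_same_lake")) {
  subset <- match.arg(subset)
  if (is.null(records$category) || is.null(records$replicate_combo)) {
    stop("records lack comparison categories; run categorize_pairs() first")
  }
  keep <- records$process != "undetermined"
  if (subset != "all") keep <- keep & records$category == subset
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no classified pair in subset '", subset, "'")
  processes <- c("variable_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  types <- split(rec$process, rec$replicate_combo, drop = TRUE)
  per_type <- t(vapply(types, function(p) {
    counts <- table(factor(as.character(p), levels = processes))
    100 * as.numeric(counts) / length(p)
  }, numeric(length(processes))))
  colnames(per_type) <- processes
  n_types <- nrow(per_type)
  means <- colMeans(per_type)
  sds <- if (n_types > 1) apply(per_type, 2, stats::sd) else rep(0, length(processes))
  out <- data.frame(subset = subset, process = processes,
                    mean_percent = as.numeric(means),
                    sd_percent = as.numeric(sds),
                    ci95_halfwidth = 1.96 * as.numeric(sds) / sqrt(n_types),
                    n_types = n_types, n_pairs = nrow(rec),
                    stringsAsFactors = FALSE)
  attr(out, "per_type") <- per_type
  out
}

#' Exact two-sided permutation test between subsets
#'
#' Compares the per-comparison-type percentage contributions of one process
#' between two subsets. The statistic is the absolute difference of group
#' means; group relabelings are enumerated exhaustively when their count is
#' at most `exact_cap` (the observed labeling is among them, so p > 0),
#' otherwise `n_perm` Monte-Carlo relabelings are drawn and the observed
#' statistic is included in the null.
#'
#' @param values_a,values_b numeric vectors of per-type percentages for the
#'   process in the two subsets.
#' @param n_perm Monte-Carlo permutations when enumeration is too large.
#' @param exact_cap maximum number of relabelings to enumerate exhaustively.
#' @param seed integer seed (Monte-Carlo branch only).
#' @return list with `p_value`, `statistic` (|mean_a - mean_b|), `exact`.
#' @export
subset_permutation_test <- function(values_a, values_b, n_perm = 1000L,
                                    exact_cap = 20000L, seed = 1L) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  if (length(values_a) + length(values_b) < 2) stop("need at least 2 values in total")
  pooled <- c(values_a, values_b)
  n_a <- length(values_a)
  n <- length(pooled)
  stat_obs <- abs(mean(values_a) - mean(values_b))
  n_comb <- choose(n, n_a)
  stat_of <- function(idx_a) {
    abs(mean(pooled[idx_a]) - mean(pooled[-idx_a]))
  }
  if (n_comb <= exact_cap) {
    combos <- utils::combn(n, n_a)
    stats <- apply(combos, 2, stat_of)
    p <- mean(stats >= stat_obs - 1e-12)
    return(list(p_value = p, statistic = stat_obs, exact = TRUE))
  }
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    if (stat_of(sample.int(n, n_a)) >= stat_obs - 1e-12) hits <- hits + 1L
  }
  list(p_value = (hits + 1) / (n_perm + 1), statistic = stat_obs, exact = FALSE)
}
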
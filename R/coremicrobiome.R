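## core-microbiome extraction: overall, spatial (per year) and temporal
## (per ecosystem) cores

core_set <- function(scope, unit, otu_ids, prevalence, detection,
                     cumulative_mean, cumulative_sd) {
  structure(list(scope = scope, unit = unit, otu_ids = otu_ids,
                 prevalence_threshold = prevalence,
                 detection_threshold = detection,
                 core_richness = length(otu_ids),
                 cumulative_abundance_mean = cumulative_mean,
                 cumulative_abundance_sd = cumulative_sd),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set [%s%s]: %d OTUs (prevalence >= %.0f%%, detection > %.2g)\n",
              x$scope, if (is.na(x$unit)) "" else paste0(": ", x$unit),
              x$core_richness, 100 * x$prevalence_threshold, x$detection_threshold))
  cat(sprintf("  cumulative relative abundance %.1f%% +/- %.1f%%\n",
              100 * x$cumulative_abundance_mean, 100 * x$cumulative_abundance_sd))
  invisible(x)
}

rel_abund <- function(m) sweep(m, 1, rowSums(m), "/")

#' Overall core microbiome
#'
#' An OTU is "present" in a sample when its relative abundance is strictly
#' above `detection` (default 0.1%), and a core member when present in at
#' least a `prevalence` fraction of samples (default 75%).
#'
#' @param table a [community_table()].
#' @param prevalence fraction in (0, 1].
#' @param detection fraction in [0, 1).
#' @return a `core_set` with member ids, core richness, and the mean +/- SD
#'   over samples of the members' cumulative relative abundance.
#' @export
core_members <- function(table, prevalence = 0.75, detection = 0.001) {
  table <- as_community_table(table)
  m <- ct_matrix(table)
  if (!nrow(m) || !ncol(m)) stop("empty community table")
  if (prevalence <= 0 || prevalence > 1) stop("'prevalence' must be in (0, 1]")
  if (detection < 0 || detection >= 1) stop("'detection' must be in [0, 1)")
  rel <- rel_abund(m)
  present <- rel > detection
  members <- colnames(m)[colMeans(present) >= prevalence]
  cum <- rowSums(rel[, members, drop = FALSE])
  core_set("overall", NA_character_, members, prevalence, detection,
           mean(cum), if (length(cum) > 1) stats::sd(cum) else 0)
}

## presence collapsed to design units (ecosystems or years): an OTU is
## present in a unit when above detection in >= 1 of its samples
## ("any_replicate"), or when its mean relative abundance across the unit's
## samples exceeds detection ("mean")
unit_presence <- function(m, unit_of_sample, detection,
                          collapse = c("any_replicate", "mean")) {
  collapse <- match.arg(collapse)
  rel <- rel_abund(m)
  units <- unique(unit_of_sample)
  pres <- t(vapply(units, function(u) {
    rows <- rel[unit_of_sample == u, , drop = FALSE]
    if (collapse == "any_replicate") {
      apply(rows > detection, 2, any)
    } else {
      colMeans(rows) > detection
    }
  }, logical(ncol(m))))
  rownames(pres) <- units
  pres
}

core_by_units <- function(table, meta, keep, unit_col, scope, unit_label,
                          prevalence, detection, collapse) {
  m <- ct_matrix(as_community_table(table))
  meta <- validate_sample_metadata(meta)
  rownames(meta) <- meta$sample_id
  meta <- meta[rownames(m), ]
  m <- m[keep(meta), , drop = FALSE]
  sub <- meta[rownames(m), ]
  if (!nrow(m)) stop("no samples selected")
  pres <- unit_presence(m, as.character(sub[[unit_col]]), detection, collapse)
  members <- colnames(m)[colMeans(pres) >= prevalence]
  rel <- rel_abund(m)
  cum <- rowSums(rel[, members, drop = FALSE])
  core_set(scope, unit_label, members, prevalence, detection,
           mean(cum), if (length(cum) > 1) stats::sd(cum) else 0)
}

#' Spatial core microbiome of one sampling year
#'
#' OTUs present (above `detection` in at least one replicate, by default) in
#' at least a `prevalence` fraction of the ecosystems sampled that year.
#' Cumulative abundance is reported relative to the year's samples.
#'
#' @inheritParams core_members
#' @param meta sample metadata.
#' @param year sampling year.
#' @param collapse how replicate samples collapse to ecosystem-level
#'   presence: `"any_replicate"` (default) or `"mean"`.
#' @return a `core_set`.
#' @export
spatial_core <- function(table, meta, year, prevalence = 0.75, detection = 0.001,
                         collapse = c("any_replicate", "mean")) {
  meta <- validate_sample_metadata(meta)
  if (!year %in% meta$year) stop("unknown year: ", year)
  core_by_units(table, meta, function(md) md$year == year, "ecosystem",
                "spatial", as.character(year), prevalence, detection,
                match.arg(collapse))
}

#' Temporal core microbiome of one ecosystem
#'
#' OTUs present in at least a `prevalence` fraction of the years in which the
#' ecosystem was sampled; symmetric to [spatial_core()] with years as units.
#' Cumulative abundance is reported relative to the ecosystem's samples.
#'
#' @inheritParams spatial_core
#' @param ecosystem ecosystem (lake) id.
#' @return a `core_set`.
#' @export
temporal_core <- function(table, meta, ecosystem, prevalence = 0.75,
                          detection = 0.001,
                          collapse = c("any_replicate", "mean")) {
  meta <- validate_sample_metadata(meta)
  if (!ecosystem %in% meta$ecosystem) stop("unknown ecosystem: ", ecosystem)
  core_by_units(table, meta, function(md) md$ecosystem == ecosystem, "year",
                "temporal", ecosystem, prevalence, detection,
                match.arg(collapse))
}

#' Overlap between two cores
#'
#' @param core_a,core_b `core_set` objects.
#' @return list with `jaccard` (|intersection| / |union|) and `shared_ids`.
#' @export
core_overlap <- function(core_a, core_b) {
  a <- core_a$otu_ids; b <- core_b$otu_ids
  if (!length(a) && !length(b)) stop("both cores are empty")
  shared <- intersect(a, b)
  list(jaccard = length(shared) / length(union(a, b)), shared_ids = shared)
}
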
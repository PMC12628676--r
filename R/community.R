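#' Community tables
#'
#' A community table is the central abundance object: an integer matrix of
#' read counts with samples as rows and OTUs as columns, carrying unique
#' sample ids (rownames) and OTU ids (colnames). `community_table()` validates
#' and classes a matrix; `as_community_table()` coerces data frames or
#' matrices.
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   samples x OTUs.
#' @param sample_ids,otu_ids optional character vectors overriding dimnames.
#' @return an integer matrix of class `community_table`.
#' @examples
#' m <- matrix(c(1, 2, 0, 5, 3, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("OTU1", "OTU2")))
#' community_table(m)
#' @export
community_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix")
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("community_table requires sample ids (rownames) and OTU ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicated OTU id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (read counts)")
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("community_table", class(counts))
  counts
}

#' @rdname community_table
#' @param x object to coerce (matrix or data.frame of counts).
#' @export
as_community_table <- function(x) {
  if (inherits(x, "community_table")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  community_table(x)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  cat("samples:", paste(utils::head(rownames(x), 5), collapse = ", "),
      if (nrow(x) > 5) "..." else "", "\n")
  invisible(x)
}

## strips the class so base matrix ops apply
ct_matrix <- function(table) {
  m <- unclass(table)
  class(m) <- setdiff(class(m), "community_table")
  m
}

#' Read an OTU table
#'
#' TSV dialect: first column holds ids, header holds the other axis' ids.
#' Orientation is samples-as-rows canonically; `orientation = "otus_as_rows"`
#' transposes on load. BIOM input (classic JSON or HDF5, via the biomformat
#' package) is stored OTUs x samples and is transposed automatically.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation for TSV input, `"samples_as_rows"` (default) or
#'   `"otus_as_rows"`.
#' @return a [community_table()].
#' @export
load_community_table <- function(path, format = c("tsv", "biom"),
                                 orientation = c("samples_as_rows", "otus_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(community_table(t(m)))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, colClasses = "character",
                          comment.char = "", quote = "")
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (orientation == "otus_as_rows") num <- t(num)
  community_table(num)
}

#' Write an OTU table as TSV
#'
#' Inverse of [load_community_table()]: first column `sample_id`, one column
#' per OTU. Round-trips counts exactly.
#'
#' @param table a [community_table()].
#' @param path output path.
#' @export
write_community_table <- function(table, path) {
  table <- as_community_table(table)
  df <- data.frame(sample_id = rownames(table), ct_matrix(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `ecosystem`, `year`, `habitat`, `replicate`,
#' `latitude`, `longitude`, `date` (extra columns pass through). Habitat must
#' be `"sediment"` or `"water"`.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @return a validated data.frame (the sample frame).
#' @export
load_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname load_sample_metadata
#' @param meta data.frame to validate in place.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "ecosystem", "year", "habitat", "replicate",
                "latitude", "longitude", "date")
  missing <- setdiff(required, names(meta))
  if (length(missing)) stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample id(s) in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (!all(meta$habitat %in% c("sediment", "water"))) {
    stop("habitat must be 'sediment' or 'water'")
  }
  if (any(meta$latitude < -90 | meta$latitude > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]")
  }
  if (any(meta$longitude < -180 | meta$longitude > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]")
  }
  meta$year <- as.integer(meta$year)
  meta$date <- as.Date(meta$date)
  meta
}

#' Read an environment table
#'
#' First column `sample_id`, remaining columns numeric environmental
#' variables. Missing values are permitted on input; use `normalize = TRUE`
#' to centre and scale complete columns.
#'
#' @param path CSV or TSV file.
#' @param normalize centre and scale the variables.
#' @return data.frame with rownames = sample ids.
#' @export
load_environment_table <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("environment table needs a 'sample_id' column")
  rownames(df) <- as.character(df$sample_id)
  env <- df[, setdiff(names(df), "sample_id"), drop = FALSE]
  if (!all(vapply(env, is.numeric, logical(1)))) {
    stop("environmental variables must be numeric")
  }
  if (normalize) env[] <- scale(env)
  env
}

#' Cross-validate table, metadata and tree
#'
#' Reports samples missing from the metadata, OTUs missing from the tree
#' tips, and all-zero rows/columns. In strict mode any finding is an error.
#'
#' @param table a [community_table()].
#' @param meta sample metadata data.frame (or `NULL` to skip).
#' @param tree an [ape::phylo] tree (or `NULL` to skip).
#' @param strict raise an error on any mismatch.
#' @return invisibly, a list of character vectors
#'   (`samples_missing_metadata`, `otus_missing_tree`, `zero_samples`,
#'   `zero_otus`) with a logical `ok`.
#' @export
validate_dataset <- function(table, meta = NULL, tree = NULL, strict = FALSE) {
  table <- as_community_table(table)
  m <- ct_matrix(table)
  report <- list(
    samples_missing_metadata = character(0),
    otus_missing_tree = character(0),
    zero_samples = rownames(m)[rowSums(m) == 0],
    zero_otus = colnames(m)[colSums(m) == 0]
  )
  if (!is.null(meta)) {
    report$samples_missing_metadata <-
      setdiff(rownames(m), as.character(meta$sample_id))
  }
  if (!is.null(tree)) {
    report$otus_missing_tree <- setdiff(colnames(m), tree$tip.label)
  }
  report$ok <- all(lengths(report[c("samples_missing_metadata", "otus_missing_tree",
                                    "zero_samples")]) == 0)
  if (strict && !report$ok) {
    offending <- unlist(report[c("samples_missing_metadata", "otus_missing_tree",
                                 "zero_samples")])
    stop("dataset cross-reference failure: ", paste(offending, collapse = ", "))
  }
  invisible(report)
}

#' Rarefy a community table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total is below `depth` are dropped with a warning
#' listing them.
#'
#' @param table a [community_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return rarefied [community_table()]; dropped samples are recorded in the
#'   `"dropped_samples"` attribute.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  table <- as_community_table(table)
  stop_if_not_scalar_number(depth, "depth")
  if (depth < 1) stop("'depth' must be >= 1")
  m <- ct_matrix(table)
  totals <- rowSums(m)
  low <- rownames(m)[totals < depth]
  if (length(low)) {
    warning("dropping sample(s) below rarefaction depth: ",
            paste(low, collapse = ", "))
    m <- m[totals >= depth, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no sample reaches the rarefaction depth")
  set.seed(seed)
  # rrarefy's advisory warning about count magnitudes duplicates the
  # depth validation already done above
  r <- suppressWarnings(vegan::rrarefy(m, depth))
  out <- community_table(r[, , drop = FALSE])
  attr(out, "dropped_samples") <- low
  out
}

#' Remove rare OTUs by table-wide relative abundance
#'
#' Drops OTUs whose total relative abundance over the whole table is strictly
#' below `min_rel_abund` (dataset-wide scope; equality retains). A
#' `scope = "per_sample"` variant drops OTUs never reaching the threshold in
#' any single sample.
#'
#' @param table a [community_table()].
#' @param min_rel_abund fraction in [0, 1); e.g. 5e-5 for a 0.005% filter.
#' @param scope `"dataset"` (default) or `"per_sample"`.
#' @return filtered [community_table()].
#' @export
filter_low_abundance <- function(table, min_rel_abund,
                                 scope = c("dataset", "per_sample")) {
  table <- as_community_table(table)
  scope <- match.arg(scope)
  stop_if_not_scalar_number(min_rel_abund, "min_rel_abund")
  if (min_rel_abund < 0 || min_rel_abund >= 1) {
    stop("'min_rel_abund' must be in [0, 1)")
  }
  m <- ct_matrix(table)
  keep <- if (scope == "dataset") {
    colSums(m) / sum(as.numeric(m)) >= min_rel_abund
  } else {
    apply(sweep(m, 1, pmax(rowSums(m), 1), "/"), 2, max) >= min_rel_abund
  }
  community_table(m[, keep, drop = FALSE])
}

#' Read a rooted phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' null-model framework needs: rooted, unique tip labels, finite non-negative
#' branch lengths.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
load_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  check_phylogeny(tree)
}

check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("tree tip labels must be unique")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  tree
}
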
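# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 31-bit seed for a named substream. Used so per-pair null
## draws are order-independent and reproducible from one master seed.
substream_seed <- function(master_seed, ...) {
  key <- paste(c(...), collapse = "\r")
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## seed for an unordered sample pair: ids are sorted first, so
## f(a, b) == f(b, a) by construction
pair_seed <- function(master_seed, id_a, id_b) {
  ids <- sort(c(as.character(id_a), as.character(id_b)))
  substream_seed(master_seed, "pair", ids[1], ids[2])
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

## Bray-Curtis between two non-negative vectors
bc_pair <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s <= 0) stop("Bray-Curtis undefined for two empty communities")
  sum(abs(a - b)) / s
}

## all unordered pairs of a character vector, columns i < j in input order
unordered_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) stop("need at least two samples to form pairs")
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(sample_i = ids[i], sample_j = ids[j], stringsAsFactors = FALSE)
}

## lower-triangle extraction keyed by sample ids, from a square matrix
pairs_from_matrix <- function(m, pairs) {
  m[cbind(match(pairs$sample_i, rownames(m)), match(pairs$sample_j, colnames(m)))]
}
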
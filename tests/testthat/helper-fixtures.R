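# fixtures and independent oracles shared across test files

# small community table with explicit ids
tiny_table <- function(counts, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otus)) otus <- paste0("OTU", seq_len(ncol(counts)))
  community_table(matrix(as.integer(counts), nrow(counts), ncol(counts),
                         dimnames = list(samples, otus)))
}

# complete design metadata: ecosystems x years x replicates, one habitat
design_meta <- function(E, Y, R, habitat = "water") {
  g <- expand.grid(replicate = LETTERS[seq_len(R)],
                   year = seq(2017L, by = 2L, length.out = Y),
                   ecosystem = paste0("L", seq_len(E)),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%d_%s", g$ecosystem, g$year, g$replicate),
             ecosystem = g$ecosystem, year = g$year, habitat = habitat,
             replicate = g$replicate,
             latitude = -62.2 + as.integer(factor(g$ecosystem)) * 0.01,
             longitude = -58.9 + as.integer(factor(g$ecosystem)) * 0.02,
             date = as.Date(sprintf("%d-01-15", g$year)),
             stringsAsFactors = FALSE)
}

# independent betaMNTD oracle: explicit double loop over taxa, no caching
oracle_beta_mntd <- function(counts, tree, weighted = TRUE) {
  D <- stats::cophenetic(tree)
  ids <- rownames(counts)
  n <- length(ids)
  directed <- function(k, m) {
    tk <- colnames(counts)[counts[k, ] > 0]
    tm <- colnames(counts)[counts[m, ] > 0]
    fk <- if (weighted) {
      counts[k, tk] / sum(counts[k, tk])
    } else {
      rep(1 / length(tk), length(tk))
    }
    total <- 0
    for (i in seq_along(tk)) {
      dmin <- Inf
      for (j in seq_along(tm)) {
        dij <- D[tk[i], tm[j]]
        if (dij < dmin) dmin <- dij
      }
      total <- total + fk[i] * dmin
    }
    total
  }
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(n)) for (m in seq_len(n)) {
    if (k != m) out[k, m] <- 0.5 * (directed(k, m) + directed(m, k))
  }
  out
}

# random community/tree instance for oracle comparisons
random_instance <- function(seed, max_tips = 12, max_samples = 6) {
  set.seed(seed)
  n_tips <- sample(4:max_tips, 1)
  n_samp <- sample(2:max_samples, 1)
  tree <- ape::rtree(n_tips, rooted = TRUE)
  tree$tip.label <- paste0("OTU", seq_len(n_tips))
  counts <- matrix(0L, n_samp, n_tips,
                   dimnames = list(paste0("S", seq_len(n_samp)), tree$tip.label))
  for (s in seq_len(n_samp)) {
    k <- sample(2:n_tips, 1)
    idx <- sample(n_tips, k)
    counts[s, idx] <- stats::rmultinom(1, 100, rep(1 / k, k))[, 1] + 1L
  }
  list(table = community_table(counts), tree = tree)
}
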
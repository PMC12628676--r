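test_that("alpha diversity matches hand-computed richness and Shannon entropy", {
  tab <- tiny_table(matrix(c(10, 10, 10, 10,
                             42, 0, 0, 0,
                             1, 1, 2, 0), nrow = 3, byrow = TRUE))
  a <- alpha_diversity(tab)
  expect_identical(a$richness, c(4L, 1L, 3L))
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$shannon[2], 0, tolerance = 1e-12)
  expect_equal(a$shannon[3], 1.039721, tolerance = 1e-6)
  zero <- tiny_table(matrix(c(1, 0, 0, 0), 2, byrow = TRUE))
  expect_error(alpha_diversity(zero), "S2")
})

test_that("Hellinger rows are unit-norm square-rooted proportions", {
  tab <- tiny_table(matrix(c(4, 0, 1, 1), nrow = 2, byrow = TRUE))
  h <- hellinger(tab)
  expect_equal(unname(h[1, ]), c(1, 0))
  expect_equal(unname(h[2, ]), rep(sqrt(0.5), 2), tolerance = 1e-7)
  expect_equal(unname(rowSums(h^2)), c(1, 1), tolerance = 1e-12)
})

test_that("Bray-Curtis agrees with the direct formula and stays in [0, 1]", {
  m <- rbind(a = c(6, 2, 0), b = c(2, 2, 4), c = c(6, 2, 0), d = c(0, 0, 5))
  colnames(m) <- paste0("o", 1:3)
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0, tolerance = 1e-12)
  expect_equal(d["a", "d"], 1, tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("PCoA recovers exact geometry for equilateral and collinear configurations", {
  ids <- c("x", "y", "z")
  eq <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(eq) <- 0
  p <- pcoa(eq)
  expect_equal(p$eigenvalues[1], p$eigenvalues[2], tolerance = 1e-9)
  expect_lt(abs(p$eigenvalues[3]), 1e-9)

  pts <- c(0, 3, 7, 10)
  dl <- abs(outer(pts, pts, "-"))
  dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pl <- pcoa(dl)
  # one positive axis; inter-point distances reproduced
  expect_identical(ncol(pl$coordinates), 1L)
  rec <- as.matrix(dist(pl$coordinates))
  expect_equal(unname(rec), unname(dl), tolerance = 1e-9)

  dup <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
  dimnames(dup) <- list(ids, ids)
  pd <- pcoa(dup)
  expect_equal(pd$coordinates[1, ], pd$coordinates[2, ], tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 samples")
})

test_that("PERMANOVA matches a brute-force sum-of-squares decomposition", {
  # 6-sample toy, 2 groups of 3; R2 from explicit SS arithmetic on distances
  set.seed(42)
  m <- matrix(rpois(6 * 5, 20), 6, 5,
              dimnames = list(paste0("S", 1:6), paste0("o", 1:5)))
  d <- bray_curtis(m)
  g <- rep(c("A", "B"), each = 3)
  sst <- sum(d[upper.tri(d)]^2) / 6
  ssw <- sum(vapply(c("A", "B"), function(gr) {
    sub <- d[g == gr, g == gr]
    sum(sub[upper.tri(sub)]^2) / 3
  }, numeric(1)))
  r2_brute <- (sst - ssw) / sst
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$R2, r2_brute, tolerance = 1e-10)

  # perfect separation: two groups of mutually identical samples
  sep <- rbind(matrix(rep(c(10, 0), each = 3), 3, 2),
               matrix(rep(c(0, 10), each = 3), 3, 2))
  rownames(sep) <- paste0("S", 1:6); colnames(sep) <- c("o1", "o2")
  dsep <- bray_curtis(sep)
  rsep <- permanova(dsep, g, n_perm = 199, seed = 1)
  expect_gt(rsep$R2, 0.999)
  expect_equal(rsep$p_value, 1 / 200, tolerance = 1e-12)
  expect_error(permanova(d, rep("A", 6)), "2 groups")
})

test_that("dispersion homogeneity separates equal from unequal spreads", {
  # two duplicated point clouds: dispersions identical, p large
  base <- matrix(rpois(4 * 6, 15), 4, 6)
  m <- rbind(base, base)
  rownames(m) <- paste0("S", 1:8); colnames(m) <- paste0("o", 1:6)
  g <- rep(c("A", "B"), each = 4)
  d <- bray_curtis(m)
  res <- dispersion_homogeneity(d, g, n_perm = 199, seed = 3)
  expect_gt(res$p_value, 0.5)
  expect_equal(unname(res$group_dispersion["A"]), unname(res$group_dispersion["B"]),
               tolerance = 1e-10)

  # zero-dispersion group versus spread group
  tight <- matrix(rep(c(5, 5, 5, 0, 0, 0), 4), 4, 6, byrow = TRUE)
  set.seed(8)
  loose <- matrix(rpois(4 * 6, 10), 4, 6)
  m2 <- rbind(tight, loose)
  rownames(m2) <- paste0("S", 1:8); colnames(m2) <- paste0("o", 1:6)
  d2 <- bray_curtis(m2)
  res2 <- dispersion_homogeneity(d2, g, n_perm = 199, seed = 3)
  expect_lt(res2$p_value, 0.05)
  expect_error(dispersion_homogeneity(d2, c("A", rep("B", 7)), seed = 1),
               "at least 2 samples")
})

test_that("geographic distances are haversine on a 6371 km sphere", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     latitude = c(0, 1, 0), longitude = c(0, 0, 0))
  d <- geographic_distance(meta)
  expect_equal(d["a", "b"], 111.1949, tolerance = 1e-4)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  meta$latitude[2] <- NA
  expect_error(geographic_distance(meta), "b")
})

test_that("distance-decay OLS matches the normal equations and flags perfect fits", {
  # 10-pair toy from 5 points: compare against an explicit normal-equation solve
  set.seed(11)
  ids <- paste0("s", 1:5)
  x <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  x <- (x + t(x)) / 2; diag(x) <- 0
  y <- matrix(runif(25), 5, 5, dimnames = list(ids, ids))
  y <- (y + t(y)) / 2; diag(y) <- 0
  fit <- distance_decay(y, x, n_perm = 99, seed = 1)
  xv <- x[upper.tri(x)]; yv <- y[upper.tri(y)]
  X <- cbind(1, xv)
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)

  # constant dissimilarity: slope and R2 are zero
  yc <- matrix(0.4, 5, 5, dimnames = list(ids, ids)); diag(yc) <- 0
  fc <- distance_decay(yc, x, n_perm = 99, seed = 1)
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$R2, 0)

  # exactly linear: R2 = 1 and the permutation p is the minimum attainable
  yl <- 0.1 + 0.05 * x; diag(yl) <- 0
  fl <- distance_decay(yl, x, n_perm = 99, seed = 1)
  expect_equal(fl$R2, 1, tolerance = 1e-12)
  expect_equal(fl$p_value, 1 / 100, tolerance = 1e-12)
})

test_that("temporal distances are absolute day differences", {
  meta <- data.frame(sample_id = c("a", "b"),
                     date = as.Date(c("2017-01-15", "2019-01-15")))
  d <- temporal_distance(meta)
  expect_equal(d["a", "b"], 730)
})
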
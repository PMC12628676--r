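test_that("betaMNTD matches the brute-force double-loop oracle", {
  for (s in 1:10) {
    inst <- random_instance(s)
    got <- beta_mntd(inst$table, inst$tree)
    want <- oracle_beta_mntd(unclass(inst$table), inst$tree)
    expect_equal(got, want, tolerance = 1e-12)
    gotu <- beta_mntd(inst$table, inst$tree, weighted = FALSE)
    wantu <- oracle_beta_mntd(unclass(inst$table), inst$tree, weighted = FALSE)
    expect_equal(gotu, wantu, tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with picante::comdistnt on abundance-weighted cases", {
  inst <- random_instance(99)
  got <- beta_mntd(inst$table, inst$tree)
  ref <- as.matrix(picante::comdistnt(unclass(inst$table),
                                      stats::cophenetic(inst$tree),
                                      abundance.weighted = TRUE))
  ref <- ref[rownames(got), colnames(got)]
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("betaMNTD degenerate geometries follow the formula", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # identical communities: every taxon's nearest neighbour is itself
  same <- tiny_table(rbind(c(3, 1, 2), c(3, 1, 2)), otus = c("A", "B", "C"))
  expect_equal(max(abs(beta_mntd(same, tree))), 0, tolerance = 1e-12)
  # singletons: betaMNTD equals the cophenetic distance
  single <- tiny_table(rbind(c(5, 0, 0), c(0, 7, 0)), otus = c("A", "B", "C"))
  expect_equal(beta_mntd(single, tree)["S1", "S2"], 2, tolerance = 1e-12)
  # mixed pair against the oracle
  mix <- tiny_table(rbind(c(1, 1, 0), c(0, 0, 4)), otus = c("A", "B", "C"))
  expect_equal(beta_mntd(mix, tree), oracle_beta_mntd(unclass(mix), tree),
               tolerance = 1e-12)
  empty <- tiny_table(rbind(c(1, 1, 0), c(0, 0, 0)), otus = c("A", "B", "C"))
  expect_error(beta_mntd(empty, tree), "empty")
})

test_that("betaMNTD scales with branch lengths while bNTI is scale-free", {
  inst <- random_instance(7)
  tree2 <- inst$tree
  tree2$edge.length <- tree2$edge.length * 3.5
  expect_equal(beta_mntd(inst$table, tree2), 3.5 * beta_mntd(inst$table, inst$tree),
               tolerance = 1e-10)
  b1 <- beta_nti(inst$table, inst$tree, n_null = 199, seed = 5)
  b2 <- beta_nti(inst$table, tree2, n_null = 199, seed = 5)
  expect_equal(b1$beta_nti, b2$beta_nti, tolerance = 1e-8)
})

test_that("identical communities are degenerate under the bNTI null", {
  tree <- simulate_tree(20, seed = 1)
  cnt <- rbind(c(rep(5L, 10), rep(0L, 10)), c(rep(5L, 10), rep(0L, 10)))
  tab <- tiny_table(cnt, otus = tree$tip.label)
  bn <- beta_nti(tab, tree, n_null = 99, seed = 1)
  expect_true(bn$degenerate[1])
  expect_true(is.na(bn$beta_nti[1]))
})

test_that("communities of close relatives yield negative bNTI on average", {
  tree <- simulate_tree(100, seed = 3)
  d <- stats::cophenetic(tree)
  # two communities drawn from one tight clade: pick the 12 nearest relatives
  # of a focal tip, then split them into two overlapping communities
  focal <- order(d["OTU1", ])[1:12]
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    c1 <- sample(focal, 8); c2 <- sample(focal, 8)
    cnt <- matrix(0L, 2, 100, dimnames = list(c("S1", "S2"), tree$tip.label))
    cnt[1, c1] <- 10L; cnt[2, c2] <- 10L
    bn <- beta_nti(community_table(cnt), tree, n_null = 99, seed = s)
    bn$beta_nti[1]
  }, numeric(1))
  expect_lt(mean(vals, na.rm = TRUE), 0)
})

test_that("Raup-Crick ordering, range and symmetry contracts hold", {
  set.seed(2)
  cnt <- matrix(rpois(6 * 30, 5), 6, 30,
                dimnames = list(paste0("S", 1:6), paste0("OTU", 1:30)))
  cnt[1, ] <- cnt[2, ]  # identical pair
  tab <- community_table(cnt)
  rc <- raup_crick_bray(tab, n_null = 999, seed = 4)
  idpair <- rc[rc$sample_i == "S1" & rc$sample_j == "S2", ]
  expect_lte(idpair$rc_bray, -0.99)
  expect_true(all(rc$rc_bray >= -1 & rc$rc_bray <= 1))
  # symmetry: reversing sample order must reproduce the same values,
  # because null substreams are seeded from the sorted id pair
  tab_rev <- community_table(cnt[6:1, ])
  rc_rev <- raup_crick_bray(tab_rev, n_null = 199, seed = 4)
  rc_fwd <- raup_crick_bray(tab, n_null = 199, seed = 4)
  key <- function(df) paste(pmin(df$sample_i, df$sample_j),
                            pmax(df$sample_i, df$sample_j))
  m <- match(key(rc_fwd), key(rc_rev))
  expect_equal(rc_fwd$rc_bray, rc_rev$rc_bray[m], tolerance = 1e-12)
  expect_error(raup_crick_bray(tab, n_null = 50), "n_null")
})

test_that("disjoint communities from a mixed pool hit the upper Raup-Crick tail", {
  # two taxonomically disjoint rich communities; remaining samples mix the pool
  set.seed(5)
  P <- 40
  cnt <- matrix(rpois(8 * P, 3) + 1L, 8, P,
                dimnames = list(paste0("S", 1:8), paste0("OTU", 1:P)))
  cnt[1, ] <- 0L; cnt[2, ] <- 0L
  cnt[1, 1:20] <- 50L
  cnt[2, 21:40] <- 50L
  rc <- raup_crick_bray(community_table(cnt), n_null = 999, seed = 6,
                        pairs = data.frame(sample_i = "S1", sample_j = "S2"))
  expect_equal(rc$bc_obs, 1)
  expect_gte(rc$rc_bray, 0.95)
})

test_that("process classification applies the strict threshold semantics", {
  # truth table including the boundary values
  bnti <- c(-2.5, -2, 2, 2.5, 0.5, 0.5, 0.5, 0, NA)
  rc <- c(0, 0, 0, 0, 0.97, -0.99, 0.2, 0.95, 0)
  got <- as.character(classify_process(bnti, rc))
  expect_identical(got, c("homogeneous_selection",
                          "drift",                 # bNTI = -2 is NOT selection
                          "drift",                 # bNTI = +2 is NOT selection
                          "variable_selection",
                          "dispersal_limitation",
                          "homogenizing_dispersal",
                          "drift",
                          "drift",                 # RCbray = 0.95 IS drift
                          "undetermined"))
  expect_error(classify_process(c(0, 0), 0.5), "length")
  expect_error(classify_process(0.5, NA_real_), "missing")
})
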
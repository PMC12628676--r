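test_that("pairs are categorized exactly as the comparison-subset definitions", {
  meta <- design_meta(2, 2, 2)
  p <- function(a, b) data.frame(sample_i = a, sample_j = b)
  cat1 <- categorize_pairs(meta, p("L1_2017_A", "L1_2017_B"))
  expect_identical(as.character(cat1$category), "intra_lake")
  expect_identical(cat1$replicate_combo, "A-B")
  cat2 <- categorize_pairs(meta, p("L1_2017_A", "L2_2017_A"))
  expect_identical(as.character(cat2$category), "inter_lake_same_year")
  cat3 <- categorize_pairs(meta, p("L1_2017_A", "L1_2019_B"))
  expect_identical(as.character(cat3$category), "inter_year_same_lake")
  cat4 <- categorize_pairs(meta, p("L1_2017_A", "L2_2019_B"))
  expect_identical(as.character(cat4$category), "other")
  # unordered combo canonicalization: B-A collapses onto A-B
  cat5 <- categorize_pairs(meta, p("L1_2017_B", "L2_2017_A"))
  expect_identical(cat5$replicate_combo, "A-B")
  cat6 <- categorize_pairs(meta, p("L1_2017_B", "L2_2017_A"), ordered_combos = TRUE)
  expect_identical(cat6$replicate_combo, "B-A")
  # cross-habitat pairs are rejected
  meta2 <- meta
  meta2$habitat[1] <- "sediment"
  expect_error(categorize_pairs(meta2, p("L1_2017_A", "L1_2017_B")), "habitat")
})

test_that("complete designs satisfy the closed-form pair counts", {
  for (dims in list(c(3, 2, 2), c(4, 3, 2), c(2, 2, 3))) {
    E <- dims[1]; Y <- dims[2]; R <- dims[3]
    meta <- design_meta(E, Y, R)
    pairs <- categorize_pairs(meta, unordered_pairs(meta$sample_id))
    counts <- table(pairs$category)
    expect_identical(unname(counts["intra_lake"]),
                     as.integer(E * Y * choose(R, 2)))
    expect_identical(unname(counts["inter_lake_same_year"]),
                     as.integer(choose(E, 2) * Y * R^2))
    expect_identical(unname(counts["inter_year_same_lake"]),
                     as.integer(E * choose(Y, 2) * R^2))
    expect_identical(nrow(pairs), as.integer(choose(E * Y * R, 2)))
    # exhaustive cross-check: recompute categories by direct metadata lookups
    rownames(meta) <- meta$sample_id
    a <- meta[pairs$sample_i, ]; b <- meta[pairs$sample_j, ]
    manual <- ifelse(a$ecosystem == b$ecosystem & a$year == b$year, "intra_lake",
              ifelse(a$year == b$year, "inter_lake_same_year",
              ifelse(a$ecosystem == b$ecosystem, "inter_year_same_lake", "other")))
    expect_identical(as.character(pairs$category), manual)
  }
})

make_records <- function(process, combo, category = "inter_lake_same_year") {
  data.frame(sample_i = "x", sample_j = "y", process = factor(process,
             levels = c("variable_selection", "homogeneous_selection",
                        "dispersal_limitation", "homogenizing_dispersal",
                        "drift", "undetermined")),
             category = factor(category,
                               levels = c("intra_lake", "inter_lake_same_year",
                                          "inter_year_same_lake", "other")),
             replicate_combo = combo, stringsAsFactors = FALSE)
}

test_that("contribution summaries average percentages across comparison types", {
  rec <- make_records(rep("drift", 10), rep(c("A-A", "A-B"), each = 5))
  out <- contributions(rec, "inter_lake_same_year")
  expect_equal(out$mean_percent[out$process == "drift"], 100)
  expect_equal(out$sd_percent[out$process == "drift"], 0)
  expect_equal(sum(out$mean_percent), 100, tolerance = 1e-9)

  # two types at 60% and 40% drift: mean 50, sd = 14.142
  rec2 <- make_records(c(rep("drift", 3), rep("variable_selection", 2),
                         rep("drift", 2), rep("variable_selection", 3)),
                       rep(c("A-A", "A-B"), each = 5))
  out2 <- contributions(rec2, "inter_lake_same_year")
  drift_row <- out2[out2$process == "drift", ]
  expect_equal(drift_row$mean_percent, 50)
  expect_equal(drift_row$sd_percent, sqrt((60 - 50)^2 + (40 - 50)^2), tolerance = 1e-6)
  expect_equal(drift_row$ci95_halfwidth, 1.96 * drift_row$sd_percent / sqrt(2),
               tolerance = 1e-9)
  # per-type percentages always sum to 100
  per_type <- attr(out2, "per_type")
  expect_equal(unname(rowSums(per_type)), rep(100, 2), tolerance = 1e-9)

  # undetermined pairs leave the denominator
  rec3 <- make_records(c("drift", "undetermined"), c("A-A", "A-A"))
  out3 <- contributions(rec3, "inter_lake_same_year")
  expect_equal(out3$mean_percent[out3$process == "drift"], 100)
  expect_identical(out3$n_pairs[1], 1L)
  expect_error(contributions(make_records("drift", "A-A", "intra_lake"),
                             "inter_year_same_lake"), "no classified pair")
})

test_that("the exact permutation test enumerates relabelings and hits known p-values", {
  same <- subset_permutation_test(c(10, 20, 30), c(10, 20, 30))
  expect_true(same$exact)
  expect_equal(same$p_value, 1)
  extreme <- subset_permutation_test(c(0, 0, 0), c(100, 100, 100))
  expect_equal(extreme$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  # Monte-Carlo branch (force by a tiny cap) includes the observed statistic
  mc <- subset_permutation_test(rnorm(8), rnorm(8), n_perm = 199,
                                exact_cap = 10, seed = 1)
  expect_false(mc$exact)
  expect_gte(mc$p_value, 1 / 200)
  expect_error(subset_permutation_test(numeric(0), 1:3), "non-empty")
})
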
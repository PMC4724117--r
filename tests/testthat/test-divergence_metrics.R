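test_that("Dice similarity matches hand-computed and boundary cases", {
  expect_equal(shared_annotation_similarity(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(shared_annotation_similarity(c("A", "B"), c("C", "D")), 0)
  expect_equal(shared_annotation_similarity(c("A", "B", "C"), c("B", "C", "D")),
               2 * 2 / (3 + 3))
  # duplicated annotations collapse before scoring
  expect_equal(shared_annotation_similarity(c("A", "A", "B"), c("A", "B")), 1)
  # empty sets are undefined, not zero
  expect_true(is.na(shared_annotation_similarity(character(), c("A"))))
})

test_that("Dice similarity agrees with a set-enumeration oracle and is symmetric", {
  universe <- sprintf("t%02d", 1:12)
  withr::with_seed(99, {
    for (i in 1:1000) {
      a <- sample(universe, sample(1:8, 1))
      b <- sample(universe, sample(1:8, 1))
      got <- shared_annotation_similarity(a, b)
      expect_identical(got, shared_annotation_similarity(b, a))
      expect_equal(got, dice_oracle(a, b))
      expect_gte(got, 0); expect_lte(got, 1)
      if (got == 1) expect_setequal(a, b)
      if (got == 0) expect_length(intersect(a, b), 0)
    }
  })
})

test_that("expression correlation matches the textbook formula exactly", {
  expect_equal(expression_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(expression_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand-derived: centred cross-sum 4, each sum of squares 5 -> 4/5
  expect_equal(expression_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  withr::with_seed(7, {
    for (i in 1:200) {
      a <- stats::runif(sample(3:30, 1), 0, 50)
      b <- stats::runif(length(a), 0, 50)
      got <- expression_correlation(a, b)
      expect_equal(got, pearson_two_pass(a, b), tolerance = 1e-12)
      # the raw-sums form the centred computation is algebraically equal to
      n <- length(a)
      raw <- (n * sum(a * b) - sum(a) * sum(b)) /
        sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
      expect_equal(got, raw, tolerance = 1e-9)
      # invariance under positive affine maps; antisymmetry under negation
      expect_equal(expression_correlation(2.5 * a + 3, b), got, tolerance = 1e-12)
      expect_equal(expression_correlation(a, -b), -got, tolerance = 1e-12)
    }
  })
})

test_that("undefined correlations return NA and mismatched tissues intersect", {
  expect_true(is.na(expression_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(expression_correlation(c(1, 2), c(1, 2))))

  a <- c(liver = 1, lung = 2, kidney = 3, skin = 9)
  b <- c(lung = 3, kidney = 2, liver = 1, spleen = 4)
  expect_equal(expression_correlation(a, b),
               expression_correlation(c(1, 2, 3), c(1, 3, 2)))
  expect_true(is.na(expression_correlation(c(liver = 1, lung = 2, skin = 3),
                                           c(liver = 1, heart = 2, brain = 3))))
})

test_that("score_all_pairs conserves pairs and logs exclusions per reason", {
  ds <- tiny_dataset()
  bp <- score_all_pairs(ds, "BP")
  # g5 has no BP annotation -> pair g4-g5 excluded
  expect_equal(nrow(bp) + sum(exclusion_log(bp)$n), nrow(ds$pairs))
  expect_equal(exclusion_log(bp)$n[exclusion_log(bp)$reason == "missing_annotation"], 1L)
  # hand-check one value: g1 {t1,t2} vs g3 {t1} -> 2*1/(2+1)
  expect_equal(bp$value[bp$gene_a == "g1" & bp$gene_b == "g3"], 2 / 3)

  cc <- score_all_pairs(ds, "CC")
  expect_equal(nrow(cc), 1)  # only g1-g2 both have CC terms
  expect_equal(cc$value, 1)

  ex <- score_all_pairs(ds, "expression")
  log <- exclusion_log(ex)
  # g5 has no profile; g3's constant profile (5,5,5) kills two pairs
  expect_equal(log$n[log$reason == "missing_expression_profile"], 1L)
  expect_equal(log$n[log$reason == "constant_profile"], 2L)
  expect_equal(nrow(ex) + sum(log$n), nrow(ds$pairs))
  expect_equal(ex$n_basis, rep(3L, nrow(ex)), ignore_attr = TRUE)
})

test_that("mean pair score recovers a 0.5 Dice target on a large sample", {
  cfg <- synthetic_config(
    n_pairs_ssd = 2000L, n_pairs_wgd = 2000L,
    dice_target = list(SSD = c(BP = 0.5, MF = 0.5, CC = 0.5),
                       WGD = c(BP = 0.5, MF = 0.5, CC = 0.5)),
    frac_both = 0, seed = 31L
  )
  scores <- score_all_pairs(generate_dataset(cfg), "BP")
  expect_lt(abs(mean(scores$value) - 0.5), 0.03)
})
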
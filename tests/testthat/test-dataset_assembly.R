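test_that("origin labelling follows the reference list and identity threshold", {
  candidates <- tibble::tibble(
    gene_a = c("a", "c", "e", "g"),
    gene_b = c("b", "d", "f", "h"),
    identity_pct = c(30, 49.9, 50.0, NA)
  )
  ref <- tibble::tibble(gene_a = "b", gene_b = "a")  # reversed orientation
  labelled <- label_pairs(candidates, ref, min_identity_pct = 50)

  # reference pair is WGD even at 30% identity
  expect_equal(labelled$origin[labelled$gene_a == "a"], "WGD")
  # 49.9% at threshold 50 is excluded; 50.0% is SSD (inclusive bound)
  expect_false("c" %in% labelled$gene_a)
  expect_equal(labelled$origin[labelled$gene_a == "e"], "SSD")
  # missing identity off the reference list is excluded with a logged reason
  expect_false("g" %in% labelled$gene_a)
  log <- exclusion_log(labelled)
  expect_equal(log$n[log$reason == "missing_identity"], 1L)
  expect_equal(log$n[log$reason == "below_identity_threshold"], 1L)
  dispositions <- attr(labelled, "disposition_log")
  expect_equal(nrow(dispositions), 4)
})

test_that("labelling is idempotent and order-independent", {
  ds <- generate_dataset(small_config())
  ref <- ds$pairs[ds$pairs$origin == "WGD", c("gene_a", "gene_b")]
  once <- label_pairs(ds$pairs, ref, 50)
  twice <- label_pairs(once, ref, 50)
  expect_equal(dplyr::as_tibble(once), dplyr::as_tibble(twice))

  shuffled <- ds$pairs[rev(seq_len(nrow(ds$pairs))), ]
  relabelled <- label_pairs(shuffled, ref, 50)
  key <- function(p) paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b), p$origin)
  expect_setequal(key(once), key(relabelled))
})

test_that("genes partition into disjoint SSD-only / WGD-only / both sets", {
  pairs <- tibble::tibble(
    gene_a = c("g1", "g1", "g2", "g5"),
    gene_b = c("g2", "g3", "g4", "g6"),
    origin = c("SSD", "WGD", "SSD", "SSD")
  )
  part <- partition_gene_sets(pairs)
  expect_equal(part$both, "g1")                 # one SSD and one WGD pair
  expect_true(all(c("g2", "g4", "g5", "g6") %in% part$ssd_only))
  expect_equal(part$wgd_only, "g3")

  ds <- generate_dataset(small_config(frac_both = 0.25, seed = 9L))
  p <- partition_gene_sets(ds$pairs)
  expect_length(intersect(p$ssd_only, p$wgd_only), 0)
  expect_length(intersect(p$ssd_only, p$both), 0)
  expect_length(intersect(p$wgd_only, p$both), 0)
  expect_setequal(c(p$ssd_only, p$wgd_only, p$both),
                  unique(c(ds$pairs$gene_a, ds$pairs$gene_b)))
})

test_that("dN bin assignment is half-open, total, and conserving", {
  expect_equal(assign_dn_bin(0.05), "0.0-0.1")
  expect_equal(assign_dn_bin(0.1), "0.1-0.2")   # boundary goes up
  expect_equal(assign_dn_bin(0.73), ">0.4")
  expect_equal(assign_dn_bin(0), "0.0-0.1")
  expect_true(is.na(assign_dn_bin(NA_real_)))

  dn <- withr::with_seed(1, stats::rgamma(500, 2, 5))
  labels <- assign_dn_bin(dn)
  expect_false(anyNA(labels))
  expect_equal(sum(table(labels)), 500)

  pairs <- tibble::tibble(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                          origin = "SSD", dn = c(0.1, NA, 0.3, 2))
  binned <- paralogdiv:::bin_pairs(pairs)
  expect_equal(nrow(binned), 3)
  expect_equal(exclusion_log(binned)$n, 1L)
})

test_that("closest-pair selection matches a brute-force oracle", {
  closest_oracle <- function(pairs) {
    keep <- rep(FALSE, nrow(pairs))
    long <- rbind(
      data.frame(g = pairs$gene_a, row = seq_len(nrow(pairs))),
      data.frame(g = pairs$gene_b, row = seq_len(nrow(pairs)))
    )
    for (g in unique(long$g)) {
      rows <- long$row[long$g == g]
      for (o in unique(pairs$origin[rows])) {
        cand <- rows[pairs$origin[rows] == o]
        cand <- cand[order(pairs$dn[cand], -pairs$identity_pct[cand],
                           ifelse(pairs$gene_a[cand] == g,
                                  pairs$gene_b[cand], pairs$gene_a[cand]))]
        keep[cand[1]] <- TRUE
      }
    }
    which(keep)
  }

  for (seed in 1:5) {
    pairs <- withr::with_seed(seed, {
      n <- sample(10:50, 1)
      g <- sprintf("g%02d", 1:12)
      ab <- t(replicate(n, sample(g, 2)))
      tibble::tibble(
        gene_a = ab[, 1], gene_b = ab[, 2],
        origin = sample(c("SSD", "WGD"), n, replace = TRUE),
        dn = round(stats::rgamma(n, 2, 5), 1),  # rounding forces dn ties
        identity_pct = sample(c(50, 60, 70), n, replace = TRUE)
      )
    })
    got <- select_closest_pairs(pairs)
    want <- pairs[closest_oracle(pairs), ]
    keyify <- function(p) sort(paste(pmin(p$gene_a, p$gene_b),
                                     pmax(p$gene_a, p$gene_b), p$origin, p$dn))
    expect_equal(keyify(got), keyify(want), info = paste("seed", seed))
    expect_lte(nrow(got), nrow(pairs))
  }

  # stated tie-breaks: equal dN -> higher identity wins the nomination
  # (p1/p2 have closer pairs of their own, so only G's choice matters here)
  tied <- tibble::tibble(
    gene_a = c("G", "G", "p1", "p2"), gene_b = c("p1", "p2", "q", "r"),
    origin = "SSD",
    dn = c(0.2, 0.2, 0.1, 0.1), identity_pct = c(55, 60, 70, 70)
  )
  kept <- select_closest_pairs(tied)
  expect_false("p1" %in% kept$gene_b[kept$gene_a == "G"])
  expect_true("p2" %in% kept$gene_b[kept$gene_a == "G"])
  # a gene's single pair is always retained
  single <- tibble::tibble(gene_a = "G", gene_b = "H", origin = "WGD",
                           dn = 0.9, identity_pct = NA_real_)
  expect_equal(nrow(select_closest_pairs(single)), 1)
})

test_that("young/old SSD split uses both members' phylostratum ranks", {
  pairs <- tibble::tibble(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                          origin = "SSD", dn = 0.1, ds = 0.2,
                          identity_pct = 60)
  ranks <- c(a = 1, b = 1, c = 15, d = 15, e = 12)  # f missing
  halves <- split_ssd_by_age(pairs, ranks, young_threshold = 10)
  expect_equal(halves$old$gene_a, "a")     # both rank 1 (oldest)
  expect_equal(halves$young$gene_a, "c")   # both rank 15 > 10
  expect_equal(halves$n_excluded_missing_rank, 1)
})
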
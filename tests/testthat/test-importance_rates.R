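make_partition <- function(ssd = character(), wgd = character(), both = character()) {
  structure(list(ssd_only = ssd, wgd_only = wgd, both = both),
            class = "gene_partition")
}

test_that("ortholog rates apply the saturation filter and ds = 0 rule", {
  orth <- tibble::tibble(
    gene_id = c("s1", "s2", "s3", "w1", "b1", "u1"),
    outgroup = "mouse",
    dn = c(0.1, 0.1, 0.1, 0.2, 0.3, 0.1),
    ds = c(0.5, 3.0, 0.0, 2.99, 0.5, 0.5)
  )
  part <- make_partition(ssd = c("s1", "s2", "s3"), wgd = "w1", both = "b1")
  rows <- ortholog_rate_table(orth, part)

  expect_false("s2" %in% rows$gene_id)            # ds = 3.0 discarded
  expect_false("b1" %in% rows$gene_id)            # both-class gene excluded
  expect_false("u1" %in% rows$gene_id)            # not in any pair set
  expect_true("w1" %in% rows$gene_id)             # ds = 2.99 kept
  s3 <- rows[rows$gene_id == "s3", ]
  expect_equal(s3$dn, 0.1)
  expect_true(is.na(s3$dnds))                     # ds = 0: dn kept, ratio absent
  expect_equal(rows$dnds[rows$gene_id == "s1"], 0.2)
  expect_true(all(is.na(rows$dnds) | rows$dnds >= 0))

  log <- exclusion_log(rows)
  expect_equal(nrow(rows) + sum(log$n), nrow(orth))      # conservation
  expect_equal(log$n[log$reason == "ds_saturated"], 1L)
  expect_equal(log$n[log$reason == "gene_in_both_classes"], 1L)
})

test_that("multifunctionality counts use set semantics and default to zero", {
  genes <- tibble::tibble(gene_id = c("s1", "s2", "w1"),
                          essential = NA, disease = NA,
                          pfam_domain_count = c(2L, NA, 4L),
                          age_rank = NA_integer_)
  pairs <- tibble::tibble(gene_a = c("s1", "w1"), gene_b = c("s2", "s1"),
                          origin = c("SSD", "WGD"), dn = 0.1, ds = 0.5,
                          identity_pct = 60)
  go <- tibble::tibble(gene_id = c("s2", "s2", "s2", "w1"),
                       go_domain = c("BP", "BP", "BP", "MF"),
                       term_id = c("P1", "P1", "P2", "M1"))
  ds <- dataset(genes, pairs, go = go)
  part <- partition_gene_sets(pairs)   # s1 in both, s2 SSD-only, w1 WGD-only

  counts <- multifunctionality_counts(ds, part)
  expect_setequal(counts$gene_id, c("s2", "w1"))
  expect_equal(counts$go_bp_count[counts$gene_id == "s2"], 2L)  # P1 dup collapses
  expect_equal(counts$go_bp_count[counts$gene_id == "w1"], 0L)  # MF doesn't count
  expect_equal(counts$pfam_domain_count[counts$gene_id == "w1"], 4L)
})

test_that("generated group mean term counts are recovered", {
  ds <- generate_dataset(synthetic_config(n_pairs_ssd = 1000L, n_pairs_wgd = 1000L,
                                          frac_both = 0, seed = 88L))
  part <- partition_gene_sets(ds$pairs)
  counts <- multifunctionality_counts(ds, part)
  m <- tapply(counts$go_bp_count, counts$group, mean)
  expect_lt(abs(m[["SSD_only"]] - 5), 0.3)
  expect_lt(abs(m[["WGD_only"]] - 10), 0.3)
  pf <- tapply(counts$pfam_domain_count, counts$group, mean)
  expect_lt(abs(pf[["SSD_only"]] - 1.61), 0.15)
  expect_lt(abs(pf[["WGD_only"]] - 2.02), 0.15)
})

test_that("importance tabulation counts flag-bearing genes per group", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    essential = c(rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2),
                  rep(c(TRUE, TRUE, FALSE, FALSE), 2), NA, NA),
    disease = TRUE,
    pfam_domain_count = 1L, age_rank = 1L
  )
  part <- make_partition(ssd = sprintf("g%02d", 1:10),
                         wgd = sprintf("g%02d", 11:18))
  tab <- importance_tabulation(genes, part)
  ess <- tab[tab$flag == "essential", ]
  expect_equal(ess$proportion[ess$group == "SSD_only"], 0.2)
  expect_equal(ess$proportion[ess$group == "WGD_only"], 0.5)
  expect_equal(ess$total, c(10, 8))
  # row totals equal the number of flag-bearing genes per group
  expect_equal(sum(tab$total[tab$flag == "essential"]),
               sum(!is.na(genes$essential[1:18])))

  genes$essential <- NA
  expect_error(importance_tabulation(genes, part),
               class = "paralogdiv_tabulation_error", regexp = "SSD_only")
})

test_that("recovered flag proportions sit inside the binomial 99% interval", {
  ds <- generate_dataset(synthetic_config(n_pairs_ssd = 1500L, n_pairs_wgd = 2500L,
                                          frac_both = 0, seed = 17L))
  part <- partition_gene_sets(ds$pairs)
  tab <- importance_tabulation(ds, part)
  dz <- tab[tab$flag == "disease", ]
  targets <- c(SSD_only = 0.2789, WGD_only = 0.6146)
  for (grp in names(targets)) {
    row <- dz[dz$group == grp, ]
    half <- stats::qnorm(0.995) * sqrt(targets[[grp]] * (1 - targets[[grp]]) / row$total)
    expect_lt(abs(row$proportion - targets[[grp]]), half)
  }
})
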
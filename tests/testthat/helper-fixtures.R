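# Hand-written and generated fixtures shared across test files.

# A 5-gene, 4-pair, 3-tissue dataset small enough to verify by hand.
tiny_dataset <- function() {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    essential = c(TRUE, FALSE, FALSE, NA, TRUE),
    disease = c(FALSE, TRUE, FALSE, TRUE, NA),
    pfam_domain_count = c(1L, 2L, NA, 3L, 1L),
    age_rank = c(1L, 2L, 12L, 15L, NA)
  )
  pairs <- tibble::tibble(
    gene_a = c("g1", "g1", "g3", "g4"),
    gene_b = c("g2", "g3", "g4", "g5"),
    origin = c("SSD", "SSD", "WGD", "WGD"),
    dn = c(0.05, 0.25, 0.15, 0.55),
    ds = c(0.2, 1.1, 0.5, 2.8),
    identity_pct = c(80, 55, 40, 35)
  )
  go <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g4", "g1", "g2"),
    go_domain = c("BP", "BP", "BP", "BP", "BP", "BP", "CC", "CC"),
    term_id = c("t1", "t2", "t2", "t3", "t1", "t9", "c1", "c1")
  )
  expression <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    liver = c(1, 2, 5, 0),
    lung = c(2, 4, 5, 1),
    kidney = c(3, 6, 5, 7)
  )
  orth <- tibble::tibble(
    gene_id = c("g1", "g2", "g5", "g5"),
    outgroup = c("mouse", "mouse", "mouse", "chimp"),
    dn = c(0.1, 0.1, 0.2, 0.01),
    ds = c(0.5, 3.0, 0.0, 0.1)
  )
  dataset(genes, pairs, go = go, expression = expression, ortholog_rates = orth)
}

# small but non-degenerate generator config for fast tests
small_config <- function(...) {
  defaults <- list(n_pairs_ssd = 200L, n_pairs_wgd = 200L, frac_both = 0.1,
                   seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# a generator config with no SSD/WGD differences at all
null_config <- function(seed, n = 600L) {
  synthetic_config(
    n_pairs_ssd = n, n_pairs_wgd = n,
    dice_target = list(SSD = c(BP = 0.5, MF = 0.5, CC = 0.5),
                       WGD = c(BP = 0.5, MF = 0.5, CC = 0.5)),
    terms_per_gene = list(SSD = c(BP = 5, MF = 5, CC = 5),
                          WGD = c(BP = 5, MF = 5, CC = 5)),
    expr_r_target = c(SSD = 0.3, WGD = 0.3),
    dn_distribution = list(SSD = c(shape = 1.8, mean = 0.3),
                           WGD = c(shape = 1.8, mean = 0.3)),
    essential_rate = c(SSD = 0.1, WGD = 0.1),
    disease_rate = c(SSD = 0.4, WGD = 0.4),
    pfam_mean = c(SSD = 2, WGD = 2),
    ortholog_rates = list(mouse = list(dn = c(SSD = 0.09, WGD = 0.09),
                                       dnds = c(SSD = 0.13, WGD = 0.13))),
    frac_both = 0, seed = seed
  )
}

# exact two-tailed Mann-Whitney p by full enumeration of rank assignments;
# independent of the implementation (no pwilcox)
mwu_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_ranks <- seq_len(n1 + n2)
  sets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(all_ranks[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  u_min <- min(u_obs, n1 * n2 - u_obs)
  min(1, 2 * mean(u_all <= u_min))
}

# brute-force Dice similarity over explicit membership vectors
dice_oracle <- function(a, b) {
  universe <- union(a, b)
  if (!length(a) || !length(b)) return(NA_real_)
  ina <- universe %in% a
  inb <- universe %in% b
  2 * sum(ina & inb) / (sum(ina) + sum(inb))
}

# textbook two-pass Pearson: means first, then centred sums
pearson_two_pass <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
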
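# Seeded generator for datasets with the statistical structure the
# SSD-vs-WGD analysis assumes: origin-dependent annotation overlap,
# correlated tissue expression, origin-shifted dN distributions, and
# origin-dependent essentiality/disease rates.
#
# Design notes (expanded in the methods vignette):
# * Annotation overlap: both genes of a pair receive the same term count n
#   (1 + Poisson(mean - 1)); the shared count is Binomial(n, dice_target),
#   so E[Dice] = dice_target exactly, for any target in [0, 1].
# * Expression: latent correlated bivariate normal per tissue; the latent
#   correlation carries a small finite-sample adjustment
#   rho + rho(1 - rho^2) / (2 (N - 1)) so the mean *sample* Pearson r over
#   pairs sits on the target; values are shifted and clamped to >= 0.
# * dN per pair is gamma with per-origin shape/mean (WGD shifted higher, as
#   the older duplicate class); dS = dN x (min + gamma) so dS >= dN
#   whenever the multiplier's lower bound is >= 1.

# The 27 normal-tissue panel used for the default expression profiles.
HPA_TISSUES <- c(
  "adipose tissue", "adrenal gland", "appendix", "bone marrow",
  "cerebral cortex", "colon", "duodenum", "oesophagus", "gallbladder",
  "heart muscle", "kidney", "liver", "lung", "lymph node", "ovary",
  "pancreas", "placenta", "prostate", "salivary gland", "skin",
  "small intestine", "spleen", "stomach", "testis", "thyroid gland",
  "urinary bladder", "uterus"
)

#' Configuration for the synthetic-data generator
#'
#' The defaults encode the study conditions the analysis is calibrated
#' against: per-origin Dice-similarity targets for the three GO domains,
#' per-origin expression-correlation targets over 27 tissues, per-origin dN
#' distributions (the WGD class shifted to higher dN, being the older
#' duplicate class), per-origin essentiality/disease rates, per-origin and
#' per-outgroup ortholog dN and dN/dS means, and mean unique-term /
#' Pfam-domain counts. All are overridable.
#'
#' @param n_pairs_ssd,n_pairs_wgd Number of base pairs per origin class.
#' @param dice_target Named list `SSD`/`WGD`, each a named numeric over
#'   `BP`, `MF`, `CC`: target mean Dice similarity in `[0, 1]`.
#' @param terms_per_gene Same shape: mean annotation-set size per domain
#'   (must be `>= 1`; sizes are `1 + Poisson(mean - 1)`).
#' @param expr_r_target Named numeric `SSD`/`WGD`: target mean pairwise
#'   Pearson correlation, in `(-1, 1)`.
#' @param n_tissues Number of tissues (`>= 3`); the first 27 take the
#'   standard normal-tissue names.
#' @param dn_distribution Named list `SSD`/`WGD`, each `c(shape=, mean=)`
#'   for the gamma pair-dN distribution.
#' @param ds_over_dn `c(min=, shape=, mean=)`: dS = dN x (min + gamma draw),
#'   gamma with the given shape and mean `mean - min`.
#' @param essential_rate,disease_rate Named numeric `SSD`/`WGD`
#'   probabilities in `[0, 1]`, applied to genes belonging to exactly one
#'   origin class.
#' @param pfam_mean Named numeric `SSD`/`WGD`: Poisson mean domain count.
#' @param ortholog_rates Named list, one element per outgroup, each a list
#'   with named numerics `dn` and `dnds` over `SSD`/`WGD` (per-gene gamma
#'   means).
#' @param frac_both Probability a base gene additionally acquires a pair of
#'   the opposite origin, making it a member of both duplicate classes.
#' @param identity_range Named list `SSD`/`WGD` of `c(lo, hi)` percent
#'   identity ranges (uniform draw).
#' @param age_rank_range Named list `SSD`/`WGD` of integer `c(lo, hi)`
#'   phylostratum-rank ranges (1 = oldest; uniform draw).
#' @param expr_location,expr_scale Location/scale applied to the latent
#'   normal expression before clamping at zero.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_pairs_ssd = 5000L,
    n_pairs_wgd = 5000L,
    dice_target = list(SSD = c(BP = 0.710, MF = 0.840, CC = 0.782),
                       WGD = c(BP = 0.415, MF = 0.659, CC = 0.541)),
    terms_per_gene = list(SSD = c(BP = 5, MF = 4, CC = 5),
                          WGD = c(BP = 10, MF = 4, CC = 5)),
    expr_r_target = c(SSD = 0.403, WGD = 0.193),
    n_tissues = 27L,
    dn_distribution = list(SSD = c(shape = 1.8, mean = 0.25),
                           WGD = c(shape = 2.2, mean = 0.55)),
    ds_over_dn = c(min = 1, shape = 2, mean = 2.5),
    essential_rate = c(SSD = 0.04601, WGD = 0.11344),
    disease_rate = c(SSD = 0.2789, WGD = 0.6146),
    pfam_mean = c(SSD = 1.61, WGD = 2.02),
    ortholog_rates = list(
      mouse = list(dn = c(SSD = 0.089, WGD = 0.062),
                   dnds = c(SSD = 0.135, WGD = 0.101)),
      chimp = list(dn = c(SSD = 0.012, WGD = 0.006),
                   dnds = c(SSD = 0.480, WGD = 0.257))
    ),
    frac_both = 0.2,
    identity_range = list(SSD = c(50, 99), WGD = c(30, 99)),
    age_rank_range = list(SSD = c(1L, 16L), WGD = c(1L, 3L)),
    expr_location = 8,
    expr_scale = 1.5,
    seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort_config(msg)
  chk(cfg$n_pairs_ssd >= 1 && cfg$n_pairs_wgd >= 1,
      "n_pairs_ssd and n_pairs_wgd must be >= 1")
  chk(cfg$n_tissues >= 3, "n_tissues must be >= 3")
  for (o in ORIGINS) {
    chk(all(cfg$dice_target[[o]] >= 0 & cfg$dice_target[[o]] <= 1) &&
          setequal(names(cfg$dice_target[[o]]), GO_DOMAINS),
        paste0("dice_target$", o, " must be named over BP/MF/CC with values in [0, 1]"))
    chk(all(cfg$terms_per_gene[[o]] >= 1),
        paste0("terms_per_gene$", o, " means must be >= 1"))
    chk(abs(cfg$expr_r_target[[o]]) < 1,
        paste0("expr_r_target['", o, "'] must lie in (-1, 1)"))
    chk(all(cfg$dn_distribution[[o]] > 0),
        paste0("dn_distribution$", o, " shape and mean must be positive"))
    chk(cfg$essential_rate[[o]] >= 0 && cfg$essential_rate[[o]] <= 1 &&
          cfg$disease_rate[[o]] >= 0 && cfg$disease_rate[[o]] <= 1,
        "essential_rate and disease_rate must be probabilities")
    chk(cfg$pfam_mean[[o]] >= 0, "pfam_mean must be >= 0")
  }
  chk(cfg$ds_over_dn[["min"]] >= 0 && cfg$ds_over_dn[["shape"]] > 0 &&
        cfg$ds_over_dn[["mean"]] > cfg$ds_over_dn[["min"]],
      "ds_over_dn must satisfy min >= 0, shape > 0, mean > min")
  chk(cfg$frac_both >= 0 && cfg$frac_both <= 1, "frac_both must be in [0, 1]")
  chk(cfg$expr_scale > 0, "expr_scale must be positive")
  for (og in cfg$ortholog_rates) {
    chk(all(og$dn > 0) && all(og$dnds > 0),
        "ortholog_rates means must be positive")
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  pairs: %d SSD + %d WGD (frac_both = %.2f), seed = %d\n",
              x$n_pairs_ssd, x$n_pairs_wgd, x$frac_both, as.integer(x$seed)))
  cat(sprintf("  Dice targets BP: %.3f / %.3f   expression r: %.3f / %.3f\n",
              x$dice_target$SSD[["BP"]], x$dice_target$WGD[["BP"]],
              x$expr_r_target[["SSD"]], x$expr_r_target[["WGD"]]))
  invisible(x)
}

# latent correlation whose mean sample r over n_tissues matches the target
latent_rho <- function(target, n_tissues) {
  min(0.999, target + target * (1 - target^2) / (2 * (n_tissues - 1)))
}

rgamma_mean <- function(n, shape, mean) {
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate a synthetic duplicate-gene dataset
#'
#' Builds a complete [dataset()] under the statistical targets of a
#' [synthetic_config()]: base pairs per origin with disjoint genes, plus a
#' `frac_both` fraction of genes that acquire an extra pair of the opposite
#' origin (so the SSD-only / WGD-only / both partition is non-trivial).
#' Identical configs (including `seed`) give identical datasets.
#'
#' @param config A `synthetic_config`.
#' @return A validated `pd_dataset` with attribute `synthetic_seed`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort_config("generate_dataset() expects a synthetic_config")
  }
  withr::with_seed(as.integer(config$seed), generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_base <- c(SSD = cfg$n_pairs_ssd, WGD = cfg$n_pairs_wgd)
  n_base_genes <- 2L * sum(n_base)

  # base pairs: disjoint genes, consecutive ids
  gene_id <- sprintf("G%06d", seq_len(n_base_genes))
  base_origin <- rep(ORIGINS, times = 2L * n_base)          # per gene
  idx_a <- seq(1L, n_base_genes, by = 2L)
  pairs <- tibble::tibble(
    gene_a = gene_id[idx_a],
    gene_b = gene_id[idx_a + 1L],
    origin = rep(ORIGINS, times = n_base)
  )

  # cross pairs: a base gene gains a partner of the opposite origin
  takes_cross <- stats::runif(n_base_genes) < cfg$frac_both
  cross_gene <- gene_id[takes_cross]
  cross_origin <- as.character(ifelse(base_origin[takes_cross] == "SSD", "WGD", "SSD"))
  n_cross <- length(cross_gene)
  partner_id <- if (n_cross) sprintf("X%06d", seq_len(n_cross)) else character()
  if (n_cross) {
    pairs <- dplyr::bind_rows(
      pairs,
      tibble::tibble(gene_a = cross_gene, gene_b = partner_id, origin = cross_origin)
    )
  }

  all_gene_id <- c(gene_id, partner_id)
  # the origin whose distributions a gene's own attributes are drawn from
  gene_origin <- c(base_origin, cross_origin)
  names(gene_origin) <- all_gene_id
  in_both <- all_gene_id %in% cross_gene

  # pair-level divergence
  np <- nrow(pairs)
  dn <- numeric(np); identity_pct <- numeric(np)
  for (o in ORIGINS) {
    sel <- pairs$origin == o
    par <- cfg$dn_distribution[[o]]
    dn[sel] <- rgamma_mean(sum(sel), par[["shape"]], par[["mean"]])
    rng <- cfg$identity_range[[o]]
    identity_pct[sel] <- stats::runif(sum(sel), rng[1], rng[2])
  }
  mult <- cfg$ds_over_dn[["min"]] +
    rgamma_mean(np, cfg$ds_over_dn[["shape"]],
                cfg$ds_over_dn[["mean"]] - cfg$ds_over_dn[["min"]])
  pairs$dn <- dn
  pairs$ds <- dn * mult
  pairs$identity_pct <- round(identity_pct, 2)

  # GO annotations: per pair and domain, both genes get n terms of which s
  # are shared; term ids are private to the pair (plus inherited terms for
  # cross pairs, built from the base gene's existing set)
  n_base_pairs <- sum(n_base)
  go <- vector("list", 3L * 2L)
  k <- 0L
  base_terms <- list()  # per domain: list of term vectors for base genes
  for (dom in GO_DOMAINS) {
    porig <- pairs$origin[seq_len(n_base_pairs)]
    mean_terms <- unname(vapply(porig, function(o) cfg$terms_per_gene[[o]][[dom]], 1.0))
    dice <- unname(vapply(porig, function(o) cfg$dice_target[[o]][[dom]], 1.0))
    n_terms <- 1L + stats::rpois(n_base_pairs, mean_terms - 1)
    s <- stats::rbinom(n_base_pairs, n_terms, dice)

    pair_of_row <- rep.int(seq_len(n_base_pairs), n_terms)
    within <- sequence(n_terms)
    shared <- within <= s[pair_of_row]
    stub <- sprintf("%s:%06d:", dom, pair_of_row)
    term_a <- paste0(stub, ifelse(shared, "s", "a"), within)
    term_b <- paste0(stub, ifelse(shared, "s", "b"), within)

    ga <- pairs$gene_a[pair_of_row]; gb <- pairs$gene_b[pair_of_row]
    k <- k + 1L
    go[[k]] <- tibble::tibble(
      gene_id = c(ga, gb), go_domain = dom, term_id = c(term_a, term_b)
    )
    terms_by_gene <- split(c(term_a, term_b), c(ga, gb))

    if (n_cross) {
      # partner inherits a Binomial(n_g, dice_target[new origin]) subset of
      # the base gene's terms plus fresh private terms up to the same size
      cross_dice <- unname(vapply(cross_origin,
                                  function(o) cfg$dice_target[[o]][[dom]], 1.0))
      ng <- lengths(terms_by_gene[cross_gene])
      sx <- stats::rbinom(n_cross, ng, cross_dice)
      rows <- lapply(seq_len(n_cross), function(i) {
        inherited <- terms_by_gene[[cross_gene[i]]][seq_len(sx[i])]
        n_priv <- ng[i] - sx[i]
        private <- if (n_priv) paste0(dom, ":x", partner_id[i], ":p",
                                      seq_len(n_priv)) else character()
        tibble::tibble(gene_id = partner_id[i], go_domain = dom,
                       term_id = c(inherited, private))
      })
      k <- k + 1L
      go[[k]] <- dplyr::bind_rows(rows)
    }
  }
  go <- dplyr::bind_rows(go[seq_len(k)])

  # expression: latent standard-normal profiles, pairwise correlated
  nt <- as.integer(cfg$n_tissues)
  tissues <- if (nt <= length(HPA_TISSUES)) HPA_TISSUES[seq_len(nt)] else
    c(HPA_TISSUES, sprintf("tissue_%02d", seq(length(HPA_TISSUES) + 1L, nt)))
  z <- matrix(NA_real_, nrow = length(all_gene_id), ncol = nt,
              dimnames = list(all_gene_id, NULL))
  z[pairs$gene_a[seq_len(n_base_pairs)], ] <-
    stats::rnorm(n_base_pairs * nt)
  for (o in ORIGINS) {
    sel <- which(pairs$origin == o & seq_len(np) <= n_base_pairs)
    rho <- latent_rho(cfg$expr_r_target[[o]], nt)
    eps <- matrix(stats::rnorm(length(sel) * nt), ncol = nt)
    z[pairs$gene_b[sel], ] <- rho * z[pairs$gene_a[sel], , drop = FALSE] +
      sqrt(1 - rho^2) * eps
  }
  if (n_cross) {
    for (o in ORIGINS) {
      sel <- which(cross_origin == o)
      if (!length(sel)) next
      rho <- latent_rho(cfg$expr_r_target[[o]], nt)
      eps <- matrix(stats::rnorm(length(sel) * nt), ncol = nt)
      z[partner_id[sel], ] <- rho * z[cross_gene[sel], , drop = FALSE] +
        sqrt(1 - rho^2) * eps
    }
  }
  expr_vals <- round(pmax(cfg$expr_location + cfg$expr_scale * z, 0), 4)
  expression <- tibble::as_tibble(as.data.frame(expr_vals))
  names(expression) <- tissues
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = all_gene_id), expression)

  # gene-level attributes; importance flags only for single-origin genes
  ng <- length(all_gene_id)
  origin_vec <- unname(gene_origin)
  essential <- disease <- rep(NA, ng)
  for (o in ORIGINS) {
    sel <- which(origin_vec == o & !in_both)
    essential[sel] <- stats::runif(length(sel)) < cfg$essential_rate[[o]]
    disease[sel] <- stats::runif(length(sel)) < cfg$disease_rate[[o]]
  }
  pfam <- age <- integer(ng)
  for (o in ORIGINS) {
    sel <- which(origin_vec == o)
    pfam[sel] <- stats::rpois(length(sel), cfg$pfam_mean[[o]])
    rng <- cfg$age_rank_range[[o]]
    age[sel] <- sample.int(rng[2] - rng[1] + 1L, length(sel), replace = TRUE) +
      rng[1] - 1L
  }
  genes <- tibble::tibble(
    gene_id = all_gene_id,
    essential = as.logical(essential),
    disease = as.logical(disease),
    pfam_domain_count = pfam,
    age_rank = age
  )

  # per-gene ortholog rates, one record per outgroup
  orth <- lapply(names(cfg$ortholog_rates), function(og) {
    par <- cfg$ortholog_rates[[og]]
    odn <- numeric(ng); ratio <- numeric(ng)
    for (o in ORIGINS) {
      sel <- which(origin_vec == o)
      odn[sel] <- rgamma_mean(length(sel), 2, par$dn[[o]])
      ratio[sel] <- rgamma_mean(length(sel), 8, par$dnds[[o]])
    }
    tibble::tibble(gene_id = all_gene_id, outgroup = og,
                   dn = odn, ds = odn / ratio)
  })
  ortholog_rates <- dplyr::bind_rows(orth)

  out <- dataset(genes, pairs, go = go, expression = expression,
                 ortholog_rates = ortholog_rates)
  attr(out, "synthetic_seed") <- as.integer(cfg$seed)
  out
}
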
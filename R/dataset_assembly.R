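# Pair labelling, filtering and stratification.
#
# Origin labelling follows the compiled-ohnolog-list convention: a pair on
# the WGD reference list is WGD regardless of identity; every other pair is
# SSD if it clears the percent-identity threshold (inclusive >= 50 by
# default), otherwise it is excluded. dN strata are half-open [lower,
# upper) with the last bin unbounded, the only partition consistent with
# five groups labelled 0.0-0.1 ... >0.4.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Label candidate paralog pairs by duplication origin
#'
#' Pairs present in the WGD reference list are labelled `WGD` (the identity
#' threshold does not apply to them); remaining pairs with
#' `identity_pct >= min_identity_pct` are labelled `SSD`; all others are
#' excluded. Pairs lacking `identity_pct` that are not on the reference
#' list are excluded with reason `missing_identity`. Order-independent and
#' idempotent.
#'
#' @param candidate_pairs Tibble in the pair-table schema (`gene_a`,
#'   `gene_b`, `identity_pct`, ...; any existing `origin` is overwritten).
#' @param wgd_reference_pairs Tibble (or data frame) with columns `gene_a`,
#'   `gene_b`: the compiled ohnolog reference list, unordered pairs.
#' @param min_identity_pct Inclusive identity threshold for SSD calls
#'   (default 50).
#' @return The retained pairs with an `origin` column; the per-disposition
#'   counts are available via [exclusion_log()] and the per-pair
#'   disposition log via `attr(., "disposition_log")`.
#' @export
label_pairs <- function(candidate_pairs, wgd_reference_pairs,
                        min_identity_pct = 50) {
  ref <- unique(pair_key(wgd_reference_pairs$gene_a, wgd_reference_pairs$gene_b))
  key <- pair_key(candidate_pairs$gene_a, candidate_pairs$gene_b)

  disposition <- dplyr::case_when(
    key %in% ref ~ "wgd_reference",
    is.na(candidate_pairs$identity_pct) ~ "missing_identity",
    candidate_pairs$identity_pct >= min_identity_pct ~ "ssd",
    TRUE ~ "below_identity_threshold"
  )

  out <- candidate_pairs
  out$origin <- dplyr::if_else(disposition == "wgd_reference", "WGD", "SSD")
  keep <- disposition %in% c("wgd_reference", "ssd")
  out <- out[keep, , drop = FALSE]

  excl <- table(disposition[!keep])
  out <- set_exclusions(out, stats::setNames(as.integer(excl), names(excl)))
  attr(out, "disposition_log") <- tibble::tibble(
    gene_a = candidate_pairs$gene_a, gene_b = candidate_pairs$gene_b,
    disposition = disposition
  )
  out
}

#' Partition genes by the origin classes of their pairs
#'
#' A gene appearing only in SSD pairs is `ssd_only`, only in WGD pairs
#' `wgd_only`, and in both classes `both`. Gene-level analyses (ortholog
#' rates, multifunctionality, essentiality/disease) use only the first two
#' sets; `both` genes are excluded downstream.
#'
#' @param pairs Origin-labelled pair tibble.
#' @return A `gene_partition`: list of disjoint sorted character vectors
#'   `ssd_only`, `wgd_only`, `both`.
#' @export
partition_gene_sets <- function(pairs) {
  long <- tibble::tibble(
    gene_id = c(pairs$gene_a, pairs$gene_b),
    origin = rep(pairs$origin, 2L)
  )
  tab <- dplyr::summarise(dplyr::group_by(long, .data$gene_id),
                          ssd = any(.data$origin == "SSD"),
                          wgd = any(.data$origin == "WGD"), .groups = "drop")
  structure(
    list(
      ssd_only = sort(tab$gene_id[tab$ssd & !tab$wgd]),
      wgd_only = sort(tab$gene_id[!tab$ssd & tab$wgd]),
      both = sort(tab$gene_id[tab$ssd & tab$wgd])
    ),
    class = "gene_partition"
  )
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> SSD-only %d | WGD-only %d | both %d\n",
              length(x$ssd_only), length(x$wgd_only), length(x$both)))
  invisible(x)
}

partition_lookup <- function(partition) {
  stats::setNames(
    rep(c("SSD_only", "WGD_only", "both"),
        times = lengths(partition[c("ssd_only", "wgd_only", "both")])),
    c(partition$ssd_only, partition$wgd_only, partition$both)
  )
}

#' Default dN strata
#'
#' Five half-open bins partitioning `[0, Inf)`: `[0, 0.1)`, `[0.1, 0.2)`,
#' `[0.2, 0.3)`, `[0.3, 0.4)` and `[0.4, Inf)`.
#'
#' @return Tibble with columns `label`, `lower` (inclusive), `upper`
#'   (exclusive).
#' @export
default_dn_bins <- function() {
  tibble::tibble(
    label = c("0.0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4", ">0.4"),
    lower = c(0, 0.1, 0.2, 0.3, 0.4),
    upper = c(0.1, 0.2, 0.3, 0.4, Inf)
  )
}

#' Assign dN values to strata
#'
#' Each value falls in the unique bin with `lower <= dn < upper`. `NA` dN
#' gives `NA` (such pairs are excluded from binned analyses, with the
#' exclusion counted by the caller).
#'
#' @param dn Numeric vector of pairwise dN values.
#' @param bins Bin table as from [default_dn_bins()].
#' @return Character vector of bin labels.
#' @export
assign_dn_bin <- function(dn, bins = default_dn_bins()) {
  if (any(diff(bins$lower) <= 0)) abort_config("bins must have increasing lower bounds")
  idx <- findInterval(dn, bins$lower)
  out <- rep(NA_character_, length(dn))
  ok <- !is.na(dn) & idx >= 1 & dn < bins$upper[pmax(idx, 1L)]
  out[ok] <- bins$label[idx[ok]]
  out
}

bin_pairs <- function(pairs, bins = default_dn_bins()) {
  pairs$dn_bin <- assign_dn_bin(pairs$dn, bins)
  keep <- !is.na(pairs$dn_bin)
  out <- pairs[keep, , drop = FALSE]
  set_exclusions(out, c(missing_dn = sum(!keep)))
}

#' Reduce each gene to its closest duplicate pair
#'
#' Within each origin class, every gene nominates its minimum-dN pair
#' (ties broken by higher `identity_pct`, then by lexicographically
#' smallest partner id); a pair is retained if it is the nomination of at
#' least one of its members. Controls for the influence of large gene
#' families.
#'
#' @param pairs Origin-labelled pair tibble with `dn`.
#' @return The retained subset of `pairs`.
#' @export
select_closest_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  row_id <- seq_len(nrow(pairs))
  long <- dplyr::bind_rows(
    tibble::tibble(gene = pairs$gene_a, partner = pairs$gene_b,
                   origin = pairs$origin, dn = pairs$dn,
                   identity_pct = pairs$identity_pct, row = row_id),
    tibble::tibble(gene = pairs$gene_b, partner = pairs$gene_a,
                   origin = pairs$origin, dn = pairs$dn,
                   identity_pct = pairs$identity_pct, row = row_id)
  )
  nominated <- long |>
    dplyr::group_by(.data$gene, .data$origin) |>
    dplyr::arrange(.data$dn, dplyr::desc(.data$identity_pct), .data$partner,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  pairs[sort(unique(nominated$row)), , drop = FALSE]
}

#' Split SSD pairs into young and old by phylostratum rank
#'
#' A pair is young when both members arose in a phylostratum more recent
#' than `young_threshold` (rank 1 = oldest, so young means
#' `age_rank > young_threshold` for both genes); otherwise old. Pairs with
#' a missing rank on either side are excluded and counted.
#'
#' @param ssd_pairs SSD pair tibble.
#' @param gene_age_ranks Either the gene table (with `gene_id`, `age_rank`)
#'   or a named integer vector of ranks.
#' @param young_threshold Rank above which a gene counts as young. No
#'   canonical default exists; it must be supplied.
#' @return List with elements `young`, `old` (pair tibbles) and
#'   `n_excluded_missing_rank`.
#' @export
split_ssd_by_age <- function(ssd_pairs, gene_age_ranks, young_threshold) {
  if (is.data.frame(gene_age_ranks)) {
    gene_age_ranks <- stats::setNames(gene_age_ranks$age_rank,
                                      gene_age_ranks$gene_id)
  }
  ra <- unname(gene_age_ranks[ssd_pairs$gene_a])
  rb <- unname(gene_age_ranks[ssd_pairs$gene_b])
  missing <- is.na(ra) | is.na(rb)
  young <- !missing & ra > young_threshold & rb > young_threshold
  list(
    young = ssd_pairs[young, , drop = FALSE],
    old = ssd_pairs[!missing & !young, , drop = FALSE],
    n_excluded_missing_rank = sum(missing)
  )
}
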
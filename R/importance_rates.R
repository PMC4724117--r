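# Gene-level analyses on the SSD-only / WGD-only partition: ortholog-based
# evolutionary rates with the dS saturation filter, multifunctionality
# counts, and essentiality/disease tabulation.

#' Per-gene ortholog evolutionary-rate rows
#'
#' Joins ortholog dN/dS records to the gene partition. Genes belonging to
#' both duplicate classes are excluded, as are records with `ds >= ds_max`
#' (mutational saturation; the default 3 discards dS of 3 and above).
#' `dnds` is `dn / ds` when `0 < ds < ds_max`; a record with `ds = 0`
#' keeps its `dn` but contributes no ratio.
#'
#' @param ortholog_rates Tibble `gene_id`, `outgroup`, `dn`, `ds`.
#' @param partition A [partition_gene_sets()] result.
#' @param ds_max Exclusive saturation bound on dS (records with
#'   `ds >= ds_max` are discarded entirely).
#' @return Tibble `gene_id`, `group` (`SSD_only`/`WGD_only`), `outgroup`,
#'   `dn`, `dnds`; exclusion counts via [exclusion_log()].
#' @export
ortholog_rate_table <- function(ortholog_rates, partition, ds_max = 3) {
  lookup <- partition_lookup(partition)
  group <- unname(lookup[ortholog_rates$gene_id])
  in_both <- !is.na(group) & group == "both"
  unpartitioned <- is.na(group)
  saturated <- !in_both & !unpartitioned & ortholog_rates$ds >= ds_max
  keep <- !in_both & !unpartitioned & !saturated

  out <- tibble::tibble(
    gene_id = ortholog_rates$gene_id[keep],
    group = group[keep],
    outgroup = ortholog_rates$outgroup[keep],
    dn = ortholog_rates$dn[keep],
    dnds = ifelse(ortholog_rates$ds[keep] > 0,
                  ortholog_rates$dn[keep] / ortholog_rates$ds[keep],
                  NA_real_)
  )
  set_exclusions(out, c(
    gene_in_both_classes = sum(in_both),
    gene_not_in_pair_set = sum(unpartitioned),
    ds_saturated = sum(saturated)
  ))
}

#' Per-gene multifunctionality counts
#'
#' For every gene in the SSD-only or WGD-only set: the number of unique
#' GO biological-process terms it is annotated with (0 when unannotated)
#' and, when available, its Pfam domain count. Duplicated annotation rows
#' do not inflate the count (term sets are sets).
#'
#' @param ds A `pd_dataset`.
#' @param partition A [partition_gene_sets()] result.
#' @return Tibble `gene_id`, `group`, `go_bp_count`, `pfam_domain_count`.
#' @export
multifunctionality_counts <- function(ds, partition) {
  genes <- c(partition$ssd_only, partition$wgd_only)
  group <- rep(c("SSD_only", "WGD_only"),
               c(length(partition$ssd_only), length(partition$wgd_only)))
  bp <- ds$go[ds$go$go_domain == "BP", ]
  bp_counts <- table(unique(bp[c("gene_id", "term_id")])$gene_id)
  pfam <- stats::setNames(ds$genes$pfam_domain_count, ds$genes$gene_id)
  tibble::tibble(
    gene_id = genes,
    group = group,
    go_bp_count = as.integer(ifelse(is.na(bp_counts[genes]), 0L, bp_counts[genes])),
    pfam_domain_count = unname(pfam[genes])
  )
}

#' Tabulate essentiality and disease flags by duplicate class
#'
#' Counts flagged and flag-bearing genes per group for each importance
#' flag, ignoring genes whose flag is absent. Proportions are
#' flagged / total-with-flag. A group with no flag-bearing genes at all
#' for a flag is an error naming the group.
#'
#' @param ds A `pd_dataset` (or its gene table).
#' @param partition A [partition_gene_sets()] result.
#' @return Tibble `flag` (`essential`/`disease`), `group`, `flagged`,
#'   `total`, `proportion`.
#' @export
importance_tabulation <- function(ds, partition) {
  genes <- if (inherits(ds, "pd_dataset")) ds$genes else ds
  out <- list()
  for (flag in c("essential", "disease")) {
    vals <- stats::setNames(genes[[flag]], genes$gene_id)
    for (grp in c("SSD_only", "WGD_only")) {
      members <- if (grp == "SSD_only") partition$ssd_only else partition$wgd_only
      v <- vals[members]
      total <- sum(!is.na(v))
      if (total == 0) {
        pd_abort("tabulation_error",
                 paste0("no ", flag, " flags available for group ", grp))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        flag = flag, group = grp,
        flagged = sum(v, na.rm = TRUE), total = total,
        proportion = sum(v, na.rm = TRUE) / total
      )
    }
  }
  dplyr::bind_rows(out)
}
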
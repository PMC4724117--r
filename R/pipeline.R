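# End-to-end orchestration: assemble -> score -> compare -> report. The
# analysis path contains no randomness; identical (dataset, config) give
# identical reports. Stages are independently skippable so a dataset
# missing a table (no expression matrix, no ortholog rates, no flags)
# still yields every other table, with the skip logged.

#' Analysis configuration
#'
#' @param bins dN strata (default [default_dn_bins()]).
#' @param min_identity Inclusive percent-identity threshold for SSD calls.
#' @param metrics Divergence metrics to score, a subset of
#'   `c("BP", "MF", "CC", "expression")`.
#' @param closest_only Restrict the main analysis to each gene's closest
#'   duplicate pair ([select_closest_pairs()]).
#' @param mirror_pairs Count each pair in both orientations in comparison
#'   tables (doubles every N; off by default — pairs are unordered).
#' @param ds_max Saturation bound on ortholog dS.
#' @param p_floor Display floor for p-values in rendered reports (values
#'   below are shown as `< p_floor`; stored values stay numeric).
#' @param confidence_level Confidence level reported with the Z tests.
#' @param robustness List of optional variants: `closest_pair = TRUE`
#'   reruns the binned comparisons on closest pairs only;
#'   `identity_thresholds` (numeric vector) reruns them at stricter SSD
#'   identity cutoffs; `age_threshold` (integer) splits SSD pairs into
#'   young/old by phylostratum rank and compares old SSD vs WGD.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(bins = default_dn_bins(), min_identity = 50,
                            metrics = c("BP", "MF", "CC", "expression"),
                            closest_only = FALSE, mirror_pairs = FALSE,
                            ds_max = 3, p_floor = 1e-6,
                            confidence_level = 0.99,
                            robustness = list(closest_pair = FALSE,
                                              identity_thresholds = NULL,
                                              age_threshold = NULL)) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full SSD-vs-WGD analysis
#'
#' Executes the whole pipeline on a validated dataset: origin labelling
#' and identity filtering, dN binning, the gene partition, all configured
#' pairwise divergence metrics with per-bin Mann-Whitney comparisons,
#' ortholog-rate comparisons per outgroup, multifunctionality comparisons,
#' the two-proportion Z tests for essentiality and disease, and any
#' enabled robustness variants. Deterministic given (dataset, config);
#' every exclusion and every skipped stage is logged in the report.
#'
#' @param ds A `pd_dataset`.
#' @param config An [analysis_config()].
#' @return An `analysis_report`: list with tables `binned`, `rates`,
#'   `multifunctionality`, `proportions`, list `robustness`, logs
#'   `exclusions` and `skipped`, and `provenance`.
#' @export
run_full_analysis <- function(ds, config = analysis_config()) {
  exclusions <- list()
  skipped <- list()
  note_excl <- function(stage, x) {
    log <- exclusion_log(x)
    if (nrow(log)) exclusions[[length(exclusions) + 1L]] <<-
        dplyr::mutate(log, stage = stage, .before = 1)
    x
  }
  note_skip <- function(stage, reason) {
    skipped[[length(skipped) + 1L]] <<- tibble::tibble(stage = stage,
                                                       reason = reason)
  }

  # --- assembly ---
  wgd_ref <- ds$pairs[ds$pairs$origin == "WGD", c("gene_a", "gene_b")]
  pairs <- note_excl("label_pairs",
                     label_pairs(ds$pairs, wgd_ref, config$min_identity))
  if (config$closest_only) pairs <- select_closest_pairs(pairs)
  pairs <- note_excl("dn_binning", bin_pairs(pairs, config$bins))
  partition <- partition_gene_sets(pairs)

  # --- pairwise metrics ---
  score_tables <- list()
  for (m in config$metrics) {
    if (m == "expression" && is.null(ds$expression)) {
      note_skip("expression_scores", "dataset has no expression table")
      next
    }
    if (m != "expression" && is.null(ds$go)) {
      note_skip(paste0(m, "_scores"), "dataset has no GO table")
      next
    }
    score_tables[[m]] <- note_excl(paste0(m, "_scores"),
                                   score_all_pairs(ds, m, pairs = pairs))
  }
  binned <- if (length(score_tables)) {
    binned_metric_comparison(dplyr::bind_rows(score_tables), config$bins,
                             mirror_pairs = config$mirror_pairs)
  } else {
    note_skip("binned_comparison", "no metric could be scored")
    NULL
  }

  # --- ortholog rates ---
  rates <- NULL
  if (is.null(ds$ortholog_rates)) {
    note_skip("ortholog_rates", "dataset has no ortholog table")
  } else {
    rate_rows <- note_excl("ortholog_rates",
                           ortholog_rate_table(ds$ortholog_rates, partition,
                                               config$ds_max))
    rates <- rate_comparison(rate_rows)
  }

  # --- multifunctionality ---
  multifun <- NULL
  if (is.null(ds$go)) {
    note_skip("multifunctionality", "dataset has no GO table")
  } else {
    counts <- multifunctionality_counts(ds, partition)
    multifun <- multifunctionality_comparison(counts)
  }

  # --- importance proportions ---
  proportions <- tryCatch(
    proportion_tests(ds, partition, config$confidence_level),
    paralogdiv_tabulation_error = function(e) {
      note_skip("proportion_tests", conditionMessage(e))
      NULL
    }
  )

  # --- robustness variants ---
  robustness <- list()
  rb <- config$robustness
  if (isTRUE(rb$closest_pair)) {
    closest <- select_closest_pairs(pairs)
    robustness$closest_pair <- rescore_binned(ds, closest, config)
  }
  for (thr in rb$identity_thresholds %||% numeric()) {
    keep <- pairs$origin == "WGD" |
      (!is.na(pairs$identity_pct) & pairs$identity_pct >= thr)
    robustness[[paste0("identity_ge_", thr)]] <-
      rescore_binned(ds, pairs[keep, , drop = FALSE], config)
  }
  if (!is.null(rb$age_threshold)) {
    ssd <- pairs[pairs$origin == "SSD", , drop = FALSE]
    halves <- split_ssd_by_age(ssd, ds$genes, rb$age_threshold)
    wgd <- pairs[pairs$origin == "WGD", , drop = FALSE]
    robustness$old_ssd_vs_wgd <-
      rescore_binned(ds, dplyr::bind_rows(halves$old, wgd), config)
    robustness$age_split_counts <- tibble::tibble(
      young_pairs = nrow(halves$young), old_pairs = nrow(halves$old),
      excluded_missing_rank = halves$n_excluded_missing_rank
    )
  }

  structure(
    list(
      binned = binned, rates = rates, multifunctionality = multifun,
      proportions = proportions, robustness = robustness,
      exclusions = if (length(exclusions)) dplyr::bind_rows(exclusions) else
        tibble::tibble(stage = character(), reason = character(), n = integer()),
      skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
        tibble::tibble(stage = character(), reason = character()),
      provenance = list(
        config_hash = rlang::hash(config),
        input_hash = rlang::hash(ds),
        synthetic_seed = attr(ds, "synthetic_seed") %||% NA_integer_,
        n_genes = nrow(ds$genes), n_pairs_in = nrow(ds$pairs),
        n_pairs_analyzed = nrow(pairs),
        p_floor = config$p_floor
      )
    ),
    class = "analysis_report"
  )
}

rescore_binned <- function(ds, pairs, config) {
  tables <- list()
  for (m in config$metrics) {
    if (m == "expression" && is.null(ds$expression)) next
    if (m != "expression" && is.null(ds$go)) next
    tables[[m]] <- score_all_pairs(ds, m, pairs = pairs)
  }
  if (!length(tables)) return(NULL)
  binned_metric_comparison(dplyr::bind_rows(tables), config$bins,
                           mirror_pairs = config$mirror_pairs)
}

rate_comparison <- function(rate_rows) {
  out <- list()
  for (og in sort(unique(rate_rows$outgroup))) {
    sub <- rate_rows[rate_rows$outgroup == og, ]
    ssd <- sub[sub$group == "SSD_only", ]
    wgd <- sub[sub$group == "WGD_only", ]
    p_dn <- p_dnds <- NA_real_
    if (nrow(ssd) && nrow(wgd)) {
      p_dn <- mann_whitney_two_tailed(ssd$dn, wgd$dn)$p_two_tailed
      if (any(!is.na(ssd$dnds)) && any(!is.na(wgd$dnds))) {
        p_dnds <- mann_whitney_two_tailed(ssd$dnds[!is.na(ssd$dnds)],
                                          wgd$dnds[!is.na(wgd$dnds)])$p_two_tailed
      }
    }
    out[[og]] <- tibble::tibble(
      outgroup = og, group = c("SSD_only", "WGD_only"),
      n = c(nrow(ssd), nrow(wgd)),
      mean_dn = c(mean(ssd$dn), mean(wgd$dn)),
      mean_dnds = c(mean(ssd$dnds, na.rm = TRUE), mean(wgd$dnds, na.rm = TRUE)),
      p_value_dn = p_dn, p_value_dnds = p_dnds
    )
  }
  dplyr::bind_rows(out)
}

multifunctionality_comparison <- function(counts) {
  ssd <- counts[counts$group == "SSD_only", ]
  wgd <- counts[counts$group == "WGD_only", ]
  row <- function(measure, vs, vw) {
    vs <- vs[!is.na(vs)]; vw <- vw[!is.na(vw)]
    p <- if (length(vs) && length(vw)) {
      mann_whitney_two_tailed(vs, vw)$p_two_tailed
    } else NA_real_
    tibble::tibble(measure = measure,
                   mean_ssd = mean(vs), n_ssd = length(vs),
                   mean_wgd = mean(vw), n_wgd = length(vw),
                   p_two_tailed = p)
  }
  dplyr::bind_rows(
    row("unique_go_bp_terms", ssd$go_bp_count, wgd$go_bp_count),
    row("pfam_domains", ssd$pfam_domain_count, wgd$pfam_domain_count)
  )
}

proportion_tests <- function(ds, partition, confidence_level) {
  tab <- importance_tabulation(ds, partition)
  out <- list()
  for (flag in unique(tab$flag)) {
    ssd <- tab[tab$flag == flag & tab$group == "SSD_only", ]
    wgd <- tab[tab$flag == flag & tab$group == "WGD_only", ]
    test <- two_proportion_z(ssd$proportion, ssd$total,
                             wgd$proportion, wgd$total,
                             confidence_level = confidence_level)
    out[[flag]] <- tibble::tibble(
      flag = flag,
      p_ssd = ssd$proportion, n_ssd = ssd$total,
      p_wgd = wgd$proportion, n_wgd = wgd$total,
      pooled_p = test$pooled_p, z_statistic = test$z_statistic,
      p_two_tailed = test$p_two_tailed, confidence_level = confidence_level
    )
  }
  dplyr::bind_rows(out)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  fmt_p <- function(p) {
    floor_ <- x$provenance$p_floor %||% 1e-6
    ifelse(is.na(p), "NA",
           ifelse(p < floor_, paste0("< ", format(floor_)), signif(p, 3)))
  }
  if (!is.null(x$binned)) {
    ov <- x$binned[x$binned$bin == "overall", ]
    cat("  overall metric comparisons (SSD vs WGD):\n")
    for (i in seq_len(nrow(ov))) {
      cat(sprintf("    %-20s %.3f (n=%d) vs %.3f (n=%d), p %s\n",
                  ov$metric[i], ov$mean_ssd[i], ov$n_ssd[i], ov$mean_wgd[i],
                  ov$n_wgd[i], fmt_p(ov$p_two_tailed[i])))
    }
  }
  if (!is.null(x$rates)) {
    for (og in unique(x$rates$outgroup)) {
      s <- x$rates[x$rates$outgroup == og, ]
      cat(sprintf("  %s orthologs: mean dN %.4f vs %.4f, mean dN/dS %.3f vs %.3f\n",
                  og, s$mean_dn[1], s$mean_dn[2], s$mean_dnds[1], s$mean_dnds[2]))
    }
  }
  if (!is.null(x$proportions)) {
    for (i in seq_len(nrow(x$proportions))) {
      p <- x$proportions[i, ]
      cat(sprintf("  %s: %.2f%% of %d SSD-only vs %.2f%% of %d WGD-only, Z = %.2f\n",
                  p$flag, 100 * p$p_ssd, p$n_ssd, 100 * p$p_wgd, p$n_wgd,
                  p$z_statistic))
    }
  }
  if (nrow(x$skipped)) {
    cat("  skipped stages:", paste(x$skipped$stage, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' One tab-separated file per present report table plus a machine-readable
#' `summary.json` (skips, exclusion log, provenance). Output contains no
#' timestamps, so writing the same report twice is byte-identical.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return Manifest tibble (`file`, `n_rows`), invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_io(paste0("cannot create directory '", out_dir, "'"))
  manifest <- list()
  emit <- function(tbl, file) {
    if (is.null(tbl) || !nrow(tbl)) return()
    write_tsv_plain(tbl, file.path(out_dir, file))
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(file = file,
                                                         n_rows = nrow(tbl))
  }
  emit(report$binned, "binned_comparison.tsv")
  emit(report$rates, "rate_comparison.tsv")
  emit(report$multifunctionality, "multifunctionality.tsv")
  emit(report$proportions, "proportion_tests.tsv")
  emit(report$exclusions, "exclusions.tsv")
  for (nm in names(report$robustness)) {
    emit(report$robustness[[nm]], paste0("robustness_", nm, ".tsv"))
  }
  summary <- list(
    tables = if (length(manifest)) dplyr::bind_rows(manifest) else
      tibble::tibble(file = character(), n_rows = integer()),
    skipped = report$skipped,
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary$tables)
}
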
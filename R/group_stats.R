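# Statistical comparisons: two-tailed Mann-Whitney U (exact for small
# untied samples, normal approximation with tie and continuity correction
# otherwise) and the pooled two-sample Z test for proportions.

#' Two-tailed Mann-Whitney U test
#'
#' The U statistic for `x` is computed by midrank rank-sum. The two-tailed
#' p-value is exact (doubled smaller tail of the null U distribution,
#' capped at 1) when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with elements `u` (U for `x`), `p_two_tailed`, and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
#' @examples
#' mann_whitney_two_tailed(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney_two_tailed <- function(x, y) {
  if (!length(x) || !length(y)) {
    abort_value("mann_whitney_two_tailed() requires non-empty samples")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  if (!ties && n1 + n2 <= 12) {
    u_min <- min(u, n1 * n2 - u)
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
    return(list(u = u, p_two_tailed = p, method = "exact"))
  }

  n <- n1 + n2
  tie_counts <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) {
    return(list(u = u, p_two_tailed = 1, method = "normal_approximation"))
  }
  correction <- sign(u - mu) * 0.5
  z <- (u - mu - correction) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u, p_two_tailed = p, method = "normal_approximation")
}

#' Pooled two-sample Z test for proportions
#'
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with
#' `p = (p1 n1 + p2 n2) / (n1 + n2)`; two-tailed p from the standard
#' normal. With `counts = TRUE`, `p1`/`p2` are successes `k1`/`k2` and are
#' converted to proportions.
#'
#' @param p1,p2 Group proportions in `[0, 1]` (or counts, see `counts`).
#' @param n1,n2 Group sizes.
#' @param counts If `TRUE`, interpret `p1`, `p2` as integer successes.
#' @param confidence_level Reported alongside the test (display only).
#' @return A `proportion_test`: list with `p1`, `n1`, `p2`, `n2`,
#'   `pooled_p`, `z_statistic`, `p_two_tailed`, `confidence_level`.
#' @export
#' @examples
#' # essentiality enrichment in WGD genes: z approx -9.99
#' two_proportion_z(0.04601, 2692, 0.11344, 5730)
two_proportion_z <- function(p1, n1, p2, n2, counts = FALSE,
                             confidence_level = 0.99) {
  if (n1 < 1 || n2 < 1) abort_value("group sizes must be >= 1")
  if (counts) {
    p1 <- p1 / n1
    p2 <- p2 / n2
  }
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    abort_value("proportions must lie in [0, 1]")
  }
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    pd_abort("degenerate_error",
             "pooled proportion is 0 or 1: the Z test has zero variance")
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  structure(
    list(p1 = p1, n1 = n1, p2 = p2, n2 = n2, pooled_p = pooled,
         z_statistic = z, p_two_tailed = min(1, 2 * stats::pnorm(-abs(z))),
         confidence_level = confidence_level),
    class = "proportion_test"
  )
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf(
    "<proportion_test> p1 = %.4f (n = %d) vs p2 = %.4f (n = %d): Z = %.3f, p = %.3g\n",
    x$p1, as.integer(x$n1), x$p2, as.integer(x$n2), x$z_statistic, x$p_two_tailed))
  invisible(x)
}

#' Per-bin SSD-vs-WGD comparison of a divergence metric
#'
#' For every (metric, dN bin) stratum, and an `overall` row per metric,
#' reports the SSD and WGD means and sample sizes and the two-tailed
#' Mann-Whitney result (U for the SSD sample). Strata where either group
#' is empty are emitted with the test marked not applicable (`NA` U and p).
#'
#' @param pair_scores Score tibble from [score_all_pairs()] carrying
#'   `origin` and `dn_bin`.
#' @param bins Bin table ordering the rows (default [default_dn_bins()]).
#' @param mirror_pairs If `TRUE`, count every pair in both orientations
#'   (doubling each group's N), matching reports that tabulate ordered
#'   pairs. Off by default: pairs are unordered and counted once.
#' @return Tibble with columns `metric`, `bin`, `mean_ssd`, `n_ssd`,
#'   `mean_wgd`, `n_wgd`, `u_statistic`, `p_two_tailed`.
#' @export
binned_metric_comparison <- function(pair_scores, bins = default_dn_bins(),
                                     mirror_pairs = FALSE) {
  scores <- tibble::as_tibble(pair_scores)
  if (mirror_pairs) scores <- dplyr::bind_rows(scores, scores)
  bin_levels <- c("overall", bins$label)

  one_row <- function(metric, bin, values, origins) {
    ssd <- values[origins == "SSD"]
    wgd <- values[origins == "WGD"]
    test <- if (length(ssd) && length(wgd)) {
      mann_whitney_two_tailed(ssd, wgd)
    } else {
      list(u = NA_real_, p_two_tailed = NA_real_)
    }
    tibble::tibble(
      metric = metric, bin = bin,
      mean_ssd = if (length(ssd)) mean(ssd) else NA_real_,
      n_ssd = length(ssd),
      mean_wgd = if (length(wgd)) mean(wgd) else NA_real_,
      n_wgd = length(wgd),
      u_statistic = test$u, p_two_tailed = test$p_two_tailed
    )
  }

  out <- list()
  for (m in unique(scores$metric)) {
    sm <- scores[scores$metric == m, ]
    out[[length(out) + 1L]] <- one_row(m, "overall", sm$value, sm$origin)
    for (b in bins$label) {
      sb <- sm[!is.na(sm$dn_bin) & sm$dn_bin == b, ]
      out[[length(out) + 1L]] <- one_row(m, b, sb$value, sb$origin)
    }
  }
  res <- dplyr::bind_rows(out)
  res$bin <- factor(res$bin, levels = bin_levels)
  dplyr::arrange(res, .data$metric, .data$bin)
}
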
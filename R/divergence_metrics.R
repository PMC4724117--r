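# Pairwise divergence scores: shared-annotation (Dice) similarity on the
# GO BP / MF / CC domains, and Pearson correlation of tissue expression
# profiles. Annotation sets are used exactly as provided (no ancestor
# propagation): an optional propagation hook exists for callers that have
# already expanded their term sets upstream.

METRICS <- c(BP = "BP_similarity", MF = "MF_similarity",
             CC = "CC_colocalization", expression = "expression_r")

#' Shared-annotation (Dice) similarity of two term sets
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical sets, 0 for disjoint
#' sets, symmetric. Duplicated entries within a vector are collapsed first
#' (term sets are sets). If either set is empty the similarity is
#' undefined and `NA` is returned; [score_all_pairs()] excludes such pairs
#' with a logged reason rather than scoring them 0.
#'
#' @param terms_a,terms_b Character vectors of annotation term ids.
#' @return Similarity in `[0, 1]`, or `NA_real_` if either set is empty.
#' @export
#' @examples
#' shared_annotation_similarity(c("A", "B", "C"), c("B", "C", "D"))  # 2/3
shared_annotation_similarity <- function(terms_a, terms_b) {
  a <- unique(terms_a); b <- unique(terms_b)
  if (!length(a) || !length(b)) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pearson correlation of two expression profiles
#'
#' Product-moment correlation over the tissues common to both profiles.
#' If both vectors are named, the intersection of names is used (at least
#' 3 shared tissues required); unnamed vectors must have equal length and
#' are matched by position. Computed in the numerically stable centred
#' form, which is algebraically identical to the raw-sums formula
#' `(N sum(ij) - sum(i) sum(j)) / sqrt(...)`.
#'
#' @param profile_a,profile_b Non-negative expression vectors.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined (fewer
#'   than 3 shared tissues, or a constant profile).
#' @export
expression_correlation <- function(profile_a, profile_b) {
  if (!is.null(names(profile_a)) && !is.null(names(profile_b))) {
    common <- intersect(names(profile_a), names(profile_b))
    if (length(common) < 3) return(NA_real_)
    profile_a <- profile_a[common]
    profile_b <- profile_b[common]
  } else if (length(profile_a) != length(profile_b)) {
    abort_value("unnamed expression profiles must have equal length")
  }
  if (length(profile_a) < 3) return(NA_real_)
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0) return(NA_real_)
  stats::cor(profile_a, profile_b)
}

#' Score every pair of a dataset on one divergence metric
#'
#' Computes, per paralog pair, the Dice similarity of the two genes' term
#' sets in one GO domain (`"BP"`, `"MF"`, `"CC"`) or the Pearson
#' correlation of their tissue expression profiles (`"expression"`). Pairs
#' failing the metric's preconditions (a gene without annotation in that
#' domain, without an expression profile, or with a constant profile) are
#' excluded and counted per reason — see [exclusion_log()] — never scored
#' zero.
#'
#' @param ds A `pd_dataset`.
#' @param metric One of `"BP"`, `"MF"`, `"CC"`, `"expression"`.
#' @param pairs Optional pair tibble to score (defaults to `ds$pairs`);
#'   pass an assembled/filtered table to keep `dn_bin` columns etc.
#' @param propagate Optional function applied to each gene's term set
#'   before scoring (hook for ontology-aware expansion; off by default).
#' @return Tibble with columns `gene_a`, `gene_b`, `origin`, `dn_bin` (if
#'   present in `pairs`), `metric`, `value`, `n_basis`.
#' @export
score_all_pairs <- function(ds, metric, pairs = NULL, propagate = NULL) {
  metric <- match.arg(metric, names(METRICS))
  pairs <- pairs %||% ds$pairs
  base <- pairs[intersect(c("gene_a", "gene_b", "origin", "dn_bin"), names(pairs))]

  if (metric == "expression") {
    if (is.null(ds$expression)) {
      abort_value("dataset has no expression table")
    }
    m <- as.matrix(ds$expression[ds$tissue_names])
    rownames(m) <- ds$expression$gene_id
    have <- pairs$gene_a %in% rownames(m) & pairs$gene_b %in% rownames(m)
    a <- m[pairs$gene_a[have], , drop = FALSE]
    b <- m[pairs$gene_b[have], , drop = FALSE]
    ca <- a - rowMeans(a); cb <- b - rowMeans(b)
    denom <- sqrt(rowSums(ca^2) * rowSums(cb^2))
    r <- ifelse(denom > 0, rowSums(ca * cb) / denom, NA_real_)
    out <- base[have, , drop = FALSE]
    out$metric <- METRICS[[metric]]
    out$value <- unname(r)
    out$n_basis <- ncol(m)
    constant <- is.na(r)
    out <- out[!constant, , drop = FALSE]
    return(set_exclusions(out, c(
      missing_expression_profile = sum(!have),
      constant_profile = sum(constant)
    )))
  }

  if (is.null(ds$go)) abort_value("dataset has no GO table")
  dom <- ds$go[ds$go$go_domain == metric, ]
  term_sets <- split(dom$term_id, dom$gene_id)
  if (!is.null(propagate)) term_sets <- lapply(term_sets, propagate)
  na <- lengths(term_sets)[pairs$gene_a]
  nb <- lengths(term_sets)[pairs$gene_b]
  have <- !is.na(na) & !is.na(nb) & na > 0 & nb > 0
  idx <- which(have)
  value <- n_basis <- numeric(length(idx))
  for (i in seq_along(idx)) {
    a <- term_sets[[pairs$gene_a[idx[i]]]]
    b <- term_sets[[pairs$gene_b[idx[i]]]]
    value[i] <- 2 * length(intersect(a, b)) / (length(a) + length(b))
    n_basis[i] <- length(a) + length(b)
  }
  out <- base[idx, , drop = FALSE]
  out$metric <- METRICS[[metric]]
  out$value <- value
  out$n_basis <- as.integer(n_basis)
  set_exclusions(out, c(missing_annotation = sum(!have)))
}
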
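# Input/output for the five Biomart-style tab-separated tables and the
# shared in-memory data model.
#
# Conventions (all five tables): UTF-8, tab-separated, one header row,
# missing optional values written as empty fields. GO annotations are one
# row per (gene, domain, term); duplicate rows collapse into the term set.

GENE_COLS  <- c("gene_id", "essential", "disease", "pfam_domain_count", "age_rank")
PAIR_COLS  <- c("gene_a", "gene_b", "origin", "dn", "ds", "identity_pct")
GO_COLS    <- c("gene_id", "go_domain", "term_id")
ORTHO_COLS <- c("gene_id", "outgroup", "dn", "ds")
GO_DOMAINS <- c("BP", "MF", "CC")
ORIGINS    <- c("SSD", "WGD")

#' Assemble a validated duplicate-gene dataset
#'
#' Bundles the gene table, the origin-labelled paralog-pair table, the GO
#' annotation table, the tissue expression matrix and the ortholog-rate
#' table into a single validated object, the unit every analysis step
#' consumes. Referential integrity is enforced: a pair, annotation,
#' expression profile or ortholog record naming a gene absent from `genes`
#' is an error, never silently dropped.
#'
#' @param genes Tibble with columns `gene_id`, `essential` (logical or 0/1),
#'   `disease`, `pfam_domain_count`, `age_rank`; all but `gene_id` optional
#'   per row (`NA`).
#' @param pairs Tibble with columns `gene_a`, `gene_b`, `origin`
#'   (`"SSD"`/`"WGD"`), `dn`, `ds`, `identity_pct`.
#' @param go Optional tibble with columns `gene_id`, `go_domain`
#'   (`"BP"`/`"MF"`/`"CC"`), `term_id`.
#' @param expression Optional tibble: `gene_id` plus one numeric column per
#'   tissue.
#' @param ortholog_rates Optional tibble with columns `gene_id`, `outgroup`,
#'   `dn`, `ds`.
#' @return An object of class `pd_dataset`: a list with elements `genes`,
#'   `pairs`, `go`, `expression`, `ortholog_rates` and `tissue_names`.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = c("g1", "g2"), essential = c(TRUE, FALSE),
#'                         disease = c(FALSE, FALSE),
#'                         pfam_domain_count = c(1L, 2L), age_rank = c(1L, 1L))
#' pairs <- tibble::tibble(gene_a = "g1", gene_b = "g2", origin = "SSD",
#'                         dn = 0.05, ds = 0.2, identity_pct = 80)
#' dataset(genes, pairs)
dataset <- function(genes, pairs, go = NULL, expression = NULL,
                    ortholog_rates = NULL) {
  genes <- normalize_gene_table(genes)
  pairs <- normalize_pair_table(pairs)
  go <- if (!is.null(go)) normalize_go_table(go)
  expression <- if (!is.null(expression)) normalize_expression_table(expression)
  ortholog_rates <- if (!is.null(ortholog_rates)) normalize_ortholog_table(ortholog_rates)

  ds <- structure(
    list(
      genes = genes, pairs = pairs, go = go, expression = expression,
      ortholog_rates = ortholog_rates,
      tissue_names = if (is.null(expression)) character() else setdiff(names(expression), "gene_id")
    ),
    class = "pd_dataset"
  )
  validate_dataset(ds)
}

#' @export
print.pd_dataset <- function(x, ...) {
  cat("<pd_dataset>\n")
  cat("  genes:         ", nrow(x$genes), "\n")
  cat("  pairs:         ", nrow(x$pairs),
      sprintf(" (SSD %d / WGD %d)", sum(x$pairs$origin == "SSD"),
              sum(x$pairs$origin == "WGD")), "\n")
  cat("  GO rows:       ", if (is.null(x$go)) "absent" else nrow(x$go), "\n")
  cat("  expression:    ", if (is.null(x$expression)) "absent" else
    paste0(nrow(x$expression), " genes x ", length(x$tissue_names), " tissues"), "\n")
  cat("  ortholog rows: ", if (is.null(x$ortholog_rates)) "absent" else
    nrow(x$ortholog_rates), "\n")
  invisible(x)
}

#' Validate a dataset's invariants
#'
#' Checks referential integrity, value ranges and uniqueness constraints.
#' Called by [dataset()] and [load_dataset()]; exposed so hand-edited
#' objects can be re-checked.
#'
#' @param ds A `pd_dataset`.
#' @return `ds`, invisibly unchanged, or a classed error.
#' @export
validate_dataset <- function(ds) {
  genes <- ds$genes
  if (anyDuplicated(genes$gene_id)) {
    abort_integrity(paste0("duplicate gene id in gene table: '",
                           genes$gene_id[duplicated(genes$gene_id)][1], "'"))
  }
  known <- genes$gene_id

  pairs <- ds$pairs
  if (any(pairs$gene_a == pairs$gene_b)) {
    abort_integrity("pair table contains a self-pair (gene_a == gene_b)")
  }
  check_refs(c(pairs$gene_a, pairs$gene_b), known, "pair")
  bad <- which(!pairs$origin %in% ORIGINS)
  if (length(bad)) {
    abort_value(paste0("pair table row ", bad[1], ": origin must be SSD or WGD, got '",
                       pairs$origin[bad[1]], "'"))
  }
  check_nonneg(pairs$dn, "pair", "dn")
  check_nonneg(pairs$ds, "pair", "ds")
  bad <- which(!is.na(pairs$identity_pct) &
                 (pairs$identity_pct < 0 | pairs$identity_pct > 100))
  if (length(bad)) {
    abort_value(paste0("pair table row ", bad[1], ": identity_pct outside [0, 100]"))
  }

  check_nonneg(genes$pfam_domain_count, "gene", "pfam_domain_count")
  bad <- which(!is.na(genes$age_rank) & genes$age_rank < 1)
  if (length(bad)) {
    abort_value(paste0("gene table row ", bad[1], ": age_rank must be >= 1"))
  }

  if (!is.null(ds$go)) {
    check_refs(ds$go$gene_id, known, "GO annotation")
    bad <- which(!ds$go$go_domain %in% GO_DOMAINS)
    if (length(bad)) {
      abort_value(paste0("GO table row ", bad[1], ": go_domain must be BP, MF or CC"))
    }
  }

  if (!is.null(ds$expression)) {
    expr <- ds$expression
    if (anyDuplicated(ds$tissue_names)) {
      abort_schema("expression table has duplicated tissue columns")
    }
    if (anyDuplicated(expr$gene_id)) {
      abort_integrity(paste0("duplicate gene id in expression table: '",
                             expr$gene_id[duplicated(expr$gene_id)][1], "'"))
    }
    check_refs(expr$gene_id, known, "expression")
    vals <- as.matrix(expr[ds$tissue_names])
    bad <- which(!is.finite(vals) | vals < 0)
    if (length(bad)) {
      row <- (bad[1] - 1L) %% nrow(vals) + 1L
      abort_value(paste0("expression table row ", row,
                         ": values must be finite and >= 0"))
    }
  }

  if (!is.null(ds$ortholog_rates)) {
    check_refs(ds$ortholog_rates$gene_id, known, "ortholog")
    check_nonneg(ds$ortholog_rates$dn, "ortholog", "dn")
    check_nonneg(ds$ortholog_rates$ds, "ortholog", "ds")
  }
  invisible(ds)
}

check_refs <- function(ids, known, table_label) {
  unknown <- setdiff(ids, known)
  if (length(unknown)) {
    abort_integrity(paste0(table_label, " table references unknown gene id '",
                           unknown[1], "'"))
  }
}

check_nonneg <- function(x, table_label, col) {
  bad <- which(!is.na(x) & x < 0)
  if (length(bad)) {
    abort_value(paste0(table_label, " table row ", bad[1], ": negative ", col))
  }
}

# ---- type normalisation (shared by the constructor and the loader so a
# written-then-reloaded dataset is identical to the original) ----

normalize_gene_table <- function(genes) {
  require_cols(genes, GENE_COLS, "gene")
  tibble::tibble(
    gene_id = as.character(genes$gene_id),
    essential = to_logical(genes$essential, "gene", "essential"),
    disease = to_logical(genes$disease, "gene", "disease"),
    pfam_domain_count = to_integer(genes$pfam_domain_count, "gene", "pfam_domain_count"),
    age_rank = to_integer(genes$age_rank, "gene", "age_rank")
  )
}

normalize_pair_table <- function(pairs) {
  require_cols(pairs, PAIR_COLS, "pair")
  tibble::tibble(
    gene_a = as.character(pairs$gene_a),
    gene_b = as.character(pairs$gene_b),
    origin = as.character(pairs$origin),
    dn = to_double(pairs$dn, "pair", "dn"),
    ds = to_double(pairs$ds, "pair", "ds"),
    identity_pct = to_double(pairs$identity_pct, "pair", "identity_pct")
  )
}

normalize_go_table <- function(go) {
  require_cols(go, GO_COLS, "GO")
  dplyr::distinct(tibble::tibble(
    gene_id = as.character(go$gene_id),
    go_domain = as.character(go$go_domain),
    term_id = as.character(go$term_id)
  ))
}

normalize_expression_table <- function(expr) {
  require_cols(expr, "gene_id", "expression")
  tissues <- setdiff(names(expr), "gene_id")
  if (!length(tissues)) {
    abort_schema("expression table has no tissue columns")
  }
  out <- tibble::as_tibble(expr)[c("gene_id", tissues)]
  out$gene_id <- as.character(out$gene_id)
  for (t in tissues) out[[t]] <- to_double(out[[t]], "expression", t)
  out
}

normalize_ortholog_table <- function(orth) {
  require_cols(orth, ORTHO_COLS, "ortholog")
  tibble::tibble(
    gene_id = as.character(orth$gene_id),
    outgroup = as.character(orth$outgroup),
    dn = to_double(orth$dn, "ortholog", "dn"),
    ds = to_double(orth$ds, "ortholog", "ds")
  )
}

require_cols <- function(tbl, cols, table_label) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort_schema(paste0(table_label, " table is missing required column '",
                        missing[1], "'"))
  }
}

to_logical <- function(x, table_label, col) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA
  out <- rep(NA, length(x))
  out[!is.na(x) & x %in% c("0", "FALSE", "false")] <- FALSE
  out[!is.na(x) & x %in% c("1", "TRUE", "true")] <- TRUE
  bad <- which(!is.na(x) & !x %in% c("0", "1", "TRUE", "FALSE", "true", "false"))
  if (length(bad)) {
    abort_value(paste0(table_label, " table row ", bad[1], ": column '", col,
                       "' must be 0/1 or empty, got '", x[bad[1]], "'"))
  }
  as.logical(out)
}

to_integer <- function(x, table_label, col) {
  d <- to_double(x, table_label, col)
  bad <- which(!is.na(d) & d != floor(d))
  if (length(bad)) {
    abort_value(paste0(table_label, " table row ", bad[1], ": column '", col,
                       "' must be an integer"))
  }
  as.integer(d)
}

to_double <- function(x, table_label, col) {
  if (is.numeric(x)) return(as.double(x))
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA
  out <- suppressWarnings(as.double(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort_value(paste0(table_label, " table row ", bad[1], ": column '", col,
                       "' is not numeric ('", x[bad[1]], "')"))
  }
  out
}

# ---- disk round trip ----

#' Load a dataset from tab-separated tables
#'
#' Reads the gene, pair, GO, expression and ortholog tables (Biomart-export
#' style: tab-separated, header row, empty field for a missing optional
#' value) and validates them into a [dataset()]. Optional tables may be
#' `NULL`, in which case the corresponding analyses are skipped downstream.
#'
#' @param gene_table_path,pair_table_path Paths to `genes.tsv` / `pairs.tsv`.
#' @param go_table_path,expression_table_path,ortholog_table_path Optional
#'   paths (`NULL` to omit the table).
#' @return A validated `pd_dataset`.
#' @export
load_dataset <- function(gene_table_path, pair_table_path,
                         go_table_path = NULL, expression_table_path = NULL,
                         ortholog_table_path = NULL) {
  paths <- c(gene_table_path, pair_table_path, go_table_path,
             expression_table_path, ortholog_table_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort_io(paste0("input table not found: '", missing[1], "'"))
  }
  dataset(
    genes = read_table_chr(gene_table_path),
    pairs = read_table_chr(pair_table_path),
    go = if (!is.null(go_table_path)) read_table_chr(go_table_path),
    expression = if (!is.null(expression_table_path)) read_table_chr(expression_table_path),
    ortholog_rates = if (!is.null(ortholog_table_path)) read_table_chr(ortholog_table_path)
  )
}

read_table_chr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE)
}

#' Write a dataset to tab-separated tables
#'
#' Inverse of [load_dataset()]: writes `genes.tsv`, `pairs.tsv` and, when
#' present, `go.tsv`, `expression.tsv`, `orthologs.tsv` under `dir`.
#' Logical flags are written as 0/1, missing values as empty fields, so
#' `load_dataset(write_dataset(ds, d))` is the identity.
#'
#' @param ds A `pd_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_io(paste0("cannot create directory '", dir, "'"))

  genes <- ds$genes
  genes$essential <- as.integer(genes$essential)
  genes$disease <- as.integer(genes$disease)

  files <- c(genes = "genes.tsv", pairs = "pairs.tsv")
  write_tsv_plain(genes, file.path(dir, "genes.tsv"))
  write_tsv_plain(ds$pairs, file.path(dir, "pairs.tsv"))
  if (!is.null(ds$go)) {
    write_tsv_plain(ds$go, file.path(dir, "go.tsv"))
    files["go"] <- "go.tsv"
  }
  if (!is.null(ds$expression)) {
    write_tsv_plain(ds$expression, file.path(dir, "expression.tsv"))
    files["expression"] <- "expression.tsv"
  }
  if (!is.null(ds$ortholog_rates)) {
    write_tsv_plain(ds$ortholog_rates, file.path(dir, "orthologs.tsv"))
    files["orthologs"] <- "orthologs.tsv"
  }
  invisible(vapply(files, function(f) file.path(dir, f), character(1)))
}

write_tsv_plain <- function(tbl, path) {
  readr::write_tsv(tbl, path, na = "", progress = FALSE)
}

#' Load a dataset from a directory written by [write_dataset()]
#'
#' @param dir Directory containing the TSV tables.
#' @return A validated `pd_dataset`.
#' @export
load_dataset_dir <- function(dir) {
  opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) p else NULL
  }
  load_dataset(file.path(dir, "genes.tsv"), file.path(dir, "pairs.tsv"),
               go_table_path = opt("go.tsv"),
               expression_table_path = opt("expression.tsv"),
               ortholog_table_path = opt("orthologs.tsv"))
}
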
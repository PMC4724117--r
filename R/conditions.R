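# Classed conditions used across the package. Every validation failure is a
# classed error so callers (and tests) can distinguish schema problems from
# value problems from referential-integrity problems.

pd_abort <- function(class, message, ...) {
  rlang::abort(message = message, class = paste0("paralogdiv_", class), ...)
}

abort_schema    <- function(message, ...) pd_abort("schema_error", message, ...)
abort_value     <- function(message, ...) pd_abort("value_error", message, ...)
abort_integrity <- function(message, ...) pd_abort("integrity_error", message, ...)
abort_config    <- function(message, ...) pd_abort("config_error", message, ...)
abort_io        <- function(message, ...) pd_abort("io_error", message, ...)

#' Retrieve the exclusion log attached to a result
#'
#' Most pipeline steps drop records they cannot use (pairs without
#' annotation, saturated dS, genes duplicated in both origin classes, ...).
#' Nothing is dropped silently: each step attaches a count-per-reason table
#' to its result, retrievable with this accessor.
#'
#' @param x An object returned by a pipeline step.
#' @return A tibble with columns `reason` and `n` (zero rows when nothing
#'   was excluded).
#' @export
exclusion_log <- function(x) {
  log <- attr(x, "exclusions", exact = TRUE)
  if (is.null(log)) {
    return(tibble::tibble(reason = character(), n = integer()))
  }
  log
}

set_exclusions <- function(x, reasons) {
  # reasons: named integer vector, possibly empty
  reasons <- reasons[reasons > 0]
  attr(x, "exclusions") <- tibble::tibble(
    reason = names(reasons) %||% character(),
    n = as.integer(unname(reasons))
  )
  x
}

`%||%` <- rlang::`%||%`
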
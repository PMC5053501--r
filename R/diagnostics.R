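#' Construct a diagnostics table
#'
#' Diagnostics are the package's uniform way of reporting problems that are
#' not immediate errors: undefined chunk references, dataflow violations,
#' duplicated display items, missing display files at weave time, and so on.
#' They are plain data frames so they can be filtered, printed, and counted
#' with ordinary tools.
#'
#' @param severity `"fatal"`, `"warning"`, or `"info"`.
#' @param code Short machine-readable identifier, e.g. `"undefined-chunk"`.
#' @param message Human-readable description.
#' @param line 1-based source line number, or `NA` when not applicable.
#' @return A one-row data frame with columns `severity`, `code`, `message`,
#'   `line`.
#' @keywords internal
lir_diag <- function(severity, code, message, line = NA_integer_) {
  stopifnot(severity %in% c("fatal", "warning", "info"))
  data.frame(
    severity = severity, code = code, message = message,
    line = as.integer(line), stringsAsFactors = FALSE
  )
}

#' @rdname lir_diag
#' @keywords internal
lir_diag_none <- function() {
  data.frame(
    severity = character(), code = character(), message = character(),
    line = integer(), stringsAsFactors = FALSE
  )
}

#' Test for fatal diagnostics
#' @param diags A diagnostics data frame.
#' @return `TRUE` if any row has severity `"fatal"`.
#' @keywords internal
has_fatal <- function(diags) {
  nrow(diags) > 0L && any(diags$severity == "fatal")
}

format_diags <- function(diags) {
  if (nrow(diags) == 0L) return(character())
  loc <- ifelse(is.na(diags$line), "", sprintf(":%d", diags$line))
  sprintf("%s%s [%s] %s", diags$severity, loc, diags$code, diags$message)
}
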
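# Internal helpers shared across modules.

#' Round half away from zero at a fixed number of decimals
#'
#' Published agronomy tables are printed with half-up rounding (the SAS
#' convention), which differs from [base::round()]'s round-half-to-even.
#' A small epsilon absorbs binary representation error so that values such
#' as 15.825 (stored as 15.82499...) round up as they would on paper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

# stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

# Collapse a named list of scalars into "key=value" provenance strings
format_provenance <- function(x) {
  paste(sprintf("%s=%s", names(x), vapply(x, format, character(1))),
        collapse = ", ")
}
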
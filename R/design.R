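#' Experimental factors of the ultrasound pretreatment design
#'
#' The three sonication factors — time (A, minutes), bath temperature
#' (B, degrees Celsius) and ultrasound output power (C, watts) — each take
#' four equally spaced levels. Column D is a *vacancy* column: it carries no
#' physical treatment and its apparent effect estimates experimental error.
#'
#' @param name factor identifier, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param unit unit string (`"min"`, `"degC"`, `"W"`, or `""` for vacancy).
#' @param levels ordered numeric vector of 4 physical values (`NULL` for the
#'   vacancy column).
#' @return An object of class `sonopt_factor`.
#' @examples
#' default_factors()
#' @export
make_factor <- function(name, unit, levels = NULL) {
  abort_if(!name %in% c("A", "B", "C", "D"),
           "factor name must be one of A, B, C, D, got '%s'", name)
  if (name != "D") {
    abort_if(length(levels) != 4, "factor %s must have exactly 4 levels", name)
    abort_if(any(diff(levels) <= 0),
             "levels of factor %s must be strictly increasing", name)
  } else {
    abort_if(!is.null(levels), "vacancy column D carries no physical levels")
  }
  structure(list(name = name, unit = unit, levels = levels),
            class = "sonopt_factor")
}

#' @rdname make_factor
#' @export
default_factors <- function() {
  list(
    A = make_factor("A", "min", c(5, 15, 25, 35)),
    B = make_factor("B", "degC", c(25, 35, 45, 55)),
    C = make_factor("C", "W", c(200, 300, 400, 500)),
    D = make_factor("D", "")
  )
}

#' Build the L16(4^5) orthogonal array (operative 4-column form)
#'
#' Returns the 16-treatment design in the row order used throughout the
#' study: columns A, B, C hold the sonication factors and column D is the
#' vacancy (error) column. Only the four assigned columns are kept; the
#' unused fifth column of the catalog array is dropped.
#'
#' @return A `data.frame` of class `sonopt_design` with columns
#'   `treatment`, `A`, `B`, `C`, `D` (level indices 1-4).
#' @examples
#' d <- build_l16()
#' subset(d, treatment == 6)  # A2 B2 C2 D4
#' @export
build_l16 <- function() {
  d <- data.frame(
    treatment = 1:16,
    A = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4),
    B = rep(1:4, each = 4),
    C = c(4, 1, 3, 2, 3, 2, 4, 1, 1, 4, 2, 3, 2, 3, 1, 4),
    D = c(3, 1, 4, 2, 2, 4, 1, 3, 4, 2, 3, 1, 1, 3, 2, 4)
  )
  class(d) <- c("sonopt_design", "data.frame")
  d
}

design_columns <- function(design) intersect(c("A", "B", "C", "D"), names(design))

#' Validate balance and orthogonality of a 4-level design
#'
#' Checks the two defining properties of an orthogonal array: every column
#' contains each level index the same number of times (balance), and for
#' every pair of columns each ordered pair of levels occurs equally often
#' (orthogonality). Offending cells are reported rather than raised, so the
#' function can be used to audit user-supplied arrays.
#'
#' @param design a design `data.frame` with columns `treatment` and level
#'   indices `A`...`D`.
#' @return A list with logical flags `balanced` and `orthogonal` and a
#'   character vector `offending` describing any violations.
#' @examples
#' validate_design(build_l16())$orthogonal
#' @export
validate_design <- function(design) {
  abort_if(nrow(design) == 0L, "design has no rows")
  cols <- design_columns(design)
  offending <- character(0)
  n <- nrow(design)
  for (cl in cols) {
    tab <- table(factor(design[[cl]], levels = 1:4))
    if (length(unique(as.integer(tab))) != 1L) {
      offending <- c(offending, sprintf(
        "column %s level counts (%s) unbalanced", cl,
        paste(as.integer(tab), collapse = ",")))
    }
  }
  balanced <- length(offending) == 0L
  orthogonal <- TRUE
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (j <= i) next
      census <- table(design[[cols[i]]], design[[cols[j]]])
      expected <- n / 16
      if (!all(dim(census) == c(4, 4)) ||
          !all(as.integer(census) == expected)) {
        orthogonal <- FALSE
        offending <- c(offending, sprintf(
          "column pair (%s,%s): level-pair census not uniform",
          cols[i], cols[j]))
      }
    }
  }
  list(balanced = balanced, orthogonal = orthogonal, offending = offending)
}

#' Decode level indices into physical sonication conditions
#'
#' Maps each treatment's level indices onto the physical factor values
#' (time in minutes, temperature in degrees Celsius, power in watts).
#' The vacancy column is carried through as an index only.
#'
#' @param design a design table as returned by [build_l16()].
#' @param factors named list of `sonopt_factor` objects covering A, B, C;
#'   defaults to [default_factors()].
#' @return A `data.frame` with columns `treatment`, `time_min`, `temp_C`,
#'   `power_W`, and `D` (index).
#' @examples
#' decode_design(build_l16())[6, ]  # 15 min, 35 degC, 300 W
#' @export
decode_design <- function(design, factors = default_factors()) {
  abort_if(!all(c("A", "B", "C") %in% names(factors)),
           "factors must cover columns A, B and C")
  dec <- function(col, fac) {
    idx <- design[[col]]
    bad <- which(!idx %in% 1:4)
    abort_if(length(bad) > 0,
             "treatment %d has out-of-range level index %s in column %s",
             design$treatment[bad[1]], format(idx[bad[1]]), col)
    fac$levels[idx]
  }
  out <- data.frame(
    treatment = design$treatment,
    time_min = dec("A", factors$A),
    temp_C = dec("B", factors$B),
    power_W = dec("C", factors$C)
  )
  if ("D" %in% names(design)) out$D <- design$D
  out
}

#' Read/write a design table as CSV
#'
#' The level-index layout has columns `treatment,A,B,C,D`; the decoded
#' layout carries physical units in the header.
#'
#' @param design design table.
#' @param path file path.
#' @param decoded write the physical-condition variant instead of indices.
#' @return `read_design` returns a `sonopt_design` data.frame.
#' @export
write_design <- function(design, path, decoded = FALSE) {
  x <- if (decoded) decode_design(design) else as.data.frame(design)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path)
  abort_if(!all(c("treatment", "A", "B", "C") %in% names(d)),
           "design CSV must have columns treatment,A,B,C[,D]")
  class(d) <- c("sonopt_design", "data.frame")
  d
}
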
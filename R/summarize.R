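# Range analysis of the orthogonal experiment: level means, ranges R,
# factor importance ordering and optimal-level selection.

response_column <- function(data, response) {
  col <- switch(toupper(response),
                GP = intersect(c("gp_pct", "gp_mean"), names(data))[1],
                PL = intersect(c("pl_mm", "pl_mean"), names(data))[1],
                RL = intersect(c("rl_mm", "rl_mean"), names(data))[1],
                stop("response must be one of GP, PL, RL", call. = FALSE))
  abort_if(is.na(col) || is.null(col),
           "no %s column found in data", toupper(response))
  col
}

# Reduce raw (dish/seedling) data to one mean per treatment; a fixture
# table of per-treatment means passes through unchanged.
treatment_means <- function(data, response) {
  col <- response_column(data, response)
  if (col %in% c("gp_mean", "pl_mean", "rl_mean")) {
    data.frame(treatment = data$treatment, value = data[[col]])
  } else {
    agg <- stats::aggregate(data[[col]],
                            by = list(treatment = data$treatment), FUN = mean)
    names(agg)[2] <- "value"
    agg[order(agg$treatment), ]
  }
}

#' Per-factor level means of one response
#'
#' For each design column (A, B, C and the vacancy D) and each of its four
#' levels, averages the response over the treatments assigned that level.
#' With a balanced orthogonal array every level mean pools exactly four
#' treatments, so averaging treatment means and averaging all raw member
#' observations coincide.
#'
#' @param data either a per-treatment summary (e.g.
#'   [response_means_fixture()]) or a raw dataset at dish/seedling
#'   granularity.
#' @param design design table ([build_l16()]).
#' @param response `"GP"`, `"PL"` or `"RL"`.
#' @return A 4x4 matrix of level means (rows = levels 1-4, columns =
#'   factors A-D), with the per-level pooled SD and n attached as
#'   attributes `sd` and `n`.
#' @examples
#' level_means(response_means_fixture(), build_l16(), "GP")
#' @export
level_means <- function(data, design, response) {
  val <- validate_design(design)
  abort_if(!val$balanced || !val$orthogonal,
           "design must be a balanced orthogonal array; got: %s",
           paste(val$offending, collapse = "; "))
  tm <- treatment_means(data, response)
  abort_if(!all(design$treatment %in% tm$treatment),
           "data must cover every design treatment")
  v <- tm$value[match(design$treatment, tm$treatment)]
  cols <- design_columns(design)
  m <- matrix(NA_real_, 4, length(cols), dimnames = list(1:4, cols))
  sdm <- m; nm <- m
  col <- response_column(data, response)
  raw <- !col %in% c("gp_mean", "pl_mean", "rl_mean")
  for (cl in cols) {
    for (l in 1:4) {
      member <- design$treatment[design[[cl]] == l]
      m[l, cl] <- mean(v[design[[cl]] == l])
      if (raw) {
        obs <- data[[col]][data$treatment %in% member]
        sdm[l, cl] <- stats::sd(obs)
        nm[l, cl] <- length(obs)
      } else {
        nm[l, cl] <- length(member)
      }
    }
  }
  structure(m, sd = sdm, n = nm, response = toupper(response))
}

#' Range analysis of a level-mean table
#'
#' Computes the Taguchi range statistic R per factor — the spread
#' (max - min) of its four level means — ranks the three treatment factors
#' by descending R, and identifies the level attaining the maximal mean.
#' Following the published tables, R is computed on level means rounded to
#' two decimals (half-up); full-precision values are retained alongside.
#' The vacancy column D is summarised like a factor but always ranked
#' last: its R reflects experimental error, not a treatment effect.
#'
#' @param lmeans a level-mean matrix from [level_means()].
#' @return A `range_report` list: `level_means` (rounded), `level_means_full`,
#'   `range` (per factor, on rounded means), `range_full`, `order` (rank of
#'   each factor, D fixed last), `best_level`, `response`.
#' @examples
#' range_analysis(level_means(response_means_fixture(), build_l16(), "GP"))
#' @export
range_analysis <- function(lmeans) {
  abort_if(any(is.na(lmeans)), "level-mean table has missing cells")
  rounded <- round_half_up(unclass(lmeans), 2)
  rng <- apply(rounded, 2, function(x) max(x) - min(x))
  rng_full <- apply(unclass(lmeans), 2, function(x) max(x) - min(x))
  fac <- colnames(lmeans)
  treatment_factors <- setdiff(fac, "D")
  # descending R, alphabetical tie-break; vacancy D pinned to last place
  ord <- order(-rng[treatment_factors], treatment_factors)
  rank <- stats::setNames(integer(length(fac)), fac)
  rank[treatment_factors[ord]] <- seq_along(treatment_factors)
  if ("D" %in% fac) rank["D"] <- length(fac)
  best <- apply(unclass(lmeans), 2, which.max)
  structure(list(level_means = rounded,
                 level_means_full = unclass(lmeans),
                 level_sd = attr(lmeans, "sd"),
                 level_n = attr(lmeans, "n"),
                 range = rng, range_full = rng_full,
                 order = rank, best_level = best,
                 response = attr(lmeans, "response")),
            class = "range_report")
}

#' @export
print.range_report <- function(x, ...) {
  cat(sprintf("Range analysis (%s)\n", x$response))
  tab <- rbind(x$level_means, Range = x$range, Order = x$order)
  print(tab, ...)
  cat("Optimal levels:",
      paste0(names(x$best_level), x$best_level, collapse = " "), "\n")
  invisible(x)
}

#' Optimal level per factor
#'
#' Per factor, the level index whose level mean is maximal (ties broken
#' toward the lowest index). The published narrative occasionally differs
#' from the printed tables; any factor where the rounded level means tie
#' within `flag_tol` of the maximum is flagged so such ambiguity is visible.
#'
#' @param report a `range_report`.
#' @param flag_tol closeness (response units) under which a runner-up level
#'   is flagged as near-optimal.
#' @return Named integer vector of best levels (factors A-D), with
#'   attribute `near_ties` listing flagged factors.
#' @export
optimal_levels <- function(report, flag_tol = 0.01) {
  m <- report$level_means_full
  best <- apply(m, 2, which.max)
  near <- vapply(colnames(m), function(cl) {
    x <- sort(m[, cl], decreasing = TRUE)
    (x[1] - x[2]) <= flag_tol
  }, logical(1))
  structure(best, near_ties = names(near)[near])
}

#' Per-treatment summary and best-treatment identification
#'
#' Means and SDs per treatment for one response, plus the treatment whose
#' mean is maximal. Accepts raw datasets or passes a fixture summary
#' through.
#'
#' @param data dataset or per-treatment summary table.
#' @param response `"GP"`, `"PL"` or `"RL"`.
#' @return A list with `table` (`treatment`, `mean`, `sd`, `n`) and
#'   `best_treatment`.
#' @examples
#' treatment_summary(response_means_fixture(), "GP")$best_treatment  # 11
#' @export
treatment_summary <- function(data, response) {
  col <- response_column(data, response)
  if (col %in% c("gp_mean", "pl_mean", "rl_mean")) {
    sdcol <- sub("mean", "sd", col)
    tab <- data.frame(treatment = data$treatment, mean = data[[col]],
                      sd = data[[sdcol]], n = NA_integer_)
  } else {
    n <- tapply(data[[col]], data$treatment, length)
    abort_if(any(n == 0), "every treatment needs at least one observation")
    tab <- data.frame(
      treatment = as.integer(names(n)),
      mean = as.numeric(tapply(data[[col]], data$treatment, mean)),
      sd = as.numeric(tapply(data[[col]], data$treatment, stats::sd)),
      n = as.integer(n))
    tab <- tab[order(tab$treatment), ]
    rownames(tab) <- NULL
  }
  list(table = tab, best_treatment = tab$treatment[which.max(tab$mean)],
       response = toupper(response))
}

#' Export a range report as CSV (published-table layout)
#'
#' Rows Level 1-4, Range and Order; columns are the design factors.
#'
#' @param report a `range_report`.
#' @param path file path.
#' @export
write_range_report <- function(report, path) {
  tab <- rbind(report$level_means, Range = report$range,
               Order = report$order)
  out <- data.frame(row = c(paste("Level", 1:4), "Range", "Order"), tab,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
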
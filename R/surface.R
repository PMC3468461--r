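# Pairwise binary quadratic response surfaces on the physical factor
# scale, with stationary-point (peak) extraction. For each response and
# each factor pair (time-temperature, time-power, temperature-power) the
# model is
#   y = b0 + bi xi + bj xj + bii xi^2 + bjj xj^2 + bij xi xj ,
# fitted by OLS; the third factor is marginalised by averaging, which the
# balanced array makes unbiased for the terms retained.

pair_physical <- list(A = "time_min", B = "temp_C", C = "power_W")

#' Experimental bounds of the physical factors
#'
#' The level-1 to level-4 spans of the design: 5-35 min, 25-55 degC,
#' 200-500 W. Stationary points outside these ranges are extrapolations
#' and are excluded from peak collection.
#'
#' @param factors factor list, default [default_factors()].
#' @return Named list of length-2 numeric ranges for `A`, `B`, `C`.
#' @export
factor_bounds <- function(factors = default_factors()) {
  lapply(factors[c("A", "B", "C")], function(f) range(f$levels))
}

#' Fit one pairwise quadratic response surface
#'
#' OLS fit of one response on two physical factors with linear, pure
#' quadratic and interaction terms (6 coefficients). The default basis is
#' the 16 treatment means — the only data the study publishes — averaging
#' over the third factor; pass raw dish/seedling data for a
#' replicate-level fit.
#'
#' @param data per-treatment summary or raw dataset.
#' @param design design table.
#' @param response `"GP"`, `"PL"` or `"RL"`.
#' @param pair character vector of two factor ids, e.g. `c("A", "B")`.
#' @param factors factor list for physical decoding.
#' @return A `quadratic_fit` list: `coef` (named `b0, bi, bj, bii, bjj,
#'   bij`), `r2`, `n`, `pair`, `response`, `basis`, plus the model frame.
#' @examples
#' fit_quadratic_pair(response_means_fixture(), build_l16(), "GP",
#'                    c("A", "B"))
#' @export
fit_quadratic_pair <- function(data, design, response, pair,
                               factors = default_factors()) {
  abort_if(length(pair) != 2 || !all(pair %in% c("A", "B", "C")) ||
             pair[1] == pair[2],
           "pair must name two distinct factors among A, B, C")
  tm <- treatment_means(data, response)
  dec <- decode_design(design, factors)
  idx <- match(tm$treatment, dec$treatment)
  xi <- dec[[pair_physical[[pair[1]]]]][idx]
  xj <- dec[[pair_physical[[pair[2]]]]][idx]
  y <- tm$value
  basis <- if (nrow(tm) == nrow(data)) "treatment-means" else "raw"
  if (basis == "raw") {
    # refit on all observations rather than their treatment means
    col <- response_column(data, response)
    didx <- match(data$treatment, dec$treatment)
    xi <- dec[[pair_physical[[pair[1]]]]][didx]
    xj <- dec[[pair_physical[[pair[2]]]]][didx]
    y <- data[[col]]
  }
  abort_if(length(unique(paste(xi, xj))) < 6,
           "need >= 6 distinct design points for a 6-parameter surface")
  X <- cbind(1, xi, xj, xi^2, xj^2, xi * xj)
  qr_X <- qr(X)
  abort_if(qr_X$rank < 6,
           "design is rank-deficient for pair (%s, %s)", pair[1], pair[2])
  beta <- qr.coef(qr_X, y)
  fitted <- drop(X %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    coef = stats::setNames(beta, c("b0", "bi", "bj", "bii", "bjj", "bij")),
    r2 = if (sst > 0) 1 - sse / sst else 1,
    n = length(y), pair = pair, response = toupper(response),
    basis = basis,
    frame = data.frame(xi = xi, xj = xj, y = y, fitted = fitted)),
    class = "quadratic_fit")
}

#' Evaluate a fitted quadratic surface
#'
#' @param object a `quadratic_fit`.
#' @param xi,xj coordinates on the physical scale of the fitted pair.
#' @param ... unused.
#' @return Predicted response values.
#' @export
predict.quadratic_fit <- function(object, xi, xj, ...) {
  b <- object$coef
  b["b0"] + b["bi"] * xi + b["bj"] * xj +
    b["bii"] * xi^2 + b["bjj"] * xj^2 + b["bij"] * xi * xj
}

#' Stationary point of a quadratic surface
#'
#' Solves the 2x2 zero-gradient system, classifies the point by the
#' Hessian eigenvalue signs (maximum / minimum / saddle), and checks it
#' against the experimental factor bounds. A singular Hessian yields a
#' degenerate result with no coordinates rather than an error.
#'
#' @param fit a `quadratic_fit`.
#' @param bounds named list of physical ranges, default [factor_bounds()].
#' @return A `stationary_point` list: `x` (coordinates named by factor),
#'   `type`, `in_bounds`, `value` (predicted response), `degenerate`.
#' @examples
#' f <- fit_quadratic_pair(response_means_fixture(), build_l16(), "GP",
#'                         c("A", "B"))
#' stationary_point(f)
#' @export
stationary_point <- function(fit, bounds = factor_bounds()) {
  b <- fit$coef
  Hm <- matrix(c(2 * b["bii"], b["bij"], b["bij"], 2 * b["bjj"]), 2, 2)
  scale <- max(abs(Hm), 1e-12)
  if (abs(det(Hm)) < 1e-10 * scale^2) {
    return(structure(list(x = NULL, type = "degenerate", in_bounds = FALSE,
                          value = NA_real_, degenerate = TRUE,
                          pair = fit$pair, response = fit$response),
                     class = "stationary_point"))
  }
  x <- solve(Hm, -c(b["bi"], b["bj"]))
  ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  type <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
          else "saddle"
  bi <- bounds[[fit$pair[1]]]; bj <- bounds[[fit$pair[2]]]
  in_bounds <- x[1] >= bi[1] && x[1] <= bi[2] &&
    x[2] >= bj[1] && x[2] <= bj[2]
  structure(list(x = stats::setNames(x, fit$pair), type = type,
                 in_bounds = in_bounds,
                 value = unname(predict(fit, x[1], x[2])),
                 degenerate = FALSE, pair = fit$pair,
                 response = fit$response),
            class = "stationary_point")
}

#' Fit all nine pairwise surfaces
#'
#' Three factor pairs x three responses.
#'
#' @inheritParams fit_quadratic_pair
#' @param responses responses to fit.
#' @return Named list of `quadratic_fit` objects (`"GP:AB"`, ...).
#' @export
fit_all_pairs <- function(data, design, responses = c("GP", "PL", "RL"),
                          factors = default_factors()) {
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  fits <- list()
  for (r in responses) for (p in pairs) {
    fits[[paste0(r, ":", p[1], p[2])]] <-
      fit_quadratic_pair(data, design, r, p, factors)
  }
  fits
}

#' Harvest per-factor peak coordinates from surface fits
#'
#' Each factor appears in two of the three pairs, so with three responses
#' it can contribute up to six peak coordinates (the inputs to the
#' grouped-mode aggregation). Only in-bounds maxima are harvested;
#' saddles, minima, degenerate fits and out-of-bounds points are excluded
#' with a logged reason, and a warning is raised when a factor ends up
#' with fewer than `2 * length(responses)` values.
#'
#' Peaks are harvested at reporting precision (`digits`, default one
#' decimal per factor): the downstream binned-mode estimator operates on
#' values as they would be read off and reported, and sub-precision
#' differences should not decide bin membership.
#'
#' @param fits list of `quadratic_fit` objects (see [fit_all_pairs()]).
#' @param bounds physical bounds, default [factor_bounds()].
#' @param digits named integer vector, rounding of harvested coordinates
#'   per factor.
#' @return A `peak_collection`: list with `peaks` (named list of numeric
#'   vectors per factor), `provenance` (data.frame of every harvested
#'   value) and `excluded` (data.frame of exclusions with reasons).
#' @export
collect_peaks <- function(fits, bounds = factor_bounds(),
                          digits = c(A = 1, B = 1, C = 1)) {
  prov <- list(); excl <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    sp <- stationary_point(fit, bounds)
    reason <- if (sp$degenerate) "degenerate Hessian"
      else if (sp$type != "maximum") paste("type:", sp$type)
      else if (!sp$in_bounds) "outside experimental bounds"
      else NA_character_
    if (!is.na(reason)) {
      excl[[nm]] <- data.frame(fit = nm, reason = reason)
      next
    }
    for (f in fit$pair) {
      prov[[paste0(nm, ":", f)]] <- data.frame(
        factor = f, response = fit$response,
        pair = paste(fit$pair, collapse = ""),
        value = round_half_up(unname(sp$x[f]),
                              if (f %in% names(digits)) digits[[f]] else 1),
        value_full = unname(sp$x[f]))
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(factor = character(), response = character(),
               pair = character(), value = numeric(),
               value_full = numeric())
  rownames(prov) <- NULL
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(fit = character(), reason = character())
  rownames(excl) <- NULL
  n_resp <- length(unique(vapply(fits, `[[`, character(1), "response")))
  peaks <- lapply(stats::setNames(nm = c("A", "B", "C")), function(f)
    prov$value[prov$factor == f])
  for (f in names(peaks)) {
    if (length(peaks[[f]]) > 0 && length(peaks[[f]]) < 2 * n_resp)
      warning(sprintf(
        "factor %s: only %d of %d surface peaks usable (see exclusions)",
        f, length(peaks[[f]]), 2 * n_resp), call. = FALSE)
  }
  structure(list(peaks = peaks, provenance = prov, excluded = excl),
            class = "peak_collection")
}

#' Rectangular prediction grid over a fitted surface
#'
#' @param fit a `quadratic_fit`.
#' @param bounds physical bounds, default [factor_bounds()].
#' @param resolution grid points per axis.
#' @return Long-format `data.frame` (`xi`, `xj`, `yhat`) suitable for any
#'   contour plotter.
#' @export
surface_grid <- function(fit, bounds = factor_bounds(), resolution = 41) {
  abort_if(resolution < 2, "resolution must be >= 2")
  bi <- bounds[[fit$pair[1]]]; bj <- bounds[[fit$pair[2]]]
  g <- expand.grid(xi = seq(bi[1], bi[2], length.out = resolution),
                   xj = seq(bj[1], bj[2], length.out = resolution))
  g$yhat <- predict(fit, g$xi, g$xj)
  names(g)[1:2] <- c(pair_physical[[fit$pair[1]]],
                     pair_physical[[fit$pair[2]]])
  g
}
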
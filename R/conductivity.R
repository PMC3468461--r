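# Logarithmic electrolyte-leakage models for seed-leachate conductivity:
# y = a + b * log(t). Conductivity of the water seeds soak in is a proxy
# for membrane damage; its rise with soaking time is well described by a
# log-time law over the 4-24 h window.

#' Fit a logarithmic leakage model
#'
#' Ordinary least squares of conductivity on `log(time)`:
#' `y = a + b * log(t)`. Readings at replicate level or group means may be
#' supplied; the basis is recorded in the fit. With zero variance in `y`
#' the fit reports `b = 0` and, by convention, `r2 = 0` (no variance
#' explained).
#'
#' @param time_h soaking times (hours), strictly positive, at least 3
#'   distinct values.
#' @param y conductivity readings, same length.
#' @param base logarithm base; natural log by default.
#' @param basis label recorded in the fit (`"means"` or `"replicates"`).
#' @return A `conductivity_fit` list: `a`, `b`, `r2`, `n`, `base`, `basis`.
#' @examples
#' with(subset(conductivity_fixture(), group == "control"),
#'      fit_log_model(time_h, conductivity))
#' @export
fit_log_model <- function(time_h, y, base = exp(1), basis = "means") {
  abort_if(length(time_h) != length(y), "time and reading lengths differ")
  abort_if(any(time_h <= 0), "soaking times must be positive")
  abort_if(length(unique(time_h)) < 3,
           "need at least 3 distinct soaking times")
  x <- log(time_h, base = base)
  fit <- stats::lm.fit(cbind(1, x), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * max(1, mean(y)^2)) 0 else 1 - sse / sst
  structure(list(a = unname(fit$coefficients[1]),
                 b = unname(fit$coefficients[2]),
                 r2 = max(0, min(1, r2)), n = length(y),
                 base = base, basis = basis),
            class = "conductivity_fit")
}

#' @export
print.conductivity_fit <- function(x, ...) {
  cat(sprintf("y = %.3f + %.3f log(t)   R2 = %.3f  (n = %d, basis = %s)\n",
              x$a, x$b, x$r2, x$n, x$basis))
  invisible(x)
}

#' Fit leakage models per treatment group
#'
#' @param records `data.frame` with columns `group`, `time_h`,
#'   `conductivity` (replicate column optional).
#' @param base logarithm base.
#' @return A `data.frame`: `group`, `a`, `b`, `r2`, `n`.
#' @examples
#' fit_log_models(conductivity_fixture())
#' @export
fit_log_models <- function(records, base = exp(1)) {
  basis <- if ("replicate" %in% names(records) &&
               any(duplicated(records[c("group", "time_h")]))) "replicates"
           else "means"
  parts <- split(records, records$group, drop = TRUE)
  out <- do.call(rbind, lapply(names(parts), function(g) {
    f <- fit_log_model(parts[[g]]$time_h, parts[[g]]$conductivity,
                       base = base, basis = basis)
    data.frame(group = g, a = f$a, b = f$b, r2 = f$r2, n = f$n)
  }))
  rownames(out) <- NULL
  out
}

#' Compare treatment groups at each soaking time
#'
#' One-way ANOVA across groups at every time point, followed by
#' Student-Newman-Keuls letter grouping of the group means (groups sharing
#' a letter are not significantly different at `alpha`).
#'
#' @param records replicate-level `data.frame` with columns `group`,
#'   `time_h`, `replicate`, `conductivity`; at least 2 replicates per
#'   group x time cell.
#' @param alpha significance level.
#' @return A named list (one element per time point) of
#'   [snk_letters()] results.
#' @export
compare_groups <- function(records, alpha = 0.05) {
  need <- c("group", "time_h", "conductivity")
  abort_if(!all(need %in% names(records)),
           "records must have columns group, time_h, conductivity")
  cells <- table(records$group, records$time_h)
  abort_if(any(cells < 2),
           "every group x time cell needs >= 2 replicates")
  out <- lapply(split(records, records$time_h), function(d) {
    d$group <- droplevels(factor(d$group))
    fit <- stats::aov(conductivity ~ group, data = d)
    ms <- stats::anova(fit)
    mse <- ms["Residuals", "Mean Sq"]
    dfe <- ms["Residuals", "Df"]
    means <- tapply(d$conductivity, d$group, mean)
    n <- unique(as.integer(table(d$group)))
    abort_if(length(n) != 1, "group sizes must be equal within a time point")
    snk_letters(means, mse, dfe, n, alpha = alpha)
  })
  out
}
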
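# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: explicit normal equations instead of qr, dense
# grid search instead of the closed-form stationary point, definitional
# sums of squares instead of aov().

# OLS coefficients via explicit 6x6 normal equations
oracle_quad_coef <- function(xi, xj, y) {
  X <- cbind(1, xi, xj, xi^2, xj^2, xi * xj)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# argmax of a fitted quadratic surface by dense grid search
oracle_grid_max <- function(fit, bounds, step_frac = 0.01) {
  bi <- bounds[[fit$pair[1]]]; bj <- bounds[[fit$pair[2]]]
  gi <- seq(bi[1], bi[2], by = step_frac * diff(bi))
  gj <- seq(bj[1], bj[2], by = step_frac * diff(bj))
  g <- expand.grid(xi = gi, xj = gj)
  yhat <- predict(fit, g$xi, g$xj)
  c(g$xi[which.max(yhat)], g$xj[which.max(yhat)])
}

# definitional main-effect SS for a balanced one-observation-per-cell
# layout: n_level * sum over levels of (level mean - grand mean)^2
oracle_main_ss <- function(y, idx) {
  gm <- mean(y)
  lv <- sort(unique(idx))
  sum(vapply(lv, function(l) sum(idx == l) * (mean(y[idx == l]) - gm)^2,
             numeric(1)))
}

# closed-form simple regression of y on x
oracle_simple_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  sse <- sum((y - a - b * x)^2)
  sst <- sum((y - mean(y))^2)
  list(a = a, b = b, r2 = 1 - sse / sst)
}

# deterministic sub-seed streams for Monte-Carlo loops
sub_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
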
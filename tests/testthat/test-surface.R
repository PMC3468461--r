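design <- build_l16()
fx <- response_means_fixture()

test_that("a noiseless quadratic is interpolated to machine precision", {
  dec <- decode_design(design)
  truth <- c(b0 = 20, bi = 4, bj = -1, bii = -0.09, bjj = -0.012, bij = 0.01)
  y <- truth["b0"] + truth["bi"] * dec$time_min + truth["bj"] * dec$temp_C +
    truth["bii"] * dec$time_min^2 + truth["bjj"] * dec$temp_C^2 +
    truth["bij"] * dec$time_min * dec$temp_C
  dat <- data.frame(treatment = 1:16, gp_mean = y, gp_sd = 0)
  fit <- fit_quadratic_pair(dat, design, "GP", c("A", "B"))
  expect_equal(unname(fit$coef), unname(truth), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
})

test_that("coefficients match the explicit normal-equations oracle", {
  seeds <- sub_seeds(314, 8)
  for (s in seeds) {
    set.seed(s)
    dat <- data.frame(treatment = 1:16, gp_mean = runif(16, 60, 95),
                      gp_sd = 1)
    pair <- sample(list(c("A", "B"), c("A", "C"), c("B", "C")), 1)[[1]]
    fit <- fit_quadratic_pair(dat, design, "GP", pair)
    expect_equal(unname(fit$coef),
                 unname(oracle_quad_coef(fit$frame$xi, fit$frame$xj,
                                         fit$frame$y)),
                 tolerance = 1e-8)
    # residual orthogonality to every design column
    X <- with(fit$frame, cbind(1, xi, xj, xi^2, xj^2, xi * xj))
    resid <- fit$frame$y - fit$frame$fitted
    expect_lt(max(abs(crossprod(X, resid))), 1e-6)
  }
})

test_that("R^2 is invariant under affine predictor rescaling", {
  fit <- fit_quadratic_pair(fx, design, "GP", c("A", "B"))
  shifted <- default_factors()
  shifted$A$levels <- (shifted$A$levels - 20) / 10    # affine reparam
  fit2 <- fit_quadratic_pair(fx, design, "GP", c("A", "B"),
                             factors = shifted)
  expect_equal(fit2$r2, fit$r2, tolerance = 1e-10)
})

test_that("stationary points are classified analytically", {
  vertex <- list(coef = c(b0 = 0, bi = 4, bj = 6, bii = -1, bjj = -1,
                          bij = 0),
                 pair = c("A", "B"), response = "GP")
  class(vertex) <- "quadratic_fit"
  sp <- stationary_point(vertex, bounds = list(A = c(0, 10), B = c(0, 10)))
  expect_equal(unname(sp$x), c(2, 3))
  expect_equal(sp$type, "maximum")
  expect_true(sp$in_bounds)
  expect_equal(sp$value, 0 + 4 * 2 + 6 * 3 - 4 - 9)

  saddle <- vertex
  saddle$coef <- c(b0 = 0, bi = 0, bj = 0, bii = 1, bjj = -1, bij = 0)
  expect_equal(stationary_point(saddle)$type, "saddle")

  degen <- vertex
  degen$coef <- c(b0 = 0, bi = 1, bj = 1, bii = 0, bjj = 0, bij = 0)
  expect_true(stationary_point(degen)$degenerate)
})

test_that("stationary points agree with a dense grid-search oracle", {
  seeds <- sub_seeds(2718, 6)
  bounds <- factor_bounds()
  for (s in seeds) {
    set.seed(s)
    dat <- data.frame(treatment = 1:16, gp_mean = runif(16, 60, 95),
                      gp_sd = 1)
    fit <- fit_quadratic_pair(dat, design, "GP", c("A", "C"))
    sp <- stationary_point(fit, bounds)
    if (sp$degenerate || sp$type != "maximum" || !sp$in_bounds) next
    gm <- oracle_grid_max(fit, bounds)
    step <- 0.01 * c(diff(bounds$A), diff(bounds$C))
    expect_lt(abs(sp$x[1] - gm[1]), step[1] + 1e-9)
    expect_lt(abs(sp$x[2] - gm[2]), step[2] + 1e-9)
  }
})

test_that("fixture surfaces peak where the study reports (loose check)", {
  fit <- fit_quadratic_pair(fx, design, "GP", c("A", "B"))
  sp <- stationary_point(fit)
  expect_equal(sp$type, "maximum")
  expect_lt(abs(sp$x["B"] - 40.6), 2)
  # all nine fixture fits are in-bounds maxima
  pk <- collect_peaks(fit_all_pairs(fx, design))
  expect_equal(nrow(pk$excluded), 0)
  expect_equal(lengths(pk$peaks), c(A = 6L, B = 6L, C = 6L))
  # harvested peak sets reproduce the published six-value lists
  for (f in c("A", "B", "C"))
    expect_setequal(pk$peaks[[f]], reported_peaks_fixture(f))
})

test_that("saddle fits are excluded from peaks with a warning", {
  fits <- fit_all_pairs(fx, design, responses = "GP")
  fits[["GP:AB"]]$coef <- c(b0 = 0, bi = 0, bj = 0, bii = 1, bjj = -1,
                            bij = 0)
  expect_warning(pk <- collect_peaks(fits), "usable")
  expect_lt(length(pk$peaks$A), 2)
  expect_true(any(grepl("saddle", pk$excluded$reason)))
})

test_that("surface grids evaluate the polynomial on the requested lattice", {
  fit <- fit_quadratic_pair(fx, design, "PL", c("B", "C"))
  g <- surface_grid(fit, resolution = 2)
  expect_equal(nrow(g), 4)
  expect_equal(g$yhat, predict(fit, g$temp_C, g$power_W))
  # grid max of a concave fit sits within one step of the stationary point
  g2 <- surface_grid(fit, resolution = 101)
  sp <- stationary_point(fit)
  gm <- g2[which.max(g2$yhat), ]
  expect_lt(abs(gm$temp_C - sp$x["B"]), diff(factor_bounds()$B) / 100 + 1e-9)

  flat <- fit
  flat$coef <- c(b0 = 5, bi = 0, bj = 0, bii = 0, bjj = 0, bij = 0)
  expect_true(all(surface_grid(flat, resolution = 3)$yhat == 5))
})

test_that("stationary-point error shrinks with the noise level", {
  truth <- fit_quadratic_pair(fx, design, "GP", c("A", "B"))
  truth_x <- stationary_point(truth)$x
  dec <- decode_design(design)
  mu <- pmin(pmax(predict(truth, dec$time_min, dec$temp_C), 1), 99)
  dev_at <- function(sd, seeds) {
    vapply(seeds, function(s) {
      eff <- effect_config(gp_mean = mu, gp_sd = rep(sd, 16))
      d <- gen_germination(design, layout_config(), eff, seed = s)
      sp <- stationary_point(fit_quadratic_pair(d, design, "GP",
                                                c("A", "B")))
      sqrt(sum((sp$x - truth_x)^2))
    }, numeric(1))
  }
  seeds <- sub_seeds(606, 20)
  lo <- dev_at(4, seeds)     # quarter of the study's dish-level SD
  hi <- dev_at(15, seeds)    # study-scale noise
  expect_lt(median(lo), median(hi))
  expect_lt(median(lo), 2)   # near-noiseless recovery is tight
})

test_that("degenerate inputs are refused", {
  expect_error(fit_quadratic_pair(fx, design, "GP", c("A", "A")), "pair")
  collinear <- design
  collinear$C <- collinear$A                         # pair spans 4 points
  expect_error(fit_quadratic_pair(fx, collinear, "GP", c("A", "C")),
               "distinct design points|rank")
})
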
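design <- build_l16()

test_that("main-effect SS match the definitional oracle on treatment means", {
  fx <- response_means_fixture()
  one <- data.frame(treatment = 1:16, gp_pct = fx$gp_mean)
  a <- factorial_anova(one, design, "GP", terms = c("A", "B", "C"))
  expect_equal(a$df[a$term != "residual"], rep(3, 3))
  expect_equal(a$df[a$term == "residual"], 6)       # 15 - 3*3
  for (cl in c("A", "B", "C"))
    expect_equal(a$ss[a$term == cl],
                 oracle_main_ss(fx$gp_mean, design[[cl]]))
  # SS conservation
  expect_equal(sum(a$ss), sum((fx$gp_mean - mean(fx$gp_mean))^2))
})

test_that("SS decomposition is conserved and order-invariant on replicated data", {
  eff <- fixture_effects()
  d <- gen_germination(design, layout_config(), eff, seed = 41)
  a1 <- factorial_anova(d, design, "GP", terms = c("A", "B", "C", "D"))
  a2 <- factorial_anova(d, design, "GP", terms = c("D", "C", "B", "A"))
  expect_equal(sum(a1$ss), sum((d$gp_pct - mean(d$gp_pct))^2))
  for (cl in c("A", "B", "C", "D"))
    expect_equal(a1$ss[a1$term == cl], a2$ss[a2$term == cl])
  # a 9-df interaction is estimable in the reduced two-factor model
  ab <- factorial_anova(d, design, "GP", terms = c("A", "B", "A:B"))
  expect_equal(ab$df[ab$term == "A:B"], 9)
  expect_equal(sum(ab$ss), sum((d$gp_pct - mean(d$gp_pct))^2))
})

test_that("interactions without replication or aliased with other columns are refused", {
  one <- data.frame(treatment = 1:16, gp_pct = rnorm(16))
  expect_error(
    factorial_anova(one, design, "GP", terms = c("A", "B", "A:B")),
    "replicated|saturates")
  expect_error(factorial_anova(one, design, "GP", terms = c("A", "B", "C", "X")),
               "unsupported")
  # the 16-run array cannot carry a 9-df interaction on top of all mains
  d <- gen_germination(design, layout_config(), fixture_effects(), seed = 2)
  expect_error(
    factorial_anova(d, design, "GP", terms = c("A", "B", "C", "D", "A:B")),
    "aliased")
})

test_that("polynomial split partitions each main effect into 1-df components", {
  eff <- fixture_effects()
  d <- gen_germination(design, layout_config(), eff, seed = 43)
  a <- factorial_anova(d, design, "GP", terms = c("A", "B", "C"),
                       split_polynomial = TRUE)
  comps <- a[grepl("B:", a$term), ]
  expect_equal(nrow(comps), 3)                      # linear/quadratic/cubic
  expect_equal(sum(comps$ss), a$ss[a$term == "B"])
  expect_equal(comps$df, rep(1, 3))
})

test_that("vacancy column stays quiet under a pure main-effect truth", {
  # strong A effect, B/C/D null: D (error check) must not light up
  gp <- c(50, 65, 80, 95)[design$A]
  eff <- effect_config(gp_mean = gp, gp_rho = 0.02)
  hits_a <- 0; hits_d <- 0
  seeds <- sub_seeds(4242, 40)
  for (s in seeds) {
    d <- gen_germination(design, layout_config(), eff, seed = s)
    a <- factorial_anova(d, design, "GP")
    hits_a <- hits_a + (a$p[a$term == "A"] < 0.05)
    hits_d <- hits_d + (a$p[a$term == "D"] < 0.05)
  }
  expect_equal(hits_a, 40)                           # enormous effect
  expect_gte(40 - hits_d, 36)                        # D null in >= 90%
})

test_that("SNK letters separate and merge as the critical range dictates", {
  # identical means share a letter
  eq <- snk_letters(c(a = 5, b = 5, c = 5), ms = 2, df = 9, n = 4)
  expect_equal(unique(eq$letters), "a")
  # huge spread, tiny error: all distinct
  tri <- snk_letters(c(g1 = 0, g2 = 10, g3 = 20), ms = 1e-4, df = 12, n = 5)
  expect_equal(tri$letters, c("a", "b", "c"))
  # two groups straddling the boundary: shared letter iff below critical
  ms <- 4; df <- 10; n <- 4
  w2 <- qtukey(0.95, 2, df) * sqrt(ms / n)
  just_below <- snk_letters(c(x = 0, y = w2 * 0.99), ms, df, n)
  just_above <- snk_letters(c(x = 0, y = w2 * 1.01), ms, df, n)
  expect_equal(unique(just_below$letters), "a")
  expect_setequal(just_above$letters, c("a", "b"))
})

test_that("SNK separation is monotone in the error mean square", {
  # decreasing the error MS never merges a previously separated pair:
  # any pair sharing a letter at the smaller MS also shared one before
  shares <- function(lt) {
    outer(lt$letters, lt$letters, Vectorize(function(x, y)
      any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])))
  }
  seeds <- sub_seeds(77, 20)
  for (s in seeds) {
    set.seed(s)
    means <- sort(rnorm(5, 0, 3))
    names(means) <- paste0("g", 1:5)
    coarse <- shares(snk_letters(means, ms = 4, df = 15, n = 4))
    fine <- shares(snk_letters(means, ms = 1, df = 15, n = 4))
    expect_true(all(coarse[fine]))   # fine-shared pairs were coarse-shared
  }
})

test_that("MANOVA statistics satisfy the eigenvalue identities", {
  seeds <- sub_seeds(123, 10)
  for (s in seeds) {
    set.seed(s)
    p <- sample(2:4, 1)
    A_ <- matrix(rnorm(p * p), p); E <- crossprod(A_) + diag(p)
    B_ <- matrix(rnorm(p * p), p); H <- crossprod(B_)
    res <- manova_tests(H, E, df_h = p + 1, df_e = 30)
    lam <- sort(Re(eigen(solve(E) %*% H, only.values = TRUE)$values),
                decreasing = TRUE)
    v <- setNames(res$value, res$statistic)
    expect_equal(unname(v["Wilks' Lambda"]), prod(1 / (1 + lam)))
    expect_equal(unname(v["Pillai's Trace"]), sum(lam / (1 + lam)))
    expect_equal(unname(v["Hotelling-Lawley Trace"]), sum(lam))
    expect_equal(unname(v["Roy's Greatest Root"]), lam[1])
    expect_true(v["Wilks' Lambda"] > 0 && v["Wilks' Lambda"] <= 1)
  }
})

test_that("zero hypothesis mass gives the no-effect identities", {
  res <- manova_tests(matrix(0, 3, 3), diag(3), df_h = 2, df_e = 20)
  expect_equal(res$value, c(1, 0, 0, 0))
  expect_error(manova_tests(diag(2), matrix(0, 2, 2), 1, 10),
               "positive definite")
})

test_that("adding hypothesis mass strictly decreases Wilks", {
  E <- diag(2); H <- diag(c(0.5, 0.2))
  w1 <- manova_tests(H, E, 2, 20)$value[1]
  w2 <- manova_tests(H + diag(c(0.3, 0.3)), E, 2, 20)$value[1]
  expect_lt(w2, w1)
})

test_that("single-response MANOVA reduces to the univariate F", {
  ss_h <- 24; ss_e <- 60; q <- 3; v <- 12
  res <- manova_tests(matrix(ss_h), matrix(ss_e), q, v)
  f_uni <- (ss_h / q) / (ss_e / v)
  expect_equal(res$f, rep(f_uni, 4))
  expect_equal(res$num_df, rep(q, 4))
  expect_equal(res$den_df, rep(v, 4))
})

test_that("F approximations agree with stats::manova on real data", {
  set.seed(5)
  g <- factor(rep(1:3, each = 12))
  Y <- cbind(rnorm(36, as.integer(g)), rnorm(36, 2 * as.integer(g)))
  ss <- sscp_oneway(Y, g)
  res <- manova_tests(ss$H, ss$E, ss$df_h, ss$df_e)
  fit <- stats::manova(Y ~ g)
  for (tst in c("Wilks", "Pillai", "Roy")) {
    sm <- summary(fit, test = tst)$stats
    row <- switch(tst, Wilks = "Wilks' Lambda", Pillai = "Pillai's Trace",
                  Roy = "Roy's Greatest Root")
    expect_equal(res$value[res$statistic == row], unname(sm["g", 2]),
                 tolerance = 1e-8)
    expect_equal(res$f[res$statistic == row], unname(sm["g", "approx F"]),
                 tolerance = 1e-6)
  }
})

test_that("published MANOVA table internals are mutually consistent", {
  # reconstruct H, E with the published eigenstructure: the printed Roy
  # root and Hotelling-Lawley trace fix both eigenvalues of H E^-1, and
  # the printed S, M, N imply p = 2, q = 2, v = 1582
  lam1 <- 1.69374420
  lam2 <- 1.73789388 - lam1
  res <- manova_tests(diag(c(lam1, lam2)), diag(2), df_h = 2, df_e = 1582)
  expect_equal(attr(res, "s"), 2)
  expect_equal(attr(res, "m"), -0.5)
  expect_equal(attr(res, "n"), 789.5)
  v <- setNames(res$value, res$statistic)
  expect_equal(unname(v["Wilks' Lambda"]), 0.35553379, tolerance = 1e-7)
  expect_equal(unname(v["Pillai's Trace"]), 0.67105241, tolerance = 1e-7)
  f <- setNames(res$f, res$statistic)
  expect_equal(unname(f["Wilks' Lambda"]), 535.25, tolerance = 1e-4)
  expect_equal(unname(f["Pillai's Trace"]), 399.42, tolerance = 1e-4)
  expect_equal(unname(f["Roy's Greatest Root"]), 1339.75, tolerance = 1e-4)
  expect_equal(res$den_df[res$statistic == "Wilks' Lambda"], 3162)
  expect_equal(res$den_df[res$statistic == "Pillai's Trace"], 3164)
  expect_equal(res$note[res$statistic == "Roy's Greatest Root"],
               "upper bound")
})
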
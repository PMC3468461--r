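# Inference machinery: factorial ANOVA over the design columns (with the
# vacancy column as an error check), Student-Newman-Keuls compact letter
# displays, and MANOVA test statistics from SSCP matrices.

#' Factorial ANOVA over the orthogonal design
#'
#' Fits a fixed-effects ANOVA of one response on the design columns,
#' treated as categorical 4-level factors (3 df each; pairwise
#' interactions 9 df). Because the array is balanced, the sequential
#' decomposition equals the Type III one and term order is immaterial.
#' The vacancy column D carries no treatment, so its term estimates
#' experimental error: a significant D is a red flag for the analysis.
#' An `experiment` term models run-to-run (block) differences.
#'
#' Factors may instead be treated as continuous with orthogonal polynomial
#' contrasts (`split_polynomial = TRUE`), which partitions each main
#' effect into linear, quadratic and cubic single-df components.
#'
#' @param data dataset with a `treatment` column and the response at dish
#'   or seedling granularity (and `experiment` if a block term is used).
#' @param design design table ([build_l16()]).
#' @param response `"GP"`, `"PL"` or `"RL"`.
#' @param terms model terms among `"A"`, `"B"`, `"C"`, `"D"`,
#'   `"A:B"`, `"B:C"`, `"A:C"`, `"experiment"`.
#' @param split_polynomial also report per-factor polynomial contrast
#'   components (factors must then be interpreted as equally spaced).
#' @return An `anova_table` data.frame: `term`, `df`, `ss`, `ms`, `f`, `p`,
#'   with the residual row last.
#' @examples
#' eff <- effect_config(gp_mean = seq(60, 90, length.out = 16), gp_rho = 0.05)
#' d <- gen_germination(build_l16(), layout_config(), eff, seed = 42)
#' factorial_anova(d, build_l16(), "GP", terms = c("A", "B", "C", "D"))
#' @export
factorial_anova <- function(data, design, response,
                            terms = c("A", "B", "C", "D"),
                            split_polynomial = FALSE) {
  col <- response_column(data, response)
  allowed <- c("A", "B", "C", "D", "A:B", "B:C", "A:C", "experiment")
  bad <- setdiff(terms, allowed)
  abort_if(length(bad) > 0, "unsupported model term(s): %s",
           paste(bad, collapse = ", "))
  df <- data.frame(y = data[[col]])
  idx <- match(data$treatment, design$treatment)
  abort_if(anyNA(idx), "data contains treatments absent from the design")
  for (cl in design_columns(design))
    df[[cl]] <- factor(design[[cl]][idx], levels = 1:4)
  if ("experiment" %in% terms) {
    abort_if(!"experiment" %in% names(data),
             "model requests an experiment term but data has no experiment column")
    df$experiment <- factor(data$experiment)
  }
  # replication check: interactions need more observations than model df
  model_df <- sum(vapply(terms, function(tm) {
    if (tm == "experiment") length(unique(df$experiment)) - 1L
    else if (grepl(":", tm)) 9L else 3L
  }, integer(1)))
  n_per_trt <- min(table(data$treatment))
  for (tm in grep(":", terms, value = TRUE))
    abort_if(n_per_trt < 2 && model_df >= nrow(df),
             "term %s requires replicated observations per treatment", tm)
  abort_if(nrow(df) - model_df - 1L <= 0L,
           "model saturates the data (residual df would be %d)",
           nrow(df) - model_df - 1L)
  # aliasing check: the 16-run array spends only 15 df between treatments,
  # so a 9-df interaction is estimable only in a reduced model (its own
  # two mains + the interaction use all 15); with other columns present
  # part of the interaction is aliased and its SS would be misattributed
  form0 <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm_rank <- qr(stats::model.matrix(form0, df))$rank
  for (tm in grep(":", terms, value = TRUE))
    abort_if(mm_rank < model_df + 1L,
             paste("term %s is aliased with the other design columns in",
                   "this 16-run array; request it in a reduced model",
                   "(its two main effects only)"), tm)
  if (split_polynomial)
    for (cl in c("A", "B", "C"))
      if (cl %in% names(df)) stats::contrasts(df[[cl]]) <- stats::contr.poly(4)
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- stats::aov(form, data = df)
  a <- stats::anova(fit)
  out <- data.frame(term = rownames(a), df = a$Df, ss = a$`Sum Sq`,
                    ms = a$`Mean Sq`, f = a$`F value`, p = a$`Pr(>F)`)
  out$term <- sub("Residuals", "residual", out$term)
  if (split_polynomial) {
    splits <- lapply(intersect(c("A", "B", "C"), terms), function(cl)
      stats::setNames(list(list(linear = 1, quadratic = 2, cubic = 3)), cl))
    sm <- summary(fit, split = do.call(c, splits))[[1]]
    comp <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                       ss = sm$`Sum Sq`, ms = sm$`Mean Sq`,
                       f = sm$`F value`, p = sm$`Pr(>F)`)
    comp <- comp[grepl(":", comp$term, fixed = TRUE) &
                   grepl("linear|quadratic|cubic", comp$term), ]
    out <- rbind(out[out$term != "residual", ], comp,
                 out[out$term == "residual", ])
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Student-Newman-Keuls compact letter display
#'
#' Stepwise studentized-range comparison of a set of equally replicated
#' group means against a pooled error mean square. Means are ordered
#' descending; a stretch of `p` adjacent ordered means is declared
#' homogeneous when its extreme difference is below
#' `q(1 - alpha, p, df) * sqrt(ms / n)`, and no subset of a homogeneous
#' stretch is tested further (the classical protection rule). Letters are
#' assigned by the insert-and-absorb display algorithm: groups sharing a
#' letter are not significantly different at `alpha`.
#'
#' @param means named numeric vector of group means.
#' @param ms pooled error mean square.
#' @param df error degrees of freedom.
#' @param n common replication per group (the design is balanced;
#'   unequal `n` is refused).
#' @param alpha significance level, default 0.05.
#' @return A `data.frame` (`group`, `mean`, `letters`) in descending mean
#'   order, with attribute `alpha`.
#' @examples
#' snk_letters(c(a = 10, b = 30, c = 31), ms = 1, df = 12, n = 5)
#' @export
snk_letters <- function(means, ms, df, n, alpha = 0.05) {
  abort_if(df < 1, "error df must be >= 1")
  abort_if(length(n) != 1 || n < 1,
           "n must be a single common group size (balanced design)")
  abort_if(ms < 0, "error mean square must be non-negative")
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se <- sqrt(ms / n)
  # ns[i, j]: means i..j (descending order) form a homogeneous stretch
  ns <- diag(TRUE, k)
  if (k > 1) {
    for (p in k:2) {
      w <- stats::qtukey(1 - alpha, p, df) * se
      for (i in seq_len(k - p + 1)) {
        j <- i + p - 1
        if (ns[i, j]) next                   # inside a homogeneous stretch
        covered <- FALSE                     # protection rule
        if (p < k) {
          for (a in seq_len(i)) for (b in j:k)
            if ((a < i || b > j) && ns[a, b]) covered <- TRUE
        }
        if (covered) { ns[i:j, i:j] <- TRUE; next }
        if (abs(m[i] - m[j]) <= w) ns[i:j, i:j] <- TRUE
      }
    }
  }
  # maximal homogeneous intervals -> letters
  intervals <- list()
  for (i in seq_len(k)) {
    j <- max(which(ns[i, ]))
    intervals[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && keep[i] &&
        intervals[[j]][1] <= intervals[[i]][1] &&
        intervals[[j]][2] >= intervals[[i]][2] &&
        !identical(intervals[[i]], intervals[[j]])) keep[i] <- FALSE
  }
  maximal <- unique(intervals[keep])
  letters_per_group <- vapply(seq_len(k), function(g) {
    lab <- vapply(seq_along(maximal), function(ii) {
      iv <- maximal[[ii]]
      if (g >= iv[1] && g <= iv[2]) letters[ii] else ""
    }, character(1))
    paste(lab[nzchar(lab)], collapse = "")
  }, character(1))
  structure(data.frame(group = names(m), mean = as.numeric(m),
                       letters = letters_per_group),
            alpha = alpha, class = c("snk_letters", "data.frame"))
}

#' MANOVA test statistics from SSCP matrices
#'
#' Computes the four classical multivariate test statistics from a
#' hypothesis SSCP matrix `H` and an error SSCP matrix `E`, via the
#' eigenvalues `lambda` of `H E^{-1}`:
#' Wilks' Lambda `= prod 1/(1+lambda)`, Pillai's trace
#' `= sum lambda/(1+lambda)`, Hotelling-Lawley trace `= sum lambda`, and
#' Roy's greatest root `= max lambda`. F approximations use the standard
#' `s`, `m`, `n` parameterisation (Rao's approximation for Wilks, exact
#' when `min(p, q) <= 2`); the F for Roy's root is an upper bound and is
#' flagged as such.
#'
#' @param H hypothesis SSCP matrix (symmetric, positive semi-definite).
#' @param E error SSCP matrix (symmetric positive definite).
#' @param df_h hypothesis degrees of freedom.
#' @param df_e error degrees of freedom.
#' @return A `manova_result` data.frame with columns `statistic`, `value`,
#'   `f`, `num_df`, `den_df`, `p`, `note`; parameters `s`, `m`, `n` are
#'   attached as attributes.
#' @examples
#' H <- diag(c(4, 1)); E <- diag(2)
#' manova_tests(H, E, df_h = 2, df_e = 10)
#' @export
manova_tests <- function(H, E, df_h, df_e) {
  H <- as.matrix(H); E <- as.matrix(E)
  abort_if(!all(dim(H) == dim(E)), "H and E must be conformable")
  abort_if(max(abs(H - t(H))) > 1e-8 * (1 + max(abs(H))),
           "H must be symmetric")
  ev_E <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  abort_if(min(ev_E) <= 0, "E must be positive definite")
  p <- nrow(H); q <- df_h; v <- df_e
  lambda <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)            # clip eigenvalue noise
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  n <- (v - p - 1) / 2
  wilks <- prod(1 / (1 + lambda))
  pillai <- sum(lambda / (1 + lambda))
  hl <- sum(lambda)
  roy <- max(lambda)
  # Rao's F for Wilks
  t_ <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w_ <- v + q - (p + q + 1) / 2
  df1_w <- p * q
  df2_w <- w_ * t_ - (p * q - 2) / 2
  lam_t <- wilks^(1 / t_)
  f_w <- (1 - lam_t) / lam_t * df2_w / df1_w
  # Pillai
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * n + s + 1)
  f_p <- (2 * n + s + 1) / (2 * m + s + 1) * pillai / (s - pillai)
  # Hotelling-Lawley (classical Pillai-Samson form)
  df1_h <- s * (2 * m + s + 1)
  df2_h <- 2 * (s * n + 1)
  f_h <- df2_h * hl / (s^2 * (2 * m + s + 1))
  # Roy upper bound
  r_ <- max(p, q)
  df1_r <- r_
  df2_r <- v - r_ + q
  f_r <- roy * df2_r / r_
  out <- data.frame(
    statistic = c("Wilks' Lambda", "Pillai's Trace",
                  "Hotelling-Lawley Trace", "Roy's Greatest Root"),
    value = c(wilks, pillai, hl, roy),
    f = c(f_w, f_p, f_h, f_r),
    num_df = c(df1_w, df1_p, df1_h, df1_r),
    den_df = c(df2_w, df2_p, df2_h, df2_r),
    p = c(stats::pf(f_w, df1_w, df2_w, lower.tail = FALSE),
          stats::pf(f_p, df1_p, df2_p, lower.tail = FALSE),
          stats::pf(f_h, df1_h, df2_h, lower.tail = FALSE),
          stats::pf(f_r, df1_r, df2_r, lower.tail = FALSE)),
    note = c(if (s <= 2) "exact" else "Rao approximation", "", "",
             "upper bound"))
  structure(out, s = s, m = m, n = n, eigenvalues = lambda,
            class = c("manova_result", "data.frame"))
}

#' SSCP matrices for a grouping factor
#'
#' Convenience builder of between-group (`H`) and within-group (`E`)
#' sums-of-squares-and-cross-products matrices for a one-way multivariate
#' layout, the inputs to [manova_tests()].
#'
#' @param Y numeric matrix of responses (rows = observations).
#' @param group grouping factor.
#' @return List `H`, `E`, `df_h`, `df_e`.
#' @export
sscp_oneway <- function(Y, group) {
  Y <- as.matrix(Y)
  group <- factor(group)
  abort_if(nrow(Y) != length(group), "Y rows and group length differ")
  gm <- colMeans(Y)
  H <- matrix(0, ncol(Y), ncol(Y))
  E <- matrix(0, ncol(Y), ncol(Y))
  for (g in levels(group)) {
    Yg <- Y[group == g, , drop = FALSE]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - gm)
    Ec <- sweep(Yg, 2, mg)
    E <- E + crossprod(Ec)
  }
  list(H = H, E = E, df_h = nlevels(group) - 1L,
       df_e = nrow(Y) - nlevels(group))
}

#' Export an ANOVA or MANOVA table as CSV
#'
#' @param x an `anova_table` or `manova_result`.
#' @param path file path.
#' @export
write_inference_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
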
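# Synthetic germination / seedling / conductivity data with the study's
# replicate structure, so every analysis stage can run and be validated
# without the (unpublished) raw records.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Replicate layout of the germination experiments
#'
#' Defaults reproduce the study layout: 100 seeds per Petri dish, three
#' experiments with 4 dishes per treatment in the first and 6 in each of
#' the second and third (16 dishes per treatment in all), and 10 germinated
#' seedlings measured per dish (160 per treatment, 2560 in total).
#'
#' @param n_seeds_per_dish seeds sown per dish.
#' @param dishes_per_experiment integer vector, dishes per treatment in
#'   each experiment.
#' @param seedlings_per_dish germinated seedlings measured per dish.
#' @return A `layout_config` list.
#' @export
layout_config <- function(n_seeds_per_dish = 100,
                          dishes_per_experiment = c(4, 6, 6),
                          seedlings_per_dish = 10) {
  abort_if(n_seeds_per_dish < 1, "n_seeds_per_dish must be positive")
  abort_if(length(dishes_per_experiment) < 1 ||
             any(dishes_per_experiment < 1),
           "dishes_per_experiment must be positive counts")
  abort_if(seedlings_per_dish < 1, "seedlings_per_dish must be positive")
  structure(list(n_seeds_per_dish = n_seeds_per_dish,
                 dishes_per_experiment = as.integer(dishes_per_experiment),
                 seedlings_per_dish = seedlings_per_dish),
            class = "layout_config")
}

#' True treatment effects for the generator
#'
#' Per-treatment true means (and dish/seedling-level SDs) for the three
#' responses. Germination overdispersion is parameterised implicitly: the
#' beta-binomial intraclass correlation rho is calibrated per treatment so
#' that the dish-level SD of the germination percentage matches `gp_sd`
#' (printed SDs far exceed the binomial standard error at 100 seeds/dish).
#' Alternatively pass `gp_rho` directly.
#'
#' @param gp_mean,gp_sd germination percentage mean and dish-level SD per
#'   treatment (percent scale, means in (0,100)).
#' @param pl_mean,pl_sd,rl_mean,rl_sd plumule / radicle length moments (mm).
#' @param gp_rho optional explicit beta-binomial intraclass correlation
#'   (overrides calibration from `gp_sd`).
#' @param block_sd SD of the additive experiment (block) effect, in the
#'   units of each response; default 0 (no block differences).
#' @param pl_rl_cor correlation between a seedling's plumule and radicle
#'   length; both lengths respond similarly across treatments, default 0.5.
#' @return An `effect_config` list.
#' @export
effect_config <- function(gp_mean, gp_sd = NULL, pl_mean = NULL,
                          pl_sd = NULL, rl_mean = NULL, rl_sd = NULL,
                          gp_rho = NULL, block_sd = 0, pl_rl_cor = 0.5) {
  abort_if(any(gp_mean < 0 | gp_mean > 100),
           "germination means must lie in [0, 100]")
  abort_if(!is.null(pl_sd) && any(pl_sd <= 0), "pl_sd must be positive")
  abort_if(!is.null(rl_sd) && any(rl_sd <= 0), "rl_sd must be positive")
  abort_if(!is.null(pl_mean) && any(pl_mean <= 0), "pl_mean must be positive")
  abort_if(!is.null(rl_mean) && any(rl_mean <= 0), "rl_mean must be positive")
  abort_if(abs(pl_rl_cor) >= 1, "pl_rl_cor must be in (-1, 1)")
  structure(list(gp_mean = gp_mean, gp_sd = gp_sd, gp_rho = gp_rho,
                 pl_mean = pl_mean, pl_sd = pl_sd,
                 rl_mean = rl_mean, rl_sd = rl_sd,
                 block_sd = block_sd, pl_rl_cor = pl_rl_cor),
            class = "effect_config")
}

# rho calibrated so Var(pct) = 100 p q (1 + (n-1) rho) matches sd^2;
# floor at 0 when the target SD is below the binomial SE.
calibrate_rho <- function(p, sd_pct, n) {
  v_bin <- 100^2 * p * (1 - p) / n   # percentage-scale binomial variance
  rho <- (sd_pct^2 / v_bin - 1) / (n - 1)
  pmin(pmax(rho, 0), 0.999)
}

rbetabinom <- function(k, size, p, rho) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  det <- rho < 1e-12
  pi <- numeric(k)
  pi[det] <- p[det]
  if (any(!det)) {
    a <- p[!det] * (1 - rho[!det]) / rho[!det]
    b <- (1 - p[!det]) * (1 - rho[!det]) / rho[!det]
    pi[!det] <- stats::rbeta(sum(!det), a, b)
  }
  stats::rbinom(k, size, pi)
}

#' Generate dish-level germination counts
#'
#' Draws one beta-binomial germinated-seed count per dish. The per-dish
#' germination probability is beta-distributed around the treatment's true
#' mean (optionally shifted by an experiment block effect), which
#' reproduces the between-dish overdispersion evident in the published
#' SDs. Deterministic for a given `seed`.
#'
#' @param design design table ([build_l16()]).
#' @param layout a [layout_config()].
#' @param effects an [effect_config()] supplying `gp_mean` (and `gp_sd` or
#'   `gp_rho`) per treatment.
#' @param seed integer RNG seed.
#' @return A `data.frame` with one row per dish: `treatment`, `experiment`,
#'   `dish`, `gp_count`, `gp_pct`; attribute `layout` records the layout.
#' @examples
#' d <- gen_germination(build_l16(), layout_config(), fixture_effects(),
#'                      seed = 1)
#' nrow(d)  # 256 dish records
#' @export
gen_germination <- function(design, layout = layout_config(),
                            effects, seed = NULL) {
  abort_if(is.null(effects$gp_mean), "effects must provide gp_mean")
  abort_if(any(effects$gp_mean < 0 | effects$gp_mean > 100),
           "germination means must lie in [0, 100]")
  n_trt <- nrow(design)
  abort_if(length(effects$gp_mean) != n_trt,
           "need one gp_mean per treatment (%d), got %d",
           n_trt, length(effects$gp_mean))
  nd <- layout$dishes_per_experiment
  grid <- expand.grid(dish_in_exp = seq_len(max(nd)),
                      experiment = seq_along(nd),
                      treatment = design$treatment)
  grid <- grid[grid$dish_in_exp <= nd[grid$experiment], ]
  grid <- grid[order(grid$treatment, grid$experiment, grid$dish_in_exp), ]
  n <- layout$n_seeds_per_dish
  p <- effects$gp_mean[match(grid$treatment, design$treatment)] / 100
  rho <- if (!is.null(effects$gp_rho)) {
    rep_len(effects$gp_rho, n_trt)[match(grid$treatment, design$treatment)]
  } else if (!is.null(effects$gp_sd)) {
    calibrate_rho(p, effects$gp_sd[match(grid$treatment, design$treatment)], n)
  } else rep(0, nrow(grid))
  out <- with_seed(seed, {
    if (effects$block_sd > 0) {
      shift <- stats::rnorm(length(nd), 0, effects$block_sd) / 100
      p <- pmin(pmax(p + shift[grid$experiment], 1e-6), 1 - 1e-6)
    }
    cnt <- rbetabinom(nrow(grid), n, p, rho)
    data.frame(treatment = grid$treatment, experiment = grid$experiment,
               dish = stats::ave(grid$treatment, grid$treatment,
                                 FUN = seq_along),
               gp_count = cnt, gp_pct = 100 * cnt / n)
  })
  rownames(out) <- NULL
  attr(out, "layout") <- layout
  attr(out, "seed") <- seed
  out
}

# Bivariate normal (given correlation) truncated to the positive quadrant,
# by rejection; truncation mass is negligible at the study's moments.
rtrunc_binorm <- function(k, mu1, sd1, mu2, sd2, rho) {
  x <- numeric(k); y <- numeric(k)
  todo <- rep(TRUE, k)
  while (any(todo)) {
    m <- sum(todo)
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    xx <- mu1[todo] + sd1[todo] * z1
    yy <- mu2[todo] + sd2[todo] * z2
    ok <- xx >= 0 & yy >= 0
    idx <- which(todo)[ok]
    x[idx] <- xx[ok]; y[idx] <- yy[ok]
    todo[idx] <- FALSE
  }
  cbind(x, y)
}

#' Generate seedling plumule/radicle lengths
#'
#' Expands a dish-level dataset to seedling granularity: for each dish,
#' `seedlings_per_dish` measured seedlings receive correlated plumular and
#' radicular lengths drawn from a bivariate normal truncated at zero.
#'
#' @param dataset dish-level dataset from [gen_germination()].
#' @param effects an [effect_config()] with `pl_mean`, `pl_sd`, `rl_mean`,
#'   `rl_sd` per treatment.
#' @param seed integer RNG seed.
#' @return A seedling-granularity `data.frame`: `treatment`, `experiment`,
#'   `dish`, `seed_index`, `pl_mm`, `rl_mm`.
#' @export
gen_seedling_lengths <- function(dataset, effects, seed = NULL) {
  for (f in c("pl_mean", "pl_sd", "rl_mean", "rl_sd"))
    abort_if(is.null(effects[[f]]), "effects must provide %s", f)
  abort_if(any(effects$pl_sd <= 0) || any(effects$rl_sd <= 0),
           "length SDs must be positive")
  layout <- attr(dataset, "layout")
  m <- if (is.null(layout)) 10 else layout$seedlings_per_dish
  trts <- sort(unique(dataset$treatment))
  idx <- rep(seq_len(nrow(dataset)), each = m)
  ti <- match(dataset$treatment[idx], trts)
  out <- with_seed(seed, {
    block <- if (effects$block_sd > 0)
      stats::rnorm(max(dataset$experiment), 0, effects$block_sd)
    else rep(0, max(dataset$experiment))
    xy <- rtrunc_binorm(length(idx),
                        effects$pl_mean[ti] + block[dataset$experiment[idx]],
                        effects$pl_sd[ti],
                        effects$rl_mean[ti] + block[dataset$experiment[idx]],
                        effects$rl_sd[ti],
                        effects$pl_rl_cor)
    data.frame(treatment = dataset$treatment[idx],
               experiment = dataset$experiment[idx],
               dish = dataset$dish[idx],
               seed_index = rep(seq_len(m), times = nrow(dataset)),
               pl_mm = xy[, 1], rl_mm = xy[, 2])
  })
  attr(out, "layout") <- layout
  attr(out, "seed") <- seed
  out
}

#' Configuration for synthetic conductivity series
#'
#' Leachate conductivity follows the logarithmic leakage model
#' `y = a + b * ln(t)` per group, plus Gaussian reading noise. Default
#' intercepts/slopes are the least-squares fits to the published group
#' means; default noise SD of 0.3 is a realistic bench conductivity-meter
#' repeatability at these magnitudes.
#'
#' @param a,b named numeric vectors of intercepts and slopes per group.
#' @param sd residual (reading) SD.
#' @param times_h soaking times in hours, positive and increasing.
#' @param replicates readings per group x time.
#' @return A `conductivity_config` list.
#' @export
conductivity_config <- function(a = NULL, b = NULL, sd = 0.3,
                                times_h = c(4, 8, 12, 24), replicates = 3) {
  abort_if(any(times_h <= 0) || any(diff(times_h) <= 0),
           "times must be positive and increasing")
  abort_if(replicates < 1, "replicates must be >= 1")
  abort_if(sd < 0, "sd must be non-negative")
  if (is.null(a) || is.null(b)) {
    fits <- lapply(split(conductivity_fixture(), conductivity_fixture()$group),
                   function(g) fit_log_model(g$time_h, g$conductivity))
    if (is.null(a)) a <- vapply(fits, `[[`, numeric(1), "a")
    if (is.null(b)) b <- vapply(fits, `[[`, numeric(1), "b")
  }
  abort_if(is.null(names(a)) || is.null(names(b)) ||
             !identical(sort(names(a)), sort(names(b))),
           "a and b must be named by group, with matching names")
  structure(list(a = a, b = b[names(a)], sd = sd, times_h = times_h,
                 replicates = replicates),
            class = "conductivity_config")
}

#' Generate replicate conductivity readings
#'
#' @param config a [conductivity_config()].
#' @param seed integer RNG seed.
#' @return A `data.frame`: `group`, `time_h`, `replicate`, `conductivity`.
#' @export
gen_conductivity <- function(config = conductivity_config(), seed = NULL) {
  abort_if(any(config$times_h <= 0), "times must be positive")
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      time_h = config$times_h,
                      group = names(config$a))
  mu <- config$a[as.character(grid$group)] +
    config$b[as.character(grid$group)] * log(grid$time_h)
  out <- with_seed(seed, {
    data.frame(group = grid$group, time_h = grid$time_h,
               replicate = grid$replicate,
               conductivity = mu + stats::rnorm(nrow(grid), 0, config$sd))
  })
  attr(out, "seed") <- seed
  out
}

#' Read/write long-format response datasets as CSV
#'
#' @param dataset dish- or seedling-level dataset.
#' @param path file path.
#' @return `read_response_csv` returns the `data.frame`.
#' @export
write_response_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  x <- utils::read.csv(path)
  abort_if(!"treatment" %in% names(x),
           "response CSV must have a 'treatment' column")
  x
}
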
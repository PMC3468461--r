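# Packaged study fixtures: the published per-treatment summary table, the
# leachate conductivity series, and the published response-surface peak
# coordinates. These are the only data printed by the study; raw per-seed
# records were never deposited.

sonopt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "sonopt")
  if (!nzchar(path)) {
    # source-tree fallback (devtools::load_all / tests before install)
    path <- file.path("inst", "extdata", file)
  }
  abort_if(!file.exists(path), "fixture '%s' not found", file)
  path
}

#' Published per-treatment means and standard deviations
#'
#' The 16-treatment summary of the orthogonal germination experiment:
#' germination percentage (GP, %), plumular length (PL, mm) and radicular
#' length (RL, mm), each as mean and SD, together with the level indices of
#' the design columns A-D.
#'
#' @return A `data.frame` with columns `treatment`, `A`, `B`, `C`, `D`,
#'   `gp_mean`, `gp_sd`, `pl_mean`, `pl_sd`, `rl_mean`, `rl_sd`.
#' @examples
#' head(response_means_fixture())
#' @export
response_means_fixture <- function() {
  utils::read.csv(sonopt_extdata("l16_response_means.csv"))
}

#' Published leachate conductivity means
#'
#' Mean electrical conductivity of seed leachates for the three
#' experimental groups (untreated control, water-soaked, ultrasound-treated)
#' after 4, 8, 12 and 24 h of soaking. Values are means of three
#' replicates; the replicate-level readings were not published.
#'
#' @return A `data.frame` with columns `group`, `time_h`, `conductivity`.
#' @export
conductivity_fixture <- function() {
  x <- utils::read.csv(sonopt_extdata("leachate_conductivity.csv"))
  x$group <- factor(x$group, levels = c("control", "water", "ultrasonic"))
  x
}

#' Published response-surface peak coordinates
#'
#' The six per-factor optimum coordinates harvested from the nine pairwise
#' quadratic response surfaces (two factor pairs x three responses per
#' factor), as printed by the study. These feed the grouped-mode
#' aggregation that produces the final recommended conditions.
#'
#' @param factor_id optionally restrict to one factor (`"A"`, `"B"`, `"C"`).
#' @return A `data.frame` with columns `factor`, `response`, `pair`,
#'   `value`; or, when `factor_id` is given, the numeric vector of its six
#'   peak values.
#' @examples
#' reported_peaks_fixture("C")  # six output-power peaks, watts
#' @export
reported_peaks_fixture <- function(factor_id = NULL) {
  x <- utils::read.csv(sonopt_extdata("reported_surface_peaks.csv"))
  if (is.null(factor_id)) return(x)
  abort_if(!factor_id %in% x$factor, "unknown factor '%s'", factor_id)
  x$value[x$factor == factor_id]
}

#' Effect configuration reproducing the published treatment means
#'
#' Wraps the published per-treatment means/SDs into an [effect_config()]
#' whose generator output matches the printed first and second moments:
#' germination counts are beta-binomial with per-treatment overdispersion
#' calibrated so the dish-level SD of the percentage equals the printed SD,
#' and seedling lengths are truncated normal at the printed mean/SD.
#'
#' @return An `effect_config` object (see [effect_config()]).
#' @export
fixture_effects <- function() {
  tab <- response_means_fixture()
  effect_config(
    gp_mean = tab$gp_mean, gp_sd = tab$gp_sd,
    pl_mean = tab$pl_mean, pl_sd = tab$pl_sd,
    rl_mean = tab$rl_mean, rl_sd = tab$rl_sd
  )
}
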
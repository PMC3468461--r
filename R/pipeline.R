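# End-to-end orchestration: simulate -> summarize -> infer -> surface ->
# optimize -> conductivity, with write-once run directories and recorded
# provenance (config + seed) so every report can be regenerated.

#' Assemble a run configuration
#'
#' Exactly one data source must be chosen per run: the packaged
#' per-treatment fixture (`source = "fixture"`), a user CSV in the
#' long/record layout (`source = "csv"`, `input` required), or the
#' synthetic generator (`source = "synthetic"`). Validation happens here,
#' before any computation.
#'
#' @param source `"fixture"`, `"csv"` or `"synthetic"`.
#' @param input path to a response CSV when `source = "csv"`.
#' @param responses responses to analyse.
#' @param terms ANOVA model terms (raw-data sources only).
#' @param binning named list of [binning_config()] per factor.
#' @param alpha significance level.
#' @param seed RNG seed; recorded in every output.
#' @param out_dir output directory (`NULL` = return results only).
#' @return A `run_config` list.
#' @export
run_config <- function(source = c("fixture", "csv", "synthetic"),
                       input = NULL, responses = c("GP", "PL", "RL"),
                       terms = c("A", "B", "C", "D"),
                       binning = default_binning(), alpha = 0.05,
                       seed = 1L, out_dir = NULL) {
  source <- match.arg(source)
  if (source == "csv") {
    abort_if(is.null(input), "source 'csv' requires an input path")
    abort_if(!file.exists(input), "input file '%s' does not exist", input)
  } else {
    abort_if(!is.null(input), "input path only applies to source 'csv'")
  }
  abort_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  structure(list(source = source, input = input, responses = responses,
                 terms = terms, binning = binning, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_run_data <- function(config, design) {
  switch(config$source,
    fixture = response_means_fixture(),
    csv = read_response_csv(config$input),
    synthetic = {
      dishes <- gen_germination(design, layout_config(), fixture_effects(),
                                seed = config$seed)
      seedlings <- gen_seedling_lengths(dishes, fixture_effects(),
                                        seed = config$seed + 1L)
      merge(dishes, stats::aggregate(
        seedlings[c("pl_mm", "rl_mm")],
        by = seedlings[c("treatment", "experiment", "dish")], FUN = mean),
        by = c("treatment", "experiment", "dish"))
    })
}

provenance <- function(config) {
  list(package = "sonopt",
       version = as.character(utils::packageVersion("sonopt")),
       source = config$source, seed = config$seed, alpha = config$alpha,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Generate the synthetic datasets of one run
#'
#' Delegates to the synthetic-data module with the study layout and the
#' published treatment means as true effects; optionally writes the
#' dish-level, seedling-level and conductivity CSVs.
#'
#' @param config a [run_config()] (its `seed` drives all draws).
#' @return List of `dishes`, `seedlings`, `conductivity` data.frames.
#' @export
run_simulate <- function(config = run_config(source = "synthetic")) {
  design <- build_l16()
  dishes <- gen_germination(design, layout_config(), fixture_effects(),
                            seed = config$seed)
  seedlings <- gen_seedling_lengths(dishes, fixture_effects(),
                                    seed = config$seed + 1L)
  cond <- gen_conductivity(conductivity_config(), seed = config$seed + 2L)
  out <- list(dishes = dishes, seedlings = seedlings, conductivity = cond,
              provenance = provenance(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_response_csv(dishes, file.path(config$out_dir, "dishes.csv"))
    write_response_csv(seedlings, file.path(config$out_dir, "seedlings.csv"))
    utils::write.csv(cond, file.path(config$out_dir, "conductivity.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the full optimization chain
#'
#' Range analysis per response, per-treatment summaries, the nine pairwise
#' quadratic surface fits with stationary points, peak harvesting, and the
#' grouped-mode final conditions. With raw-data sources an ANOVA per
#' response is included. All stage outputs are returned in one report
#' bundle (and written as CSVs when `out_dir` is set); the bundle embeds
#' the config and seed needed to regenerate it.
#'
#' @param config a [run_config()].
#' @return A `run_report` list: `range_reports`, `summaries`, `fits`,
#'   `peaks`, `final`, optionally `anova`, plus `provenance`.
#' @examples
#' rep <- run_optimize(run_config(source = "fixture"))
#' rep$final$modes
#' @export
run_optimize <- function(config = run_config()) {
  design <- build_l16()
  data <- load_run_data(config, design)
  is_raw <- config$source != "fixture"
  range_reports <- lapply(stats::setNames(nm = config$responses), function(r)
    range_analysis(level_means(data, design, r)))
  summaries <- lapply(stats::setNames(nm = config$responses), function(r)
    treatment_summary(data, r))
  anova_tabs <- if (is_raw)
    lapply(stats::setNames(nm = config$responses), function(r)
      factorial_anova(data, design, r, terms = config$terms))
  fits <- fit_all_pairs(data, design, config$responses)
  peaks <- collect_peaks(fits)
  final <- final_conditions(peaks, binning = config$binning,
                            on_tie = "widen")
  report <- structure(list(range_reports = range_reports,
                           summaries = summaries, anova = anova_tabs,
                           fits = fits, peaks = peaks, final = final,
                           provenance = provenance(config),
                           config = config),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

write_run_report <- function(report, out_dir) {
  abort_if(dir.exists(out_dir) &&
             length(list.files(out_dir, pattern = "\\.csv$")) > 0,
           "output directory '%s' already holds a report (write-once runs)",
           out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in names(report$range_reports))
    write_range_report(report$range_reports[[r]],
                       file.path(out_dir, sprintf("range_%s.csv", r)))
  for (r in names(report$summaries))
    utils::write.csv(report$summaries[[r]]$table,
                     file.path(out_dir, sprintf("treatments_%s.csv", r)),
                     row.names = FALSE)
  if (!is.null(report$anova))
    for (r in names(report$anova))
      write_inference_csv(report$anova[[r]],
                          file.path(out_dir, sprintf("anova_%s.csv", r)))
  fit_tab <- do.call(rbind, lapply(names(report$fits), function(nm) {
    f <- report$fits[[nm]]
    data.frame(fit = nm, response = f$response,
               pair = paste(f$pair, collapse = ""),
               t(f$coef), r2 = f$r2, n = f$n, basis = f$basis)
  }))
  utils::write.csv(fit_tab, file.path(out_dir, "surface_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(report$peaks$provenance,
                   file.path(out_dir, "peaks.csv"), row.names = FALSE)
  write_final_conditions(report$final,
                         file.path(out_dir, "final_conditions.csv"))
  prov <- report$provenance
  writeLines(format_provenance(prov), file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("sonopt run report (", format_provenance(x$provenance), ")\n\n",
      sep = "")
  for (r in names(x$range_reports)) {
    print(x$range_reports[[r]])
    cat("\n")
  }
  print(x$final)
  invisible(x)
}

#' Conductivity stage: fits plus per-time group comparison
#'
#' @param records replicate-level conductivity records; defaults to the
#'   published group means (fit only, no comparison possible there).
#' @param alpha significance level for the letter display.
#' @return List of `fits` (per group) and, when replicates are available,
#'   `letters` per time point.
#' @export
run_conductivity <- function(records = conductivity_fixture(),
                             alpha = 0.05) {
  fits <- fit_log_models(records)
  letters <- NULL
  if ("replicate" %in% names(records) &&
      any(duplicated(records[c("group", "time_h")])))
    letters <- compare_groups(records, alpha = alpha)
  list(fits = fits, letters = letters)
}
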
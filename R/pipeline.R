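# End-to-end pipeline driver: simulate -> prevalence -> relative risks ->
# PAFs -> attributable burden -> Monte Carlo uncertainty, with stages
# skippable when precomputed tables are supplied.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for the synthetic-data stages (ignored for the
#'   stages replaced by supplied tables).
#' @param seed Integer master seed; stage seeds are derived from it and
#'   recorded in the manifest.
#' @param coding Exposure coding mode (`"count"` or `"patterns"`).
#' @param adjustment RR adjustment set (`"simply"`, `"fully"`, `"none"`).
#' @param prevalence_csv,rr_csv,burden_csv Optional paths to precomputed
#'   tables; supplying prevalence + RR tables skips the microdata stages
#'   entirely (the "spreadsheet-equivalent" mode: externally supplied tables
#'   in, PAFs and attributable burden out).
#' @param ptsd_share PTSD share of the anxiety burden.
#' @param iterations Monte Carlo iterations (0 skips the uncertainty stage).
#' @param out_dir Output directory (created if needed); `NULL` returns results
#'   without writing files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L,
                            coding = c("count", "patterns"),
                            adjustment = c("simply", "fully", "none"),
                            prevalence_csv = NULL, rr_csv = NULL,
                            burden_csv = NULL, ptsd_share = 0.25,
                            iterations = 2000, out_dir = NULL) {
  coding <- match.arg(coding)
  adjustment <- match.arg(adjustment)
  for (p in c(prevalence_csv, rr_csv, burden_csv)) {
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(sim = sim, seed = as.integer(seed), coding = coding,
                 adjustment = adjustment, prevalence_csv = prevalence_csv,
                 rr_csv = rr_csv, burden_csv = burden_csv,
                 ptsd_share = ptsd_share, iterations = as.integer(iterations),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full attribution pipeline
#'
#' Executes, in order: microdata simulation, smoothed prevalence estimation,
#' relative-risk estimation, PAF computation, burden attribution and Monte
#' Carlo uncertainty. Stages are skipped when the corresponding table is
#' supplied in the config (e.g. prevalence + RR CSVs yield PAFs without any
#' microdata). When `out_dir` is set, every output table is written as CSV
#' together with a `manifest.json` recording the seed, stage seeds, a config
#' hash and the package version, so a run can be reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `microdata`,
#'   `prevalence` (fit or supplied table), `rr`, `paf`, `attributable`,
#'   `summary`, `uncertainty` (any of which may be `NULL` for skipped
#'   stages) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(exposures = config$seed, outcomes = config$seed + 1L,
                burden = config$seed + 2L, mc = config$seed + 3L)
  coding <- exposure_coding(config$coding)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  microdata <- NULL
  if (is.null(config$prevalence_csv) || is.null(config$rr_csv)) {
    microdata <- stage("simulate",
      simulate_outcomes(simulate_exposures(config$sim, seeds$exposures),
                        config$sim, seeds$outcomes))
  }

  if (!is.null(config$prevalence_csv)) {
    prev_tab <- read_prevalence_csv(config$prevalence_csv)
    if (!"effective_n" %in% names(prev_tab)) {
      prev_tab$effective_n <- config$sim$n_respondents / 28
    }
    prevalence <- NULL
  } else {
    prevalence <- stage("prevalence", fit_joint_prevalence(microdata))
    prev_tab <- prevalence$table
  }

  if (!is.null(config$rr_csv)) {
    rr_tab <- read_rr_csv(config$rr_csv)
    rr_fit_obj <- NULL
  } else {
    rr_fit_obj <- stage("rr", fit_rr(microdata, coding = config$coding,
                                     adjustment = config$adjustment))
    rr_tab <- rr_fit_obj$estimates
  }

  paf <- stage("paf", paf_table(prev_tab, rr_tab, coding))

  burden <- if (!is.null(config$burden_csv)) {
    read_burden_csv(config$burden_csv)
  } else {
    simulate_burden_table(config$sim, seeds$burden)
  }

  attributable <- stage("burden", list(
    mdd = attribute_cause(paf, burden, "mdd"),
    anxiety = attribute_anxiety(paf, dplyr::filter(burden, .data$cause == "anxiety"),
                                config$ptsd_share),
    self_harm = attribute_self_harm(paf, dplyr::filter(burden, .data$cause == "self_harm")),
    aud = attribute_cause(paf, burden, "aud"),
    smoking = attribute_smoking(paf, dplyr::filter(burden, .data$cause == "smoking"))
  ))
  summary <- stage("burden", summarise_attribution(attributable, burden))

  uncertainty <- NULL
  if (config$iterations > 0) {
    uncertainty <- stage("uncertainty",
      run_monte_carlo(prev_tab, rr_fit_obj %||% rr_tab, burden,
                      ptsd_share = config$ptsd_share, coding = coding,
                      spec = uncertainty_spec(config$iterations, seeds$mc)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cmburden")),
    seed = config$seed, stage_seeds = seeds,
    coding = config$coding, adjustment = config$adjustment,
    iterations = config$iterations,
    supplied = list(prevalence = !is.null(config$prevalence_csv),
                    rr = !is.null(config$rr_csv),
                    burden = !is.null(config$burden_csv)),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )

  result <- structure(list(microdata = microdata, prevalence = prevalence,
                           prevalence_table = prev_tab, rr = rr_fit_obj,
                           rr_table = rr_tab, paf = paf,
                           attributable = attributable, summary = summary,
                           uncertainty = uncertainty, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)
  write_table_csv(result$prevalence_table, out("prevalence.csv"))
  write_table_csv(result$rr_table, out("relative_risks.csv"))
  write_table_csv(result$paf, out("paf.csv"))
  write_table_csv(dplyr::bind_rows(result$attributable), out("attributable_burden.csv"))
  write_table_csv(result$summary$by_cause, out("summary_by_cause.csv"))
  write_table_csv(result$summary$total, out("summary_total.csv"))
  if (!is.null(result$uncertainty)) {
    write_table_csv(result$uncertainty$paf, out("paf_uncertainty.csv"))
    write_table_csv(result$uncertainty$total, out("total_uncertainty.csv"))
  }
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("cmburden pipeline result (seed ", x$manifest$seed, ", coding ",
      x$manifest$coding, ", ", x$manifest$adjustment, " adjusted)\n", sep = "")
  cat("\nAttributable share of all DALYs (%):\n")
  print(x$summary$total)
  invisible(x)
}
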
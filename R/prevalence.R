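# Weighted prevalence of the 32 maltreatment patterns by gender x age group.
#
# Direct cell proportions are unstable at this disaggregation (32 cells x 28
# strata from a survey of a few thousand), so the primary estimator is a
# log-linear (Poisson) model of weighted cell counts: per-type main effects,
# all ten two-way type interactions, and smooth age trends per type via a
# second-order fractional polynomial (default powers (0, 2): log age and age
# squared), with gender-specific terms.

#' Direct weighted pattern prevalence
#'
#' Raw weighted proportions of the 32 patterns per gender x age group, with
#' the Kish effective sample size of each stratum. Zero cells are allowed;
#' empty strata are flagged with `NA` proportions.
#'
#' @param data Microdata with `gender`, `age_years`, `survey_weight` and the
#'   five exposure columns (or `pattern`).
#' @return Tibble `gender, age_group, pattern, proportion, weighted_count,
#'   effective_n, n` with 32 rows per observed stratum; proportions sum to 1
#'   within each non-empty stratum.
#' @export
direct_prevalence <- function(data) {
  if (!"pattern" %in% names(data)) data$pattern <- pattern_code(data)
  if (any(data$survey_weight <= 0)) stop("survey weights must be positive")
  data$gender <- validate_gender(data$gender)
  data$age_group <- assign_age_group(data$age_years)

  strata <- data |>
    dplyr::group_by(.data$gender, .data$age_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      total_w = sum(.data$survey_weight),
      effective_n = sum(.data$survey_weight)^2 / sum(.data$survey_weight^2),
      .groups = "drop"
    )
  cells <- data |>
    dplyr::count(.data$gender, .data$age_group, .data$pattern,
                 wt = .data$survey_weight, name = "weighted_count")

  # full grid over both genders and all 14 age bands: strata with no
  # respondents are kept with NA proportions (flagged missing)
  tidyr::expand_grid(
    gender = factor(GENDER_LEVELS, levels = GENDER_LEVELS),
    age_group = factor(age_group_levels(), levels = age_group_levels()),
    pattern = enumerate_patterns()$pattern
  ) |>
    dplyr::left_join(strata, by = c("gender", "age_group")) |>
    dplyr::left_join(cells, by = c("gender", "age_group", "pattern")) |>
    dplyr::mutate(
      weighted_count = dplyr::if_else(is.na(.data$total_w), NA_real_,
                                      dplyr::coalesce(.data$weighted_count, 0)),
      proportion = .data$weighted_count / .data$total_w
    ) |>
    dplyr::select("gender", "age_group", "pattern", "proportion",
                  "weighted_count", "effective_n", "n") |>
    dplyr::arrange(.data$gender, .data$age_group, .data$pattern)
}

#' Smoothed joint prevalence via a log-linear model
#'
#' Fits a Poisson log-linear regression to the weighted 32-cell counts of each
#' gender x age-group stratum. The linear predictor contains stratum
#' intercepts (so fitted stratum totals match the observed totals), per-type
#' main effects interacted with gender and with the standardised fractional-
#' polynomial age basis (gender-specific age curves per type), and all ten
#' two-way type interactions (plus their gender interactions). Weights are
#' rescaled within stratum to sum to the observed stratum size, so the weight
#' scale cannot distort the counts.
#'
#' @param data Microdata (see [direct_prevalence()]).
#' @param fp_powers Length-2 fractional-polynomial powers from
#'   `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` (0 = log). Default `c(0, 2)`.
#' @param select_fp If `TRUE`, search all 36 FP2 power pairs and keep the
#'   deviance-minimising pair instead of `fp_powers`.
#' @param model `"smoothed"` (the log-linear model above) or `"saturated"`
#'   (all interactions up to fifth order; on a single stratum this reproduces
#'   the direct estimates exactly).
#' @return Object of class `prevalence_fit`: list with `table` (tibble
#'   `gender, age_group, pattern, proportion, modelled_count, effective_n`),
#'   `fit` (the `glm`), `fp_powers`, and `model`.
#' @export
fit_joint_prevalence <- function(data, fp_powers = c(0, 2), select_fp = FALSE,
                                 model = c("smoothed", "saturated")) {
  model <- match.arg(model)
  direct <- dplyr::filter(direct_prevalence(data), !is.na(.data$proportion))
  if (model == "smoothed" &&
      dplyr::n_distinct(direct$age_group) < 2) {
    stop("smoothed model needs at least 2 age groups per gender; use model = \"saturated\"")
  }
  if (!all(fp_powers %in% FP_POWER_SET)) {
    stop("fp_powers must come from {", paste(FP_POWER_SET, collapse = ", "), "}")
  }

  cells <- build_cell_frame(direct)
  if (select_fp && model == "smoothed") {
    pairs <- t(utils::combn(length(FP_POWER_SET), 2))
    cand <- rbind(matrix(FP_POWER_SET[pairs], ncol = 2),
                  cbind(FP_POWER_SET, FP_POWER_SET))
    dev <- apply(cand, 1, function(pw) fit_cell_glm(cells, pw, model)$deviance)
    fp_powers <- cand[which.min(dev), ]
  }
  fit <- fit_cell_glm(cells, fp_powers, model)
  if (!fit$converged) {
    stop("log-linear prevalence model did not converge (model = ", model,
         ", fp powers ", paste(fp_powers, collapse = ","),
         "); consider pruning interactions or pooling strata")
  }

  fitted_counts <- stats::fitted(fit)
  tab <- cells |>
    dplyr::mutate(modelled_count = fitted_counts) |>
    dplyr::group_by(.data$gender, .data$age_group) |>
    dplyr::mutate(proportion = .data$modelled_count / sum(.data$modelled_count)) |>
    dplyr::ungroup() |>
    dplyr::select("gender", "age_group", "pattern", "proportion",
                  "modelled_count", "effective_n")
  structure(list(table = tab, fit = fit, fp_powers = fp_powers, model = model),
            class = "prevalence_fit")
}

# One row per stratum x pattern with scaled counts and design columns.
build_cell_frame <- function(direct) {
  pats <- enumerate_patterns()
  direct |>
    dplyr::group_by(.data$gender, .data$age_group) |>
    # scale weighted counts to sum to the stratum n (effective-size preserving)
    dplyr::mutate(count = .data$proportion * .data$n) |>
    dplyr::ungroup() |>
    dplyr::left_join(pats, by = "pattern") |>
    dplyr::mutate(
      stratum = interaction(.data$gender, .data$age_group, drop = TRUE),
      midage = age_group_midpoint(.data$age_group)
    )
}

fit_cell_glm <- function(cells, fp_powers, model) {
  types <- names(MALTREATMENT_TYPES)
  if (model == "saturated") {
    fml <- stats::as.formula(paste(
      "count ~",
      if (nlevels(cells$stratum) > 1) "stratum +" else "",
      paste(types, collapse = " * ")
    ))
    return(suppressWarnings(stats::glm(fml, family = stats::quasipoisson(), data = cells)))
  }
  fp <- fp_basis(cells$midage, fp_powers)
  cells$fp1 <- fp[, 1]
  cells$fp2 <- fp[, 2]
  pair_terms <- utils::combn(types, 2, FUN = paste, collapse = ":")
  multi_gender <- dplyr::n_distinct(cells$gender) > 1
  type_terms <- unlist(lapply(types, function(t) {
    c(t,
      paste0(t, ":fp1"), paste0(t, ":fp2"),
      if (multi_gender) c(paste0(t, ":gender"),
                          paste0(t, ":gender:fp1"), paste0(t, ":gender:fp2")))
  }))
  terms <- c("stratum", type_terms, pair_terms,
             if (multi_gender) paste0(pair_terms, ":gender"))
  fml <- stats::as.formula(paste("count ~", paste(terms, collapse = " + ")))
  suppressWarnings(stats::glm(fml, family = stats::quasipoisson(), data = cells))
}

#' Summaries of a pattern-prevalence table
#'
#' Derived proportions per stratum: any maltreatment (1 minus the unexposed
#' cell), multi-type (total mass on patterns with two or more types), or the
#' five per-type margins.
#'
#' @param table Tibble `gender, age_group, pattern, proportion` (e.g. from
#'   [direct_prevalence()] or a `prevalence_fit$table`).
#' @param by One of `"any"`, `"multi"`, `"per_type"`.
#' @return Tibble per stratum (`gender, age_group`) with `proportion` (and
#'   `type` for `"per_type"`).
#' @export
aggregate_prevalence <- function(table, by = c("any", "multi", "per_type")) {
  by <- match.arg(by)
  pats <- enumerate_patterns()
  tab <- dplyr::left_join(table, pats, by = "pattern")
  grp <- dplyr::group_by(tab, .data$gender, .data$age_group)
  switch(by,
    any = dplyr::summarise(grp, proportion = 1 - sum(.data$proportion[.data$n_types == 0]),
                           .groups = "drop"),
    multi = dplyr::summarise(grp, proportion = sum(.data$proportion[.data$n_types >= 2]),
                             .groups = "drop"),
    per_type = {
      long <- tidyr::pivot_longer(tab, dplyr::all_of(names(MALTREATMENT_TYPES)),
                                  names_to = "type", values_to = "flag")
      long |>
        dplyr::group_by(.data$gender, .data$age_group, .data$type) |>
        dplyr::summarise(proportion = sum(.data$proportion * .data$flag), .groups = "drop")
    }
  )
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat("Smoothed 32-pattern prevalence (", x$model, " log-linear model)\n", sep = "")
  cat("  FP age powers:", paste(x$fp_powers, collapse = ", "),
      " strata:", dplyr::n_distinct(paste(x$table$gender, x$table$age_group)), "\n")
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prevalence fit
#'
#' @param x A `prevalence_fit`.
#' @param ... Unused.
#' @return The fitted prevalence table (one row per stratum x pattern).
#' @export
#' @exportS3Method generics::tidy
tidy.prevalence_fit <- function(x, ...) x$table

#' Glance at a prevalence fit
#'
#' @param x A `prevalence_fit`.
#' @param ... Unused.
#' @return One-row tibble with deviance, residual df, and FP powers.
#' @export
#' @exportS3Method generics::glance
glance.prevalence_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    deviance = x$fit$deviance,
    df_residual = x$fit$df.residual,
    fp1 = x$fp_powers[1], fp2 = x$fp_powers[2],
    n_strata = dplyr::n_distinct(paste(x$table$gender, x$table$age_group))
  )
}
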
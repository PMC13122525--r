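# Adjusted relative risks by exposure level, via log-binomial regression.
#
# One model per outcome x gender (all ages combined). The exposure enters as a
# factor over the coding's levels with "no maltreatment" as the reference
# (RR = 1 by construction). If the log-link binomial GLM fails to converge,
# the model is refit as a Poisson regression with robust (sandwich) standard
# errors -- the standard log-binomial rescue, which preserves the RR
# interpretation -- and flagged in the output.

RR_OUTCOMES <- c("mdd", "gad", "ptsd", "aud", "smoking", "suicide_attempt")

ADJUSTMENT_SETS <- list(
  none = character(),
  simply = c("financial_stress", "remoteness"),
  fully = c("financial_stress", "remoteness", "other_aces", "bullying")
)

#' Fit relative risks of an outcome by exposure level
#'
#' Estimates relative risks per exposure level, separately by gender, with
#' Wald 95% confidence intervals on the log scale. Age is always adjusted for
#' (standardised log-age and age-squared terms); `"simply"` additionally
#' adjusts for childhood financial stress and geographical remoteness,
#' `"fully"` also for other adverse childhood experiences and bullying
#' victimisation; `"none"` adjusts for nothing (not even age).
#'
#' @param data Microdata with the outcome column, exposure columns (or
#'   `pattern`), `gender`, `age_years` and the adjustment covariates.
#' @param outcome Name(s) of binary outcome column(s); default all six.
#' @param coding `"count"` (number of types 0-5) or `"patterns"` (six common
#'   patterns, count fallback); see [exposure_coding()].
#' @param adjustment `"simply"`, `"fully"` or `"none"`.
#' @param gender `"both"`, `"women"` or `"men"`.
#' @return Object of class `rr_fit`; `tidy()` returns the estimates tibble
#'   (`outcome, gender, coding, adjustment, level, rr, lcl, ucl, fallback`).
#' @export
fit_rr <- function(data, outcome = RR_OUTCOMES, coding = c("count", "patterns"),
                   adjustment = c("simply", "fully", "none"), gender = "both") {
  coding <- match.arg(coding)
  adjustment <- match.arg(adjustment)
  genders <- if (identical(gender, "both")) GENDER_LEVELS else match.arg(gender, GENDER_LEVELS)
  if (!"pattern" %in% names(data)) data$pattern <- pattern_code(data)
  missing_out <- setdiff(outcome, names(data))
  if (length(missing_out) > 0) stop("outcome column(s) not in data: ",
                                    paste(missing_out, collapse = ", "))
  covars <- ADJUSTMENT_SETS[[adjustment]]
  missing_cov <- setdiff(covars, names(data))
  if (length(missing_cov) > 0) stop("adjustment covariate(s) not in data: ",
                                    paste(missing_cov, collapse = ", "))

  ctab <- exposure_coding(coding)
  levs <- coding_levels(ctab)
  data$level <- factor(map_to_level(data$pattern, ctab), levels = levs)
  data$gender <- validate_gender(data$gender)

  models <- list()
  vcovs <- list()
  est <- purrr::map_dfr(outcome, function(out) {
    purrr::map_dfr(genders, function(g) {
      d <- data[data$gender == g, , drop = FALSE]
      d$level <- droplevels(d$level)
      check_level_support(d, out)
      d$ln_age_std <- standardise(log(d$age_years))
      d$age2_std <- standardise(d$age_years^2)
      age_terms <- if (adjustment == "none") character() else c("ln_age_std", "age2_std")
      fml <- stats::as.formula(paste(
        out, "~ level",
        if (length(c(age_terms, covars)) > 0)
          paste("+", paste(c(age_terms, covars), collapse = " + ")) else ""
      ))
      fit <- fit_log_binomial_one(fml, d)
      models[[paste(out, g, sep = ".")]] <<- fit$model
      coefs <- fit$coef
      ses <- fit$se
      lev_idx <- grep("^level", names(coefs))
      lev_names <- sub("^level", "", names(coefs)[lev_idx])
      # full covariance of the level log-RRs (they share the reference group,
      # so they are strongly positively correlated); used by the Monte Carlo
      vc <- fit$vcov[lev_idx, lev_idx, drop = FALSE]
      dimnames(vc) <- list(lev_names, lev_names)
      vcovs[[paste(out, g, sep = ".")]] <<- vc
      z <- stats::qnorm(0.975)
      tibble::tibble(
        outcome = out, gender = g, coding = coding, adjustment = adjustment,
        level = c(levs[1], lev_names),
        rr = c(1, exp(coefs[lev_idx])),
        lcl = c(1, exp(coefs[lev_idx] - z * ses[lev_idx])),
        ucl = c(1, exp(coefs[lev_idx] + z * ses[lev_idx])),
        fallback = fit$fallback
      )
    })
  })
  est$level <- factor(est$level, levels = levs)
  structure(list(estimates = est, models = models, vcov = vcovs,
                 coding = coding, adjustment = adjustment), class = "rr_fit")
}

check_level_support <- function(d, out) {
  supp <- table(d$level, factor(d[[out]], levels = c(0, 1)))
  bad <- rownames(supp)[supp[, "1"] == 0 | supp[, "0"] == 0]
  if (length(bad) > 0) {
    stop("outcome ", out, ": level(s) without both cases and non-cases ",
         "(quasi-separation): ", paste(bad, collapse = ", "))
  }
}

# Log-binomial GLM with Poisson + sandwich-variance fallback.
fit_log_binomial_one <- function(fml, d) {
  y <- stats::model.response(stats::model.frame(fml, d))
  start <- c(log(max(mean(y), 1e-6)),
             rep(0, ncol(stats::model.matrix(fml, d)) - 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm(fml, family = stats::binomial(link = "log"),
                                data = d, start = start)),
    error = function(e) NULL
  )
  if (!is.null(fit) && fit$converged && all(is.finite(stats::coef(fit)))) {
    vc <- stats::vcov(fit)
    return(list(model = fit, coef = stats::coef(fit), vcov = vc,
                se = sqrt(diag(vc)), fallback = FALSE))
  }
  pfit <- suppressWarnings(stats::glm(fml, family = stats::poisson(), data = d))
  if (!pfit$converged) {
    stop("log-binomial and Poisson fallback both failed to converge for ",
         deparse(fml[[2]]))
  }
  vc <- sandwich::vcovHC(pfit, type = "HC0")
  list(model = pfit, coef = stats::coef(pfit), vcov = vc,
       se = sqrt(diag(vc)), fallback = TRUE)
}

#' Dose-response monotonicity report
#'
#' Checks, for count-coded estimates, whether the relative risk is
#' non-decreasing in the number of maltreatment types. Non-monotone sequences
#' are flagged (with the offending levels), not rejected.
#'
#' @param rrset An `rr_fit` or its estimates tibble.
#' @return Tibble `outcome, gender, monotone, flagged_levels`.
#' @export
rr_trend_check <- function(rrset) {
  est <- if (inherits(rrset, "rr_fit")) rrset$estimates else rrset
  if (!all(as.character(est$level) %in% as.character(0:5))) {
    stop("trend check requires count coding (levels 0-5)")
  }
  est |>
    dplyr::group_by(.data$outcome, .data$gender) |>
    dplyr::arrange(as.integer(as.character(.data$level)), .by_group = TRUE) |>
    dplyr::summarise(
      monotone = all(diff(.data$rr) >= 0),
      flagged_levels = paste(as.character(.data$level)[-1][diff(.data$rr) < 0],
                             collapse = ","),
      .groups = "drop"
    )
}

#' Load and validate a relative-risk table
#'
#' Reads externally supplied relative risks (e.g. published estimates) with
#' schema `outcome, gender, coding, level, rr, lcl, ucl` (an `adjustment`
#' column is optional). The unexposed reference level is auto-inserted with
#' RR = 1 when absent. Confidence limits must bracket the point estimate and
#' outcome labels must be among the supported outcomes.
#'
#' @param x Path to a CSV file, or a data frame.
#' @return Validated tibble `outcome, gender, coding, level, rr, lcl, ucl`
#'   (plus `adjustment` if supplied).
#' @export
load_rr_table <- function(x) {
  tab <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE)
  } else tibble::as_tibble(x)
  required <- c("outcome", "gender", "coding", "level", "rr", "lcl", "ucl")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) stop("RR table missing column(s): ",
                                paste(missing, collapse = ", "))
  bad_out <- setdiff(unique(tab$outcome), RR_OUTCOMES)
  if (length(bad_out) > 0) {
    stop("unknown outcome label(s): ", paste(bad_out, collapse = ", "),
         "; allowed: ", paste(RR_OUTCOMES, collapse = ", "))
  }
  tab$gender <- validate_gender(tab$gender)
  tab$level <- as.character(tab$level)
  for (col in c("rr", "lcl", "ucl")) {
    if (!is.numeric(tab[[col]])) stop("column ", col, " must be numeric")
  }
  ref <- tab$lcl == tab$rr & tab$ucl == tab$rr
  bad_ci <- which(!ref & !(tab$lcl > 0 & tab$lcl <= tab$rr & tab$rr <= tab$ucl))
  if (length(bad_ci) > 0) {
    stop("confidence interval does not bracket the point estimate (0 < lcl <= rr <= ucl) in row(s): ",
         paste(bad_ci, collapse = ", "))
  }
  # auto-insert the unexposed reference per outcome x gender x coding
  keys <- dplyr::distinct(tab, .data$outcome, .data$gender, .data$coding)
  have_ref <- dplyr::filter(tab, .data$level == "0")
  need <- dplyr::anti_join(keys, have_ref, by = c("outcome", "gender", "coding"))
  if (nrow(need) > 0) {
    tab <- dplyr::bind_rows(tab, dplyr::mutate(need, level = "0", rr = 1, lcl = 1, ucl = 1))
  }
  dplyr::arrange(tab, .data$outcome, .data$gender, .data$level)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("Relative risks (", x$coding, " coding, ", x$adjustment, " adjusted)\n", sep = "")
  print(x$estimates, n = 14)
  invisible(x)
}

#' Tidy relative-risk estimates
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return Estimates tibble (one row per outcome x gender x level).
#' @export
#' @exportS3Method generics::tidy
tidy.rr_fit <- function(x, ...) x$estimates

#' Glance at a relative-risk fit
#'
#' @param x An `rr_fit`.
#' @param ... Unused.
#' @return One row per fitted model with convergence/fallback status.
#' @export
#' @exportS3Method generics::glance
glance.rr_fit <- function(x, ...) {
  x$estimates |>
    dplyr::group_by(.data$outcome, .data$gender) |>
    dplyr::summarise(coding = .data$coding[1], adjustment = .data$adjustment[1],
                     n_levels = dplyr::n(), fallback = any(.data$fallback),
                     .groups = "drop")
}
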
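# Population attributable fractions for the polytomous maltreatment exposure.
#
# The counterfactual (theoretical minimum risk exposure level, TMREL) puts all
# exposure mass on the unexposed pattern. For exposure-category proportions
# p_i and relative risks RR_i (RR = 1 for the unexposed category),
#
#   PAF = sum_i p_i (RR_i - 1) / (1 + sum_i p_i (RR_i - 1))
#       = (sum_i p_i RR_i - 1) / (sum_i p_i RR_i),
#
# i.e. the proportional change in risk if exposure were reduced to the TMREL.

#' Population attributable fraction for a polytomous exposure
#'
#' @param p Exposure-category proportions (must sum to 1 within `1e-6`). The
#'   first element (or `reference`) is the unexposed category.
#' @param rr Relative risks per category, same length as `p`; the reference
#'   category must have RR exactly 1, all RRs non-negative.
#' @param reference Index of the unexposed category (default 1).
#' @return The PAF, a scalar in (-Inf, 1); 0 when all RRs are 1 or all mass is
#'   unexposed, strictly below 1 always, non-negative when all RRs >= 1.
#' @export
#' @examples
#' compute_paf(c(0.5, 0.5), c(1, 3))   # 0.5
#' compute_paf(c(0.8, 0.1, 0.1), c(1, 2, 4))  # 0.4 / 1.4
compute_paf <- function(p, rr, reference = 1L) {
  if (length(p) != length(rr)) stop("p and rr must have equal length")
  if (abs(sum(p) - 1) > 1e-6) stop("exposure proportions must sum to 1 (got ",
                                   format(sum(p)), ")")
  if (any(p < 0)) stop("exposure proportions must be non-negative")
  if (any(rr < 0)) stop("relative risks must be non-negative")
  if (rr[reference] != 1) stop("the unexposed reference category must have RR = 1")
  if (all(rr == 1)) return(0)  # TMREL identity, exact
  mean_rr <- sum(p * rr)
  (mean_rr - 1) / mean_rr
}

#' PAF table from prevalence and relative risks
#'
#' Pairs age-gender-specific pattern prevalence with level relative risks
#' (the same RRs apply across all age groups): each of the 32 patterns is
#' mapped to its exposure level via the coding, the level RR is attached, and
#' the polytomous PAF is computed per outcome x gender x age group.
#'
#' @param prevalence Tibble `gender, age_group, pattern, proportion` (32
#'   patterns per stratum).
#' @param rrset An `rr_fit`, or an RR tibble with `outcome, gender, level, rr`
#'   (e.g. from [load_rr_table()]).
#' @param coding Coding table from [exposure_coding()] or its mode string;
#'   must match the RR levels.
#' @return Tibble `outcome, gender, age_group, paf`.
#' @export
paf_table <- function(prevalence, rrset, coding = exposure_coding("count")) {
  if (is.character(coding) && length(coding) == 1) coding <- exposure_coding(coding)
  rr <- if (inherits(rrset, "rr_fit")) rrset$estimates else tibble::as_tibble(rrset)
  rr$level <- as.character(rr$level)
  rr$gender <- validate_gender(rr$gender)
  prevalence <- prevalence |>
    dplyr::filter(!is.na(.data$proportion)) |>
    dplyr::mutate(gender = validate_gender(.data$gender),
                  age_group = normalise_age_group(.data$age_group),
                  level = map_to_level(.data$pattern, coding))

  needed <- dplyr::distinct(prevalence, .data$gender, .data$level)
  have <- dplyr::distinct(rr, .data$gender, .data$level)
  miss <- dplyr::anti_join(needed, have, by = c("gender", "level"))
  if (nrow(miss) > 0) {
    stop("no relative risk for level(s): ",
         paste(unique(paste0(miss$gender, "/", miss$level)), collapse = ", "))
  }

  purrr::map_dfr(unique(rr$outcome), function(out) {
    rro <- rr[rr$outcome == out, c("gender", "level", "rr")]
    prevalence |>
      dplyr::inner_join(rro, by = c("gender", "level")) |>
      dplyr::group_by(.data$gender, .data$age_group) |>
      dplyr::summarise(
        outcome = out,
        paf = compute_paf(.data$proportion, .data$rr,
                          reference = which(.data$pattern == "00000")),
        .groups = "drop"
      )
  }) |>
    dplyr::select("outcome", "gender", "age_group", "paf") |>
    dplyr::arrange(.data$outcome, .data$gender, .data$age_group)
}

#' Burden-weighted all-ages PAF
#'
#' Aggregates age-specific PAFs into an all-ages PAF per outcome x gender,
#' weighting each age group by its share of the cause burden:
#' `sum_a PAF_a B_a / sum_a B_a`.
#'
#' @param paf PAF tibble from [paf_table()].
#' @param weights Tibble `gender, age_group, weight` (optionally with an
#'   `outcome` column for cause-specific weights); typically DALYs by age.
#' @return Tibble `outcome, gender, paf`.
#' @export
aggregate_paf <- function(paf, weights) {
  weights <- dplyr::mutate(weights,
                           gender = validate_gender(.data$gender),
                           age_group = normalise_age_group(.data$age_group))
  by <- c("gender", "age_group", if ("outcome" %in% names(weights)) "outcome")
  joined <- dplyr::inner_join(paf, weights, by = by)
  out <- joined |>
    dplyr::group_by(.data$outcome, .data$gender) |>
    dplyr::summarise(total_weight = sum(.data$weight),
                     paf = sum(.data$paf * .data$weight) / sum(.data$weight),
                     .groups = "drop")
  if (any(out$total_weight == 0)) {
    stop("zero total burden weight for: ",
         paste(paste0(out$outcome[out$total_weight == 0], "/",
                      out$gender[out$total_weight == 0]), collapse = ", "))
  }
  dplyr::select(out, "outcome", "gender", "paf")
}
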
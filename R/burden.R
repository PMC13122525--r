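# Attributable burden: PAF x burden-of-disease envelopes, with the anxiety
# disaggregation, the self-harm mapping and the two-step smoking attribution.

OUTCOME_TO_CAUSE <- c(mdd = "mdd", aud = "aud",
                      suicide_attempt = "self_harm", smoking = "smoking")

#' Attribute the burden of one cause
#'
#' Applies age-gender-specific PAFs to a cause's burden: attributable deaths,
#' YLL and YLD are `PAF * total`, and attributable DALY is the sum of
#' attributable YLL and YLD. Burden rows in age groups below 15 receive PAF 0
#' (attribution starts at the 15-19 band, whose PAF is estimated from
#' 16-19-year-old respondents). Any other burden stratum without a PAF is an
#' error.
#'
#' @param paf PAF tibble (`outcome, gender, age_group, paf`).
#' @param burden Burden tibble (`cause, gender, age_group, deaths, yll, yld,
#'   daly`, optionally `burden_type`).
#' @param cause Cause label to attribute.
#' @param outcome Outcome whose PAF applies (default: the cause's conventional
#'   outcome, e.g. `suicide_attempt` for `self_harm`).
#' @return Tibble `cause, gender, age_group, paf, attributable_deaths,
#'   attributable_yll, attributable_yld, attributable_daly, share_of_cause`.
#' @export
attribute_cause <- function(paf, burden, cause,
                            outcome = names(OUTCOME_TO_CAUSE)[match(cause, OUTCOME_TO_CAUSE)]) {
  if (is.na(outcome)) stop("no default outcome for cause '", cause,
                           "'; pass outcome explicitly")
  b <- dplyr::filter(burden, .data$cause == !!cause)
  if (nrow(b) == 0) stop("cause '", cause, "' not present in burden table")
  p <- dplyr::filter(paf, .data$outcome == !!outcome)
  if (nrow(p) == 0) stop("outcome '", outcome, "' not present in PAF table")
  apply_paf_to_burden(p, b)
}

# Shared join + multiply step; under-15 rows get PAF 0.
apply_paf_to_burden <- function(paf, burden) {
  burden <- dplyr::mutate(burden,
                          gender = validate_gender(.data$gender),
                          age_group = normalise_age_group(.data$age_group))
  paf <- dplyr::mutate(paf,
                       gender = validate_gender(.data$gender),
                       age_group = normalise_age_group(.data$age_group))
  joined <- dplyr::left_join(burden, paf[c("gender", "age_group", "paf")],
                             by = c("gender", "age_group"))
  under15 <- is.na(joined$paf) & age_band_below_15(joined$age_group)
  joined$paf[under15] <- 0
  if (anyNA(joined$paf)) {
    miss <- unique(paste0(joined$gender, "/", joined$age_group)[is.na(joined$paf)])
    stop("burden strata without a matching PAF: ", paste(miss, collapse = ", "))
  }
  joined |>
    dplyr::mutate(
      attributable_deaths = .data$paf * .data$deaths,
      attributable_yll = .data$paf * .data$yll,
      attributable_yld = .data$paf * .data$yld,
      attributable_daly = .data$attributable_yll + .data$attributable_yld,
      share_of_cause = dplyr::if_else(.data$daly > 0,
                                      .data$attributable_daly / .data$daly, 0)
    ) |>
    dplyr::select("cause", "gender", "age_group", "paf",
                  dplyr::starts_with("attributable_"), "share_of_cause")
}

age_band_below_15 <- function(label) {
  label <- normalise_age_group(label)
  hi <- suppressWarnings(as.integer(sub(".*–", "", label)))
  !is.na(hi) & hi < 15
}

#' Attribute anxiety-disorder burden with a PTSD split
#'
#' Burden studies report anxiety disorders as one aggregate cause, while the
#' survey measures PTSD and GAD. The aggregate is split by the PTSD share `s`
#' (from an external mental-health survey): the PTSD PAF applies to the PTSD
#' share of the burden and the GAD PAF (a proxy for the remaining anxiety
#' disorders) to the rest, and the two parts are added:
#' `attributable = paf_ptsd * s * B + paf_gad * (1 - s) * B` per measure.
#'
#' @param paf PAF tibble containing `ptsd` and `gad` outcomes.
#' @param anxiety_burden Burden rows for the aggregate anxiety cause.
#' @param ptsd_share Scalar in `[0, 1]`, or a tibble `gender, age_group,
#'   ptsd_share` for a stratified split.
#' @return Attributable-burden tibble as in [attribute_cause()], with cause
#'   `"anxiety"` and an `effective_paf` column (the burden-weighted blend).
#' @export
attribute_anxiety <- function(paf, anxiety_burden, ptsd_share) {
  b <- dplyr::mutate(anxiety_burden,
                     gender = validate_gender(.data$gender),
                     age_group = normalise_age_group(.data$age_group))
  if (is.numeric(ptsd_share) && length(ptsd_share) == 1) {
    b$ptsd_share <- ptsd_share
  } else {
    ps <- dplyr::mutate(ptsd_share,
                        gender = validate_gender(.data$gender),
                        age_group = normalise_age_group(.data$age_group))
    b <- dplyr::left_join(b, ps, by = c("gender", "age_group"))
    if (anyNA(b$ptsd_share)) stop("ptsd_share missing for some burden strata")
  }
  if (any(b$ptsd_share < 0 | b$ptsd_share > 1)) stop("ptsd_share must be in [0, 1]")

  split_part <- function(paf_out, share) {
    part <- dplyr::mutate(b,
                          deaths = .data$deaths * share, yll = .data$yll * share,
                          yld = .data$yld * share, daly = .data$daly * share)
    ap <- dplyr::filter(paf, .data$outcome == paf_out)
    if (nrow(ap) == 0) stop("outcome '", paf_out, "' not present in PAF table")
    apply_paf_to_burden(ap, part)
  }
  ptsd_part <- split_part("ptsd", b$ptsd_share)
  gad_part <- split_part("gad", 1 - b$ptsd_share)

  measures <- c("attributable_deaths", "attributable_yll",
                "attributable_yld", "attributable_daly")
  out <- ptsd_part
  for (m in measures) out[[m]] <- ptsd_part[[m]] + gad_part[[m]]
  out$cause <- "anxiety"
  out$effective_paf <- ifelse(b$daly > 0, out$attributable_daly / b$daly, 0)
  out$share_of_cause <- out$effective_paf
  out$paf <- NULL
  out
}

#' Attribute intentional self-harm burden
#'
#' The PAF for suicide attempts (ever) is applied to the whole intentional
#' self-harm envelope: deaths (suicides), YLL (suicides) and YLD (non-fatal
#' self-harm injuries) are all scaled by the same PAF, assuming the same
#' relative risk of death from suicide.
#'
#' @param paf PAF tibble containing the `suicide_attempt` outcome.
#' @param self_harm_burden Burden rows for the self-harm cause.
#' @return Attributable-burden tibble.
#' @export
attribute_self_harm <- function(paf, self_harm_burden) {
  p <- dplyr::filter(paf, .data$outcome == "suicide_attempt")
  if (nrow(p) == 0) stop("outcome 'suicide_attempt' not present in PAF table")
  apply_paf_to_burden(p, self_harm_burden)
}

#' Attribute smoking-attributable burden (two-step chain)
#'
#' The smoking PAF applies not to total burden but to the burden already
#' attributed to tobacco smoking by the source burden study (child
#' maltreatment -> smoking -> smoking-attributable burden). To guard against
#' double counting, the input table must be flagged as attributable burden
#' (`burden_type == "attributable"`).
#'
#' @param paf PAF tibble containing the `smoking` outcome.
#' @param smoking_attributable_burden Burden rows for the smoking-attributable
#'   envelope, with `burden_type = "attributable"`.
#' @return Attributable-burden tibble.
#' @export
attribute_smoking <- function(paf, smoking_attributable_burden) {
  bt <- smoking_attributable_burden[["burden_type"]]
  if (is.null(bt) || !all(bt == "attributable")) {
    stop("smoking attribution requires a burden table flagged burden_type = ",
         "\"attributable\" (the smoking-attributable envelope, not total burden)")
  }
  p <- dplyr::filter(paf, .data$outcome == "smoking")
  if (nrow(p) == 0) stop("outcome 'smoking' not present in PAF table")
  apply_paf_to_burden(p, smoking_attributable_burden)
}

#' Summarise attributable burden across causes
#'
#' Combines per-cause attributable-burden tables into per-gender summaries:
#' attributable DALYs per cause with the share of that cause's burden, the
#' cross-cause total, the percentage of all DALYs, and the percentage of the
#' studied-outcomes burden.
#'
#' @param attributables List (or bind_rows-able tibble) of attributable-burden
#'   tables from the `attribute_*` functions (each cause at most once).
#' @param burden The full burden table, containing the studied causes and an
#'   `all_causes` envelope.
#' @return List with `by_cause` (tibble `cause, gender, attributable_daly,
#'   share_of_cause`) and `total` (tibble `gender, attributable_daly,
#'   pct_of_all_daly, pct_of_studied_daly`).
#' @export
summarise_attribution <- function(attributables, burden) {
  att <- dplyr::bind_rows(attributables)
  if (anyDuplicated(att[c("cause", "gender", "age_group")]) > 0) {
    stop("duplicated cause/stratum rows in attributables (double counting)")
  }
  burden <- dplyr::mutate(burden, gender = validate_gender(.data$gender))
  cause_totals <- burden |>
    dplyr::group_by(.data$cause, .data$gender) |>
    dplyr::summarise(total_daly = sum(.data$daly), .groups = "drop")
  by_cause <- att |>
    dplyr::group_by(.data$cause, .data$gender) |>
    dplyr::summarise(attributable_daly = sum(.data$attributable_daly), .groups = "drop") |>
    dplyr::left_join(cause_totals, by = c("cause", "gender")) |>
    dplyr::mutate(share_of_cause = dplyr::if_else(.data$total_daly > 0,
                                                  .data$attributable_daly / .data$total_daly,
                                                  0))
  all_daly <- cause_totals |>
    dplyr::filter(.data$cause == "all_causes") |>
    dplyr::select("gender", all_daly = "total_daly")
  if (nrow(all_daly) == 0) stop("burden table has no 'all_causes' envelope")
  studied <- by_cause |>
    dplyr::group_by(.data$gender) |>
    dplyr::summarise(attributable_daly = sum(.data$attributable_daly),
                     studied_daly = sum(.data$total_daly), .groups = "drop")
  total <- studied |>
    dplyr::left_join(all_daly, by = "gender") |>
    dplyr::mutate(pct_of_all_daly = 100 * .data$attributable_daly / .data$all_daly,
                  pct_of_studied_daly = 100 * .data$attributable_daly / .data$studied_daly) |>
    dplyr::select("gender", "attributable_daly", "pct_of_all_daly", "pct_of_studied_daly")
  list(by_cause = by_cause, total = total)
}
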
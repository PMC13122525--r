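# Diagnostic figures for the main result types.

#' Plot smoothed prevalence age trends
#'
#' Any-maltreatment and multi-type prevalence by age group and gender from a
#' fitted prevalence table.
#'
#' @param object A `prevalence_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.prevalence_fit <- function(object, ...) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(aggregate_prevalence(object$table, "any"), summary = "any maltreatment"),
    dplyr::mutate(aggregate_prevalence(object$table, "multi"), summary = "multi-type (2+)")
  )
  dat$midage <- age_group_midpoint(dat$age_group)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$midage, y = .data$proportion,
                                    colour = .data$gender, linetype = .data$summary)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "age (midpoint of 5-year band)", y = "prevalence",
                  title = "Smoothed maltreatment prevalence by age and gender") +
    ggplot2::theme_minimal()
}

#' Plot the relative-risk dose-response
#'
#' Point estimates and 95% confidence intervals per exposure level, facetted
#' by outcome.
#'
#' @param object An `rr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.rr_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$level, y = .data$rr,
                                    colour = .data$gender, group = .data$gender)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lcl, ymax = .data$ucl),
                             position = ggplot2::position_dodge(width = 0.4),
                             size = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome), scales = "free_y") +
    ggplot2::labs(x = "exposure level", y = "relative risk (log scale)",
                  title = paste0("Relative risks (", object$coding, " coding, ",
                                 object$adjustment, " adjusted)")) +
    ggplot2::theme_minimal()
}

#' Plot a PAF table
#'
#' Age profiles of the population attributable fraction per outcome and
#' gender.
#'
#' @param paf Tibble from [paf_table()].
#' @return A ggplot.
#' @export
plot_paf <- function(paf) {
  paf$midage <- age_group_midpoint(paf$age_group)
  ggplot2::ggplot(paf, ggplot2::aes(x = .data$midage, y = .data$paf,
                                    colour = .data$gender)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::labs(x = "age (midpoint of 5-year band)",
                  y = "population attributable fraction",
                  title = "PAF by age group, gender and outcome") +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo uncertainty for attributable burden
#'
#' Attributable DALYs per cause and gender with 95% uncertainty intervals.
#'
#' @param object An `mc_result` computed with a burden table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mc_result <- function(object, ...) {
  if (is.null(object$by_cause)) stop("mc_result has no burden summaries (PAF-only run)")
  ggplot2::ggplot(object$by_cause,
                  ggplot2::aes(x = .data$cause, y = .data$attributable_daly,
                               colour = .data$gender)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "attributable DALYs",
                  title = "Attributable burden with 95% uncertainty intervals") +
    ggplot2::theme_minimal()
}
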
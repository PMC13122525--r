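# Shared simulated fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# A configuration with no confounding and no age trend: the joint exposure
# model is the same in every stratum, so exact cell probabilities are easy to
# reason about and adjusted/unadjusted estimators coincide.
null_confounders <- function() {
  conf <- default_confounders()
  conf$exposure_log_odds <- 0
  conf$outcome_rr <- 1
  conf
}

clean_config <- function(n = 1e5, outcomes = default_outcomes(), ...) {
  sim_config(n_respondents = n, age_effect = c(0, 0),
             confounders = null_confounders(), outcomes = outcomes, ...)
}

# Recovery scenario: one outcome with true RRs (1, 2, 3, 4, 6, 10), no
# confounding, n = 100,000.
recovery_config <- function(n = 1e5) {
  clean_config(n = n, outcomes = list(
    mdd = list(p0 = c(women = 0.05, men = 0.05), rr = c(1, 2, 3, 4, 6, 10))
  ))
}

recovery_microdata <- function() {
  fixture("recovery_md", simulate_microdata(recovery_config(), seed = 424242L))
}

recovery_truth <- function() fixture("recovery_gt", ground_truth(recovery_config()))

# Default-conditions microdata at survey scale, used by several modules.
default_microdata <- function() {
  fixture("default_md", simulate_microdata(sim_config(), seed = 20260919L))
}

# Independent PAF oracle: enumerate a finite population with the given
# category proportions and relative risks and compute the counterfactual risk
# ratio (R_current - R_tmrel) / R_current directly.
paf_oracle <- function(p, rr, pop = 1e6) {
  n <- round(p * pop)
  r_current <- sum(n * rr)
  r_tmrel <- sum(n) * rr[1]
  (r_current - r_tmrel) / r_current
}

# |z| for a log-RR estimate against truth given a Wald CI.
log_rr_z <- function(rr, lcl, ucl, true_rr) {
  se <- (log(ucl) - log(lcl)) / (2 * stats::qnorm(0.975))
  abs(log(rr) - log(true_rr)) / se
}
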
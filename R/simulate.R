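# Synthetic survey-microdata generator with exact exported ground truth.
#
# Exposures are drawn from a quadratic exponential (log-linear) joint model
# over the 32 patterns: cell log-probability = sum of per-type main effects
# plus pairwise two-way interaction terms. The 32 cells are enumerated and
# normalised exactly, so the generating distribution is known in closed form.

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a national survey of
#' adults reporting five correlated binary childhood maltreatment exposures,
#' binary confounders that raise both exposure and outcome risk, and binary
#' health outcomes whose risk increases with the number of maltreatment types
#' (dose-response).
#'
#' Default marginal prevalences and pairwise dependence are calibrated so the
#' exact joint distribution gives roughly 67% (women) / 59% (men)
#' any-maltreatment prevalence and roughly 39% multi-type prevalence overall,
#' with prevalence peaking near ages 40-44.
#'
#' @param n_respondents Number of respondents (default 8377, split roughly
#'   evenly between women and men).
#' @param gender_split Proportion of women.
#' @param age_range Integer ages sampled uniformly (default 16 to 85).
#' @param marginal_prevalence Named list (`women`, `men`) of length-5 vectors
#'   of per-type marginal prevalences (order PA, SA, EA, N, EDV), realised
#'   exactly at the age-effect reference age with no confounders.
#' @param pairwise_log_odds Named list (`women`, `men`); each a scalar or
#'   length-10 vector of two-way interaction coefficients on the log-linear
#'   scale (pair order `combn(5, 2)` over PA, SA, EA, N, EDV).
#' @param age_effect Length-2 vector `c(ln, sq)`: each type's main effect is
#'   shifted by `ln * (log(age) - log(peak)) + sq * (age^2 - peak^2)`. The
#'   default peaks at age 42 (the 40-44 band). Set `c(0, 0)` to disable.
#' @param age_peak Age at which the default age effect peaks.
#' @param confounders Tibble with columns `name`, `prevalence`,
#'   `exposure_log_odds` (shift applied to all five main effects when the
#'   flag is set) and `outcome_rr` (multiplicative risk on every outcome).
#' @param outcomes Named list; each element `list(p0 = c(women=, men=),
#'   rr = <length-6 vector>)` giving baseline risk among the unexposed and the
#'   true relative risk at 0-5 maltreatment types.
#' @param weights_mode `"unit"` (all survey weights 1) or `"random"`
#'   (lognormal weights, exercising the weighted estimators).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_respondents = 8377,
                       gender_split = 0.5,
                       age_range = c(16L, 85L),
                       marginal_prevalence = list(
                         women = c(0.301, 0.373, 0.341, 0.097, 0.420),
                         men   = c(0.340, 0.186, 0.276, 0.081, 0.371)
                       ),
                       pairwise_log_odds = list(women = 0.9, men = 1.0),
                       age_effect = c(ln = 0.7056, sq = -2e-4),
                       age_peak = 42,
                       confounders = default_confounders(),
                       outcomes = default_outcomes(),
                       weights_mode = c("unit", "random")) {
  weights_mode <- match.arg(weights_mode)
  stopifnot(n_respondents >= 1, gender_split > 0, gender_split < 1,
            length(age_range) == 2, age_range[1] >= 16)
  for (g in GENDER_LEVELS) {
    p <- marginal_prevalence[[g]]
    if (length(p) != 5 || any(p <= 0 | p >= 1)) {
      stop("marginal_prevalence$", g, " must be 5 probabilities in (0,1)")
    }
    lo <- pairwise_log_odds[[g]]
    if (length(lo) == 1) lo <- rep(lo, 10)
    if (length(lo) != 10 || any(!is.finite(lo))) {
      stop("pairwise_log_odds$", g, " must be a finite scalar or length-10 vector")
    }
    pairwise_log_odds[[g]] <- lo
  }
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (any(o$p0 <= 0 | o$p0 >= 1)) stop("outcome ", nm, ": p0 must be in (0,1)")
    if (length(o$rr) != 6 || any(o$rr < 0) || o$rr[1] != 1) {
      stop("outcome ", nm, ": rr must be length 6 with rr[1] (unexposed) = 1")
    }
  }
  structure(list(
    n_respondents = as.integer(n_respondents),
    gender_split = gender_split,
    age_range = as.integer(age_range),
    marginal_prevalence = marginal_prevalence,
    pairwise_log_odds = pairwise_log_odds,
    age_effect = age_effect,
    age_peak = age_peak,
    confounders = confounders,
    outcomes = outcomes,
    weights_mode = weights_mode
  ), class = "sim_config")
}

#' Default confounder specification
#'
#' Childhood financial stress and geographical remoteness raise both exposure
#' (shift on the log-linear main effects) and every outcome (multiplicative
#' risk), mirroring the simply-adjusted confounding structure. The additional
#' sensitivity-analysis covariates (other adverse childhood experiences,
#' bullying victimisation) are present as columns but carry null effects by
#' default; tests switch them on explicitly.
#'
#' @return Tibble with columns `name`, `prevalence`, `exposure_log_odds`,
#'   `outcome_rr`.
#' @export
default_confounders <- function() {
  tibble::tibble(
    name = c("financial_stress", "remoteness", "other_aces", "bullying"),
    prevalence = c(0.15, 0.28, 0.25, 0.30),
    exposure_log_odds = c(0.5, 0.2, 0, 0),
    outcome_rr = c(1.4, 1.15, 1, 1)
  )
}

#' Default outcome specification
#'
#' Baseline risks among the unexposed and true relative risks at 0-5
#' maltreatment types, chosen to mimic the reported dose-response: steepest
#' for post-traumatic stress disorder and suicide attempt, shallowest for
#' smoking.
#'
#' @return Named list of `list(p0, rr)` per outcome.
#' @export
default_outcomes <- function() {
  list(
    mdd            = list(p0 = c(women = 0.14,  men = 0.09),  rr = c(1, 1.5, 2.0, 2.5, 3.1, 3.8)),
    gad            = list(p0 = c(women = 0.07,  men = 0.04),  rr = c(1, 1.7, 2.3, 3.0, 3.8, 4.7)),
    ptsd           = list(p0 = c(women = 0.04,  men = 0.02),  rr = c(1, 2.5, 4.0, 6.0, 8.5, 11.0)),
    aud            = list(p0 = c(women = 0.05,  men = 0.11),  rr = c(1, 1.4, 1.8, 2.3, 2.9, 3.5)),
    smoking        = list(p0 = c(women = 0.10,  men = 0.13),  rr = c(1, 1.3, 1.6, 1.9, 2.3, 2.7)),
    suicide_attempt = list(p0 = c(women = 0.015, men = 0.012), rr = c(1, 2.0, 3.5, 5.0, 7.5, 11.0))
  )
}

#' Names of the simulated outcomes
#' @param config A `sim_config`.
#' @return Character vector.
#' @export
outcome_names <- function(config = sim_config()) names(config$outcomes)

# Run expr with a local RNG stream; restores the caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# 32 x 5 flag matrix in canonical order, plus 32 x 10 pairwise products.
pattern_design <- function() {
  flags <- as.matrix(enumerate_patterns()[names(MALTREATMENT_TYPES)])
  idx <- utils::combn(5, 2)
  pairs <- sapply(seq_len(ncol(idx)), function(k) flags[, idx[1, k]] * flags[, idx[2, k]])
  list(flags = flags, pairs = pairs)
}

# Exact 32-cell probabilities for main effects beta (5) and pairwise gamma (10).
cell_probs <- function(beta, gamma) {
  d <- pattern_design()
  lp <- as.vector(d$flags %*% beta + d$pairs %*% gamma)
  p <- exp(lp - max(lp))
  p / sum(p)
}

cell_marginals <- function(p) as.vector(t(pattern_design()$flags) %*% p)

# Solve main effects so exact marginals equal the targets, by damped
# fixed-point iteration on the logit scale. Deterministic; the independence
# case (gamma = 0) returns qlogis(target) exactly.
solve_main_effects <- function(target, gamma, damp = 0.3, tol = 1e-12, maxit = 5000) {
  beta <- stats::qlogis(target)
  if (all(gamma == 0)) return(beta)
  for (i in seq_len(maxit)) {
    m <- cell_marginals(cell_probs(beta, gamma))
    if (max(abs(m - target)) < tol) return(beta)
    beta <- beta + damp * (stats::qlogis(target) - stats::qlogis(m))
  }
  stop("main-effect calibration did not converge; check marginal_prevalence / pairwise_log_odds")
}

# Age shift on each main effect: ln/quadratic trend, zero at the peak age.
age_shift <- function(age, config) {
  a <- config$age_effect
  a[1] * (log(age) - log(config$age_peak)) + a[2] * (age^2 - config$age_peak^2)
}

# Exact 32-cell table for one gender at a given age and confounder shift.
stratum_cell_probs <- function(config, gender, age, conf_shift = 0, beta0 = NULL) {
  if (is.null(beta0)) {
    beta0 <- solve_main_effects(config$marginal_prevalence[[gender]],
                                config$pairwise_log_odds[[gender]])
  }
  cell_probs(beta0 + age_shift(age, config) + conf_shift,
             config$pairwise_log_odds[[gender]])
}

#' Simulate maltreatment exposures
#'
#' Draws respondents (gender, age, survey weight, confounder flags) and their
#' maltreatment pattern from the exact enumerated 32-cell log-linear joint
#' model: main effects are calibrated to the configured marginal prevalences,
#' shifted by the age trend and by each active confounder, with the configured
#' pairwise dependence.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical tables.
#' @return Tibble with one row per respondent: `id`, `gender`, `age_years`,
#'   `survey_weight`, confounder flags, the five exposure flags, `pattern`
#'   and `n_types`.
#' @export
simulate_exposures <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, {
    n <- config$n_respondents
    gender <- factor(ifelse(stats::runif(n) < config$gender_split, "women", "men"),
                     levels = GENDER_LEVELS)
    age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
    weight <- switch(config$weights_mode,
                     unit = rep(1, n),
                     random = stats::rlnorm(n, 0, 0.3))
    conf <- config$confounders
    conf_flags <- vapply(seq_len(nrow(conf)),
                         function(i) stats::rbinom(n, 1, conf$prevalence[i]),
                         integer(n))
    colnames(conf_flags) <- conf$name

    # Only confounders with a nonzero exposure effect change the cell table.
    active <- which(conf$exposure_log_odds != 0)
    conf_shift <- if (length(active) > 0) {
      as.vector(conf_flags[, active, drop = FALSE] %*% conf$exposure_log_odds[active])
    } else rep(0, n)

    beta0 <- lapply(stats::setNames(GENDER_LEVELS, GENDER_LEVELS), function(g) {
      solve_main_effects(config$marginal_prevalence[[g]], config$pairwise_log_odds[[g]])
    })

    pattern_idx <- integer(n)
    grp <- interaction(gender, age, conf_shift, drop = TRUE)
    for (g in levels(grp)) {
      rows <- which(grp == g)
      r1 <- rows[1]
      p <- stratum_cell_probs(config, as.character(gender[r1]), age[r1],
                              conf_shift[r1], beta0[[as.character(gender[r1])]])
      pattern_idx[rows] <- sample.int(32, length(rows), replace = TRUE, prob = p)
    }
    pats <- enumerate_patterns()
    out <- tibble::tibble(id = seq_len(n), gender = gender, age_years = age,
                          survey_weight = weight)
    out <- dplyr::bind_cols(out, tibble::as_tibble(conf_flags))
    dplyr::bind_cols(out, pats[pattern_idx, ])
  })
}

#' Simulate health outcomes on exposure microdata
#'
#' Each outcome is Bernoulli with probability `p0(gender) * RR(n_types) *`
#' product of confounder risk multipliers, capped at `1 - 1e-6`. Capping
#' indicates a misconfigured risk model, so a warning reports the number of
#' capped probabilities.
#'
#' @param data Microdata from [simulate_exposures()].
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @return `data` with one 0/1 column per configured outcome.
#' @export
simulate_outcomes <- function(data, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("gender", "n_types") %in% names(data))) {
    stop("exposure columns missing; run simulate_exposures() first")
  }
  conf <- config$confounders
  log_conf_mult <- as.vector(
    as.matrix(data[conf$name]) %*% log(conf$outcome_rr)
  )
  eps <- 1e-6
  with_local_seed(seed, {
    n_capped <- 0L
    for (nm in names(config$outcomes)) {
      o <- config$outcomes[[nm]]
      p <- o$p0[as.character(data$gender)] * o$rr[data$n_types + 1] * exp(log_conf_mult)
      over <- p > 1 - eps
      n_capped <- n_capped + sum(over)
      p[over] <- 1 - eps
      data[[nm]] <- stats::rbinom(nrow(data), 1, p)
    }
    if (n_capped > 0) {
      warning(sprintf("%d outcome probabilities exceeded 1 - 1e-6 and were capped; check p0/rr/confounder configuration", n_capped))
    }
    data
  })
}

#' Simulate a full microdata table
#'
#' Convenience wrapper: [simulate_exposures()] then [simulate_outcomes()]
#' (outcome draws use `seed + 1`).
#'
#' @inheritParams simulate_exposures
#' @return Microdata tibble with exposures and outcomes.
#' @export
simulate_microdata <- function(config = sim_config(), seed = 1L) {
  simulate_outcomes(simulate_exposures(config, seed), config, seed + 1L)
}

BURDEN_CAUSES <- c("mdd", "anxiety", "self_harm", "aud", "smoking", "all_causes")

#' Simulate a burden-of-disease table
#'
#' Generates a cause x gender x 5-year-age-group table of deaths, years of
#' life lost (YLL), years lived with disability (YLD) and disability-adjusted
#' life years (DALY = YLL + YLD exactly), shaped like national burden-study
#' output. Mental-disorder causes (`mdd`, `anxiety`) are non-fatal (deaths
#' and YLL zero). The `smoking` rows are the smoking-ATTRIBUTABLE burden
#' envelope (`burden_type = "attributable"`), for the two-step smoking
#' attribution; all other rows are total burden. An `all_causes` envelope
#' supports percentage-of-all-DALY summaries. A `10–14` age band is included
#' (maltreatment attribution starts at 15-19, so it receives a zero fraction).
#'
#' @param config A [sim_config()] (used only for the cause list via outcomes).
#' @param seed Integer seed.
#' @return Tibble `cause, gender, age_group, deaths, yll, yld, daly,
#'   burden_type`.
#' @export
simulate_burden_table <- function(config = sim_config(), seed = 1L) {
  ages <- c("10–14", age_group_levels())
  n_age <- length(ages)
  # Rough per-cause magnitudes (per stratum): deaths, mean YLL per death, YLD.
  shape <- list(
    mdd        = list(deaths = 0,   yll_per = 0,  yld = 9000),
    anxiety    = list(deaths = 0,   yll_per = 0,  yld = 8000),
    self_harm  = list(deaths = 110, yll_per = 40, yld = 900),
    aud        = list(deaths = 30,  yll_per = 28, yld = 4000),
    smoking    = list(deaths = 350, yll_per = 16, yld = 2500),
    all_causes = list(deaths = 5200, yll_per = 18, yld = 160000)
  )
  # Age profiles: mental-disorder burden peaks mid-life; smoking/all-cause
  # mortality rises with age.
  midage <- c(12.5, age_group_midpoint(age_group_levels()))
  prof_mid <- exp(-((midage - 40) / 28)^2)
  prof_old <- pmin(1, (midage / 85)^2.5)
  profile <- list(mdd = prof_mid, anxiety = prof_mid, self_harm = prof_mid,
                  aud = prof_mid, smoking = prof_old, all_causes = 0.3 + 0.7 * prof_old)
  with_local_seed(seed, {
    rows <- purrr::map_dfr(BURDEN_CAUSES, function(cs) {
      purrr::map_dfr(GENDER_LEVELS, function(g) {
        gmult <- if (g == "men") 1.15 else 1
        noise <- stats::rlnorm(n_age, 0, 0.08)
        deaths <- shape[[cs]]$deaths * profile[[cs]] * gmult * noise
        yll <- deaths * shape[[cs]]$yll_per
        yld <- shape[[cs]]$yld * profile[[cs]] * gmult * stats::rlnorm(n_age, 0, 0.08)
        tibble::tibble(cause = cs, gender = g, age_group = ages,
                       deaths = deaths, yll = yll, yld = yld, daly = yll + yld,
                       burden_type = if (cs == "smoking") "attributable" else "total")
      })
    })
    rows$gender <- factor(rows$gender, levels = GENDER_LEVELS)
    rows
  })
}

#' Exact ground truth implied by a simulation configuration
#'
#' Computes, without any sampling, the quantities the pipeline is supposed to
#' recover: the exact 32-pattern prevalence per gender x age group (cell
#' probabilities of the normalised log-linear table, averaged over the integer
#' ages in each band and over the confounder distribution), the configured
#' true relative risks per outcome and exposure count, and the true population
#' attributable fractions obtained by applying the PAF formula to that truth.
#'
#' @param config A [sim_config()].
#' @return List with tibbles `pattern_prevalence` (`gender, age_group,
#'   pattern, proportion`), `rr` (`outcome, gender, level, rr`) and `paf`
#'   (`outcome, gender, age_group, paf`).
#' @export
ground_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  conf <- config$confounders
  active <- which(conf$exposure_log_odds != 0)
  combos <- if (length(active) > 0) {
    m <- as.matrix(expand.grid(rep(list(0:1), length(active))))
    w <- apply(m, 1, function(z) prod(ifelse(z == 1, conf$prevalence[active],
                                             1 - conf$prevalence[active])))
    list(shift = as.vector(m %*% conf$exposure_log_odds[active]), w = w)
  } else list(shift = 0, w = 1)

  pats <- enumerate_patterns()
  prev <- purrr::map_dfr(GENDER_LEVELS, function(g) {
    beta0 <- solve_main_effects(config$marginal_prevalence[[g]],
                                config$pairwise_log_odds[[g]])
    purrr::map_dfr(age_group_levels(), function(ag) {
      ages <- intersect(age_band_ages(ag), seq(config$age_range[1], config$age_range[2]))
      if (length(ages) == 0) return(NULL)
      p <- Reduce(`+`, lapply(ages, function(a) {
        Reduce(`+`, lapply(seq_along(combos$w), function(k) {
          combos$w[k] * stratum_cell_probs(config, g, a, combos$shift[k], beta0)
        }))
      })) / length(ages)
      tibble::tibble(gender = g, age_group = ag, pattern = pats$pattern, proportion = p)
    })
  })
  prev$gender <- factor(prev$gender, levels = GENDER_LEVELS)

  rr <- purrr::map_dfr(names(config$outcomes), function(nm) {
    tidyr::expand_grid(outcome = nm, gender = GENDER_LEVELS, level = as.character(0:5)) |>
      dplyr::mutate(rr = config$outcomes[[nm]]$rr[as.integer(.data$level) + 1])
  })

  coding <- exposure_coding("count")
  paf <- prev |>
    dplyr::mutate(level = map_to_level(.data$pattern, coding)) |>
    dplyr::group_by(.data$gender, .data$age_group) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(names(config$outcomes), function(nm) {
        rrs <- config$outcomes[[nm]]$rr[as.integer(d$level) + 1]
        tibble::tibble(outcome = nm, paf = compute_paf(d$proportion, rrs))
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::select("outcome", "gender", "age_group", "paf")

  list(pattern_prevalence = prev, rr = rr, paf = paf)
}

# Integer ages covered by an age band label.
age_band_ages <- function(label) {
  label <- normalise_age_group(label)
  if (label == "80+") return(80:85)
  lo <- as.integer(sub("–.*", "", label))
  hi <- as.integer(sub(".*–", "", label))
  lo:hi
}
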
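# Monte Carlo propagation of sampling uncertainty into PAFs and attributable
# burden: Dirichlet draws for the 32-pattern prevalence of each stratum,
# lognormal draws for the relative risks (one draw per outcome x gender x
# level per iteration, shared across age groups), full recomputation of the
# PAF -> burden chain per iteration, and empirical percentile intervals.

#' Uncertainty-analysis settings
#'
#' @param iterations Number of Monte Carlo iterations (default 2000).
#' @param seed Integer seed.
#' @param ci_level Interval level (default 0.95: 2.5th and 97.5th empirical
#'   percentiles).
#' @param rr_correlation `"auto"`: when the RR set is a fitted `rr_fit`, level
#'   log-RRs are drawn jointly from the fit's multivariate normal (they share
#'   the reference group, so they are strongly positively correlated);
#'   externally supplied tables, which carry only marginal intervals, fall
#'   back to independent lognormal draws. `"independent"` forces independent
#'   draws (the spreadsheet-style behaviour) in all cases.
#' @param keep_draws If `TRUE`, iteration draws are returned in the result.
#' @return List of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(iterations = 2000, seed = 1L, ci_level = 0.95,
                             rr_correlation = c("auto", "independent"),
                             keep_draws = FALSE) {
  stopifnot(iterations >= 2, ci_level > 0, ci_level < 1)
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 ci_level = ci_level, rr_correlation = match.arg(rr_correlation),
                 keep_draws = keep_draws),
            class = "uncertainty_spec")
}

#' Dirichlet draws of exposure-category proportions
#'
#' Samples category proportions from a Dirichlet distribution with
#' concentration `alpha = proportion * effective_n`, the conjugate posterior
#' shape for multinomial sampling, so every draw sums to exactly 1. Empty
#' categories (proportion 0) receive a 0.5 pseudo-count, since Dirichlet
#' concentrations must be positive.
#'
#' @param p Proportions summing to 1.
#' @param effective_n Effective sample size behind `p` (> 0).
#' @param n_draws Number of draws.
#' @return Matrix `n_draws x length(p)`; rows sum to 1.
#' @export
sample_prevalence <- function(p, effective_n, n_draws = 1) {
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  if (effective_n <= 0) stop("effective_n must be positive")
  alpha <- p * effective_n
  alpha[alpha == 0] <- 0.5
  g <- matrix(stats::rgamma(n_draws * length(p), shape = rep(alpha, each = n_draws)),
              nrow = n_draws)
  g / rowSums(g)
}

#' Lognormal sigma implied by a relative risk's confidence interval
#'
#' `sigma = (log(ucl) - log(lcl)) / (2 * qnorm(0.975))`, the standard rule for
#' recovering the log-scale standard error from a Wald 95% interval.
#'
#' @param lcl,ucl Confidence limits (0 < lcl <= ucl).
#' @return Sigma on the log scale (0 for a degenerate interval).
#' @export
rr_sigma <- function(lcl, ucl) {
  stopifnot(all(lcl > 0), all(ucl >= lcl))
  (log(ucl) - log(lcl)) / (2 * stats::qnorm(0.975))
}

#' Lognormal draws of a relative risk
#'
#' Draws `exp(N(log rr, sigma))` with sigma from [rr_sigma()], so the median
#' of the draws is the point estimate and the 2.5th/97.5th quantiles match the
#' supplied interval. A degenerate interval (`lcl = ucl = rr`) returns the
#' point estimate.
#'
#' @param rr Point estimate (> 0).
#' @param lcl,ucl 95% confidence limits bracketing `rr`.
#' @param n_draws Number of draws.
#' @return Numeric vector of draws.
#' @export
sample_rr <- function(rr, lcl, ucl, n_draws = 1) {
  stopifnot(rr > 0, lcl > 0, lcl <= rr, rr <= ucl)
  s <- rr_sigma(lcl, ucl)
  if (s == 0) return(rep(rr, n_draws))
  exp(stats::rnorm(n_draws, log(rr), s))
}

#' Monte Carlo uncertainty for PAFs and attributable burden
#'
#' Per iteration: draw each stratum's 32-pattern prevalence from its Dirichlet
#' distribution, draw one relative risk per outcome x gender x level (shared
#' across all age groups, since the same RRs apply to every age group),
#' recompute all PAFs and the full attribution chain (anxiety split, self-harm
#' mapping, two-step smoking), and record the outputs. Uncertainty intervals
#' are empirical percentiles (linear interpolation between closest ranks) of
#' the iteration values; point estimates come from the undrawn inputs through
#' the same chain. Burden envelopes are treated as fixed: only exposure and
#' relative-risk sampling uncertainty is propagated.
#'
#' @param prevalence Tibble `gender, age_group, pattern, proportion,
#'   effective_n` (e.g. a `prevalence_fit$table`); `effective_n = Inf` marks a
#'   stratum's proportions as exact (excluded from Dirichlet sampling).
#' @param rrset RR tibble `outcome, gender, level, rr, lcl, ucl` (or an
#'   `rr_fit`).
#' @param burden Burden table with the studied causes (`mdd`, `anxiety`,
#'   `self_harm`, `aud`, smoking-attributable `smoking`) and an `all_causes`
#'   envelope.
#' @param ptsd_share PTSD share of the anxiety burden (scalar in `[0, 1]`).
#' @param coding Exposure coding (table or mode string).
#' @param spec An [uncertainty_spec()].
#' @return Object of class `mc_result` with tibbles `paf` (`outcome, gender,
#'   age_group, point, lower, upper`), `by_cause` (`cause, gender`,
#'   attributable DALYs with bounds), `total` (`gender`, percentage of all
#'   DALYs with bounds), the number of excluded iterations, and (optionally)
#'   the draws.
#' @export
run_monte_carlo <- function(prevalence, rrset, burden = NULL, ptsd_share = 0.25,
                            coding = exposure_coding("count"),
                            spec = uncertainty_spec()) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  if (is.character(coding) && length(coding) == 1) coding <- exposure_coding(coding)
  rr <- if (inherits(rrset, "rr_fit")) rrset$estimates else tibble::as_tibble(rrset)
  rr$level <- as.character(rr$level)
  if (!all(c("lcl", "ucl") %in% names(rr))) stop("rrset needs lcl/ucl columns")
  if (length(ptsd_share) != 1 || ptsd_share < 0 || ptsd_share > 1) {
    stop("ptsd_share must be a scalar in [0, 1]")
  }

  prevalence <- prevalence |>
    dplyr::filter(!is.na(.data$proportion)) |>
    dplyr::mutate(gender = validate_gender(.data$gender),
                  age_group = normalise_age_group(.data$age_group)) |>
    dplyr::arrange(.data$gender, .data$age_group, .data$pattern)
  pats <- enumerate_patterns()$pattern
  strata <- dplyr::distinct(prevalence, .data$gender, .data$age_group)
  S <- nrow(strata)
  P <- matrix(prevalence$proportion, nrow = S, byrow = TRUE)  # S x 32
  stopifnot(all(prevalence$pattern == rep(pats, times = S)))
  n_eff <- prevalence$effective_n[seq(1, nrow(prevalence), by = 32)]
  # effective_n = Inf marks a stratum's proportions as exact (not drawn)
  fixed_strata <- !is.finite(n_eff)
  alpha <- P * ifelse(fixed_strata, 1, n_eff)
  alpha[alpha == 0] <- 0.5

  levs <- coding_levels(coding)
  M <- outer(map_to_level(pats, coding), levs, `==`) * 1  # 32 x L
  outcomes <- unique(rr$outcome)
  # mu/sigma arrays [outcome x gender x level]; array() fills its first index
  # fastest, so the key must vary outcome fastest and level slowest
  key <- tidyr::expand_grid(level = levs, gender = GENDER_LEVELS, outcome = outcomes)
  rr_aligned <- dplyr::left_join(key, rr, by = c("outcome", "gender", "level"))
  if (anyNA(rr_aligned$rr)) {
    miss <- rr_aligned[is.na(rr_aligned$rr), c("outcome", "gender", "level")]
    stop("missing RR for: ", paste(do.call(paste, c(miss, sep = "/")), collapse = ", "))
  }
  dims <- c(length(outcomes), 2L, length(levs))
  mu <- array(log(rr_aligned$rr), dim = dims)
  sg <- array(rr_sigma(rr_aligned$lcl, rr_aligned$ucl), dim = dims)

  # joint (correlated) level draws when the fit's covariance is available
  joint_rr <- NULL
  if (inherits(rrset, "rr_fit") && spec$rr_correlation == "auto" &&
      !is.null(rrset$vcov)) {
    joint_rr <- list()
    for (o in seq_along(outcomes)) {
      for (gi in 1:2) {
        vc <- rrset$vcov[[paste(outcomes[o], GENDER_LEVELS[gi], sep = ".")]]
        if (is.null(vc) || nrow(vc) == 0) next
        lev_pos <- match(rownames(vc), levs)
        if (anyNA(lev_pos)) next
        ch <- tryCatch(chol(vc), error = function(e) NULL)
        if (is.null(ch)) next
        joint_rr[[length(joint_rr) + 1]] <- list(
          o = o, g = gi, pos = lev_pos, mu = mu[o, gi, lev_pos], chol = ch)
      }
    }
  }

  g_idx <- as.integer(strata$gender)  # 1 = women, 2 = men
  with_burden <- !is.null(burden)
  if (with_burden) {
    needed <- c("mdd", "gad", "ptsd", "aud", "smoking", "suicide_attempt")
    if (!all(needed %in% outcomes)) {
      stop("burden attribution needs RRs for all of: ", paste(needed, collapse = ", "),
           "; pass burden = NULL for PAF-only uncertainty")
    }
    if (dplyr::n_distinct(strata$gender) != 2) {
      stop("burden attribution needs prevalence for both genders")
    }
    # burden DALYs aligned to PAF strata per cause (under-15 rows contribute
    # nothing: attribution starts at the 15-19 band)
    cause_daly <- function(cs) {
      b <- burden |>
        dplyr::filter(.data$cause == cs) |>
        dplyr::mutate(gender = validate_gender(.data$gender),
                      age_group = normalise_age_group(.data$age_group))
      al <- dplyr::left_join(strata, b, by = c("gender", "age_group"))
      dplyr::coalesce(al$daly, 0)
    }
    dalys <- list(mdd = cause_daly("mdd"), anxiety = cause_daly("anxiety"),
                  self_harm = cause_daly("self_harm"), aud = cause_daly("aud"),
                  smoking = cause_daly("smoking"))
    all_daly <- burden |>
      dplyr::filter(.data$cause == "all_causes") |>
      dplyr::group_by(gender = validate_gender(.data$gender)) |>
      dplyr::summarise(daly = sum(.data$daly), .groups = "drop")
    if (nrow(all_daly) != 2) stop("burden table needs an 'all_causes' envelope for both genders")
    all_daly_g <- stats::setNames(all_daly$daly, as.character(all_daly$gender))
  }

  # one iteration: PAF matrix [S x outcomes] (+ cause/total summaries)
  chain <- function(Pd, rrd) {
    Pl <- Pd %*% M  # S x L
    paf <- matrix(vapply(seq_along(outcomes), function(o) {
      rro <- matrix(rrd[o, g_idx, ], nrow = S)
      mean_rr <- rowSums(Pl * rro)
      1 - 1 / mean_rr
    }, numeric(S)), nrow = S)
    if (!with_burden) return(list(paf = paf, att = NULL, pct = NULL))
    pafc <- function(out) paf[, match(out, outcomes)]
    att <- rbind(
      mdd = pafc("mdd") * dalys$mdd,
      anxiety = (pafc("ptsd") * ptsd_share + pafc("gad") * (1 - ptsd_share)) * dalys$anxiety,
      self_harm = pafc("suicide_attempt") * dalys$self_harm,
      aud = pafc("aud") * dalys$aud,
      smoking = pafc("smoking") * dalys$smoking
    )
    att_g <- t(apply(att, 1, function(v) tapply(v, g_idx, sum)))
    colnames(att_g) <- GENDER_LEVELS
    pct <- 100 * colSums(att_g) / all_daly_g[GENDER_LEVELS]
    list(paf = paf, att = att_g, pct = pct)
  }

  point <- chain(P, array(exp(mu), dim = dims))

  it <- spec$iterations
  paf_draws <- array(NA_real_, dim = c(it, S, length(outcomes)))
  att_draws <- if (with_burden) array(NA_real_, dim = c(it, 5, 2),
                                      dimnames = list(NULL, rownames(point$att), GENDER_LEVELS))
  pct_draws <- if (with_burden) matrix(NA_real_, it, 2, dimnames = list(NULL, GENDER_LEVELS))
  failed <- 0L
  with_local_seed(spec$seed, {
    for (i in seq_len(it)) {
      g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = S)
      Pd <- g / rowSums(g)
      if (any(fixed_strata)) Pd[fixed_strata, ] <- P[fixed_strata, ]
      if (is.null(joint_rr)) {
        rrd <- array(exp(mu + sg * stats::rnorm(length(mu))), dim = dims)
      } else {
        rrd <- array(exp(mu), dim = dims)
        for (jr in joint_rr) {
          z <- stats::rnorm(length(jr$mu))
          rrd[jr$o, jr$g, jr$pos] <- exp(jr$mu + drop(crossprod(jr$chol, z)))
        }
      }
      res <- chain(Pd, rrd)
      if (!all(is.finite(res$paf)) || (with_burden && !all(is.finite(res$pct)))) {
        failed <- failed + 1L
        next
      }
      paf_draws[i, , ] <- res$paf
      if (with_burden) {
        att_draws[i, , ] <- res$att
        pct_draws[i, ] <- res$pct
      }
    }
  })
  if (failed > 0) {
    warning(failed, " iteration(s) produced non-finite output and were excluded")
    if (failed > 0.01 * it) stop("more than 1% of Monte Carlo iterations failed")
  }

  pr <- c((1 - spec$ci_level) / 2, 1 - (1 - spec$ci_level) / 2)
  qs <- function(x) stats::quantile(x, probs = pr, na.rm = TRUE, type = 7, names = FALSE)

  paf_tbl <- purrr::map_dfr(seq_along(outcomes), function(o) {
    bounds <- apply(paf_draws[, , o, drop = FALSE], 2, qs)
    tibble::tibble(outcome = outcomes[o], gender = strata$gender,
                   age_group = strata$age_group, point = point$paf[, o],
                   lower = bounds[1, ], upper = bounds[2, ])
  })
  by_cause <- total <- NULL
  if (with_burden) {
    by_cause <- purrr::map_dfr(rownames(point$att), function(cs) {
      purrr::map_dfr(GENDER_LEVELS, function(g) {
        b <- qs(att_draws[, cs, g])
        tibble::tibble(cause = cs, gender = g,
                       attributable_daly = point$att[cs, g],
                       lower = b[1], upper = b[2])
      })
    })
    total <- purrr::map_dfr(GENDER_LEVELS, function(g) {
      b <- qs(pct_draws[, g])
      tibble::tibble(gender = g, pct_of_all_daly = point$pct[g],
                     lower = b[1], upper = b[2])
    })
  }

  structure(list(
    paf = paf_tbl, by_cause = by_cause, total = total,
    n_failed = failed, spec = spec,
    draws = if (spec$keep_draws) list(paf = paf_draws, attributable_daly = att_draws,
                                      pct_of_all_daly = pct_draws)
  ), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo uncertainty (", x$spec$iterations, " iterations, seed ",
      x$spec$seed, ")\n", sep = "")
  if (!is.null(x$total)) {
    cat("Attributable share of all DALYs (%):\n")
    print(x$total)
  } else {
    print(utils::head(x$paf, 5))
  }
  invisible(x)
}

#' Tidy a Monte Carlo result
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return The PAF tibble with point estimates and uncertainty bounds.
#' @export
#' @exportS3Method generics::tidy
tidy.mc_result <- function(x, ...) x$paf

#' Glance at a Monte Carlo result
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return One-row tibble with iteration count, failures and interval level.
#' @export
#' @exportS3Method generics::glance
glance.mc_result <- function(x, ...) {
  tibble::tibble(iterations = x$spec$iterations, failed = x$n_failed,
                 ci_level = x$spec$ci_level, seed = x$spec$seed)
}
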
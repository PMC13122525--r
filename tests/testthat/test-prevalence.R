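make_md <- function(n = 400, pattern = "00000", weight = 1) {
  flags <- parse_pattern(rep(pattern, n))
  tibble::tibble(
    gender = rep(c("women", "men"), length.out = n),
    age_years = rep(seq(16, 85), length.out = n),
    survey_weight = weight
  ) |>
    dplyr::bind_cols(flags)
}

test_that("direct prevalence: degenerate and weighting identities", {
  md <- make_md(400, "00000")
  dp <- direct_prevalence(md)
  obs <- dp[!is.na(dp$proportion), ]
  expect_true(all(obs$proportion[obs$pattern == "00000"] == 1))
  expect_true(all(obs$proportion[obs$pattern != "00000"] == 0))

  # uniform weights equal unweighted relative frequencies; doubling weights is a no-op
  md2 <- default_microdata()[1:4000, ]
  dp1 <- direct_prevalence(md2)
  freq <- md2 |>
    dplyr::mutate(age_group = assign_age_group(age_years)) |>
    dplyr::count(gender, age_group, pattern) |>
    dplyr::group_by(gender, age_group) |>
    dplyr::mutate(rel = n / sum(n))
  j <- dplyr::inner_join(dp1, freq, by = c("gender", "age_group", "pattern"))
  expect_equal(j$proportion, j$rel, tolerance = 1e-12)
  md3 <- dplyr::mutate(md2, survey_weight = survey_weight * 2)
  expect_equal(direct_prevalence(md3)$proportion, dp1$proportion, tolerance = 1e-12)
  expect_error(direct_prevalence(dplyr::mutate(md2, survey_weight = 0)), "positive")
})

test_that("empty strata are flagged missing, not dropped silently", {
  md <- default_microdata()[1:2000, ]
  md <- md[md$age_years < 60, ]
  dp <- direct_prevalence(md)
  expect_true(any(is.na(dp$proportion[dp$age_group == "80+"])))
  expect_equal(nrow(dp), 2 * 14 * 32)
})

test_that("fitted distributions are proper and smooth in age", {
  md <- default_microdata()
  fit <- fit_joint_prevalence(md)
  sums <- fit$table |>
    dplyr::group_by(gender, age_group) |>
    dplyr::summarise(s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_true(all(fit$table$proportion >= 0))
  # age trend of any-maltreatment: first differences change sign at most twice
  any_tab <- aggregate_prevalence(fit$table, "any")
  for (g in c("women", "men")) {
    y <- any_tab$proportion[any_tab$gender == g][order(age_group_midpoint(
      any_tab$age_group[any_tab$gender == g]))]
    d <- diff(y)
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 2)
  }
})

test_that("two-way interaction terms are near zero on independence data", {
  cfg <- clean_config(n = 1e5,
                      pairwise_log_odds = list(women = 0, men = 0))
  md <- fixture("indep_md", simulate_exposures(cfg, seed = 51))
  fit <- fit_joint_prevalence(md)
  sm <- summary(fit$fit)$coefficients
  pair_rows <- grepl(":", rownames(sm)) & !grepl("fp|gender", rownames(sm))
  z <- sm[pair_rows, "Estimate"] / sm[pair_rows, "Std. Error"]
  expect_equal(sum(pair_rows), 10)
  expect_true(all(abs(z) < 4))
})

test_that("smoothed fit recovers exact cell probabilities within 0.01", {
  cfg <- clean_config(n = 2e5)
  md <- fixture("tv_md", simulate_exposures(cfg, seed = 23))
  fit <- fit_joint_prevalence(md)
  gt <- ground_truth(cfg)$pattern_prevalence
  j <- dplyr::inner_join(fit$table, gt, by = c("gender", "age_group", "pattern"),
                         suffix = c("_fit", "_true"))
  expect_equal(nrow(j), 28 * 32)
  expect_lt(max(abs(j$proportion_fit - j$proportion_true)), 0.01)
})

test_that("saturated fit on a single stratum reproduces direct estimates", {
  cfg <- sim_config(n_respondents = 3000, age_range = c(40, 44))
  md <- simulate_exposures(cfg, seed = 61)
  md <- md[md$gender == "women", ]
  fit <- fit_joint_prevalence(md, model = "saturated")
  dp <- direct_prevalence(md)
  j <- dplyr::inner_join(fit$table, dp, by = c("gender", "age_group", "pattern"))
  expect_lt(max(abs(j$proportion.x - j$proportion.y)), 1e-6)
})

test_that("age smoothing beats direct estimation at survey scale (MSE)", {
  cfg <- sim_config(n_respondents = 28 * 250)
  md <- simulate_exposures(cfg, seed = 71)
  truth <- ground_truth(cfg)$pattern_prevalence
  fit <- fit_joint_prevalence(md)
  dp <- dplyr::filter(direct_prevalence(md), !is.na(proportion))
  mse <- function(tab) {
    j <- dplyr::inner_join(tab, truth, by = c("gender", "age_group", "pattern"),
                           suffix = c("", "_true"))
    mean((j$proportion - j$proportion_true)^2)
  }
  expect_lt(mse(fit$table), mse(dp))
})

test_that("optional FP search returns a power pair from the standard set", {
  md <- default_microdata()[1:6000, ]
  fit <- fit_joint_prevalence(md, select_fp = TRUE)
  expect_true(all(fit$fp_powers %in% c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)))
  expect_error(fit_joint_prevalence(md, fp_powers = c(0, 4)), "fp_powers")
})

test_that("aggregate_prevalence matches hand arithmetic", {
  base <- tibble::tibble(gender = "women", age_group = "20–24",
                         pattern = enumerate_patterns()$pattern, proportion = 0)
  # all mass unexposed
  t1 <- dplyr::mutate(base, proportion = ifelse(pattern == "00000", 1, 0))
  expect_equal(aggregate_prevalence(t1, "any")$proportion, 0)
  expect_equal(aggregate_prevalence(t1, "multi")$proportion, 0)
  # all mass on the all-five pattern
  t2 <- dplyr::mutate(base, proportion = ifelse(pattern == "11111", 1, 0))
  expect_equal(aggregate_prevalence(t2, "any")$proportion, 1)
  expect_equal(aggregate_prevalence(t2, "multi")$proportion, 1)
  expect_true(all(aggregate_prevalence(t2, "per_type")$proportion == 1))
  # handcrafted three-pattern distribution: 00000 .5, 10000 .3, 10100 .2
  t3 <- dplyr::mutate(base, proportion = dplyr::case_when(
    pattern == "00000" ~ 0.5, pattern == "10000" ~ 0.3, pattern == "10100" ~ 0.2,
    TRUE ~ 0))
  expect_equal(aggregate_prevalence(t3, "any")$proportion, 0.5)
  expect_equal(aggregate_prevalence(t3, "multi")$proportion, 0.2)
  per <- aggregate_prevalence(t3, "per_type")
  expect_equal(per$proportion[per$type == "physical_abuse"], 0.5)
  expect_equal(per$proportion[per$type == "emotional_abuse"], 0.2)
  expect_equal(per$proportion[per$type == "neglect"], 0)
})
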
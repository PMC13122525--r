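test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(n_respondents = 2000)
  a <- simulate_microdata(cfg, seed = 3)
  b <- simulate_microdata(cfg, seed = 3)
  expect_identical(a, b)
  c <- simulate_microdata(cfg, seed = 4)
  expect_false(identical(a, c))
  expect_identical(simulate_burden_table(cfg, 9), simulate_burden_table(cfg, 9))
})

test_that("independent exposures have pairwise odds ratios near 1", {
  cfg <- clean_config(n = 5e4,
                      marginal_prevalence = list(women = rep(0.5, 5), men = rep(0.5, 5)),
                      pairwise_log_odds = list(women = 0, men = 0))
  md <- simulate_exposures(cfg, seed = 21)
  types <- maltreatment_types()$type
  prs <- utils::combn(types, 2)
  ors <- apply(prs, 2, function(pr) {
    t <- table(md[[pr[1]]], md[[pr[2]]])
    (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  })
  # log-OR ~ N(0, 4/n_cell-ish); all 10 within 5 SD of 0
  se <- sqrt(4 / (5e4 / 4))
  expect_true(all(abs(log(ors)) < 5 * se))
  # marginals recover 0.5
  expect_true(all(abs(colMeans(as.matrix(md[types])) - 0.5) < 0.02))
})

test_that("a positive pairwise term induces a positive empirical association", {
  lo <- rep(0, 10)
  # pair (EA, EDV) = (3, 5) in combn(5, 2) ordering
  idx <- which(apply(utils::combn(5, 2), 2, paste, collapse = ",") == "3,5")
  lo[idx] <- 1.2
  cfg <- clean_config(n = 5e4, pairwise_log_odds = list(women = lo, men = lo))
  md <- simulate_exposures(cfg, seed = 22)
  t <- table(md$emotional_abuse, md$exposure_dv)
  or_emp <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  expect_gt(or_emp, 1.5)
  # and the empirical joint matches the exact cell probabilities
  gt <- ground_truth(cfg)
  exact <- gt$pattern_prevalence |>
    dplyr::filter(gender == "women", age_group == "40–44")
  emp <- prop.table(table(factor(md$pattern[md$gender == "women"],
                                 levels = exact$pattern)))
  expect_lt(max(abs(as.numeric(emp) - exact$proportion)), 0.02)
})

test_that("empirical 32-cell distribution converges to the exact table (TV < 0.01)", {
  cfg <- clean_config(n = 2e5)
  md <- simulate_exposures(cfg, seed = 23)
  gt <- ground_truth(cfg)
  for (g in c("women", "men")) {
    exact <- gt$pattern_prevalence |>
      dplyr::filter(gender == g, age_group == "40–44")  # no age effect: any band
    emp <- prop.table(table(factor(md$pattern[md$gender == g], levels = exact$pattern)))
    tv <- sum(abs(as.numeric(emp) - exact$proportion)) / 2
    expect_lt(tv, 0.01)
  }
})

test_that("null outcome model reproduces the baseline risk in every exposure group", {
  cfg <- clean_config(n = 5e4, outcomes = list(
    mdd = list(p0 = c(women = 0.2, men = 0.2), rr = rep(1, 6))
  ))
  md <- simulate_microdata(cfg, seed = 31)
  by_level <- tapply(md$mdd, md$n_types, mean)
  counts <- table(md$n_types)
  se <- sqrt(0.2 * 0.8 / as.numeric(counts))
  expect_true(all(abs(by_level - 0.2) < 4 * se))
})

test_that("configured dose-response is realised (level-5 vs level-0 risk ratio)", {
  md <- recovery_microdata()
  risk <- tapply(md$mdd, md$n_types, mean)
  rr_emp <- risk["5"] / risk["0"]
  expect_gt(rr_emp, 8)
  expect_lt(rr_emp, 12.5)
})

test_that("outcome probabilities above 1 are capped with a warning", {
  cfg <- clean_config(n = 2000, outcomes = list(
    mdd = list(p0 = c(women = 0.5, men = 0.5), rr = c(1, 1, 1, 1, 1, 10))
  ))
  md <- simulate_exposures(cfg, seed = 32)
  expect_warning(simulate_outcomes(md, cfg, seed = 33), "capped")
})

test_that("burden table satisfies its construction identities", {
  b <- simulate_burden_table(sim_config(), seed = 41)
  expect_true(all(b$daly - (b$yll + b$yld) == 0))
  nf <- b[b$cause %in% c("mdd", "anxiety"), ]
  expect_true(all(nf$deaths == 0) && all(nf$yll == 0))
  expect_true(all(b$burden_type[b$cause == "smoking"] == "attributable"))
  expect_true(all(b$burden_type[b$cause != "smoking"] == "total"))
  expect_true("10–14" %in% b$age_group)
  expect_true(all(b[c("deaths", "yll", "yld", "daly")] >= 0))
})

test_that("ground truth: independence config gives product-of-marginals cells", {
  p <- c(0.3, 0.25, 0.2, 0.1, 0.4)
  cfg <- clean_config(n = 10, marginal_prevalence = list(women = p, men = p),
                      pairwise_log_odds = list(women = 0, men = 0))
  gt <- ground_truth(cfg)
  cells <- gt$pattern_prevalence |>
    dplyr::filter(gender == "women", age_group == "20–24")
  flags <- as.matrix(parse_pattern(cells$pattern)[maltreatment_types()$type])
  expected <- apply(flags, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  expect_equal(cells$proportion, expected, tolerance = 1e-10)
})

test_that("ground-truth PAF matches independent arithmetic and is 0 under null RRs", {
  cfg <- clean_config(n = 10, outcomes = list(
    mdd = list(p0 = c(women = 0.1, men = 0.1), rr = rep(1, 6)),
    ptsd = list(p0 = c(women = 0.05, men = 0.05), rr = c(1, 2, 3, 4, 6, 10))
  ))
  gt <- ground_truth(cfg)
  expect_true(all(gt$paf$paf[gt$paf$outcome == "mdd"] == 0))
  # brute-force oracle: sum p (RR - 1) / (1 + sum p (RR - 1)) by hand
  cells <- gt$pattern_prevalence |>
    dplyr::filter(gender == "men", age_group == "55–59")
  rrs <- c(1, 2, 3, 4, 6, 10)[count_types(cells$pattern) + 1]
  excess <- sum(cells$proportion * (rrs - 1))
  expected <- excess / (1 + excess)
  got <- gt$paf$paf[gt$paf$outcome == "ptsd" & gt$paf$gender == "men" &
                    gt$paf$age_group == "55–59"]
  expect_equal(got, expected, tolerance = 1e-12)
})
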
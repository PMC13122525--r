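test_that("compute_paf matches hand-derived values and the TMREL identity", {
  expect_equal(compute_paf(c(0.5, 0.5), c(1, 3)), 0.5)
  expect_equal(compute_paf(c(0.8, 0.1, 0.1), c(1, 2, 4)), 0.4 / 1.4)
  expect_equal(compute_paf(c(0.8, 0.1, 0.1), c(1, 2, 4)),
               paf_oracle(c(0.8, 0.1, 0.1), c(1, 2, 4)), tolerance = 1e-9)
  expect_identical(compute_paf(rep(1 / 32, 32), rep(1, 32)), 0)
  expect_identical(compute_paf(c(1, rep(0, 31)), c(1, rep(5, 31))), 0)
})

test_that("compute_paf validates its inputs", {
  expect_error(compute_paf(c(0.5, 0.4), c(1, 2)), "sum to 1")
  expect_error(compute_paf(c(0.5, 0.5), c(2, 2)), "RR = 1")
  expect_error(compute_paf(c(0.5, 0.5), c(1, -2)), "non-negative")
  expect_error(compute_paf(c(0.5, 0.5), c(1, 2, 3)), "equal length")
})

test_that("compute_paf equals the enumerated-population counterfactual (1000 random draws)", {
  set.seed(1001)
  errs <- replicate(1000, {
    k <- sample(2:32, 1)
    p <- as.numeric(stats::rgamma(k, 1))
    p <- p / sum(p)
    rr <- c(1, stats::rlnorm(k - 1, 0.5, 0.6))
    abs(compute_paf(p, rr) - paf_oracle(p, rr))
  })
  expect_lt(max(errs), 1e-3)
})

test_that("PAF is monotone in RRs and in shifting mass to exposed categories", {
  set.seed(1002)
  for (i in 1:50) {
    p <- as.numeric(stats::rgamma(6, 1)); p <- p / sum(p)
    rr <- c(1, sort(stats::rlnorm(5, 0.5, 0.5) + 0.1))
    base <- compute_paf(p, rr)
    # raise one exposed RR
    j <- sample(2:6, 1)
    rr2 <- rr; rr2[j] <- rr2[j] * 1.5
    expect_gte(compute_paf(p, rr2), base)
    # move mass from unexposed to an exposed category with RR > 1
    k <- which(rr > 1)[1]
    if (p[1] > 0.05 && !is.na(k)) {
      p2 <- p; p2[1] <- p2[1] - 0.05; p2[k] <- p2[k] + 0.05
      expect_gte(compute_paf(p2, rr), base)
    }
  }
})

test_that("grouping patterns into levels is collapsible: level RRs = pattern RRs", {
  gt <- recovery_truth()
  prev <- gt$pattern_prevalence |>
    dplyr::filter(gender == "women", age_group == "30–34")
  level_rr <- c(1, 2, 3, 4, 6, 10)
  via_levels <- compute_paf(
    tapply(prev$proportion, count_types(prev$pattern), sum),
    level_rr
  )
  via_patterns <- compute_paf(prev$proportion, level_rr[count_types(prev$pattern) + 1])
  expect_equal(via_levels, via_patterns, tolerance = 1e-12)
})

test_that("paf_table pairs age-specific prevalence with shared RRs", {
  pats <- enumerate_patterns()$pattern
  mk_prev <- function(age_group, multi_mass) {
    tibble::tibble(gender = "women", age_group = age_group, pattern = pats,
                   proportion = dplyr::case_when(
                     pats == "00000" ~ 1 - 0.2 - multi_mass,
                     pats == "10000" ~ 0.2,
                     pats == "11111" ~ multi_mass,
                     TRUE ~ 0))
  }
  prev <- dplyr::bind_rows(mk_prev("20–24", 0.1), mk_prev("40–44", 0.3))
  rr <- tidyr::expand_grid(outcome = "mdd", gender = "women", level = as.character(0:5)) |>
    dplyr::mutate(rr = c(1, 2, 3, 4, 6, 10))
  paf <- paf_table(prev, rr, "count")
  # hand arithmetic: sum p(RR-1) = .2*1 + mass*9
  expect_equal(paf$paf[paf$age_group == "20–24"], (0.2 + 0.9) / (1 + 0.2 + 0.9))
  expect_equal(paf$paf[paf$age_group == "40–44"], (0.2 + 2.7) / (1 + 0.2 + 2.7))
  # more multi-type mass, monotone RRs => higher PAF
  expect_gt(paf$paf[paf$age_group == "40–44"], paf$paf[paf$age_group == "20–24"])

  # all mass unexposed => PAF 0 for every outcome
  prev0 <- mk_prev("20–24", 0); prev0$proportion[prev0$pattern == "10000"] <- 0
  prev0$proportion[prev0$pattern == "00000"] <- 1
  expect_equal(paf_table(prev0, rr, "count")$paf, 0)

  # missing RR level is an error naming it
  rr_missing <- rr[rr$level != "5", ]
  expect_error(paf_table(prev, rr_missing, "count"), "level")
})

test_that("PAF peaks where prevalence peaks (age trend flows through)", {
  gt <- recovery_truth()
  paf_w <- gt$paf[gt$paf$gender == "women", ]
  agg <- aggregate_prevalence(
    dplyr::filter(gt$pattern_prevalence, gender == "women"), "any")
  # with no age effect in the clean config the PAF profile is flat;
  # with the default age effect both peak in the same band
  cfg <- sim_config()
  gt2 <- ground_truth(cfg)
  paf2 <- gt2$paf[gt2$paf$outcome == "ptsd" & gt2$paf$gender == "women", ]
  any2 <- aggregate_prevalence(
    dplyr::filter(gt2$pattern_prevalence, gender == "women"), "any")
  expect_equal(paf2$age_group[which.max(paf2$paf)],
               as.character(any2$age_group[which.max(any2$proportion)]))
  expect_equal(paf2$age_group[which.max(paf2$paf)], "40–44")
})

test_that("aggregate_paf is the burden-weighted mean of age-specific PAFs", {
  paf <- tibble::tibble(outcome = "mdd", gender = "women",
                        age_group = c("20–24", "40–44"), paf = c(0.2, 0.8))
  w <- tibble::tibble(gender = "women", age_group = c("20–24", "40–44"),
                      weight = c(1, 3))
  expect_equal(aggregate_paf(paf, w)$paf, 0.65)
  # constant PAF: any weights give the constant
  pafc <- dplyr::mutate(paf, paf = 0.37)
  expect_equal(aggregate_paf(pafc, w)$paf, 0.37)
  # weights concentrated on one age: aggregate equals that age
  w1 <- dplyr::mutate(w, weight = c(0, 7))
  expect_equal(aggregate_paf(paf, w1)$paf, 0.8)
  # zero total weight errors
  w0 <- dplyr::mutate(w, weight = 0)
  expect_error(aggregate_paf(paf, w0), "zero total burden")
})
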
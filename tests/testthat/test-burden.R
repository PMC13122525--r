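mk_paf <- function(outcome, paf_w, paf_m = paf_w,
                   ages = c("20–24", "40–44")) {
  tidyr::expand_grid(outcome = outcome, gender = c("women", "men"), age_group = ages) |>
    dplyr::mutate(paf = ifelse(gender == "women", paf_w, paf_m))
}

mk_burden <- function(cause, deaths, yll, yld, ages = c("20–24", "40–44"),
                      burden_type = "total") {
  tidyr::expand_grid(cause = cause, gender = c("women", "men"), age_group = ages) |>
    dplyr::mutate(deaths = deaths, yll = yll, yld = yld, daly = yll + yld,
                  burden_type = burden_type)
}

test_that("attribute_cause scales each measure by the PAF and sums DALYs", {
  paf <- mk_paf("mdd", 0.5, 0.25)
  burden <- mk_burden("mdd", deaths = 0, yll = 0, yld = 100)
  att <- attribute_cause(paf, burden, "mdd")
  expect_equal(att$attributable_daly[att$gender == "women"], c(50, 50))
  expect_equal(att$attributable_daly[att$gender == "men"], c(25, 25))
  expect_equal(att$attributable_daly, att$attributable_yll + att$attributable_yld)
  expect_equal(att$share_of_cause, att$paf)

  # PAF 0 everywhere => zero attribution
  att0 <- attribute_cause(mk_paf("mdd", 0), burden, "mdd")
  expect_true(all(att0$attributable_daly == 0))

  # handcrafted two-stratum arithmetic with fatal burden
  paf2 <- mk_paf("suicide_attempt", 0.7, 0.6)
  b2 <- mk_burden("self_harm", deaths = 10, yll = 400, yld = 50)
  att2 <- attribute_self_harm(paf2, b2)
  expect_equal(att2$attributable_deaths[att2$gender == "women"], c(7, 7))
  expect_equal(att2$attributable_daly[att2$gender == "men"], c(0.6 * 450, 0.6 * 450))
})

test_that("burden strata below 15 get PAF zero; other unmatched strata error", {
  paf <- mk_paf("mdd", 0.5)
  b <- mk_burden("mdd", 0, 0, 100, ages = c("10–14", "20–24", "40–44"))
  att <- attribute_cause(paf, b, "mdd")
  expect_equal(att$paf[att$age_group == "10–14"], c(0, 0))
  expect_equal(att$attributable_daly[att$age_group == "10–14"], c(0, 0))
  b_bad <- mk_burden("mdd", 0, 0, 100, ages = c("20–24", "40–44", "60–64"))
  expect_error(attribute_cause(paf, b_bad, "mdd"), "60–64")
})

test_that("anxiety attribution blends PTSD and GAD PAFs by the PTSD share", {
  paf <- dplyr::bind_rows(mk_paf("ptsd", 0.8), mk_paf("gad", 0.5))
  b <- mk_burden("anxiety", 0, 0, 1000)
  # s = 0.3: 0.8 * 300 + 0.5 * 700 = 590
  att <- attribute_anxiety(paf, b, ptsd_share = 0.3)
  expect_equal(att$attributable_daly, rep(590, 4))
  expect_equal(att$cause, rep("anxiety", 4))
  # boundary shares reduce to single-outcome attribution
  expect_equal(attribute_anxiety(paf, b, 1)$attributable_daly, rep(800, 4))
  expect_equal(attribute_anxiety(paf, b, 0)$attributable_daly, rep(500, 4))
  expect_error(attribute_anxiety(paf, b, 1.2), "\\[0, 1\\]")
})

test_that("smoking attribution requires the attributable-burden flag", {
  paf <- mk_paf("smoking", 0.4)
  b_att <- mk_burden("smoking", 5, 100, 100, burden_type = "attributable")
  att <- attribute_smoking(paf, b_att)
  expect_equal(att$attributable_daly, rep(80, 4))
  expect_equal(attribute_smoking(mk_paf("smoking", 0), b_att)$attributable_daly,
               rep(0, 4))
  b_total <- mk_burden("smoking", 5, 100, 100, burden_type = "total")
  expect_error(attribute_smoking(paf, b_total), "attributable")
  expect_error(attribute_smoking(paf, dplyr::select(b_total, -burden_type)),
               "attributable")
})

test_that("summary shares follow hand arithmetic and the additivity identity", {
  paf <- mk_paf("mdd", 0.5)
  b_mdd <- mk_burden("mdd", 0, 0, 100)     # cause daly 200 per gender
  b_all <- mk_burden("all_causes", 0, 0, 1000)  # all daly 2000 per gender
  att <- attribute_cause(paf, b_mdd, "mdd")
  s <- summarise_attribution(list(att), dplyr::bind_rows(b_mdd, b_all))
  # single cause, PAF .5, cause = 10% of all DALYs => 5% of all DALYs
  expect_equal(s$total$pct_of_all_daly, c(5, 5))
  expect_equal(s$total$pct_of_studied_daly, c(50, 50))
  expect_equal(s$by_cause$share_of_cause, c(0.5, 0.5))
  # total equals the sum over causes by construction
  expect_equal(s$total$attributable_daly,
               tapply(att$attributable_daly, att$gender, sum)[c("women", "men")],
               ignore_attr = TRUE)
  # duplicated cause rows (double counting) are rejected
  expect_error(summarise_attribution(list(att, att), dplyr::bind_rows(b_mdd, b_all)),
               "double counting")
})

test_that("attribution is scale-equivariant and shares are scale-invariant", {
  md_paf <- mk_paf("mdd", 0.42, 0.3)
  b <- mk_burden("mdd", 2, 40, 60)
  b_all <- mk_burden("all_causes", 10, 500, 500)
  s1 <- summarise_attribution(list(attribute_cause(md_paf, b, "mdd")),
                              dplyr::bind_rows(b, b_all))
  k <- 7.5
  scale_b <- function(x) dplyr::mutate(x, deaths = deaths * k, yll = yll * k,
                                       yld = yld * k, daly = daly * k)
  s2 <- summarise_attribution(list(attribute_cause(md_paf, scale_b(b), "mdd")),
                              dplyr::bind_rows(scale_b(b), scale_b(b_all)))
  expect_equal(s2$total$attributable_daly, k * s1$total$attributable_daly)
  expect_equal(s2$total$pct_of_all_daly, s1$total$pct_of_all_daly)
  expect_equal(s2$by_cause$share_of_cause, s1$by_cause$share_of_cause)
})
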
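# cmburden

Comparative risk assessment of the disease burden attributable to child
maltreatment, treated as a single polytomous exposure.

## The problem

Five forms of child maltreatment — physical abuse (PA), sexual abuse (SA),
emotional abuse (EA), neglect (N) and exposure to domestic violence (EDV) —
strongly co-occur, and the risk of mental disorders and health-risk
behaviours rises with the number of types experienced. Adding up
single-exposure attributable burdens double-counts the overlap; ignoring
multi-type exposure understates the dose–response. `cmburden` implements the
attribution pipeline for the unified exposure: every respondent falls in
exactly one of the `2^5 = 32` mutually exclusive maltreatment patterns, and
burden is attributed against the counterfactual population with zero exposure
(the theoretical minimum risk exposure level, TMREL).

The pipeline, per gender:

1. **Joint prevalence** of the 32 patterns by 5-year age group, from a
   log-linear model of weighted cell counts (type main effects, all ten
   two-way type interactions, second-order fractional-polynomial age
   smoothing with default powers (0, 2): log age and age²) —
   `fit_joint_prevalence()`.
2. **Relative risks** per exposure level (count of types 0–5, or the six most
   common patterns), by log-binomial regression with a robust-Poisson
   fallback, simply or fully adjusted — `fit_rr()`.
3. **Population attributable fractions** per outcome × gender × age group:

   PAF = Σᵢ pᵢ(RRᵢ − 1) / (1 + Σᵢ pᵢ(RRᵢ − 1))

   with the 32 pattern proportions pᵢ paired with level RRs — `compute_paf()`,
   `paf_table()`.
4. **Attributable burden**: PAF × deaths/YLL/YLD per cause, with the anxiety
   aggregate split between PTSD and other anxiety disorders, suicide-attempt
   PAFs applied to the intentional self-harm envelope, and smoking PAFs
   applied to the smoking-*attributable* envelope (two-step chain) —
   `attribute_*()`, `summarise_attribution()`.
5. **Uncertainty** by Monte Carlo (default 2,000 iterations): Dirichlet draws
   of each stratum's pattern proportions, lognormal (jointly normal for
   fitted sets) draws of the relative risks, full recomputation per
   iteration, 95% intervals from the 2.5th/97.5th percentiles —
   `run_monte_carlo()`.

Because microdata of this kind are access-restricted, the package includes a
synthetic survey generator with exact exported ground truth
(`simulate_microdata()`, `ground_truth()`): exposures come from an exactly
enumerated 32-cell log-linear joint model, outcomes follow configurable
dose–response relative risks with confounding, and every estimator in the
pipeline is validated against the generating truth. Precomputed prevalence
and relative-risk tables (e.g. published estimates) can be supplied as CSVs
to bypass the estimation stages entirely (`run_pipeline()` "spreadsheet
mode").

## Worked example

```r
library(cmburden)

md   <- simulate_microdata(sim_config(), seed = 1)   # 8,377 respondents
prev <- fit_joint_prevalence(md)
rr   <- fit_rr(md, coding = "count", adjustment = "simply")
paf  <- paf_table(prev$table, rr, "count")

dplyr::filter(paf, outcome == "ptsd", age_group == "40–44")
#> # A tibble: 2 × 4
#>   outcome gender age_group   paf
#> 1 ptsd    women  40–44     0.715
#> 2 ptsd    men    40–44     0.778

burden <- simulate_burden_table(sim_config(), seed = 3)
mc <- run_monte_carlo(prev$table, rr, burden, ptsd_share = 0.25,
                      spec = uncertainty_spec(iterations = 2000, seed = 4))
mc$total
#> # A tibble: 2 × 4
#>   gender pct_of_all_daly lower upper
#> 1 women             7.27  6.72  7.75
#> 2 men               6.24  5.69  6.74
```

Reading: on this synthetic survey, 71.5% of PTSD risk among women aged 40–44
would be removed if nobody had experienced maltreatment, and maltreatment
accounts for 7.3% (95% UI 6.7–7.8) of all female DALYs in the synthetic
burden table. `tidy()` on a fitted `rr_fit` shows the dose–response, e.g.
suicide attempt in women rising from RR 1.81 (1 type) to 11.0 (95% CI
6.4–19.0; all 5 types). `autoplot()` methods draw the prevalence age trends,
the RR dose–response and the attributable-burden intervals.

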
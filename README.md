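# injurypheno

Data-driven dissection of injury events in matched case-control health
administrative data.

## The problem

Injury events such as traumatic brain injury (TBI) arise from the interplay
of the **host** (the injured person's health status), the **agent** (the
energy-transfer mechanism — a fall, a collision, an assault), and the
**environment** (the physical and social context) — the columns of the
Haddon Matrix. Hypothesis-driven surveillance struggles to enumerate these
jointly. `injurypheno` implements a data-driven alternative for 1:1 matched
case-reference cohorts built from ICD-10 coded hospital/ED records:

1. **Event window.** Visit frequency is histogrammed by day offset from the
   index date (first case-defining visit for cases; midpoint of the visit
   span for references). The event phase is the window outside of which the
   histogram settles at its baseline — canonically ±30 days, a 61-day
   window.
2. **Screening.** Every three-character diagnosis code (excluding the
   provisional categories U98/U99) becomes a binary variable and is tested
   against case status with the matched McNemar test on the discordant-pair
   counts *b*, *c*: exact two-sided binomial
   `p = min(1, 2·P(Bin(b+c, ½) ≤ min(b, c)))` for small `b+c`, else
   `χ² = (b−c)²/(b+c)`. The Benjamini–Yekutieli step-up procedure controls
   the FDR at q = 5% under arbitrary dependence — rank-*i* threshold
   `i·q / (m·H_m)` with `H_m = Σ 1/j`. Codes must additionally have matched
   OR `b/c > 1` and survive in *both* the training and validation splits.
3. **Phenotypes.** Retained codes are factor-analyzed by the
   principal-components method (eigendecomposition of their phi-coefficient
   matrix; loadings = eigenvectors × √eigenvalue). Factor count is chosen by
   the Kaiser rule, the scree breakpoint, cumulative variance, and/or a
   conditional-logistic AUC loop. A code joins every factor where
   |loading| ≥ 0.2; a patient scores 1 on a factor if they carry any of its
   codes.
4. **Designation & effect sizes.** Each factor is designated H, A, E, or a
   combination via an editable code-prefix map. Factor odds ratios with 95%
   CIs come from conditional logistic regression for matched pairs
   (equivalent to intercept-free logistic regression on within-pair
   differences), adjusting for age, rurality, and income quintile.
5. **Sex differences.** Per-sex factor correlation matrices (phi
   coefficients among cases) are compared with Fisher-transformed z-tests:
   `r′ = ½·ln((1+r)/(1−r))` with variance `1/(n−3)`;
   `z = (r′_F − r′_M)/√(1/(n_F−3) + 1/(n_M−3))`. The three hypothesis
   families (female, male, difference) are BY-masked separately so heatmaps
   show only correlations surviving FDR control, and factors are clustered
   with Ward linkage on the correlation distance `1 − r`.

Because the motivating data (Ontario health administrative records) are
access-restricted, the package ships a **synthetic matched-cohort
generator** with planted ground truth — latent factor blocks with known
case-vs-reference odds ratios, sex-specific latent correlations via a
Gaussian copula, and visit dates peaking at the index date — so every stage
is testable end to end.

## Worked example

```r
library(injurypheno)

# Stated world: 2,000 pairs/sex, six planted phenotypes (ORs 1.5-5),
# 200 null codes, and a female-dominant latent correlation (0.6 vs 0.1)
# planted between the falls/syncope and transport phenotypes.
tg  <- data.frame(f = "falls_syncope", g = "transport", rho_F = 0.6, rho_M = 0.1)
cfg <- simulation_config(correlation_targets = tg, seed = 42L)
cohort <- generate_cohort(cfg)

res <- suppressWarnings(run_pipeline(cohort, q = 0.05, split_seed = 1L))
res$window
#> event window: -31..+31 days around the index date (63 days)
res$screen
#> matched McNemar + BY screen (q = 0.05 )
#>            n_codes tested skipped_absent by_rejected or_gt_1 retained
#> training       220    220              0          20      19       19
#> validation     220    220              0          16      15       15
#> retained in both datasets: 15 codes
res$designations
#>   factor_id label       categories
#> 1       F01   H/A       host,agent
#> 2       F02   H/E host,environment
#> 3       F05     E      environment
res$association[order(-res$association$or),
                c("factor_id", "or", "ci_low", "ci_high")]
#>   factor_id       or   ci_low  ci_high
#> 2       F02 2.244604 1.837955 2.741225
#> 3       F05 1.924528 1.380987 2.682001
#> 1       F01 1.596774 1.329382 1.917950
```

Reading the output: the detector recovers the generator's ±30-day event
phase to within a day. Of 220 candidate codes, 15 survive the dual
McNemar + BY + OR>1 screen — the planted signal codes with odds ratios
large enough for this cohort size (the OR ≈ 1.5 cardiometabolic block is
correctly underpowered here, a feature of the method, not a bug). The
planted 0.6 female latent correlation makes the falls/syncope and
transport blocks load on one component, so they emerge as a single merged
host/agent phenotype (F01); the assault+geriatric codes form F02 and the
abuse codes F05, with conditional-logistic ORs attenuated from the latent
targets by the code-emission noise, each covered by its 95% CI.

Sex-specific correlation structure on the factor scores:

```r
case_scores <- function(sex) {
  ids <- cohort$patients$patient_id[cohort$patients$cohort_arm == "case" &
                                    cohort$patients$sex == sex]
  res$scores[intersect(rownames(res$scores), ids), ]
}
phi_F <- phi_matrix(case_scores("F"), sex = "F")  # phi, n as attribute
phi_M <- phi_matrix(case_scores("M"), sex = "M")
tests <- sex_corr_tests(phi_F, phi_M)             # Fisher z, three families
fdr_mask(tests, q = 0.05)$diff                    # BY-masked F-minus-M map
```

The word-cloud weight table (`wordcloud_weights`), the external-cause /
severity association maps (`build_cause_profiles`,
`cause_severity_matrix`, `mask_correlation_difference`), and ordered
numeric heatmap exports (`ward_linkage`, `export_heatmap`) follow the same
pattern; see the methods vignette (`vignettes/injury-event-dissection.Rmd`)
for the full account of the model and its assumptions.

A command-line interface wraps the main stages:

```sh
Rscript inst/cli/injurypheno.R simulate --out fixture/ --seed 3 --pairs 500
Rscript inst/cli/injurypheno.R screen --dir fixture/ --out screen.csv --q 0.05
Rscript inst/cli/injurypheno.R pipeline --dir fixture/ --out results/
```

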
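---
title: "Dissecting injury events in matched cohorts: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting injury events in matched cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurypheno)
```

# Scope and model

`injurypheno` re-implements, as a reusable and fully tested pipeline, a
data-driven procedure for characterizing what is happening *around* an
injury event in 1:1 matched case-reference cohorts drawn from coded
hospital and emergency-department records. The unit of analysis is the
matched pair (case and reference agree on sex, age, rurality, and income
quintile), and the raw material is the set of three-character ICD-10
diagnosis categories recorded in a window around each patient's index
date. All inference respects the matching: screening uses the matched
McNemar test, effect sizes come from conditional logistic regression, and
the discrimination measure is within-pair concordance.

This vignette documents the statistical model of each stage, the tunable
parameters with their defaults and units, what the synthetic generator
does and does not emulate, and the design choices made where the
procedure's published description left the design genuinely open.

# The event window

**Model.** Visits are histogrammed by integer day offset from the index
date. Cases anchor on their first case-defining visit; references, who
have no defining event, anchor on the midpoint of their visit span (floor
of the average of the earliest and latest visit days — a deterministic
tie-break for even spans). The event phase is the contiguous window around
offset 0 outside of which the histogram is statistically indistinguishable
from its baseline.

**Operationalization.** "Settles at baseline" is a visual notion in the
source procedure; `detect_event_window()` makes it testable:

* baseline = median of the counts in the outer third of the span
  (both tails pooled); spread = `mad()` of the same counts;
* scanning outward from 0 on each side, the boundary is the first offset
  whose count lies within `tolerance_k` (default 2) robust deviations of
  the baseline *and* from which at least `within_frac` (default 0.8) of
  the remaining counts out to the span edge also lie inside that band.

The fraction condition replaces the literal "all further offsets stay in
the band": with a band of ±2 robust deviations, roughly 5% of genuinely
baseline days fall outside it, so the all-points rule would almost surely
push the boundary to the span edge on any real histogram. Conversely a
single outlying day far from the peak should not drag the window out to
meet it; 0.8 balances the two failure modes and recovers a planted ±30-day
window within ±2 days in ≥95% of seeded replicates (see the test suite).

**Smoothing.** A centered moving average (`smooth_days`, odd) is
available, and `run_pipeline()` uses a 7-day average on empirical
histograms. It is *not* the default of the detector itself because a
k-day average widens a sharp stationary point by (k−1)/2 days — on a
noiseless histogram reaching baseline exactly at ±30 it would report ±33.
When smoothing is on, the tolerance band is still estimated from the *raw*
outer-third counts: a moving average both shrinks and serially correlates
the series, which biases a MAD taken on the smoothed values downward and
makes the band spuriously narrow. The smoothed series is used only for the
boundary condition.

The canonical result on administrative TBI data is a 61-day window
(30 + 30 + 1, inclusive coordinates); the degenerate flat histogram yields
a 1-day window by construction.

# Screening: matched McNemar + Benjamini–Yekutieli + OR filter

For each code, only discordant pairs are informative: `b` pairs where the
case carries the code and the reference does not, `c` the reverse. With
`b + c < exact_threshold` (default 25, standard small-sample practice) the
exact two-sided binomial p-value `min(1, 2·P(Bin(b+c, ½) ≤ min(b, c)))` is
used; otherwise the 1-df chi-square `(b − c)²/(b + c)` without continuity
correction (a `correct` flag exists; the source is silent on the
correction and the uncorrected statistic matches its large-sample
description). `b + c = 0` gives p = 1 by convention, and codes absent from
both arms are skipped entirely so they do not inflate the number of tests
`m`.

The BY procedure rejects the `k` smallest p-values where
`k = max{ i : p(i) ≤ i·q / (m·Σ_{j≤m} 1/j) }`. The harmonic constant is
what makes the procedure valid under arbitrary dependence among the
2,600-odd code tests — which are certainly dependent. (The typeset formula
in the source shows `Σ i` in the denominator; that constant would be
~`m/ln m` times smaller than the cited method's and is treated here as a
typesetting error for the standard harmonic sum.)

A code is retained if it is BY-significant *and* has matched OR
`b/c > 1` — the direction filter keeping case-enriched codes — in *both*
the training and validation partitions (pair-preserving random split,
default 50/25/25 with largest-remainder rounding). The matched
(discordant-pair) OR is used rather than the unconditional OR because it
is the design-consistent estimate under 1:1 matching; `b > 0, c = 0` is
reported as +Inf (passes the filter), `b = c = 0` as undefined (fails it).

The guarantee that matters operationally — mean false-discovery
proportion ≤ q across replicated cohorts — is verified by simulation in
the acceptance suite (200 cohorts of 2,000 pairs, 500 null + 50 OR-2
signal codes); BY under these conditions is strongly conservative (the
realized mean FDP is well under 1%).

# Factor construction

The retained codes' Pearson correlation matrix (phi coefficients, since
the variables are binary on a common scale — the reason the correlation
rather than covariance matrix is decomposed) is eigendecomposed; loadings
are eigenvector columns scaled by the square root of their eigenvalue,
with the sign convention that each column's dominant loading is positive.
No rotation is applied by default because the source names only "the
principal components method"; varimax is available behind a flag.

**Factor count.** Four criteria are implemented: Kaiser (eigenvalues > 1),
the scree breakpoint (position of the largest second difference of the
eigenvalue sequence), cumulative variance (smallest count reaching
`cum_var_target`, default 0.8), and an AUC loop (joint conditional
logistic fit on the first k factor scores, within-pair concordance AUC,
argmax over k). The final count is the median of the invoked criteria,
rounded up. A caution discovered during testing and preserved honestly:
the in-sample AUC loop is nearly non-decreasing in k, because additional
loading-defined code subsets refine the binary any-of scores even when no
new phenotype exists, so the argmax can overshoot; the median combiner
absorbs this. In the source, the final count (34) was also moderated by
interpretability — inherently manual, here exposed as the `n_factors`
override.

**Definitions and scores.** A code joins every factor on which its
absolute loading meets the cutoff (default 0.2, the conventional value);
negative loadings count because a reversed indicator is equally
informative for a set definition, and multi-membership is allowed because
the scoring rule is an unrestricted any-of. Factors whose code set
duplicates an earlier factor's are dropped with a warning (`dedupe =
TRUE`): exactly degenerate eigenvalue pairs — common with tight code
blocks — produce component pairs that select identical sets, which carry
no additional phenotype and merely duplicate every downstream row. Empty
factors are likewise dropped, and codes meeting no cutoff are reported as
unassigned. Patients score 1 on a factor if they carry at least one of its
codes.

# Haddon designation

Host/agent/environment designation is domain judgment, not computation.
`designate_factor()` categorizes each member code by the first matching
prefix in an ordered, fully editable map and renders the canonical label
(H, A, E, H/A, H/E, A/E, H/A/E — the latter two combinations beyond the
source's named pair are permitted so the true category set is never
silently coerced). The shipped default map is *illustrative*: disease and
symptom chapters A–R → host; transport/fall/strike external causes (V, W,
X00–X59) → agent; maltreatment, assault, care complications, and adverse
social circumstances (T74, X85–Y09, Y40–Y84, Z55–Z65) → environment;
unmatched codes default to host. Ambiguous ranges (notably drug
adversities Y40–Y59) are provisional and expected to be edited per study.

# Matched association

The 1:1 conditional likelihood reduces to intercept-free logistic
regression on within-pair (case − reference) differences with an all-ones
response; `fit_conditional_logit()` maximizes it by Newton–Raphson to
gradient norm < 1e-8. Covariates that are constant within every pair — the
matching variables under exact matching — have identically zero
differences; they are accepted in the interface (faithful to the stated
adjusted model, and meaningful under caliper or coarsened matching) but
dropped from the design with a note, since they provably cannot move the
estimate. Wald 95% intervals `exp(β ± 1.96·se)` are reported (the source
states no interval method); complete separation (all informative
differences of one sign) is flagged and reported as a ±Inf/0 OR rather
than silently Firth-corrected or thrown. For a single binary factor
without covariates the estimate collapses to `ln(b/c)` with
`se = √(1/b + 1/c)` — an identity the tests exploit as a closed-form
oracle, alongside agreement with `survival::clogit` under continuous
covariate adjustment. One model per factor is the default reporting mode
(matching the per-factor OR tables); the joint fit over all scores backs
the AUC loop.

# Sex differences in correlation structure

Pearson correlation of binary factor scores equals the phi coefficient;
matrices are computed among each sex's cases (the population whose
phenotype structure is being compared). Entries with |r| = 1 — possible on
degenerate synthetic fixtures — are clamped to ±(1 − 1e−12) and flagged
so the Fisher transform stays finite. With `r′ = ½·ln((1+r)/(1−r))` and
variance `1/(n − 3)` (n = the per-sex case count used to compute r, the
natural reading), the within-sex statistics are `z = r′·√(n−3)` and the
between-sex statistic `z = (r′_F − r′_M)/√(1/(n_F−3) + 1/(n_M−3))`, both
against the standard normal. The three hypothesis families — female,
male, difference — are BY-corrected *separately* by default, mirroring
the three stated test sets (a joint flag exists). Masked matrices keep the
raw `r` (or `r_F − r_M`) where significant and 0 elsewhere; per-sex
diagonals are fixed at 1, the difference diagonal at 0, so a positive cell
in the difference map always reads "stronger in females".

The nominal behaviour of the difference test on binary data is itself
verified: under independent latent-normal binaries (n = 200/sex) its
type-I error is 5% within ±1.5 points over 2,000 replicates, and its
p-values agree with a sex-label permutation oracle within Monte-Carlo
error.

# Clustering and association maps

Factors are clustered on the correlation distance `d = 1 − r` — the
simplest reading of "correlation-based distance"; the chord variant
`√(2(1−r))` is a monotone transform with the same merge order on tight
clusters — using Ward linkage in the "ward.D" convention (Lance–Williams
recurrence applied to the supplied distances as-is). That convention is
stated explicitly because the two common Ward variants differ on
non-Euclidean inputs; the implementation is backed by `stats::hclust` and
cross-checked in the tests against an independently written greedy
Lance–Williams agglomerator on all small fixtures. Heatmap exports are
numeric (value matrix, leaf orders, mask); square matrices reuse one tree
for both axes, and image rendering is deliberately left to dedicated
heatmap packages.

External-cause profiles flag falls (W00–W19), struck by/against (W20–W22,
W50–W52), motor-vehicle collisions (V02–V79), and assault (X85–Y09) from
any in-window visit; the ranges are an editable, illustrative
approximation of the standard injury matrix, flags are deliberately not
mutually exclusive, sports injuries require a user-supplied activity code
list (the published criteria are not reproduced), and unmapped
external-cause codes count as "other". Severity is accepted as a patient
table column (generator-assigned in synthetic data; real-data severity
classification rules are out of scope). The factor-by-cause/severity
association matrices then pass through the same Fisher/BY masking
machinery as the factor-factor maps.

# The synthetic generator: what a green test establishes

`generate_cohort()` emulates the *designed* features of the target data:

* exact 1:1 matching — covariates drawn once per pair and copied to both
  members; age from a young/old mixture (0.6·N(30, 12²) + 0.4·N(75, 8²),
  truncated to [0, 105]) so age-structured factors can be planted;
* latent phenotype blocks — per blueprint, a latent activation with
  reference probability `p_ref` and case probability
  `logit⁻¹(logit(p_ref) + ln OR)` (so `p_ref = 0.10, OR = 2` gives exactly
  2/11), member codes emitted with probability `q_on` given activation and
  `q_bg` otherwise, and independent noise codes at equal prevalence in
  both arms;
* sex-specific dependence — activations thresholded from correlated
  Gaussians; the `rho_F`/`rho_M` targets are correlations of the latent
  normals (checkable to ±0.05 at 5,000 pairs), applied to both arms, with
  infeasible (non-positive-definite) target sets rejected by name;
* visit timing — an anchor visit on the index date (cases carry the
  concussion code S06.0 there) plus Poisson extra visits at offsets
  weighted by a linear peak (default 10× baseline, decaying to baseline at
  ±30 days over a ±90-day span).

Defaults are the package's stated testing world: 2,000 pairs per sex, six
blueprints with ORs 1.5–5 and reference activations 2–15%
(`q_on = 0.9, q_bg = 0.02`), 200 noise codes at 5% prevalence, and a
female-dominant correlation (0.6 vs 0.1) between the falls/syncope and
cardiometabolic phenotypes. These were chosen once as plausible
administrative-data magnitudes and are not tuned to test outcomes; the
deliberately weak OR = 1.5 block is *expected* to fail screening at this
scale.

What the generator does **not** emulate — and hence what no green test
establishes: realistic marginal frequency distributions of actual ICD-10
code inventories, within-patient comorbidity dependence beyond the planted
blocks, healthcare-utilization dynamics outside the event window, coding
errors, or the sheer scale (hundreds of thousands of patients) of the
motivating study. Recovery results on synthetic cohorts validate the
*machinery*, not any substantive epidemiological claim.

One interaction worth knowing: the generator stamps the case-defining
anchor code on every case, so that code is perfectly case-discriminating
by construction; `run_pipeline()` therefore excludes the case-defining
categories (S02/S04/S06/S07 by default, configurable) from the screened
universe, exactly as the outcome definition is not a predictor in the
motivating design. Similarly, planting a strong latent correlation between
two blueprints can legitimately merge them into a single factor — the
factor-analytic model has no way, and no reason, to distinguish one
correlated phenotype from two.

# Numerical choices and degenerate inputs

* BY thresholds and adjusted p-values are computed in closed form; the
  adjusted values equal `stats::p.adjust(method = "BY")` (test oracle).
* Eigenvalues are floored at 0 before the square root; zero-variance code
  columns are an error in `fit_pca_factors` (they have no correlation) but
  zero-variance *factors* are excluded with a warning in `phi_matrix`
  (routine on subsets).
* Newton–Raphson: start β = 0, ≤50 iterations, gradient tolerance 1e-8;
  a singular Hessian stops iteration with `converged = FALSE`.
* Ward ties break by `stats::hclust`'s deterministic ordering; merge
  heights are asserted monotone.
* Seeds: one master seed per simulation config, split into fixed per-stage
  substreams (codes, covariates, visits) so each table is independently
  reproducible; helper RNG use is wrapped so the caller's RNG state is
  never clobbered.
* Dates are integer day offsets; the event window is inclusive on both
  ends (hence 61 = 30 + 30 + 1).

# Known limitations

* The AUC factor-count criterion is in-sample and optimistic; prefer the
  combined criteria or an explicit override.
* Wald intervals degrade near separation; profile likelihood is not
  implemented (flagged ORs make the cases visible).
* The Fisher variance `1/(n−3)` is exact for bivariate normal data and
  only approximate for phi coefficients; the approximation is validated at
  the package's working sample sizes (n ≥ ~200 per sex) but should not be
  trusted for very small strata.
* The default Haddon map and external-cause ranges are illustrative
  stand-ins for judgment-based and licensed classifications respectively;
  both are plain-text editable and should be reviewed per study.
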
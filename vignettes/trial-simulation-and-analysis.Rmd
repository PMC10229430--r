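---
title: "Simulating and analysing beta-cell dose-response trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing beta-cell dose-response trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosedi)
```

## The scientific problem

In people with type 2 diabetes, beta-cell function must be judged relative to
the prevailing insulin sensitivity: a given insulin secretion rate (ISR) means
something very different in an insulin-resistant and an insulin-sensitive
person. The **disposition index** (DI), the product of a glucose-normalized
secretion measure and a sensitivity measure, captures this. `dosedi`
implements, end to end, the computational pipeline of a four-arm randomized
trial asking whether adding exercise — at two weekly doses — to diet-induced
weight loss improves the late-phase DI measured during a three-stage
hyperglycemic clamp, with a mixed meal tolerance test (MMTT) providing oral
analogues.

Because individual-level trial data of this kind are not publicly available,
the package is built around a **synthetic cohort generator with known ground
truth**: every derived quantity (deconvolved ISR, sensitivity index, DI,
glucose turnover, treatment effects, mediated fractions) can be checked
against the latent truth that generated the data.

## The synthetic cohort

Each participant carries two latent physiologic factors:

* `s_i` — insulin sensitivity, the glucose disposal rate per unit of
  circulating insulin times glucose, geometric mean `3.6e-4`
  (mg/kg/min)/(pmol/l x mmol/l);
* `isr_amp` — secretory amplitude, a dimensionless multiplier on the whole
  insulin-secretion response, geometric mean 1.

Both are log-normal between subjects (default CV 0.40) with an additional
within-subject visit-to-visit perturbation (default CV 0.25); these defaults
reproduce the between-subject spread (CV ≈ 0.6 for the DI) and the
change-score log-SD (≈ 0.5) implied by a trial of this design at n ≈ 20/arm.
Arm effects enter *only* as multiplicative follow-up/baseline ratios on the
two factors. The default sensitivity ratios across
CON/DCON/MED/HED are 1 / 1.18 / 1.50 / 1.83 (the trial-scale secondary
outcome), and the secretion ratios are chosen so that the product — the true
DI ratio — equals 1 / 1.58 / 2.05 / 2.37, i.e. increases of 58 / 105 / 137%
(the trial-scale primary outcome). Weight changes default to 0 / −7 / −10 /
−12% with a 1.5% individual SD; dropout is missing-completely-at-random at
probability 5/82.

The fasting state is *closed over* the latent physiology rather than drawn
independently: fasting glucose rises as secretion and sensitivity fall
(exponents −0.2 and −0.1), while fasting insulin and C-peptide scale with
secretory amplitude and with insulin resistance (`s_i` exponents −0.6 and
−0.3). Fasting C-peptide is tied to fasting insulin through a tight molar
ratio (CV 0.10), because the two are co-secreted. This closure is what makes
clamp-derived and meal-derived indices share the latent signal, as they do in
real cohorts.

### The clamp simulator

`simulate_clamp()` produces the full three-stage record on a 0.5-min internal
grid: a 120-min tracer equilibration, a 15-min square-wave glucose infusion
raising glucose 5.4 mmol/l above fasting (the follow-up visit clamps at the
*baseline* absolute level), steady hyperglycemia held by a
proportional–integral controller updated every 5 min on measured glucose
(velocity-form gains 2.0 and 0.2x5, chosen so the noiseless trace reaches
target within 20 min without oscillation), GLP-1 infusion from 120 min, and an
arginine bolus at 180 min.

Three deliberate identities make the measured indices exact in the noiseless
limit:

1. glucose disposal above the non-insulin-mediated uptake is purely
   insulin-mediated (`s_i * I * G`), and endogenous glucose production decays
   (time constant 25 min) to exactly that constant uptake, so the late-phase
   steady state satisfies GIR = `s_i * I * G` and the clamp ISI recovers
   `s_i` exactly (small renal-spill and transient residuals < 2%);
2. the whole true ISR curve scales with `isr_amp`, and the clamp glucose
   level is the same at both visits, so the glucose-normalized late-phase ISR
   scales with `isr_amp`;
3. the single glucose pool is the Steele effective pool (p x V = 0.65 x 145
   ml/kg), and the tracer infusion mass is included in the balance, so the
   non-steady-state tracer equations are exact on generator data up to
   smoothing error.

The true ISR shape is a basal rate (from the visit's fasting C-peptide) plus
a blunted first-phase Gaussian (peak at 4 min), a logistic late-phase rise to
a plateau of 6.7x the stimulated reference, a 2.5-fold smooth GLP-1
amplification and a large 10-min arginine spike — reproducing the
characteristic phase ordering (arginine > GLP-1 > late phase > first phase in
this population). The *stimulated* scale derives from the participant's
reference C-peptide (beta-cell mass) while the *basal* rate follows the
resistance-driven fasting state; without this split, the fall in fasting
C-peptide that accompanies improving sensitivity would attenuate the measured
secretion ratio relative to the configured truth.

C-peptide is the exact forward two-compartment convolution of the true ISR
(closed-form step responses, no ODE integration error); insulin follows
secretion with a 1/0.15 min turnover; enrichment is simulated as the tracer
mole fraction from the one-pool mass balance with a fasting-glucose-scaled
prime. Measurement noise is multiplicative log-normal with geometric mean 1,
CV 5% for hormone assays and 2% for glucose and enrichment (plasma-glucose
analyzers and isotope-ratio measurements are substantially more precise than
immunoassays; a 5% glucose error would also make the closed-loop controller
unrealistically jittery).

### The meal-test simulator

`simulate_mmtt()` uses a small feedback model: gamma-shaped meal glucose
appearance (700 mg/kg absorbed, peak at 40 min — calibrated so the baseline
cohort's 0–120-min glucose tAUC is ≈ 27 mmol/l x h), insulin-mediated
disposal, insulin-suppressed endogenous production, and glucose-driven
secretion `amp * (isr_b + 1.35 * isr_stim * (G - G_fasting))` fed through the
same C-peptide kinetics. GLP-1, GIP and paracetamol are deterministic
response curves with the conventional shapes and scales. Doubling the true
secretion amplitude reduces the glucose incremental AUC by roughly a third
under this feedback — the generator's own ODE defines that expectation.

### What the generator does not emulate

Medication titration dynamics, diet adherence, training physiology,
accelerometry, assay drift, circadian effects and visit-scheduling artifacts
are all outside the model; arm effects are purely multiplicative latent
ratios. Passing tests therefore demonstrate that the *pipeline* recovers
known truth under realistic noise — not that the physiologic model would fit
any individual patient's traces.

## The derivation layer

* **C-peptide kinetics** (`cpeptide_population_params()`): standard
  population two-compartment constants — short half-life 4.52/4.55/4.95 min
  and short-phase fraction 0.78/0.78/0.76 for type-2-diabetic/obese/lean
  status, long half-life `0.14 x age + 29.2` min, distribution volume
  `1.92 x BSA + 0.64` l (DuBois surface area). These are config data, not
  hard-coded truth: `overrides` replaces any field.
* **Deconvolution** (`deconvolve_isr()`): non-negative Tikhonov with a
  second-difference penalty on the sampling grid, solved by non-negative
  least squares on the stacked system. The penalty is scaled by the mean
  squared column norm of the design so `lambda_reg` is dimensionless; the
  `"auto"` default picks the smallest penalty whose residual matches the
  assumed 5% measurement CV (discrepancy principle, 30-step bisection on a
  log grid). Secretion before the first sample is assumed at steady state
  with the first interval's rate.
* **Clamp indices**: time-weighted (trapezoid) window means over the phase
  windows 0–10, 90–120, 120–180, 180–190 min; ISI = GIR / (insulin x
  glucose); DI = normalized ISR x ISI, exactly. GIR is not corrected for
  urinary glucose by default (the protocol measured urine glucose but does
  not state that GIR was corrected); `urinary = "subtract"` distributes the
  measured total as a constant rate, floored at zero.
* **Tracer turnover** (`steele_nonsteady()`): single-pool non-steady-state
  equations in tracer-to-tracee-ratio form with p = 0.65, V = 145 ml/kg.
  Enrichment is stored as the tracer mole fraction E in (0,1); z = E/(1−E)
  and the tracee concentration is C(1−E), so the basal identity is
  Ra = F(1−E)/E. Derivatives come from 5-point local linear fits (bandwidth
  two sampling intervals), which leave truly steady segments unbiased.
  Basal summaries use the equilibrated −60 to −20 min window: the prime
  transient (early) and the smoothing window crossing the start of
  hyperglycemia (late) are excluded.
* **Meal indices**: trapezoid tAUC/iAUC in concentration x hours (negative
  increments retained); the Matsuda index with the full four-term product
  under the square root and unit conversions (18.0156 (mg/dl)/(mmol/l), 6.00
  (pmol/l)/(uU/ml)) from one constants table; oral secretion as
  insulin-AUC/glucose-AUC (a secretion measure must increase with insulin;
  `invert` gives the reciprocal convention) or the insulinogenic index; oral
  DI for both variants.

## The statistical layer

`fit_clda()` is a constrained-baseline longitudinal analysis: the baseline is
part of the outcome vector with a common mean across arms (valid under
randomization), treatment is coded 0 for all groups at baseline, and the
within-participant covariance over the two visits is unstructured (which
nests the random-intercept model). Estimation is direct maximum likelihood of
the bivariate normal with the fixed effects profiled by GLS at each
covariance evaluation; participants missing follow-up contribute their
baseline through the marginal likelihood. With complete data the treatment
estimates coincide with baseline-adjusted ANCOVA, and the tests cross-check
the full fit against `nlme::gls` (ML, `corSymm` + `varIdent`). Outcomes are
log-transformed by default and back-transformed to geometric-mean-ratio
percentage changes. Wald tests use the t/F distribution with residual
degrees of freedom (number of follow-ups minus number of coefficients); no
small-sample covariance correction is applied. Under the global null the
per-pair type-I error is ≈ 5–6% and the dose-trend p-value is uniform (both
verified by the 1,000-replicate calibration test).

Inference mirrors the trial's prespecified strategy: a global Wald F-test of
the three treatment coefficients gated at P < 0.1, then the six pairwise
hypotheses in the fixed order HED–CON, MED–CON, DCON–CON, HED–DCON,
MED–DCON, HED–MED, confirmatory until the first p-value above 0.05 and
descriptive from that point on; no other multiplicity correction. The dose
trend refits the model with the treatment category as a continuous 0–3
score. Sparse binary endpoints use a plain 2x2 odds ratio with the
treatment-arm continuity correction (each cell of group g gets
n_g/(n_A+n_B) when a zero cell occurs) and a Wald interval — exact
conditional logistic regression is deliberately out of scope.
`mi_sensitivity()` imputes missing change scores by Bayesian linear
regression on arm, sex and baseline and pools by Rubin's rules;
`contrast_power()` computes noncentral-t power for a mean contrast (the
design contrast (1, 0, 0, −1) on means (1.5, 1.0, 0.5, 0.0) with SD 1.5 and
20/group gives 87.7%).

## Mediation

`mediate_effect()` partitions a two-arm treatment effect into the average
causal mediation effect through a mediator (weight change, in the trial's
question) and the average direct effect, using linear change-score models
with no treatment–mediator interaction: ACME = a x b, ADE = c′, and
ACME + ADE equals the unadjusted total effect exactly (an OLS identity, so
additivity holds to numerical precision). With two visits and a person-level
mediator this change-score formulation gives the same point decomposition as
a mixed-model formulation. Uncertainty comes from a nonparametric bootstrap
over participants, resampled within arm so both arms always remain
represented (2,000 resamples by default), with bias-corrected and
accelerated intervals; the acceleration is the jackknife skewness. BCa
intervals carry O(1/n) coverage error: in our experiments coverage is ≈ 93%
at 100–200 participants and ≈ 94–95% at 500, so the coverage test runs at
250/arm, where the asymptotic statement is actually testable, while smaller
samples are exercised for point recovery.

## Problem sizes used by the test suite

The statistical calibration and effect-recovery experiments simulate at the
outcome level — latent per-visit truth plus measurement noise feeding
`fit_clda()` directly — which is the appropriate resolution for testing the
inference layer (200 trials for effect recovery, 1,000 replicates for
calibration). The trace-level chain (simulate → deconvolve → index → analyze)
is validated separately and deterministically: with noise switched off, the
geometric-mean DI ratio derived from raw traces must match the configured
truth within 3% per arm, and the full pipeline (`run_pipeline()`) is run
end-to-end at a reduced cohort size with byte-identical reproducibility
checks. The BCa coverage experiment uses 500 datasets of 250/arm with 999
resamples.

## Known limitations

* The fasting-state closure uses fixed power-law exponents; they are
  calibrated to reproduce direction and rough magnitude of fasting changes,
  not fitted to data.
* The PI controller is a generic design; a site's actual clamp algorithm
  will differ in transient behavior (the first-phase GIR here is ~8
  mg/kg/min versus ~10.6 in the trial's tables).
* Single-pool Steele only; two-pool or circulatory tracer models are out of
  scope, as is an enriched ("hot") glucose infusate — the infused glucose is
  assumed unlabeled, which changes the EGP identity if false.
* Population C-peptide kinetics only; no individual kinetic fitting from
  bolus experiments.
* The mediation layer offers a single mediator and no sensitivity analysis
  for sequential ignorability.

## A minimal run

```{r example, eval = FALSE}
cfg <- trial_config(n_per_arm = 20)
out <- run_pipeline(cfg, out_dir = "run1", seed = 1)

sim <- simulate_trial(cfg, seed = 1)
der <- derive_indices(sim)
rep <- analyze_trial(der$indices, sim$participants, outcome = "di")
print(rep)
autoplot(rep)
```
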
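# dosedi

Simulation and analysis of four-arm diet/exercise dose-response trials of
beta-cell function in type 2 diabetes.

## What problem this solves, and for whom

Trials probing whether lifestyle interventions restore beta-cell function
measure it as the **disposition index (DI)** — insulin secretion adjusted for
the prevailing insulin sensitivity — during a hyperglycemic clamp, with a
mixed meal tolerance test (MMTT) providing oral analogues. Reproducing such a
trial's computational pipeline requires many interlocking pieces: C-peptide
deconvolution into insulin secretion rates, phase-windowed clamp indices,
stable-isotope glucose turnover, a constrained-baseline longitudinal model
with gatekeeping inference, and causal mediation through weight change.
Individual-level data from these trials are typically not shareable, so none
of those pieces can be verified against the original cohort.

`dosedi` is for trial statisticians and metabolism researchers who need that
pipeline as tested, reusable code. Its core is a **synthetic cohort generator
with known ground truth**: a four-arm trial (standard care CON, calorie
restriction DCON, restriction + exercise 3x/week MED, restriction + exercise
6x/week HED; ~20 participants/arm; baseline and 16-week follow-up) whose
latent physiology drives simulated clamp and meal-test time series, so every
downstream estimate can be checked against the truth that generated it.

## The quantities at the core

* **ISR(t)** — insulin secretion rate, reconstructed from plasma C-peptide by
  non-negative Tikhonov deconvolution of the two-compartment kinetic model
  (population parameters; `dq1/dt = −(k01+k21)q1 + k12 q2 + ISR·W`,
  `c = q1/V`).
* **ISI** — clamp insulin sensitivity index, `GIR / (insulin × glucose)` over
  the late phase (90–120 min of hyperglycemia).
* **DI = ISR_norm × ISI**, with ISR normalized to ambient glucose — the
  primary outcome, analyzed as change from baseline.
* **Ra, Rd, EGP** — glucose appearance/disappearance and endogenous glucose
  production from Steele's non-steady-state equations in tracer-to-tracee
  ratio form: `Ra = (F − pV·C_t·dz/dt)/z`, `EGP = Ra − GIR`.
* **Oral indices** — Matsuda index `10,000/√(FG·FI·Ḡ·Ī)`, insulinogenic
  index, insulin/glucose AUC ratio, oral DI.
* **Treatment effects** — a constrained-baseline longitudinal model (cLDA; the
  baseline is part of the outcome vector with a common mean across arms) on
  log-transformed outcomes, back-transformed to geometric-mean-ratio %
  changes; Wald dose trend; global test gated at P < 0.1 followed by six
  fixed-sequence pairwise hypotheses; ACME/ADE mediation through weight
  change with BCa bootstrap intervals.

## Worked example

Simulate a trial at the default configuration (true DI ratios 1 / 1.58 /
2.05 / 2.37 across CON / DCON / MED / HED), fit the log-scale cLDA and read
the gatekept comparison report:

```r
library(dosedi)

cfg <- trial_config(n_per_arm = 20)
coh <- apply_missingness(generate_cohort(cfg, seed = 7), seed = 8)
d   <- simulate_outcome_data(coh, "di", seed = 9)
fit <- fit_clda(d)                     # log scale, adjusted for sex
gatekeep_report(fit, trend = trend_test(d))
#>          pair pct_change pct_low pct_high  p.value       status
#> 1  HED vs CON      120.4   63.71    196.6 1.27e-06 confirmatory
#> 2  MED vs CON       79.4   33.30    141.5 2.01e-04 confirmatory
#> 3 DCON vs CON       16.3  -13.95     57.2 3.21e-01  descriptive
#> 4 HED vs DCON       89.5   39.64    157.1 8.39e-05  descriptive
#> 5 MED vs DCON       54.3   13.70    109.3 6.01e-03  descriptive
#> 6  HED vs MED       22.8   -9.11     65.9 1.78e-01  descriptive
#> global p: 1.89e-06   trend p: 1.23e-07
```

Reading: in this simulated replicate the high-dose arm's DI increased 120%
(95% CI 64 to 197) more than standard care. The global test passes its 0.1
gate; the first two hypotheses in the prespecified sequence are confirmatory;
the third (DCON vs CON, p = 0.32) fails its 0.05 step, so it and everything
after it are descriptive only. One replicate at n = 20/arm scatters widely
around the configured truth (137% / 105% / 58%) — averaging the estimator
over 200 replicates recovers it (see below).

The full trace-level pipeline — clamp and MMTT time series, deconvolution,
turnover, indices, reports, run manifest — is one call:

```r
run_pipeline(trial_config(n_per_arm = 20), out_dir = "run1", seed = 1)
```

and the design power of the primary contrast:

```r
100 * contrast_power(c(1.5, 1.0, 0.5, 0.0), c(1, 0, 0, -1),
                     sd = 1.5, n_per_group = 20)
#> 87.7
```

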
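test_that("degenerate noise with unit ratios gives identical visits", {
  cfg <- trial_config(
    n_per_arm = 3, cv_between = 0, cv_within = 0, dropout_prob = 0,
    effect_ratio = list(isi = c(CON = 1, DCON = 1, MED = 1, HED = 1),
                        isr = c(CON = 1, DCON = 1, MED = 1, HED = 1)),
    weight_change = c(CON = 0, DCON = 0, MED = 0, HED = 0)
  )
  coh <- generate_cohort(cfg, seed = 2)
  tr <- coh$truth
  bl <- tr[tr$visit == "baseline", ]
  fu <- tr[tr$visit == "followup", ]
  expect_equal(bl$s_i, fu$s_i)
  expect_equal(bl$isr_amp, fu$isr_amp)
  expect_equal(bl$di_true, fu$di_true)
  # all participants share the same latent truth when cv_between = 0
  expect_equal(length(unique(round(bl$s_i, 12))), 1)
})

test_that("generator geometric-mean ratios match the configured effects", {
  # effect fidelity at large n: within 1% of the configured ratios
  # (40,000 participants so the Monte-Carlo error is well inside the band)
  cfg <- trial_config(n_per_arm = 10000, dropout_prob = 0)
  coh <- generate_cohort(cfg, seed = 5)
  tr <- coh$truth
  wide <- tidyr::pivot_wider(tr[, c("participant_id", "group", "visit", "di_true")],
                             names_from = visit, values_from = di_true)
  gm <- tapply(log(wide$followup / wide$baseline), wide$group, mean)
  ratios <- exp(gm - gm[["CON"]])
  truth <- cfg$effect_ratio$isi * cfg$effect_ratio$isr
  expect_equal(as.numeric(ratios), as.numeric(truth / truth[["CON"]]),
               tolerance = 0.01)
  # the default DI effects are the trial's reported 58/105/137% increases
  expect_equal(unname(round(100 * (truth[c("DCON", "MED", "HED")] - 1))),
               c(58, 105, 137))
})

test_that("mean weight changes match the configured arm effects", {
  cfg <- trial_config(n_per_arm = 800, dropout_prob = 0)
  coh <- generate_cohort(cfg, seed = 9)
  tr <- coh$truth
  wide <- tidyr::pivot_wider(tr[, c("participant_id", "group", "visit", "weight")],
                             names_from = visit, values_from = weight)
  chg <- tapply(wide$followup / wide$baseline - 1, wide$group, mean)
  expect_lt(max(abs(chg - cfg$weight_change)), 0.0025)
})

test_that("dropout is MCAR with the right expectation and spares baseline", {
  cfg <- trial_config(n_per_arm = c(CON = 20, DCON = 21, MED = 20, HED = 21),
                      dropout_prob = 5 / 82)
  coh <- generate_cohort(cfg, seed = 3)

  none <- apply_missingness(coh, dropout_prob = 0, seed = 1)
  expect_equal(nrow(none$truth), nrow(coh$truth))

  n_drop <- vapply(1:1000, function(i) {
    length(apply_missingness(coh, seed = i)$dropped)
  }, numeric(1))
  expect_equal(mean(n_drop), 5, tolerance = 0.15)

  miss <- apply_missingness(coh, seed = 12)
  d <- simulate_outcome_data(miss, "di", seed = 1)
  expect_true(all(miss$dropped %in% d$participant_id[d$visit == 0]))
  expect_false(any(miss$dropped %in% d$participant_id[d$visit == 1]))
})

test_that("profiles respect the eligibility and marginal constraints", {
  coh <- generate_cohort(trial_config(n_per_arm = 50), seed = 8)
  p <- coh$profiles
  expect_true(all(p$bmi > 27 & p$bmi < 40))
  expect_true(all(p$fasting_glucose > 0 & p$fasting_insulin > 0 &
                    p$fasting_cpeptide > 0))
  expect_equal(mean(p$sex == "F"), 0.35, tolerance = 0.01)
  # permuted blocks leave at most a +-1 imbalance from partial blocks
  expect_true(all(abs(table(p$group) - 50) <= 1))
})

test_that("cohort generation is deterministic under a fixed seed", {
  c1 <- generate_cohort(trial_config(n_per_arm = 4), seed = 42)
  c2 <- generate_cohort(trial_config(n_per_arm = 4), seed = 42)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$truth, c2$truth)
})
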
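test_that("noiseless clamp tracks the target and scales with the truth", {
  pp <- make_participant(seed = 4)
  rec <- simulate_clamp(pp$profile, pp$latent, seed = 1, noise = FALSE)
  target <- pp$profile$fasting_glucose + 5.4
  late <- rec[rec$time >= 90 & rec$time <= 120, ]
  # reaches target within 20 min and stays within 10% during the late phase
  expect_lt(abs(rec$glucose[rec$time == 20] - target) / target, 0.10)
  expect_true(all(abs(late$glucose - target) / target < 0.10))

  # controller steady state is linear in sensitivity: GIR balances
  # s_i * insulin * glucose, so the measured sensitivity index doubles when
  # the latent sensitivity doubles (fasting insulin adapts with it, so raw
  # GIR scales with s_i at the prevailing insulin)
  lat2 <- pp$latent; lat2$s_i <- 2 * lat2$s_i
  lat2$clamp_target <- NULL          # re-anchor to this latent state
  rec2a <- simulate_clamp(pp$profile, lat2, seed = 1, noise = FALSE)
  expect_equal(clamp_isi(rec2a) / clamp_isi(rec), 2, tolerance = 0.06)
  ins_glc <- window_mean(rec2a, "insulin", c(90, 120)) *
    window_mean(rec2a, "glucose", c(90, 120))
  expect_equal(window_mean(rec2a, "gir", c(90, 120)),
               2 * pp$latent$s_i * ins_glc, tolerance = 0.06)

  # phase structure of the true secretion: arginine peak > GLP-1 peak >
  # late-phase plateau
  tr <- attr(rec, "truth")
  mean_in <- function(a, b) {
    mean(tr$isr_t[tr$t_grid >= a & tr$t_grid <= b])
  }
  expect_gt(max(tr$isr_t[tr$t_grid >= 180]), max(tr$isr_t[tr$t_grid >= 120 &
                                                            tr$t_grid < 180]))
  expect_gt(max(tr$isr_t[tr$t_grid >= 120 & tr$t_grid < 180]),
            max(tr$isr_t[tr$t_grid >= 60 & tr$t_grid < 120]))
  expect_gt(mean_in(180, 190), mean_in(120, 180))
})

test_that("deconvolution recovers the generator's true late-phase secretion", {
  pp <- make_participant(seed = 4)
  rec <- simulate_clamp(pp$profile, pp$latent, seed = 1, noise = FALSE)
  tr <- attr(rec, "truth")
  prm <- tr$kparams
  dec <- deconvolve_isr(rec$time, rec$cpeptide, prm, pp$latent$weight,
                        lambda_reg = 1e-3)
  true_late <- mean(tr$isr_t[tr$t_grid >= 90 & tr$t_grid <= 120])
  expect_equal(phase_response(dec, c(90, 120), "mean"), true_late,
               tolerance = 0.05)
})

test_that("basal enrichment settles at the tracer dilution steady state", {
  pp <- make_participant(seed = 4)
  # long equilibration, no noise: E -> F / (F + EGP_true)
  proto <- clamp_protocol(basal_minutes = 420)
  rec <- simulate_clamp(pp$profile, pp$latent, protocol = proto,
                        seed = 1, noise = FALSE)
  e_end <- rec$enrichment[rec$time == -10]
  e_expect <- 0.04 / (0.04 + pp$latent$egp_basal)
  expect_equal(e_end, e_expect, tolerance = 0.01)
  expect_equal(basal_ra(0.04, e_end), pp$latent$egp_basal, tolerance = 0.01)
})

test_that("clamp record respects its contracts and is seed-deterministic", {
  pp <- make_participant(seed = 6)
  r1 <- simulate_clamp(pp$profile, pp$latent, seed = 5)
  r2 <- simulate_clamp(pp$profile, pp$latent, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$glucose > 0 & r1$insulin > 0 & r1$cpeptide > 0))
  expect_true(all(r1$gir >= 0))
  expect_true(all(r1$enrichment > 0 & r1$enrichment < 1))
  expect_true(all(diff(r1$time) > 0))
  expect_identical(r1$time, clamp_sampling_grid())

  bad <- pp$latent; bad$s_i <- -1
  expect_error(simulate_clamp(pp$profile, bad), "non-positive")
})

test_that("measured clamp sensitivity tracks the latent truth across a cohort", {
  cfg <- trial_config(n_per_arm = 8, dropout_prob = 0)
  coh <- generate_cohort(cfg, seed = 21)
  bl <- coh$truth[coh$truth$visit == "baseline", ]
  isis <- vapply(seq_len(nrow(bl)), function(i) {
    prof <- coh$profiles[coh$profiles$id == bl$participant_id[i], ]
    rec <- simulate_clamp(prof, bl[i, ], seed = 100 + i, noise = TRUE)
    clamp_isi(rec)
  }, numeric(1))
  expect_gt(cor(isis, bl$s_i, method = "spearman"), 0.95)
})

test_that("meal test responds to the latent truth through its feedback rule", {
  pp <- make_participant(seed = 4)
  m1 <- simulate_mmtt(pp$profile, pp$latent, seed = 1, noise = FALSE)
  m2 <- simulate_mmtt(pp$profile, pp$latent, seed = 2, noise = FALSE)
  expect_equal(m1$glucose, m2$glucose)   # noiseless: identical curves

  # doubling secretion lowers the glucose iAUC substantially (the expected
  # factor comes from solving the generator's own feedback ODE)
  lat2 <- pp$latent; lat2$isr_amp <- 2 * lat2$isr_amp
  m3 <- simulate_mmtt(pp$profile, lat2, seed = 1, noise = FALSE)
  i1 <- iauc(m1$time, m1$glucose, 0, 180)
  i3 <- iauc(m3$time, m3$glucose, 0, 180)
  expect_lt(i3 / i1, 0.75)
  expect_gt(i3 / i1, 0.30)

  # curves return toward fasting by 180 min
  peak <- max(m1$glucose)
  expect_lt(m1$glucose[m1$time == 180] - m1$glucose[m1$time == 0],
            0.6 * (peak - m1$glucose[m1$time == 0]))
  expect_true(all(c(0, 120) %in% m1$time))
})

test_that("baseline meal-test summaries sit at the expected scales", {
  cfg <- trial_config(n_per_arm = 5, dropout_prob = 0)
  coh <- generate_cohort(cfg, seed = 31)
  bl <- coh$truth[coh$truth$visit == "baseline", ]
  idx <- lapply(seq_len(nrow(bl)), function(i) {
    prof <- coh$profiles[coh$profiles$id == bl$participant_id[i], ]
    mmtt_indices(simulate_mmtt(prof, bl[i, ], seed = 300 + i))
  })
  idx <- dplyr::bind_rows(idx)
  g_auc <- vapply(seq_len(nrow(bl)), function(i) {
    prof <- coh$profiles[coh$profiles$id == bl$participant_id[i], ]
    m <- simulate_mmtt(prof, bl[i, ], seed = 300 + i)
    tauc(m$time, m$glucose, 0, 120)
  }, numeric(1))
  # glucose tAUC near the 27 mmol/l x h calibration point
  expect_equal(mean(g_auc), 27, tolerance = 0.2)
  # composite sensitivity index at its conventional single-digit scale
  expect_gt(median(idx$matsuda), 1)
  expect_lt(median(idx$matsuda), 8)
  expect_gt(median(idx$oral_isr_auc), 10)
  expect_lt(median(idx$oral_isr_auc), 100)
})
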
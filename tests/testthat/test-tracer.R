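test_that("basal appearance follows the tracer dilution identity", {
  expect_equal(basal_ra(0.04, 0.0235), 0.04 * (1 - 0.0235) / 0.0235)
  expect_equal(basal_ra(0.04, 0.0235), 1.66, tolerance = 0.01)
  expect_equal(basal_ra(0.05, 0.999), 0.05 * 0.001 / 0.999)  # ~0: all tracer
  expect_error(basal_ra(0.04, 0), "enrichment")
  expect_error(basal_ra(0.04, 1.2), "enrichment")
})

test_that("constant series collapse the non-steady terms", {
  tt <- seq(0, 120, by = 5)
  gl <- rep(9, length(tt)); en <- rep(0.02, length(tt))
  gir <- rep(1.5, length(tt))
  to <- steele_nonsteady(tt, gl, en, gir, F_inf = 0.04)
  expect_equal(to$ra, rep(basal_ra(0.04, 0.02), length(tt)))
  expect_equal(to$rd, to$ra)
  expect_equal(to$egp, to$ra - 1.5)
})

test_that("doubling the pool volume doubles only the non-steady correction", {
  tt <- seq(0, 100, by = 5)
  gl <- 9 + 0.02 * tt
  en <- 0.02 - 5e-5 * tt
  gir <- rep(2, length(tt))
  t1 <- steele_nonsteady(tt, gl, en, gir, F_inf = 0.04, V = 145)
  t2 <- steele_nonsteady(tt, gl, en, gir, F_inf = 0.04, V = 290)
  z <- en / (1 - en)
  steady_part <- 0.04 / z
  expect_equal(t2$ra - steady_part, 2 * (t1$ra - steady_part),
               tolerance = 1e-10)
})

test_that("errors name the offending time point", {
  tt <- c(0, 5, 10); en <- c(0.02, -0.01, 0.02)
  expect_error(steele_nonsteady(tt, rep(9, 3), en, rep(0, 3), 0.04),
               "time 5")
})

test_that("smoothing does not bias truly steady segments", {
  tt <- seq(0, 200, by = 5)
  gl <- rep(8.4, length(tt)); en <- rep(0.025, length(tt))
  to <- steele_nonsteady(tt, gl, en, rep(0, length(tt)), F_inf = 0.04)
  truth <- basal_ra(0.04, 0.025)
  expect_true(all(abs(to$ra - truth) / truth < 0.001))
})

test_that("turnover recovered from generator data matches the latent truth", {
  pp <- make_participant(seed = 4)
  rec <- simulate_clamp(pp$profile, pp$latent, seed = 1, noise = FALSE)
  tr <- attr(rec, "truth")
  to <- clamp_turnover(rec)

  # equilibrated basal window: EGP equals the latent basal truth
  expect_equal(as.numeric(egp_summary(to, c(-60, -20))), pp$latent$egp_basal,
               tolerance = 0.02)

  # late phase: suppression below basal, recovered within 10%
  true_late <- mean(tr$egp[tr$t_grid >= 90 & tr$t_grid <= 120])
  est_late <- as.numeric(egp_summary(to, c(90, 120)))
  expect_equal(est_late, true_late, tolerance = 0.10)
  expect_lt(est_late, pp$latent$egp_basal)

  # mass balance: integrated appearance within 5% of the generator's truth
  ra_true <- tr$egp + approx(rec$time, rec$gir, xout = tr$t_grid,
                             method = "constant", rule = 2)$y + 0.04
  keep <- tr$t_grid >= 0
  int_true <- pracma::trapz(tr$t_grid[keep], ra_true[keep])
  int_est <- pracma::trapz(to$time[to$time >= 0], to$ra[to$time >= 0])
  expect_equal(int_est, int_true, tolerance = 0.05)

  # window summary against a dense-grid oracle of the pointwise series
  dense_t <- seq(90, 120, by = 0.01)
  oracle <- pracma::trapz(dense_t, approx(to$time, to$egp, xout = dense_t)$y) / 30
  expect_equal(est_late, oracle, tolerance = 1e-9)
})

test_that("negative EGP values are retained and flagged", {
  tt <- seq(0, 60, by = 5)
  to <- steele_nonsteady(tt, rep(9, 13), rep(0.02, 13), rep(5, 13), 0.04)
  expect_true(all(to$egp < 0))
  expect_warning(m <- egp_summary(to, c(0, 60)), "negative")
  expect_lt(as.numeric(m), 0)
  expect_equal(attr(m, "n_negative"), 13)
})
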
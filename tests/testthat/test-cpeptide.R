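test_that("population parameters are reproducible, monotone and overridable", {
  p1 <- cpeptide_population_params(58, "M", 100, 33)
  p2 <- cpeptide_population_params(58, "M", 100, 33)
  expect_identical(p1, p2)

  # distribution volume is monotone in body surface area
  weights <- seq(60, 140, by = 10)
  vols <- vapply(weights, function(w) {
    cpeptide_population_params(58, "M", w, 33)$dist_volume
  }, numeric(1))
  expect_true(all(diff(vols) > 0))

  ov <- list(short_halflife = 5, long_halflife = 40, fraction = 0.7,
             dist_volume = 6)
  p3 <- cpeptide_population_params(58, "M", 100, 33, overrides = ov)
  expect_equal(p3[names(ov)], ov)
})

test_that("rate-constant derivation satisfies the eigenvalue relations", {
  p <- study_params
  expect_equal(p$k01 + p$k21 + p$k12, p$alpha + p$beta)
  expect_equal(p$k01 * p$k12, p$alpha * p$beta)
  expect_gt(p$short_halflife, 0)
  expect_error(cpeptide_params(10, 5, 0.5, 5), "long_halflife")
})

test_that("forward model: steady state, linearity, biexponential decay", {
  p <- study_params
  w <- 100
  # constant rate forever settles at r * weight / (k01 * V)
  cst <- isr_curve(c(-100, 300), 3, w)
  cc <- forward_cpeptide(cst, p, c(0, 50, 200))
  expect_equal(cc, rep(3 * w / (p$k01 * p$dist_volume), 3), tolerance = 1e-10)

  # doubling ISR doubles concentration at all times
  stp <- isr_curve(c(-50, 20, 120), c(2, 8), w)
  stp2 <- isr_curve(c(-50, 20, 120), c(4, 16), w)
  tt <- seq(0, 120, by = 5)
  expect_equal(forward_cpeptide(stp2, p, tt), 2 * forward_cpeptide(stp, p, tt),
               tolerance = 1e-12)

  # secretion switched off from steady state decays with the two configured
  # half-lives: by superposition the decay is the steady level minus the
  # response to the same rate switched on at 0, which the forward model
  # gives in closed form
  tt <- seq(0, 200, by = 1)
  a1 <- (p$alpha - p$k12) / (p$alpha - p$beta)
  expected <- 5 * w / p$dist_volume *
    (a1 * exp(-p$alpha * tt) / p$alpha + (1 - a1) * exp(-p$beta * tt) / p$beta)
  fitfun <- function(par) {
    sum((expected - (par[1] * exp(-log(2) / par[2] * tt) +
                       par[3] * exp(-log(2) / par[4] * tt)))^2)
  }
  opt <- optim(c(expected[1] * 0.6, 5, expected[1] * 0.4, 35), fitfun,
               control = list(reltol = 1e-14, maxit = 5000))
  halflives <- sort(opt$par[c(2, 4)])
  expect_equal(halflives[1], p$short_halflife, tolerance = 0.02)
  expect_equal(halflives[2], p$long_halflife, tolerance = 0.02)
})

test_that("deconvolution round trip recovers a step secretion profile", {
  p <- study_params
  w <- 100
  times <- seq(0, 180, by = 5)
  true <- isr_curve(c(-60, 60, 120, 181), c(3, 12, 6), w)
  cp <- forward_cpeptide(true, p, times)
  dec <- deconvolve_isr(times, cp, p, w, lambda_reg = 1e-3)
  # windowed means away from the step edges, within 5%
  expect_equal(phase_response(dec, c(10, 50), "mean"), 3, tolerance = 0.05)
  expect_equal(phase_response(dec, c(75, 115), "mean"), 12, tolerance = 0.05)
  expect_equal(phase_response(dec, c(135, 175), "mean"), 6, tolerance = 0.05)
  # the reconstruction reproduces the data
  refit <- forward_cpeptide(dec, p, times)
  expect_lt(sqrt(mean((refit - cp)^2)) / mean(cp), 0.01)
})

test_that("deconvolution handles degenerate and closed-form inputs", {
  p <- study_params
  w <- 100
  times <- seq(0, 60, by = 5)
  expect_warning(z <- deconvolve_isr(times, rep(0, 13), p, w), "all-zero")
  expect_equal(z$rates, rep(0, 12))

  # constant concentration c implies constant ISR = c k01 V / W
  cst <- deconvolve_isr(times, rep(900, 13), p, w, lambda_reg = 1e-6)
  expect_equal(cst$rates, rep(900 * p$k01 * p$dist_volume / w, 12),
               tolerance = 1e-4)
})

test_that("deconvolution is shift-invariant and linear in concentration", {
  p <- study_params
  w <- 80
  times <- seq(0, 120, by = 5)
  true <- isr_curve(c(-60, 40, 121), c(2, 9), w)
  cp <- forward_cpeptide(true, p, times)
  d0 <- deconvolve_isr(times, cp, p, w, lambda_reg = 1e-2)
  dshift <- deconvolve_isr(times + 37, cp, p, w, lambda_reg = 1e-2)
  expect_equal(d0$rates, dshift$rates, tolerance = 1e-9)
  dscale <- deconvolve_isr(times, 3 * cp, p, w, lambda_reg = 1e-2)
  expect_equal(dscale$rates, 3 * d0$rates, tolerance = 1e-7)
})

test_that("regularization trades residual against roughness monotonically", {
  p <- study_params
  w <- 100
  times <- seq(0, 120, by = 5)
  true <- isr_curve(c(-60, 30, 70, 121), c(3, 10, 5), w)
  cp <- forward_cpeptide(true, p, times) *
    withr::with_seed(1, exp(rnorm(length(times), 0, 0.05)))
  lambdas <- 10^seq(-4, 2, by = 1)
  fits <- lapply(lambdas, function(l) {
    deconvolve_isr(times, cp, p, w, lambda_reg = l)
  })
  resid <- vapply(fits, attr, numeric(1), which = "residual")
  rough <- vapply(fits, function(f) sum(diff(f$rates, differences = 2)^2),
                  numeric(1))
  expect_true(all(diff(resid) >= -1e-8))
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("normalization to ambient glucose is a guarded division", {
  expect_equal(normalize_isr(100, 10), 10)
  expect_equal(normalize_isr(0, 5), 0)
  expect_error(normalize_isr(10, 0), "positive")
})
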
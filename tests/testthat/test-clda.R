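test_that("complete balanced data reproduce the ANCOVA closed form", {
  # 12-participant fixture with exactly equal baseline arm means: the
  # treatment coefficients equal the differences in mean change vs control
  base <- c(1.0, 1.2, 1.4)
  chg <- list(CON = c(0.1, 0.2, 0.0), DCON = c(0.3, 0.1, 0.5),
              MED = c(0.4, 0.6, 0.2), HED = c(0.9, 0.7, 0.8))
  d <- purrr::imap(chg, function(ch, g) {
    dplyr::bind_rows(
      tibble::tibble(participant_id = paste0(g, 1:3), visit = 0, group = g,
                     sex = c("F", "M", "F"), value = exp(base)),
      tibble::tibble(participant_id = paste0(g, 1:3), visit = 1, group = g,
                     sex = c("F", "M", "F"), value = exp(base + ch))
    )
  }) %>% dplyr::bind_rows() %>%
    dplyr::mutate(group = factor(group, levels = c("CON", "DCON", "MED", "HED")))
  fit <- fit_clda(d, covariates = character(0))
  dm <- vapply(chg, mean, numeric(1))
  expect_equal(unname(coef(fit)[c("trt_DCON", "trt_MED", "trt_HED")]),
               unname(dm[c("DCON", "MED", "HED")] - dm["CON"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)["time"]), dm[["CON"]], tolerance = 1e-6)

  # general complete data: equals the baseline-adjusted ANCOVA estimator
  d2 <- make_long_data(n_per_arm = 8, seed = 3)
  fit2 <- fit_clda(d2, covariates = character(0))
  y <- log(d2$value)
  wide <- data.frame(bl = y[d2$visit == 0], fu = y[d2$visit == 1],
                     grp = d2$group[d2$visit == 0])
  anc <- lm(I(fu - bl) ~ bl + grp, data = wide)
  expect_equal(unname(coef(fit2)[3:5]), unname(coef(anc)[3:5]),
               tolerance = 1e-6)
})

test_that("estimates agree with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  d <- make_long_data(n_per_arm = 10, ratios = c(CON = 1, DCON = 1.3,
                                                 MED = 1.6, HED = 2.1),
                      seed = 8, dropout = 0.1)
  fit <- fit_clda(d)
  dd <- d
  dd$y <- log(dd$value)
  dd$t1 <- as.integer(dd$visit == 1)
  dd$g1 <- dd$t1 * (dd$group == "DCON")
  dd$g2 <- dd$t1 * (dd$group == "MED")
  dd$g3 <- dd$t1 * (dd$group == "HED")
  dd$sexF <- as.integer(dd$sex == "F")
  g <- nlme::gls(y ~ t1 + g1 + g2 + g3 + sexF, data = dd,
                 correlation = nlme::corSymm(form = ~ visit + 1 | participant_id),
                 weights = nlme::varIdent(form = ~ 1 | visit), method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("degenerate inputs are caught or handled", {
  d <- make_long_data(n_per_arm = 4, seed = 2)
  d0 <- d; d0$value <- 3
  expect_warning(fit0 <- fit_clda(d0), "zero variance")
  expect_equal(unname(coef(fit0)[-1]), rep(0, 5))

  # an arm with no follow-ups is named in the error
  d1 <- d[!(d$group == "MED" & d$visit == 1), ]
  expect_error(fit_clda(d1), "MED")

  # participants without baseline are rejected
  d2 <- d[-1, ]
  expect_error(fit_clda(d2), "baseline")
})

test_that("baseline-only participants inform the fit via the marginal", {
  d <- make_long_data(n_per_arm = 12, ratios = c(CON = 1, DCON = 1.4,
                                                 MED = 1.8, HED = 2.4),
                      seed = 5, dropout = 0.15)
  fit <- fit_clda(d)
  expect_gt(fit$n_baseline_only, 0)
  expect_equal(fit$n, 48)
  expect_equal(fit$df, sum(d$visit == 1) - 6)
  td <- tidy(fit)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_baseline_only, fit$n_baseline_only)
  expect_gt(gl$rho, 0)   # shared subject level induces positive correlation
})

test_that("back-transformation maps log effects to percentage changes", {
  d <- make_long_data(n_per_arm = 30, ratios = c(CON = 1, DCON = 1, MED = 1,
                                                 HED = 2), sd_change = 0.05,
                      sd_base = 0.05, seed = 10)
  fit <- fit_clda(d)
  bt <- backtransform(fit)
  expect_equal(bt$pct_change[bt$term == "trt_HED"], 100, tolerance = 5)
  expect_equal(bt$pct_change[bt$term == "trt_MED"], 0, tolerance = 5)
  expect_true(bt$conf.low[bt$term == "trt_MED"] < 0 &&
                bt$conf.high[bt$term == "trt_MED"] > 0)
  expect_error(backtransform(fit_clda(d, log_scale = FALSE)), "log-scale")
})

test_that("trend slope estimates the per-step log effect", {
  r <- 1.35
  d <- make_long_data(n_per_arm = 25,
                      ratios = c(CON = 1, DCON = r, MED = r^2, HED = r^3),
                      sd_change = 0.1, sd_base = 0.2, seed = 6)
  tr <- trend_test(d)
  expect_equal(tr$slope, log(r), tolerance = 0.05)
  expect_lt(tr$p.value, 1e-6)

  # non-monotone arm effects: slope equals the least-squares gradient over
  # the dose scores (documented behavior)
  eff <- c(CON = 1, DCON = 2, MED = 0.6, HED = 1.4)
  d2 <- make_long_data(n_per_arm = 60, ratios = eff, sd_change = 0.02,
                       sd_base = 0.05, seed = 7)
  tr2 <- trend_test(d2)
  ls_grad <- unname(coef(lm(log(eff) ~ c(0, 1, 2, 3)))[2])
  expect_equal(tr2$slope, ls_grad, tolerance = 0.02)
})

test_that("gatekeeping statuses follow the fixed-sequence rule", {
  expect_equal(gatekeep_status(rep(0.01, 6), global_p = 0.001),
               rep("confirmatory", 6))
  expect_equal(gatekeep_status(c(0.01, 0.2, 0.01, 0.01, 0.01, 0.01),
                               global_p = 0.001),
               c("confirmatory", rep("descriptive", 5)))
  expect_equal(gatekeep_status(rep(0.001, 6), global_p = 0.5),
               rep("not_tested", 6))

  # property: never confirmatory after a failure, for random p-vectors
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- runif(6)
      st <- gatekeep_status(p, global_p = runif(1))
      fail_at <- which(st != "confirmatory")
      if (length(fail_at)) {
        expect_false(any(st[min(fail_at):6] == "confirmatory"))
      }
    }
  })
})

test_that("the full comparison report carries estimates, statuses and gates", {
  d <- make_long_data(n_per_arm = 15,
                      ratios = c(CON = 1, DCON = 1.6, MED = 2.0, HED = 2.4),
                      seed = 12)
  fit <- fit_clda(d)
  rep <- gatekeep_report(fit, trend = trend_test(d))
  expect_equal(nrow(rep), 6)
  expect_equal(rep$pair[1:3], c("HED vs CON", "MED vs CON", "DCON vs CON"))
  expect_true(all(rep$status %in% c("confirmatory", "descriptive",
                                    "not_tested")))
  expect_lt(attr(rep, "global_p"), 0.1)
  expect_lt(attr(rep, "trend_p"), 0.05)
  # contrasts are consistent: (HED vs DCON) = (HED vs CON) - (DCON vs CON)
  est <- setNames(rep$estimate, rep$pair)
  expect_equal(unname(est["HED vs DCON"]),
               unname(est["HED vs CON"] - est["DCON vs CON"]),
               tolerance = 1e-10)
})

test_that("multiplicative-effect data are correctly modeled on the log scale", {
  # unbiasedness of the log-ratio across replicates
  ratios <- c(CON = 1, DCON = 1, MED = 1, HED = 2)
  ests <- vapply(1:80, function(i) {
    d <- make_long_data(n_per_arm = 30, ratios = ratios, sd_change = 0.3,
                        sd_base = 0.4, seed = 400 + i)
    unname(coef(fit_clda(d))["trt_HED"])
  }, numeric(1))
  expect_equal(mean(ests), log(2), tolerance = 0.03)

  # the same data violate the linear-scale model: follow-up residuals are
  # right-skewed on the raw scale but symmetric after the log transform
  d <- make_long_data(n_per_arm = 150, ratios = ratios, sd_change = 0.45,
                      sd_base = 0.4, seed = 99)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  fu <- d$value[d$visit == 1 & d$group == "CON"]
  expect_gt(skew(fu), 0.5)
  expect_lt(abs(skew(log(fu))), 0.4)
})
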
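#' Continuity-corrected odds ratio for a two-arm binary endpoint
#'
#' Plain 2x2 odds ratio with a Wald confidence interval on the log scale.
#' When any cell is zero, a treatment-arm continuity correction is applied:
#' each cell of group g receives n_g / (n_a + n_b) — the correction for a
#' group is inversely proportional to the relative size of the opposite
#' group. This keeps sparse-event odds ratios finite while penalizing the
#' smaller arm less.
#'
#' @param events_a,n_a Events and size of group A (numerator).
#' @param events_b,n_b Events and size of group B (reference).
#' @param conf.level Confidence level.
#' @return One-row tibble: `or`, `conf.low`, `conf.high`, `p.value`,
#'   `corrected` (logical flag).
#' @export
#' @examples
#' continuity_or(15, 18, 5, 13)  # uncorrected OR 8
#' continuity_or(0, 10, 5, 10)   # corrected, finite
continuity_or <- function(events_a, n_a, events_b, n_b, conf.level = 0.95) {
  stopifnot(events_a >= 0, events_b >= 0, events_a <= n_a, events_b <= n_b,
            n_a > 0, n_b > 0)
  a <- events_a; b <- n_a - events_a
  c_ <- events_b; d <- n_b - events_b
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    ca <- n_a / (n_a + n_b); cb <- n_b / (n_a + n_b)
    a <- a + ca; b <- b + ca
    c_ <- c_ + cb; d <- d + cb
  }
  log_or <- log((a / b) / (c_ / d))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    or = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    p.value = 2 * pnorm(-abs(log_or / se)),
    corrected = corrected
  )
}

#' Multiple-imputation sensitivity analysis of change scores
#'
#' Imputes missing follow-up change scores by Bayesian linear regression on
#' arm, sex and baseline (posterior draws of the coefficients and residual
#' variance, then draws from the predictive distribution), analyzes each
#' completed set with the change-score linear model `change ~ group + sex`,
#' and pools estimates across imputations by Rubin's rules (total variance =
#' within + (1 + 1/m) between).
#'
#' @param data Long dataset as for [fit_clda()] (missing follow-ups allowed).
#' @param m Number of imputed data sets (default 30).
#' @param seed Integer seed.
#' @param log_scale Analyze log(value).
#' @param deterministic Degenerate test mode: impute the conditional mean with
#'   no posterior or residual draws (between-imputation variance is then 0).
#' @return Tibble with one row per treatment term: pooled `estimate`,
#'   `std.error`, `statistic`, `df` (Rubin), `p.value`, and the
#'   between-imputation variance `b_var`.
#' @export
mi_sensitivity <- function(data, m = 30, seed = 1, log_scale = TRUE,
                           deterministic = FALSE) {
  data <- as_tibble(data)
  if (!is.factor(data$group)) data$group <- factor(data$group)
  data$visit01 <- .normalize_visit(data$visit)
  data$y <- if (log_scale) log(data$value) else data$value
  wide <- data %>%
    dplyr::select(participant_id, group, sex, visit01, y) %>%
    tidyr::pivot_wider(names_from = visit01, values_from = y,
                       names_prefix = "v") %>%
    dplyr::mutate(change = .data$v1 - .data$v0)
  obs <- !is.na(wide$change)
  Ximp <- model.matrix(~ group + sex + v0, data = wide)
  Xan <- model.matrix(~ group + sex, data = wide)
  trt_terms <- grep("^group", colnames(Xan), value = TRUE)

  analyse <- function(ch) {
    f <- stats::lm.fit(Xan, ch)
    rss <- sum(f$residuals^2)
    sigma2 <- rss / f$df.residual
    XtXinv <- chol2inv(chol(crossprod(Xan)))
    list(est = f$coefficients[trt_terms],
         var = sigma2 * diag(XtXinv)[match(trt_terms, colnames(Xan))],
         df = f$df.residual)
  }

  if (all(obs)) m_eff <- 1 else m_eff <- m
  fit_obs <- stats::lm.fit(Ximp[obs, , drop = FALSE], wide$change[obs])
  bhat <- fit_obs$coefficients
  rdf <- fit_obs$df.residual
  rss <- sum(fit_obs$residuals^2)
  XtXinv_i <- chol2inv(chol(crossprod(Ximp[obs, , drop = FALSE])))

  res <- withr::with_seed(seed, {
    purrr::map(seq_len(m_eff), function(k) {
      ch <- wide$change
      if (any(!obs)) {
        if (deterministic) {
          ch[!obs] <- drop(Ximp[!obs, , drop = FALSE] %*% bhat)
        } else {
          sigma2_star <- rss / rchisq(1, rdf)
          bstar <- bhat + drop(t(chol(sigma2_star * XtXinv_i)) %*%
                                 rnorm(length(bhat)))
          mu <- drop(Ximp[!obs, , drop = FALSE] %*% bstar)
          ch[!obs] <- mu + rnorm(sum(!obs), 0, sqrt(sigma2_star))
        }
      }
      analyse(ch)
    })
  })

  est_mat <- do.call(rbind, purrr::map(res, "est"))
  var_mat <- do.call(rbind, purrr::map(res, "var"))
  qbar <- colMeans(est_mat)
  wbar <- colMeans(var_mat)
  bvar <- if (m_eff > 1) apply(est_mat, 2, var) else rep(0, length(qbar))
  tvar <- wbar + (1 + 1 / m_eff) * bvar
  r <- (1 + 1 / m_eff) * bvar / wbar
  df_rubin <- ifelse(bvar > 0, (m_eff - 1) * (1 + 1 / r)^2, res[[1]]$df)
  stat <- qbar / sqrt(tvar)
  tibble::tibble(
    term = sub("^group", "trt_", trt_terms),
    estimate = unname(qbar), std.error = unname(sqrt(tvar)),
    statistic = unname(stat), df = unname(df_rubin),
    p.value = unname(2 * pt(-abs(stat), df_rubin)),
    b_var = unname(bvar)
  )
}

#' Power of a single-df contrast in a balanced one-way ANOVA
#'
#' Power of the t-test of psi = sum(c_i * mu_i) with noncentrality
#' psi / (sd * sqrt(sum(c_i^2 / n_i))) and df = sum(n_i) - k, via the
#' noncentral t distribution.
#'
#' @param means Group means.
#' @param coeffs Contrast coefficients; must sum to zero.
#' @param sd Error standard deviation.
#' @param n_per_group Group sizes (scalar recycled, or vector).
#' @param alpha Significance level.
#' @param two_sided Two-sided test (default).
#' @return Power (probability of rejection).
#' @export
#' @examples
#' contrast_power(c(1.5, 1.0, 0.5, 0.0), c(1, 0, 0, -1), sd = 1.5,
#'                n_per_group = 20)
contrast_power <- function(means, coeffs, sd, n_per_group, alpha = 0.05,
                           two_sided = TRUE) {
  stopifnot(length(means) == length(coeffs), sd > 0, all(n_per_group >= 2))
  if (abs(sum(coeffs)) > 1e-9) {
    stop("contrast coefficients must sum to zero", call. = FALSE)
  }
  k <- length(means)
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, k)
  psi <- sum(coeffs * means)
  se <- sd * sqrt(sum(coeffs^2 / n_per_group))
  ncp <- psi / se
  df <- sum(n_per_group) - k
  if (two_sided) {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  } else {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}
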
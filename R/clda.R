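# Constrained-baseline longitudinal analysis (cLDA).
#
# The baseline is part of the outcome vector: the model for participant i with
# visits (baseline, follow-up) is bivariate normal with a common baseline mean
# across arms, fixed effects for time, treatment-at-follow-up (coded 0 for all
# groups at baseline) and covariates, and an unstructured 2x2 within-
# participant covariance (which nests the random-intercept model).
# Participants missing follow-up contribute their baseline via the marginal
# likelihood. Estimation is direct maximum likelihood: the fixed effects are
# profiled by generalized least squares at each covariance evaluation.

.normalize_visit <- function(visit) {
  if (is.numeric(visit)) as.integer(visit > 0)
  else as.integer(tolower(as.character(visit)) %in% c("followup", "follow-up", "1"))
}

.clda_design <- function(data, covariates, dose) {
  arms <- levels(data$group)
  t1 <- data$visit01
  X <- cbind(`(Intercept)` = 1, time = t1)
  if (dose) {
    dose_num <- match(as.character(data$group), arms) - 1
    X <- cbind(X, trend = t1 * dose_num)
  } else {
    for (g in arms[-1]) {
      X <- cbind(X, t1 * as.integer(data$group == g))
      colnames(X)[ncol(X)] <- paste0("trt_", g)
    }
  }
  for (cv in covariates) {
    v <- data[[cv]]
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      v <- as.integer(as.character(v) == sort(unique(as.character(v)))[1])
      X <- cbind(X, v); colnames(X)[ncol(X)] <- paste0(cv, "_ind")
    } else {
      X <- cbind(X, v); colnames(X)[ncol(X)] <- cv
    }
  }
  X
}

#' Fit a constrained-baseline longitudinal model
#'
#' Maximum-likelihood fit of the bivariate (baseline, follow-up) normal model
#' with a common baseline mean across arms, fixed effects for time,
#' treatment-at-follow-up and covariates, and an unstructured 2x2
#' within-participant covariance. With `log_scale = TRUE` (the default) the
#' outcome is log-transformed first, so exponentiated coefficients are
#' geometric-mean ratios (see [backtransform()]).
#'
#' @param data Long dataset: one row per participant-visit with columns
#'   `participant_id`, `visit` (0/1 or baseline/followup), `group` (factor,
#'   first level = control), `value`, and any covariate columns. Every
#'   participant must have a baseline row; follow-ups may be missing.
#' @param log_scale Analyze log(value).
#' @param covariates Character vector of covariate column names (default sex).
#' @return Object of class `clda_fit`: coefficients, their covariance, the
#'   fitted 2x2 residual covariance, residual degrees of freedom
#'   (n follow-ups minus number of coefficients), and bookkeeping.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   participant_id = rep(sprintf("P%02d", 1:12), each = 2),
#'   visit = rep(0:1, 12),
#'   group = factor(rep(c("CON", "DCON", "MED", "HED"), each = 6),
#'                  levels = c("CON", "DCON", "MED", "HED")),
#'   sex = rep(c("F", "M"), 12),
#'   value = exp(rnorm(24))
#' )
#' fit <- fit_clda(d)
#' tidy(fit)
fit_clda <- function(data, log_scale = TRUE, covariates = "sex") {
  stopifnot(all(c("participant_id", "visit", "group", "value") %in% names(data)))
  data <- as_tibble(data)
  if (!is.factor(data$group)) data$group <- factor(data$group)
  data$group <- droplevels(data$group)
  if (nlevels(data$group) < 2) stop("need at least 2 groups", call. = FALSE)
  data$visit01 <- .normalize_visit(data$visit)
  if (log_scale) {
    if (any(data$value <= 0)) {
      stop("log-scale analysis requires positive values", call. = FALSE)
    }
    data$y <- log(data$value)
  } else data$y <- data$value

  ids <- unique(data$participant_id)
  has_base <- tapply(data$visit01, data$participant_id, function(v) any(v == 0))
  if (!all(has_base[as.character(ids)])) {
    stop("every participant needs a baseline row", call. = FALSE)
  }
  fu <- data[data$visit01 == 1, ]
  missing_arms <- setdiff(levels(data$group), unique(as.character(fu$group)))
  if (length(missing_arms)) {
    stop("all follow-ups missing in arm ", paste(missing_arms, collapse = ", "),
         call. = FALSE)
  }

  X <- .clda_design(data, covariates, dose = FALSE)
  if (var(data$y) < 1e-12) {
    # degenerate data: every value identical; exact fit with zero effects
    warning("outcome has zero variance; returning a degenerate exact fit",
            call. = FALSE)
    p <- ncol(X)
    beta <- c(mean(data$y), numeric(p - 1))
    names(beta) <- colnames(X)
    fit <- list(coefficients = beta,
                vcov = matrix(0, p, p, dimnames = list(colnames(X),
                                                       colnames(X))),
                sigma = matrix(0, 2, 2),
                df = sum(data$visit01 == 1) - p,
                n = length(unique(data$participant_id)),
                n_completers = NA_integer_, n_baseline_only = NA_integer_,
                logLik = Inf)
  } else {
    fit <- .clda_ml(data, X)
  }
  fit$log_scale <- log_scale
  fit$groups <- levels(data$group)
  fit$covariates <- covariates
  fit$call <- match.call()
  class(fit) <- "clda_fit"
  fit
}

# core ML machinery shared by fit_clda and trend_test; `X` row-matched to data
.clda_ml <- function(data, X) {
  id <- data$participant_id
  b_rows <- which(data$visit01 == 0)
  f_rows <- which(data$visit01 == 1)
  fid <- id[f_rows]
  comp <- intersect(id[b_rows], fid)
  b_of <- setNames(b_rows, id[b_rows])
  f_of <- setNames(f_rows, fid)
  i0c <- b_of[comp]; i1c <- f_of[comp]
  i0b <- b_of[setdiff(id[b_rows], comp)]
  X0c <- X[i0c, , drop = FALSE]; X1c <- X[i1c, , drop = FALSE]
  y0c <- data$y[i0c]; y1c <- data$y[i1c]
  X0b <- X[i0b, , drop = FALSE]; y0b <- data$y[i0b]
  nc <- length(i0c); nb <- length(i0b); p <- ncol(X)

  C00 <- crossprod(X0c); C11 <- crossprod(X1c); C01 <- crossprod(X0c, X1c)
  Cb <- if (nb) crossprod(X0b) else matrix(0, p, p)
  v00 <- crossprod(X0c, y0c); v11 <- crossprod(X1c, y1c)
  v01 <- crossprod(X0c, y1c); v10 <- crossprod(X1c, y0c)
  vb <- if (nb) crossprod(X0b, y0b) else matrix(0, p, 1)
  s00 <- sum(y0c^2); s11 <- sum(y1c^2); s01 <- sum(y0c * y1c)
  sb <- if (nb) sum(y0b^2) else 0

  neg2ll <- function(th, want = "value") {
    s0 <- exp(th[1]); s1 <- exp(th[2]); rho <- tanh(th[3])
    det_s <- s0^2 * s1^2 * (1 - rho^2)
    w00 <- s1^2 / det_s; w11 <- s0^2 / det_s; w01 <- -rho * s0 * s1 / det_s
    A <- w00 * C00 + w01 * (C01 + t(C01)) + w11 * C11 + Cb / s0^2
    bv <- w00 * v00 + w01 * (v01 + v10) + w11 * v11 + vb / s0^2
    beta <- tryCatch(solve(A, bv), error = function(e) NULL)
    if (is.null(beta)) return(if (want == "value") 1e10 else NULL)
    q00 <- s00 - 2 * sum(beta * v00) + drop(t(beta) %*% C00 %*% beta)
    q11 <- s11 - 2 * sum(beta * v11) + drop(t(beta) %*% C11 %*% beta)
    q01 <- s01 - sum(beta * v01) - sum(beta * v10) +
      drop(t(beta) %*% C01 %*% beta)
    qb <- if (nb) sb - 2 * sum(beta * vb) + drop(t(beta) %*% Cb %*% beta) else 0
    val <- nc * log(det_s) + w00 * q00 + 2 * w01 * q01 + w11 * q11 +
      nb * log(s0^2) + qb / s0^2
    if (want == "value") val else list(beta = beta, A = A, val = val)
  }

  # moment starting values from complete cases
  d0 <- y0c - mean(y0c); d1 <- y1c - mean(y1c)
  v0 <- max(var(y0c), 1e-8); v1 <- max(var(y1c), 1e-8)
  r0 <- if (nc > 2) sum(d0 * d1) / sqrt(sum(d0^2) * sum(d1^2)) else 0
  start <- c(0.5 * log(v0), 0.5 * log(v1), atanh(max(min(r0, 0.95), -0.95)))
  opt <- optim(start, neg2ll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 3000))
  sol <- neg2ll(opt$par, want = "all")
  if (is.null(sol)) stop("cLDA likelihood is singular", call. = FALSE)
  s0 <- exp(opt$par[1]); s1 <- exp(opt$par[2]); rho <- tanh(opt$par[3])
  beta <- drop(sol$beta); names(beta) <- colnames(X)
  vc <- solve(sol$A); dimnames(vc) <- list(colnames(X), colnames(X))
  n_obs <- 2 * nc + nb
  list(
    coefficients = beta,
    vcov = vc,
    sigma = matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2, 2,
                   dimnames = list(c("baseline", "followup"),
                                   c("baseline", "followup"))),
    df = length(f_rows) - ncol(X),
    n = nc + nb, n_completers = nc, n_baseline_only = nb,
    logLik = -0.5 * (sol$val + n_obs * log(2 * pi))
  )
}

#' @export
print.clda_fit <- function(x, ...) {
  cat("Constrained-baseline longitudinal model",
      if (x$log_scale) "(log scale)" else "(linear scale)", "\n")
  cat("  ", x$n, "participants (", x$n_baseline_only, "baseline-only );",
      "residual df", x$df, "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.clda_fit <- function(object, ...) object$coefficients

#' @export
vcov.clda_fit <- function(object, ...) object$vcov

#' @export
logLik.clda_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 3,
            class = "logLik")
}

#' @rdname fit_clda
#' @param x,object A `clda_fit`.
#' @param conf.level Confidence level for Wald intervals (t distribution with
#'   residual df).
#' @param ... Unused.
#' @export
tidy.clda_fit <- function(x, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  tc <- qt(1 - (1 - conf.level) / 2, x$df)
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pt(-abs(stat), x$df)),
    conf.low = unname(est - tc * se), conf.high = unname(est + tc * se)
  )
}

#' @rdname fit_clda
#' @export
glance.clda_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_completers = x$n_completers,
    n_baseline_only = x$n_baseline_only,
    df.residual = x$df, logLik = x$logLik,
    sigma.baseline = sqrt(x$sigma[1, 1]), sigma.followup = sqrt(x$sigma[2, 2]),
    rho = x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2])
  )
}

#' Back-transform a log-scale fit to geometric-mean ratios
#'
#' Exponentiates the time and treatment coefficients (and their Wald CI
#' bounds) of a log-scale cLDA fit and reports them as percentage changes,
#' `100 * (ratio - 1)`: the `time` row is the within-control change from
#' baseline; each `trt_*` row is the between-group difference in change
#' versus control.
#'
#' @param fit A `clda_fit` with `log_scale = TRUE`.
#' @param conf.level Confidence level.
#' @return Tibble: `term`, `estimate` (log ratio), `ratio`, `pct_change`,
#'   `conf.low`/`conf.high` (percent), `p.value`.
#' @export
backtransform <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "clda_fit"))
  if (!fit$log_scale) {
    stop("backtransform() requires a log-scale fit", call. = FALSE)
  }
  td <- tidy(fit, conf.level = conf.level)
  td <- td[td$term == "time" | grepl("^trt_", td$term), ]
  tibble::tibble(
    term = td$term,
    estimate = td$estimate,
    ratio = exp(td$estimate),
    pct_change = 100 * (exp(td$estimate) - 1),
    conf.low = 100 * (exp(td$conf.low) - 1),
    conf.high = 100 * (exp(td$conf.high) - 1),
    p.value = td$p.value
  )
}

#' Linear dose-trend test
#'
#' Refits the constrained-baseline model with the treatment category entered
#' as a single continuous 0-3 slope at follow-up (0 for all groups at
#' baseline) and reports the Wald test on the slope. With non-monotone arm
#' effects the slope estimates the least-squares linear gradient across the
#' ordered arms; this is the documented behavior, not an error.
#'
#' @inheritParams fit_clda
#' @return One-row tibble: `slope`, `std.error`, `statistic`, `p.value`, `df`.
#' @export
trend_test <- function(data, log_scale = TRUE, covariates = "sex") {
  data <- as_tibble(data)
  if (!is.factor(data$group)) data$group <- factor(data$group)
  data$group <- droplevels(data$group)
  data$visit01 <- .normalize_visit(data$visit)
  data$y <- if (log_scale) log(data$value) else data$value
  X <- .clda_design(data, covariates, dose = TRUE)
  fit <- .clda_ml(data, X)
  est <- fit$coefficients["trend"]
  se <- sqrt(fit$vcov["trend", "trend"])
  stat <- est / se
  tibble::tibble(slope = unname(est), std.error = unname(se),
                 statistic = unname(stat),
                 p.value = unname(2 * pt(-abs(stat), fit$df)),
                 df = fit$df)
}

#' Fixed-sequence gatekeeping statuses
#'
#' Applies the hierarchical testing rule to an ordered vector of pairwise
#' p-values: if the global p-value is at or above `alpha_global`, nothing is
#' tested; otherwise hypotheses are confirmatory until the first p-value
#' above `alpha_pair` and descriptive from that one on. A later hypothesis is
#' never confirmatory after a failure.
#'
#' @param p_values Ordered pairwise p-values.
#' @param global_p Global test p-value.
#' @param alpha_global,alpha_pair Gate and pairwise levels.
#' @return Character vector in
#'   `c("confirmatory", "descriptive", "not_tested")`.
#' @export
gatekeep_status <- function(p_values, global_p, alpha_global = 0.1,
                            alpha_pair = 0.05) {
  if (global_p >= alpha_global) return(rep("not_tested", length(p_values)))
  failed <- FALSE
  vapply(p_values, function(p) {
    if (!failed && p <= alpha_pair) "confirmatory"
    else { failed <<- TRUE; "descriptive" }
  }, character(1))
}

# the six prespecified pairwise hypotheses, in gatekeeping order
.pair_order <- function() {
  tibble::tribble(
    ~pair,          ~plus,      ~minus,
    "HED vs CON",   "trt_HED",  NA,
    "MED vs CON",   "trt_MED",  NA,
    "DCON vs CON",  "trt_DCON", NA,
    "HED vs DCON",  "trt_HED",  "trt_DCON",
    "MED vs DCON",  "trt_MED",  "trt_DCON",
    "HED vs MED",   "trt_HED",  "trt_MED"
  )
}

#' Pairwise treatment contrasts of a 4-arm cLDA fit
#'
#' @param fit A `clda_fit` on the four arms CON/DCON/MED/HED.
#' @param conf.level Confidence level.
#' @return Tibble with one row per pair in the prespecified order: estimate
#'   (log scale if fitted on logs), percentage change when log scale, Wald CI
#'   and p-value (t, residual df).
#' @export
clda_pairwise <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "clda_fit"))
  po <- .pair_order()
  cn <- names(fit$coefficients)
  stopifnot(all(stats::na.omit(c(po$plus, po$minus)) %in% cn))
  tc <- qt(1 - (1 - conf.level) / 2, fit$df)
  out <- purrr::map(seq_len(nrow(po)), function(i) {
    L <- setNames(numeric(length(cn)), cn)
    L[po$plus[i]] <- 1
    if (!is.na(po$minus[i])) L[po$minus[i]] <- -1
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    stat <- est / se
    tibble::tibble(pair = po$pair[i], estimate = est, std.error = se,
                   statistic = stat, p.value = 2 * pt(-abs(stat), fit$df),
                   conf.low = est - tc * se, conf.high = est + tc * se)
  })
  out <- dplyr::bind_rows(out)
  if (fit$log_scale) {
    out <- out %>% dplyr::mutate(
      pct_change = 100 * (exp(estimate) - 1),
      pct_low = 100 * (exp(conf.low) - 1),
      pct_high = 100 * (exp(conf.high) - 1)
    )
  }
  out
}

#' Global test and hierarchical gatekeeping report
#'
#' Performs the global Wald test of the three treatment-at-follow-up
#' coefficients (F with residual df). If the global p-value is below
#' `alpha_global` the six prespecified pairwise hypotheses are walked in
#' order, marked `confirmatory` until the first p-value above `alpha_pair`
#' and `descriptive` from that point on; otherwise all pairs are
#' `not_tested` (estimates are still reported). This fixed-sequence approach
#' preserves the family-wise error rate on the primary outcome without any
#' further multiplicity correction.
#'
#' @param fit A `clda_fit` over the four arms.
#' @param alpha_global Global-test gate (default 0.1).
#' @param alpha_pair Pairwise significance level (default 0.05).
#' @param trend Optional result of [trend_test()] to carry along.
#' @param conf.level Confidence level for the pairwise intervals.
#' @return A `comparison_report`: the pairwise tibble plus a `status` column,
#'   with attributes `global_p` and (optionally) `trend_p`.
#' @export
gatekeep_report <- function(fit, alpha_global = 0.1, alpha_pair = 0.05,
                            trend = NULL, conf.level = 0.95) {
  stopifnot(inherits(fit, "clda_fit"))
  cn <- names(fit$coefficients)
  trt <- grep("^trt_", cn, value = TRUE)
  L <- matrix(0, length(trt), length(cn), dimnames = list(trt, cn))
  for (g in trt) L[g, g] <- 1
  est <- L %*% fit$coefficients
  Fstat <- drop(t(est) %*% solve(L %*% fit$vcov %*% t(L)) %*% est) / length(trt)
  global_p <- pf(Fstat, length(trt), fit$df, lower.tail = FALSE)

  pares <- clda_pairwise(fit, conf.level = conf.level)
  pares$status <- gatekeep_status(pares$p.value, global_p,
                                  alpha_global = alpha_global,
                                  alpha_pair = alpha_pair)
  attr(pares, "global_p") <- global_p
  if (!is.null(trend)) attr(pares, "trend_p") <- trend$p.value
  class(pares) <- c("comparison_report", class(pares))
  pares
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Pairwise geometric-mean-ratio comparisons (global P =",
      signif(attr(x, "global_p"), 3), ")\n")
  if (!is.null(attr(x, "trend_p"))) {
    cat("P for trend =", signif(attr(x, "trend_p"), 3), "\n")
  }
  NextMethod()
}
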
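#' Total area under the curve (trapezoidal rule)
#'
#' @param times Minutes, strictly increasing.
#' @param values Concentrations.
#' @param t0,t1 Integration limits (min); endpoints are linearly interpolated
#'   if not on the grid.
#' @return AUC in concentration x hours.
#' @export
#' @examples
#' tauc(c(0, 60, 120), c(5, 5, 5), 0, 120)  # 10 mmol/l x h
tauc <- function(times, values, t0, t1) {
  stopifnot(all(diff(times) > 0), length(values) == length(times),
            t1 > t0, t0 >= min(times) - 1e-9, t1 <= max(times) + 1e-9)
  inside <- times > t0 & times < t1
  tt <- c(t0, times[inside], t1)
  vv <- c(approx(times, values, xout = t0)$y, values[inside],
          approx(times, values, xout = t1)$y)
  pracma::trapz(tt, vv) / 60
}

#' Incremental area under the curve
#'
#' tAUC minus the rectangle at the t0 value. Negative increments are retained
#' (no truncation at zero), so a series dipping below its baseline can give a
#' negative iAUC.
#'
#' @inheritParams tauc
#' @return Incremental AUC in concentration x hours.
#' @export
iauc <- function(times, values, t0, t1) {
  v0 <- approx(times, values, xout = t0)$y
  tauc(times, values, t0, t1) - v0 * (t1 - t0) / 60
}

#' Matsuda composite whole-body insulin sensitivity index
#'
#' 10,000 / sqrt(fasting glucose x fasting insulin x mean glucose x mean
#' insulin), with all four terms under the square root and inputs converted to
#' the index's conventional units (glucose mg/dl, insulin uU/ml) via
#' [unit_constants()].
#'
#' @param fg,fi Fasting glucose (mmol/l) and insulin (pmol/l).
#' @param mean_g,mean_i Mean post-load glucose (mmol/l) and insulin (pmol/l)
#'   over 0-120 min.
#' @return Dimensionless index.
#' @export
matsuda <- function(fg, fi, mean_g, mean_i) {
  if (any(c(fg, fi, mean_g, mean_i) <= 0)) {
    stop("all Matsuda inputs must be positive", call. = FALSE)
  }
  g_conv <- .const("glucose_mgdl_per_mmoll")
  i_conv <- 1 / .const("insulin_pmoll_per_uUml")
  10000 / sqrt((fg * g_conv) * (fi * i_conv) *
                 (mean_g * g_conv) * (mean_i * i_conv))
}

#' Oral insulin secretion measures
#'
#' `auc_ratio`: tAUC(insulin) / tAUC(glucose) over 0-120 min — a secretion
#' measure must increase with insulin, so insulin is the numerator (set
#' `invert = TRUE` for the reciprocal convention). `igi`: insulinogenic index
#' (insulin_30 - insulin_0) / (glucose_30 - glucose_0).
#'
#' @param times,glucose,insulin Sampled meal-test series (min, mmol/l, pmol/l).
#' @param variant `"auc_ratio"` or `"igi"`.
#' @param invert For `auc_ratio`, return glucose/insulin instead.
#' @return Scalar secretion measure. For `igi` with a zero glucose increment,
#'   `NA` with a warning.
#' @export
oral_secretion <- function(times, glucose, insulin,
                           variant = c("auc_ratio", "igi"), invert = FALSE) {
  variant <- match.arg(variant)
  if (variant == "auc_ratio") {
    r <- tauc(times, insulin, 0, 120) / tauc(times, glucose, 0, 120)
    if (invert) 1 / r else r
  } else {
    g0 <- approx(times, glucose, xout = 0)$y
    g30 <- approx(times, glucose, xout = 30)$y
    i0 <- approx(times, insulin, xout = 0)$y
    i30 <- approx(times, insulin, xout = 30)$y
    if (abs(g30 - g0) < 1e-12) {
      warning("zero glucose increment at 30 min; IGI undefined", call. = FALSE)
      return(NA_real_)
    }
    (i30 - i0) / (g30 - g0)
  }
}

#' Oral disposition index
#'
#' @param matsuda Matsuda index.
#' @param secretion An oral secretion measure (AUC ratio or IGI).
#' @return Product.
#' @export
oral_di <- function(matsuda, secretion) matsuda * secretion

#' All meal-test indices for one participant-visit
#'
#' @param record An MMTTRecord tibble for one participant-visit.
#' @return One-row tibble: tAUC and iAUC (0-30 and 0-120 min) for each
#'   analyte, Matsuda index, both oral secretion variants, and the two oral
#'   disposition indices.
#' @export
mmtt_indices <- function(record) {
  stopifnot(all(c(0, 30, 120) %in% record$time))
  analytes <- c("glucose", "insulin", "cpeptide", "glp1_total", "gip_total",
                "paracetamol")
  aucs <- purrr::map(analytes, function(a) {
    tibble::tibble(
      !!paste0("tauc_", a, "_0_30") := tauc(record$time, record[[a]], 0, 30),
      !!paste0("tauc_", a, "_0_120") := tauc(record$time, record[[a]], 0, 120),
      !!paste0("iauc_", a, "_0_120") := iauc(record$time, record[[a]], 0, 120)
    )
  })
  fg <- record$glucose[record$time == 0]
  fi <- record$insulin[record$time == 0]
  mean_g <- tauc(record$time, record$glucose, 0, 120) / 2
  mean_i <- tauc(record$time, record$insulin, 0, 120) / 2
  mats <- matsuda(fg, fi, mean_g, mean_i)
  sec_auc <- oral_secretion(record$time, record$glucose, record$insulin,
                            "auc_ratio")
  sec_igi <- oral_secretion(record$time, record$glucose, record$insulin, "igi")
  dplyr::bind_cols(
    tibble::tibble(
      participant_id = record$participant_id[1],
      visit = record$visit[1],
      matsuda = mats,
      oral_isr_auc = sec_auc,
      igi = sec_igi,
      oral_di_auc = oral_di(mats, sec_auc),
      oral_di_igi = oral_di(mats, sec_igi)
    ),
    dplyr::bind_cols(aucs)
  )
}
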
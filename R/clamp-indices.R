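#' Time-weighted mean of an analyte over a phase window
#'
#' Trapezoid AUC over the window divided by its duration, with linear
#' interpolation at the window endpoints. Time-weighted (rather than
#' arithmetic) means are robust to the mixed 5-min / 10-min sampling grids.
#'
#' @param record Data frame with a `time` column and the analyte column.
#' @param analyte Column name, e.g. `"glucose"`.
#' @param window Numeric `c(start, end)` in minutes.
#' @return Scalar mean value.
#' @export
#' @examples
#' rec <- tibble::tibble(time = 0:10, glucose = 5 + 0 * (0:10))
#' window_mean(rec, "glucose", c(2, 8))
window_mean <- function(record, analyte, window) {
  stopifnot(length(window) == 2, window[2] > window[1],
            analyte %in% names(record), "time" %in% names(record))
  tt <- record$time; vv <- record[[analyte]]
  ord <- order(tt); tt <- tt[ord]; vv <- vv[ord]
  inside <- tt > window[1] & tt < window[2]
  t_in <- c(window[1], tt[inside], window[2])
  v_in <- c(approx(tt, vv, xout = window[1], rule = 2)$y,
            vv[inside],
            approx(tt, vv, xout = window[2], rule = 2)$y)
  if (sum(tt >= window[1] & tt <= window[2]) < 2) {
    stop("fewer than 2 samples in window [", window[1], ", ", window[2], "]",
         call. = FALSE)
  }
  pracma::trapz(t_in, v_in) / (window[2] - window[1])
}

#' Clamp insulin sensitivity index
#'
#' GIR divided by the product of circulating insulin and glucose over a phase
#' window (time-weighted window means). Units: (mg/kg/min) per
#' (pmol/l x mmol/l).
#'
#' @param record A ClampRecord tibble.
#' @param window Phase window, default late-phase 90-120 min.
#' @param urinary `"off"` (default) or `"subtract"`: correct GIR for urinary
#'   glucose loss before averaging (see [urinary_correction()]).
#' @return Scalar ISI.
#' @export
clamp_isi <- function(record, window = c(90, 120), urinary = c("off", "subtract")) {
  urinary <- match.arg(urinary)
  rec <- urinary_correction(record, mode = urinary)
  mg <- window_mean(rec, "gir", window)
  mi <- window_mean(rec, "insulin", window)
  mgl <- window_mean(rec, "glucose", window)
  if (mi <= 0 || mgl <= 0) {
    stop("window means of insulin and glucose must be positive", call. = FALSE)
  }
  mg / (mi * mgl)
}

#' Disposition index
#'
#' The product of a glucose-normalized secretion measure and a sensitivity
#' measure; quantifies beta-cell function adjusted for prevailing sensitivity.
#'
#' @param isr_norm Glucose-normalized secretion (pmol/kg/min per mmol/l).
#' @param isi Sensitivity index.
#' @return Product, arbitrary units.
#' @export
#' @examples
#' disposition_index(10, 0.17)
disposition_index <- function(isr_norm, isi) {
  stopifnot(all(isr_norm >= 0), all(isi >= 0))
  isr_norm * isi
}

#' Mean or peak secretion over a phase window
#'
#' @param isr An [isr_curve()].
#' @param window `c(start, end)` minutes; must be covered by the curve.
#' @param kind `"mean"` (time-weighted) or `"peak"` (maximum interval rate
#'   among intervals overlapping the window).
#' @return pmol/kg/min.
#' @export
phase_response <- function(isr, window, kind = c("mean", "peak")) {
  kind <- match.arg(kind)
  stopifnot(inherits(isr, "isr_curve"), length(window) == 2,
            window[2] > window[1])
  bp <- isr$breakpoints
  if (window[1] < min(bp) - 1e-9 || window[2] > max(bp) + 1e-9) {
    stop("window not covered by the ISR curve", call. = FALSE)
  }
  lo <- pmax(head(bp, -1), window[1])
  hi <- pmin(tail(bp, -1), window[2])
  dur <- pmax(hi - lo, 0)
  if (kind == "mean") {
    sum(isr$rates * dur) / sum(dur)
  } else {
    max(isr$rates[dur > 0])
  }
}

#' Correct the glucose infusion rate for urinary glucose loss
#'
#' With `mode = "subtract"`, the total urinary glucose excreted over the clamp
#' is converted to mass (180.156 mg/mmol) and distributed as a constant rate
#' over the clamp duration, then subtracted from the GIR trace. The corrected
#' GIR is floored at zero (with a warning). Default is no correction: the
#' study protocol measured urinary glucose but did not state that GIR was
#' corrected before the sensitivity index.
#'
#' @param record A ClampRecord tibble (needs `urine_glucose_mmol` and
#'   `weight_kg` when subtracting).
#' @param mode `"off"` or `"subtract"`.
#' @return The record with its `gir` column adjusted.
#' @export
urinary_correction <- function(record, mode = c("off", "subtract")) {
  mode <- match.arg(mode)
  if (mode == "off") return(record)
  stopifnot(all(c("urine_glucose_mmol", "weight_kg") %in% names(record)))
  dur <- max(record$time) - min(pmax(record$time, 0))
  rate <- record$urine_glucose_mmol[1] * 180.156 /
    (dur * record$weight_kg[1])
  adj <- record$gir - rate
  if (any(adj < 0 & record$gir > 0)) {
    warning("urinary correction drove GIR below zero; floored at 0",
            call. = FALSE)
  }
  record$gir <- pmax(adj, 0)
  record
}

#' All clamp indices for one participant-visit
#'
#' Deconvolves C-peptide into secretion, then computes the phase summaries:
#' late-phase GIR, mean/peak secretion per phase, glucose-normalized
#' late-phase secretion, the sensitivity index and the disposition index
#' (di = isr_norm x isi exactly).
#'
#' @param record A ClampRecord tibble for one participant-visit.
#' @param params Optional [cpeptide_params()]; when `NULL` they are derived
#'   from `profile`.
#' @param profile Optional one-row profile (age, sex, bmi) for population
#'   kinetics.
#' @param lambda_reg Deconvolution penalty (see [deconvolve_isr()]).
#' @param urinary Passed to [clamp_isi()].
#' @param isr Optional precomputed [isr_curve()] (skips the deconvolution).
#' @return One-row tibble of indices plus per-phase mean/peak secretion.
#' @export
clamp_indices <- function(record, params = NULL, profile = NULL,
                          lambda_reg = "auto", urinary = "off", isr = NULL) {
  w <- record$weight_kg[1]
  if (is.null(params) && is.null(isr)) {
    stopifnot(!is.null(profile))
    params <- cpeptide_population_params(profile$age, profile$sex, w,
                                         profile$bmi, diabetic = TRUE)
  }
  if (is.null(isr)) {
    isr <- deconvolve_isr(record$time, record$cpeptide, params, w,
                          lambda_reg = lambda_reg)
  }
  win_late <- c(90, 120)
  mean_isr <- phase_response(isr, win_late, "mean")
  mean_glc <- window_mean(record, "glucose", win_late)
  isi <- clamp_isi(record, win_late, urinary = urinary)
  isr_norm <- normalize_isr(mean_isr, mean_glc)
  phases <- phase_windows()
  phases <- phases[phases$name != "rise", ]
  resp <- purrr::map(seq_len(nrow(phases)), function(i) {
    wdw <- c(phases$start[i], phases$end[i])
    tibble::tibble(
      !!paste0("isr_mean_", phases$name[i]) := phase_response(isr, wdw, "mean"),
      !!paste0("isr_peak_", phases$name[i]) := phase_response(isr, wdw, "peak")
    )
  })
  dplyr::bind_cols(
    tibble::tibble(
      participant_id = record$participant_id[1],
      visit = record$visit[1],
      mean_gir = window_mean(record, "gir", win_late),
      mean_isr = mean_isr,
      peak_isr = phase_response(isr, win_late, "peak"),
      isr_norm = isr_norm,
      isi = isi,
      di = disposition_index(isr_norm, isi)
    ),
    dplyr::bind_cols(resp)
  )
}
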
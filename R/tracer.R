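# Stable-isotope glucose turnover via Steele's non-steady-state equations.
#
# Enrichment convention, documented once here and used everywhere: the
# `enrichment` column E is the tracer mole fraction (tracer / total glucose),
# in (0, 1). The tracer-to-tracee ratio is z = E / (1 - E), and the tracee
# concentration is C_tracee = C_total * (1 - E). At isotopic steady state the
# rate of appearance is F / z = F * (1 - E) / E, which reduces to F / E for
# small E.

# derivative by local linear fit over +-`half` points (5-point default);
# shrinks to the available points near the edges
.local_slope <- function(x, y, half = 2) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    xx <- x[lo:hi] - x[i]; yy <- y[lo:hi]
    sum(xx * (yy - mean(yy))) / sum(xx^2)
  }, numeric(1))
}

#' Basal (steady-state) glucose rate of appearance
#'
#' @param F_inf Tracer infusion rate (mg/kg/min).
#' @param enrichment_basal Tracer mole fraction E in (0, 1).
#' @return Ra = F * (1 - E) / E, mg/kg/min.
#' @export
#' @examples
#' basal_ra(0.04, 0.0235)
basal_ra <- function(F_inf, enrichment_basal) {
  stopifnot(F_inf > 0)
  if (any(enrichment_basal <= 0 | enrichment_basal >= 1)) {
    stop("enrichment must lie in (0, 1)", call. = FALSE)
  }
  F_inf * (1 - enrichment_basal) / enrichment_basal
}

#' Non-steady-state glucose turnover (single-pool Steele equations)
#'
#' Computes the rates of glucose appearance and disappearance and endogenous
#' glucose production from plasma glucose, tracer enrichment and the glucose
#' infusion rate. With z = E/(1-E) the tracer-to-tracee ratio and
#' C_t = C (1 - E) the tracee concentration (mg/ml),
#' Ra(t) = (F - p V C_t dz/dt) / z and Rd(t) = Ra(t) - p V dC_t/dt, with
#' derivatives estimated by 5-point local linear fits; EGP(t) = Ra(t) - GIR(t).
#' p = 0.65 and V = 145 ml/kg are the classic single-pool constants and can be
#' overridden.
#'
#' @param time Minutes, strictly increasing.
#' @param glucose Total plasma glucose (mmol/l).
#' @param enrichment Tracer mole fraction, in (0, 1).
#' @param gir Exogenous (unlabeled) glucose infusion rate (mg/kg/min).
#' @param F_inf Tracer infusion rate (mg/kg/min).
#' @param p Pool fraction (dimensionless, in (0, 1]).
#' @param V Distribution volume (ml/kg).
#' @return Tibble (TurnoverSeries): `time`, `ra`, `rd`, `egp` (mg/kg/min).
#' @export
steele_nonsteady <- function(time, glucose, enrichment, gir, F_inf,
                             p = 0.65, V = 145) {
  stopifnot(all(diff(time) > 0), length(glucose) == length(time),
            length(enrichment) == length(time), length(gir) == length(time),
            F_inf > 0, p > 0, p <= 1, V > 0)
  bad <- which(enrichment <= 0)
  if (length(bad)) {
    stop("non-positive enrichment at time ", time[bad[1]], " min",
         call. = FALSE)
  }
  z <- enrichment / (1 - enrichment)
  c_t <- glucose * 0.180156 * (1 - enrichment)      # tracee, mg/ml
  dz <- .local_slope(time, z)
  dct <- .local_slope(time, c_t)
  ra <- (F_inf - p * V * c_t * dz) / z
  rd <- ra - p * V * dct
  tibble::tibble(time = time, ra = ra, rd = rd, egp = ra - gir)
}

#' Window summary of endogenous glucose production
#'
#' Time-weighted mean EGP over a phase window. Negative values are retained
#' (they flag tracer noise or model misfit) and reported via the
#' `n_negative` attribute plus a warning.
#'
#' @param turnover A tibble from [steele_nonsteady()].
#' @param window `c(start, end)` minutes.
#' @return Scalar mean EGP (mg/kg/min) with attribute `n_negative`.
#' @export
egp_summary <- function(turnover, window) {
  m <- window_mean(turnover, "egp", window)
  inw <- turnover$egp[turnover$time >= window[1] & turnover$time <= window[2]]
  n_neg <- sum(inw < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative EGP value(s) in window", call. = FALSE)
  }
  attr(m, "n_negative") <- n_neg
  m
}

#' Turnover series for one clamp record
#'
#' Convenience wrapper running [steele_nonsteady()] on a ClampRecord tibble
#' using the protocol's tracer infusion rate.
#'
#' @param record A ClampRecord tibble.
#' @param protocol A [clamp_protocol()].
#' @param ... Passed to [steele_nonsteady()].
#' @return TurnoverSeries tibble with `participant_id` and `visit` columns.
#' @export
clamp_turnover <- function(record, protocol = clamp_protocol(), ...) {
  out <- steele_nonsteady(record$time, record$glucose, record$enrichment,
                          record$gir, F_inf = protocol$tracer_infusion, ...)
  dplyr::bind_cols(
    tibble::tibble(participant_id = record$participant_id[1],
                   visit = record$visit[1]),
    out
  )
}
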
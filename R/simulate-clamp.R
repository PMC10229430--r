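# Trace-level simulators for the two experimental days.
#
# The clamp generator is built so that, in the noiseless limit, the measured
# indices recover the latent truth exactly:
#  * disposal above basal is purely insulin-mediated (rate s_i * I * G), and
#    suppressed endogenous glucose production converges to the constant
#    non-insulin-mediated uptake, so at steady state GIR = s_i * I * G and the
#    clamp sensitivity index equals s_i;
#  * the whole secretion response scales with the latent amplitude, and the
#    clamp glucose level is the same at both visits, so glucose-normalized
#    secretion scales with the amplitude.
# The single glucose pool uses the Steele effective volume (p * V), which makes
# the non-steady-state tracer equations exact on generator data up to
# smoothing error.

# true insulin secretion rate (pmol/kg/min) at time t (min, hyperglycemia
# starts at 0). `isr_b` is the (amplitude-free) basal rate implied by the
# visit's fasting state; `isr_stim` sets the scale of the stimulated
# response, a property of beta-cell mass independent of insulin resistance;
# the latent amplitude multiplies the whole curve
.isr_truth <- function(t, isr_b, amp, isr_stim = isr_b,
                       glp1_from = 120, arg_from = 180) {
  stim <- numeric(length(t))
  hyper <- t > 0
  if (any(hyper)) {
    th <- t[hyper]
    first <- 1.5 * isr_stim * exp(-((th - 4)^2) / (2 * 2.5^2))
    late <- 6.7 * isr_stim / (1 + exp(-(th - 40) / 12))
    glp1_fac <- ifelse(th >= glp1_from,
                       1 + 1.5 * (1 - exp(-(th - glp1_from) / 8)), 1)
    arg <- ifelse(th >= arg_from,
                  59 * isr_stim * exp(-((th - 182.5)^2) / (2 * 2.5^2)), 0)
    stim[hyper] <- (first + late) * glp1_fac + arg
  }
  amp * (isr_b + stim)
}

#' Simulate one hyperglycemic clamp record
#'
#' Simulates the three-stage clamp for one participant-visit from the latent
#' truth: a tracer-equilibration basal period, a square-wave glucose infusion
#' raising glucose by the protocol increment, steady hyperglycemia maintained
#' by a proportional-integral controller updated every 5 min on measured
#' glucose, GLP-1 amplification of secretion from 120 min and an arginine
#' spike at 180 min. C-peptide is the exact forward two-compartment
#' convolution of the true secretion curve; insulin follows secretion with
#' first-order kinetics; enrichment follows the one-pool tracer mass balance
#' (prime + continuous infusion, diluted by unlabeled glucose infusion).
#' Multiplicative log-normal measurement noise is applied to sampled analytes
#' (half CV for glucose and enrichment, which are measured with tighter
#' analytic precision).
#'
#' @param profile One-row data frame from a cohort's `profiles`.
#' @param latent One row of the cohort `truth` for this participant-visit
#'   (fields `s_i`, `isr_amp`, `egp_basal`, `weight`, `visit`, and the
#'   visit-level fasting state `fg_v`, `fi_v`, `fc_v` plus `clamp_target`,
#'   the absolute glucose level targeted at both visits).
#' @param protocol A [clamp_protocol()].
#' @param seed Integer seed.
#' @param noise Apply measurement noise (and controller noise); `FALSE` gives
#'   the noiseless trace.
#' @param cv_meas Measurement CV (defaults 0.05).
#' @return Tibble (ClampRecord): `participant_id`, `visit`, `time`, `glucose`,
#'   `insulin`, `cpeptide`, `gir`, `enrichment`, `urine_glucose_mmol`,
#'   `weight_kg`.
#' @export
simulate_clamp <- function(profile, latent, protocol = clamp_protocol(),
                           seed = 1, noise = TRUE, cv_meas = 0.05) {
  s_i <- latent$s_i; amp <- latent$isr_amp
  egp_b <- latent$egp_basal; w <- latent$weight
  if (any(c(s_i, amp, egp_b, w) <= 0)) {
    stop("non-positive latent parameters for participant ", profile$id,
         call. = FALSE)
  }
  # this visit's fasting state follows from the latent physiology
  fs <- .fasting_state(profile$fasting_glucose, profile$fasting_insulin,
                       profile$fasting_cpeptide, s_i, amp)
  fg <- fs$fg; fi <- fs$fi; fc <- fs$fc
  target <- if ("clamp_target" %in% names(latent)) latent$clamp_target else
    fg + protocol$hyper_target_increment

  kparams <- cpeptide_population_params(profile$age, profile$sex, w,
                                        profile$bmi, diabetic = TRUE)
  # amplitude-free basal secretion; the visit's true basal ISR is amp * isr_b,
  # consistent with the visit's fasting C-peptide. The stimulated-response
  # scale derives from the participant's reference C-peptide (beta-cell
  # mass), not the resistance-driven fasting state
  isr_b <- fc * kparams$k01 * kparams$dist_volume / (w * amp)
  isr_stim <- profile$fasting_cpeptide * kparams$k01 * kparams$dist_volume / w

  vg <- 0.65 * 145                      # effective glucose pool, ml/kg
  vgc <- vg * 0.180156                  # mg/kg per mmol/l
  kI <- 0.15                            # insulin turnover, 1/min
  renal_thresh <- 10; renal_coef <- 0.02
  # the tracer infusion adds glucose mass too; basal steady state balances
  # EGP + tracer against uptake
  F_tr <- protocol$tracer_infusion
  nimgu <- max(egp_b + F_tr - s_i * fi * fg, 0.15)

  dt <- 0.5
  t_grid <- seq(-protocol$basal_minutes, 190, by = dt)
  nt <- length(t_grid)
  Tsq <- protocol$square_wave_minutes
  sq_rate <- vgc * protocol$hyper_target_increment / Tsq * 1.12

  withr::with_seed(seed, {
    G <- numeric(nt); I <- numeric(nt); qt_tr <- numeric(nt)
    gir <- numeric(nt); egp <- numeric(nt)
    G[1] <- fg; I[1] <- fi
    # prime scaled to fasting glucose (higher glycemia needs a larger bolus
    # to reach the target enrichment quickly)
    qt_tr[1] <- protocol$tracer_prime * fg / 8
    urine_mgkg <- 0
    cur_gir <- 0; e_prev <- 0; ctrl_on <- FALSE
    isr_t <- .isr_truth(t_grid, isr_b, amp, isr_stim = isr_stim)
    cv_g <- if (noise) cv_meas / 2.5 else 0

    for (k in seq_len(nt - 1)) {
      tk <- t_grid[k]
      # controller: square wave for 0 <= t < Tsq, then PI updates every 5 min
      if (tk >= 0 && tk < Tsq) {
        cur_gir <- sq_rate
      } else if (tk >= Tsq && (tk %% 5 == 0)) {
        g_meas <- G[k] * exp(rnorm(1, 0, .sdlog(cv_g)))
        e <- target - g_meas
        if (!ctrl_on) {         # initialize near the current requirement
          cur_gir <- max(s_i * I[k] * G[k], 0)
          ctrl_on <- TRUE
        } else {
          cur_gir <- max(cur_gir + 2.0 * (e - e_prev) + 0.2 * 5 * e, 0)
        }
        e_prev <- e
      } else if (tk < 0) {
        cur_gir <- 0
      }
      gir[k] <- cur_gir
      egp[k] <- if (tk < 0) egp_b else nimgu + (egp_b - nimgu) * exp(-tk / 25)
      renal <- renal_coef * max(G[k] - renal_thresh, 0)
      rd_ins <- s_i * I[k] * G[k]
      rd_tot <- nimgu + rd_ins + renal
      dG <- (cur_gir + F_tr + egp[k] - rd_tot) / vgc
      G[k + 1] <- max(G[k] + dG * dt, 0.1)
      I[k + 1] <- I[k] + kI * (fi * isr_t[k] / (amp * isr_b) - I[k]) * dt
      Q <- vgc * G[k]
      qt_tr[k + 1] <- max(qt_tr[k] +
                            (protocol$tracer_infusion - rd_tot * qt_tr[k] / Q) * dt, 0)
      urine_mgkg <- urine_mgkg + renal * dt
    }
    gir[nt] <- cur_gir
    egp[nt] <- nimgu + (egp_b - nimgu) * exp(-190 / 25)

    samp <- clamp_sampling_grid(protocol)
    idx <- match(round(samp / dt) * dt, round(t_grid / dt) * dt)
    enr <- qt_tr[idx] / (vgc * G[idx])
    cp_curve <- isr_curve(t_grid, head(isr_t, -1), w)
    cp <- forward_cpeptide(cp_curve, kparams, samp)

    ns <- length(samp)
    mnoise <- function(n, cv) if (noise) exp(rnorm(n, 0, .sdlog(cv))) else rep(1, n)
    rec <- tibble::tibble(
      participant_id = profile$id,
      visit = latent$visit,
      time = samp,
      glucose = G[idx] * mnoise(ns, cv_meas / 2.5),
      insulin = I[idx] * mnoise(ns, cv_meas),
      cpeptide = cp * mnoise(ns, cv_meas),
      gir = gir[idx],
      enrichment = pmin(pmax(enr * mnoise(ns, cv_meas / 2.5), 1e-6), 0.999),
      urine_glucose_mmol = urine_mgkg * w / 180.156,
      weight_kg = w
    )
  })
  attr(rec, "truth") <- list(isr_b = isr_b, nimgu = nimgu, egp = egp,
                             t_grid = t_grid, isr_t = isr_t,
                             target = target, kparams = kparams)
  rec
}

#' Simulate one mixed-meal tolerance test record
#'
#' Simulates a 3-h liquid-meal test for one participant-visit from the latent
#' truth, via a small feedback model: a gamma-shaped meal glucose appearance,
#' insulin-mediated disposal (rate `s_i * I * G`), glucose-driven insulin
#' secretion scaled by the latent amplitude (C-peptide as the exact forward
#' two-compartment convolution of the secretion curve), insulin-suppressed
#' endogenous glucose production, and deterministic incretin (GLP-1, GIP) and
#' paracetamol response curves. Glucose and insulin excursions therefore scale
#' inversely with true sensitivity/secretion, and curves return toward fasting
#' by 180 min.
#'
#' @inheritParams simulate_clamp
#' @return Tibble (MMTTRecord): `participant_id`, `visit`, `time`, `glucose`,
#'   `insulin`, `cpeptide`, `glp1_total`, `gip_total`, `paracetamol`.
#' @export
simulate_mmtt <- function(profile, latent, seed = 1, noise = TRUE,
                          cv_meas = 0.05) {
  s_i <- latent$s_i; amp <- latent$isr_amp
  egp_b <- latent$egp_basal; w <- latent$weight
  if (any(c(s_i, amp, egp_b, w) <= 0)) {
    stop("non-positive latent parameters for participant ", profile$id,
         call. = FALSE)
  }
  fs <- .fasting_state(profile$fasting_glucose, profile$fasting_insulin,
                       profile$fasting_cpeptide, s_i, amp)
  fg <- fs$fg; fi <- fs$fi; fc <- fs$fc
  kparams <- cpeptide_population_params(profile$age, profile$sex, w,
                                        profile$bmi, diabetic = TRUE)
  isr_b <- fc * kparams$k01 * kparams$dist_volume / (w * amp)
  isr_stim <- profile$fasting_cpeptide * kparams$k01 * kparams$dist_volume / w

  vgc <- 0.65 * 145 * 0.180156
  kI <- 0.15
  # glucose-stimulated secretion scales with the participant's stimulated
  # secretory capacity: relative response per mmol/l above fasting
  phi_rel <- 1.35
  meal_D <- 700                      # absorbed meal glucose, mg/kg
  tau_meal <- 40
  renal_thresh <- 10; renal_coef <- 0.02
  nimgu <- max(egp_b - s_i * fi * fg, 0.15)

  dt <- 0.5
  t_grid <- seq(0, 180, by = dt)
  nt <- length(t_grid)
  G <- numeric(nt); I <- numeric(nt); sig <- numeric(nt)
  G[1] <- fg; I[1] <- fi
  for (k in seq_len(nt - 1)) {
    tk <- t_grid[k]
    ra_meal <- meal_D * tk / tau_meal^2 * exp(-tk / tau_meal)
    sig[k] <- amp * (isr_b + phi_rel * isr_stim * max(G[k] - fg, 0))
    egp_m <- egp_b * sqrt(fi / max(I[k], 1))
    renal <- renal_coef * max(G[k] - renal_thresh, 0)
    dG <- (ra_meal + egp_m - nimgu - s_i * I[k] * G[k] - renal) / vgc
    G[k + 1] <- max(G[k] + dG * dt, 0.1)
    I[k + 1] <- I[k] + kI * (fi * sig[k] / (amp * isr_b) - I[k]) * dt
  }
  sig[nt] <- amp * (isr_b + phi_rel * isr_stim * max(G[nt] - fg, 0))

  samp <- c(0, 10, 20, 30, 45, 60, 90, 120, 150, 180)
  idx <- match(samp, t_grid)
  cp <- forward_cpeptide(isr_curve(t_grid, head(sig, -1), w), kparams, samp)
  gamma_curve <- function(t, a, tau) a * t / tau^2 * exp(-t / tau)
  glp1 <- 14 + gamma_curve(samp, 14 * 35 * exp(1) * 35 / 35, 35)
  gip <- 15 + gamma_curve(samp, 95 * 45 * exp(1), 45)
  par_c <- 0.09 * (1 - exp(-samp / 45))

  ns <- length(samp)
  withr::with_seed(seed, {
    mnoise <- function(n, cv) if (noise) exp(rnorm(n, 0, .sdlog(cv))) else rep(1, n)
    rec <- tibble::tibble(
      participant_id = profile$id,
      visit = latent$visit,
      time = samp,
      glucose = G[idx] * mnoise(ns, cv_meas),
      insulin = I[idx] * mnoise(ns, cv_meas),
      cpeptide = cp * mnoise(ns, cv_meas),
      glp1_total = glp1 * mnoise(ns, cv_meas),
      gip_total = gip * mnoise(ns, cv_meas),
      paracetamol = pmax(par_c * mnoise(ns, cv_meas), 0)
    )
  })
  attr(rec, "truth") <- list(G = G, I = I, sig = sig, t_grid = t_grid)
  rec
}

#' Simulate a complete trial (participants, clamp and meal-test time series)
#'
#' Generates a cohort with [generate_cohort()], applies missing-at-random
#' dropout of follow-up visits, and simulates a clamp and an MMTT record for
#' every remaining participant-visit.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; all per-record seeds derive from it.
#' @param noise Apply measurement noise.
#' @return List of class `trial_sim` with tibbles `participants`, `clamp`,
#'   `mmtt`, `truth`, plus `dropped` and the `config`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1, noise = TRUE) {
  cohort <- generate_cohort(config, seed = seed)
  cohort <- apply_missingness(cohort, seed = seed + 1L)
  tr <- cohort$truth
  seeds <- withr::with_seed(seed + 2L, sample.int(.Machine$integer.max - 1,
                                                  2 * nrow(tr)))
  recs <- purrr::map(seq_len(nrow(tr)), function(i) {
    prof <- cohort$profiles[cohort$profiles$id == tr$participant_id[i], ]
    list(
      clamp = simulate_clamp(prof, tr[i, ], config$protocol,
                             seed = seeds[2 * i - 1], noise = noise,
                             cv_meas = config$cv_meas),
      mmtt = simulate_mmtt(prof, tr[i, ], seed = seeds[2 * i], noise = noise,
                           cv_meas = config$cv_meas)
    )
  })
  structure(list(
    participants = cohort$profiles,
    clamp = dplyr::bind_rows(purrr::map(recs, "clamp")),
    mmtt = dplyr::bind_rows(purrr::map(recs, "mmtt")),
    truth = tr,
    dropped = cohort$dropped,
    config = config,
    seed = seed
  ), class = "trial_sim")
}
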
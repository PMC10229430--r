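#' Unit-conversion and protocol constants
#'
#' All unit conversions used across the package live in this one table so that
#' every module shares the same factors. Glucose molar mass 180.156 g/mol;
#' insulin immunoassay convention 1 uU/ml = 6.00 pmol/l.
#'
#' @return A tibble with columns `constant`, `value`, `unit`.
#' @export
#' @examples
#' unit_constants()
unit_constants <- function() {
  tibble::tribble(
    ~constant,                ~value,   ~unit,
    "glucose_mg_per_mmol",    180.156,  "mg/mmol",
    "glucose_mgdl_per_mmoll", 18.0156,  "(mg/dl)/(mmol/l)",
    "insulin_pmoll_per_uUml", 6.0,      "(pmol/l)/(uU/ml)"
  )
}

.const <- function(name) {
  tab <- unit_constants()
  tab$value[match(name, tab$constant)]
}

#' Hyperglycemic clamp protocol description
#'
#' Defines the three-stage hyperglycemic clamp: a tracer-equilibration basal
#' period, a square-wave glucose infusion raising plasma glucose to a fixed
#' increment above fasting, steady hyperglycemia maintained by feedback-adjusted
#' glucose infusion with 5-min glucose measurements, a GLP-1 infusion stage and
#' a terminal arginine bolus. Analysis phase windows (minutes relative to the
#' start of hyperglycemia) are `basal` (-basal_minutes, 0), `first_phase`
#' (0, 10), `steady_late` (90, 120), `glp1` (120, 180) and `arginine`
#' (180, 190).
#'
#' @param basal_minutes Tracer equilibration period before hyperglycemia (min).
#' @param hyper_target_increment Clamp target above fasting glucose (mmol/l).
#' @param square_wave_minutes Duration of the priming square-wave infusion (min).
#' @param glp1_rate GLP-1 infusion rate from 120 min (pmol/kg/min).
#' @param arginine_dose_g Arginine bolus at 180 min (g).
#' @param basal_sampling,hyper_sampling Sampling intervals (min) in the basal
#'   and hyperglycemic periods.
#' @param tracer_prime Priming tracer bolus (mg/kg).
#' @param tracer_infusion Continuous tracer infusion rate (mg/kg/min).
#' @return An object of class `clamp_protocol`.
#' @export
#' @examples
#' clamp_protocol()
clamp_protocol <- function(basal_minutes = 120,
                           hyper_target_increment = 5.4,
                           square_wave_minutes = 15,
                           glp1_rate = 0.5,
                           arginine_dose_g = 5,
                           basal_sampling = 10,
                           hyper_sampling = 5,
                           tracer_prime = 3.0,
                           tracer_infusion = 0.04) {
  stopifnot(
    basal_minutes > 0, hyper_target_increment > 0,
    square_wave_minutes > 0, glp1_rate >= 0, arginine_dose_g >= 0,
    basal_sampling > 0, hyper_sampling > 0,
    tracer_prime >= 0, tracer_infusion > 0
  )
  p <- list(
    basal_minutes = basal_minutes,
    hyper_target_increment = hyper_target_increment,
    square_wave_minutes = square_wave_minutes,
    glp1_rate = glp1_rate,
    arginine_dose_g = arginine_dose_g,
    basal_sampling = basal_sampling,
    hyper_sampling = hyper_sampling,
    tracer_prime = tracer_prime,
    tracer_infusion = tracer_infusion
  )
  class(p) <- "clamp_protocol"
  p
}

#' Analysis phase windows of the clamp
#'
#' @param protocol A [clamp_protocol()].
#' @return Tibble with `name`, `start`, `end` (min). Hyperglycemia phases are
#'   contiguous over 0-10, 10-90, 90-120, 120-180 and 180-190 min.
#' @export
phase_windows <- function(protocol = clamp_protocol()) {
  stopifnot(inherits(protocol, "clamp_protocol"))
  tibble::tribble(
    ~name,          ~start,                    ~end,
    "basal",        -protocol$basal_minutes,   0,
    "first_phase",  0,                         10,
    "rise",         10,                        90,
    "steady_late",  90,                        120,
    "glp1",         120,                       180,
    "arginine",     180,                       190
  )
}

#' Sampling grid of the clamp (minutes relative to start of hyperglycemia)
#' @param protocol A [clamp_protocol()].
#' @return Strictly increasing numeric vector of sampling times.
#' @export
clamp_sampling_grid <- function(protocol = clamp_protocol()) {
  c(
    seq(-protocol$basal_minutes, -protocol$basal_sampling,
        by = protocol$basal_sampling),
    seq(0, 190, by = protocol$hyper_sampling)
  )
}

# default multiplicative true follow-up/baseline effect ratios per arm.
# Sensitivity ratios follow the reported pairwise sensitivity effects; the
# secretion ratios are chosen so that the product (the disposition index)
# matches the reported primary-outcome effects of 58/105/137% exactly.
default_effect_ratio <- function() {
  list(
    isi = c(CON = 1, DCON = 1.18, MED = 1.50, HED = 1.83),
    isr = c(CON = 1, DCON = 1.58 / 1.18, MED = 2.05 / 1.50, HED = 2.37 / 1.83)
  )
}

#' Trial configuration for the synthetic cohort generator
#'
#' Collects all generator knobs: arm sizes, true multiplicative follow-up /
#' baseline effect ratios on the two latent physiologic factors (insulin
#' sensitivity `isi` and secretory capacity `isr`; the true disposition-index
#' ratio is their product), between- and within-subject log-normal coefficients
#' of variation, analytic measurement noise, dropout probability, arm-specific
#' relative weight change, and cohort marginals. Defaults reproduce the
#' conditions of a 4-arm diet/exercise dose trial in newly diagnosed type 2
#' diabetes: ~20 participants/arm, 35% female, age 58.2 (9.8) years, BMI
#' 33.1 (3.7) kg/m2, dropout 5/82, weight change 0/-7/-10/-12% in
#' CON/DCON/MED/HED, and true disposition-index ratios 1/1.58/2.05/2.37.
#'
#' @param n_per_arm Participants per arm (scalar or named vector over
#'   CON, DCON, MED, HED).
#' @param effect_ratio List with named numeric vectors `isi` and `isr`, true
#'   follow-up/baseline geometric-mean ratios per arm. All ratios must be > 0
#'   and CON defaults to 1.
#' @param cv_between Between-subject CV of each latent factor at baseline.
#' @param cv_within Within-subject visit-to-visit CV of each latent factor.
#' @param cv_meas Multiplicative measurement CV applied to sampled analytes.
#' @param dropout_prob Probability that a participant misses follow-up.
#' @param weight_change Named vector of mean relative weight change per arm.
#' @param med_reduction_prob Named vector: probability of glucose-lowering
#'   medication reduction at follow-up per arm (binary endpoint).
#' @param protocol A [clamp_protocol()].
#' @param age_mean,age_sd,female_prop,bmi_mean,bmi_sd,weight_mean,weight_sd
#'   Cohort marginals.
#' @param fasting_glucose,fasting_insulin,fasting_cpeptide Geometric means of
#'   fasting values (mmol/l, pmol/l, pmol/l).
#' @param egp_basal Basal endogenous glucose production (mg/kg/min).
#' @return An object of class `trial_config`.
#' @export
#' @examples
#' cfg <- trial_config(n_per_arm = 10, dropout_prob = 0)
#' cfg$effect_ratio$isi
trial_config <- function(n_per_arm = 20,
                         effect_ratio = default_effect_ratio(),
                         cv_between = 0.40,
                         cv_within = 0.25,
                         cv_meas = 0.05,
                         dropout_prob = 5 / 82,
                         weight_change = c(CON = 0, DCON = -0.07,
                                           MED = -0.10, HED = -0.12),
                         med_reduction_prob = c(CON = 0.11, DCON = 0.64,
                                                MED = 0.65, HED = 0.76),
                         protocol = clamp_protocol(),
                         age_mean = 58.2, age_sd = 9.8,
                         female_prop = 0.35,
                         bmi_mean = 33.1, bmi_sd = 3.7,
                         weight_mean = 101.4, weight_sd = 14.6,
                         fasting_glucose = 8.0,
                         fasting_insulin = 70,
                         fasting_cpeptide = 800,
                         egp_basal = 1.8) {
  arms <- c("CON", "DCON", "MED", "HED")
  if (length(n_per_arm) == 1) n_per_arm <- setNames(rep(n_per_arm, 4), arms)
  stopifnot(
    all(arms %in% names(n_per_arm)), all(n_per_arm >= 1),
    is.list(effect_ratio), all(c("isi", "isr") %in% names(effect_ratio)),
    cv_between >= 0, cv_within >= 0, cv_meas >= 0,
    dropout_prob >= 0, dropout_prob <= 1,
    all(arms %in% names(weight_change)),
    all(med_reduction_prob >= 0 & med_reduction_prob <= 1),
    inherits(protocol, "clamp_protocol"),
    fasting_glucose > 0, fasting_insulin > 0, fasting_cpeptide > 0,
    egp_basal > 0
  )
  for (f in c("isi", "isr")) {
    er <- effect_ratio[[f]]
    if (is.null(er["CON"]) || is.na(er["CON"])) er["CON"] <- 1
    if (any(er <= 0)) stop("effect ratios must be > 0", call. = FALSE)
    stopifnot(all(arms %in% names(er)))
    effect_ratio[[f]] <- er[arms]
  }
  cfg <- list(
    arms = arms,
    n_per_arm = n_per_arm[arms],
    effect_ratio = effect_ratio,
    cv_between = cv_between, cv_within = cv_within, cv_meas = cv_meas,
    dropout_prob = dropout_prob,
    weight_change = weight_change[arms],
    med_reduction_prob = med_reduction_prob[arms],
    protocol = protocol,
    age_mean = age_mean, age_sd = age_sd, female_prop = female_prop,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    fasting_glucose = fasting_glucose,
    fasting_insulin = fasting_insulin,
    fasting_cpeptide = fasting_cpeptide,
    egp_basal = egp_basal
  )
  class(cfg) <- "trial_config"
  cfg
}

#' Read a trial configuration from a YAML file
#'
#' The YAML document mirrors the arguments of [trial_config()]; nested keys
#' `effect_ratio: {isi: {...}, isr: {...}}` and `protocol: {...}` override the
#' defaults field by field.
#'
#' @param path Path to a YAML file.
#' @return A `trial_config` object.
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$protocol)) {
    args$protocol <- do.call(clamp_protocol, raw$protocol)
  }
  if (!is.null(raw$effect_ratio)) {
    er <- default_effect_ratio()
    for (f in names(raw$effect_ratio)) {
      er[[f]][names(raw$effect_ratio[[f]])] <- unlist(raw$effect_ratio[[f]])
    }
    args$effect_ratio <- er
  }
  for (nm in c("n_per_arm", "weight_change", "med_reduction_prob")) {
    if (!is.null(raw[[nm]]) && is.list(raw[[nm]])) {
      args[[nm]] <- unlist(raw[[nm]])
    }
  }
  do.call(trial_config, args)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat("  arms:", paste0(x$arms, " (n=", x$n_per_arm, ")", collapse = ", "), "\n")
  di <- x$effect_ratio$isi * x$effect_ratio$isr
  cat("  true DI ratios:", paste0(x$arms, "=", signif(di, 4), collapse = ", "), "\n")
  cat("  cv_between:", x$cv_between, " cv_within:", x$cv_within,
      " cv_meas:", x$cv_meas, "\n")
  cat("  dropout_prob:", signif(x$dropout_prob, 3), "\n")
  invisible(x)
}
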
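#' Stratified permuted-block randomization
#'
#' Allocates participants to the four arms in a 1:1:1:1 ratio using permuted
#' blocks within sex strata, as is standard for small parallel-arm trials.
#'
#' @param profiles Data frame with columns `id` and `sex` (`"F"`/`"M"`).
#' @param ratio Integer allocation ratio over CON, DCON, MED, HED.
#' @param block_size Block size; must be a multiple of `sum(ratio)`.
#' @param strata_by_sex Randomize within sex strata (default TRUE).
#' @param seed Integer seed; the allocation is deterministic given the seed.
#' @return Tibble with columns `id` and `group` (factor CON/DCON/MED/HED).
#' @export
#' @examples
#' prof <- tibble::tibble(id = sprintf("P%02d", 1:16),
#'                        sex = rep(c("F", "M"), each = 8))
#' randomize_arms(prof, seed = 1)
randomize_arms <- function(profiles, ratio = c(1, 1, 1, 1), block_size = 4,
                           strata_by_sex = TRUE, seed = 1) {
  arms <- c("CON", "DCON", "MED", "HED")
  if (block_size %% sum(ratio) != 0) {
    stop("`block_size` must be a multiple of sum(ratio) = ", sum(ratio),
         call. = FALSE)
  }
  stopifnot(all(c("id", "sex") %in% names(profiles)))
  block_pattern <- rep(arms, times = ratio * (block_size / sum(ratio)))
  withr::with_seed(seed, {
    strata <- if (strata_by_sex) split(profiles$id, profiles$sex) else
      list(all = profiles$id)
    out <- purrr::map(strata, function(ids) {
      n_blocks <- ceiling(length(ids) / block_size)
      alloc <- unlist(lapply(seq_len(n_blocks), function(b) sample(block_pattern)))
      tibble::tibble(id = ids, group = alloc[seq_along(ids)])
    })
  })
  dplyr::bind_rows(out) %>%
    dplyr::mutate(group = factor(group, levels = arms)) %>%
    dplyr::arrange(match(id, profiles$id))
}

# lognormal sd on the log scale for a given CV
.sdlog <- function(cv) sqrt(log(1 + cv^2))

# geometric-mean latent insulin sensitivity, mg/kg/min per (pmol/l x mmol/l)
.S_I_GM <- 3.6e-4

# visit-level fasting state closed over the latent physiology: fasting
# hyperglycemia worsens as secretion/sensitivity fall; fasting insulin and
# C-peptide rise with insulin resistance and with secretory capacity
.fasting_state <- function(fg_ref, fi_ref, fc_ref, s_i, amp) {
  s_rel <- s_i / .S_I_GM
  list(
    fg = pmin(pmax(fg_ref * amp^-0.2 * s_rel^-0.1, 4.5), 18),
    fi = fi_ref * amp * s_rel^-0.6,
    fc = fc_ref * amp * s_rel^-0.3
  )
}

#' Generate a synthetic trial cohort with latent ground truth
#'
#' Draws participant profiles (sex, age, body size, fasting values), assigns
#' arms by stratified permuted-block randomization, and draws each
#' participant's latent physiology: a true insulin-sensitivity factor `s_i`
#' (glucose disposal per unit insulin x glucose) and a true secretory
#' amplitude `isr_amp` multiplying the whole insulin-secretion response.
#' Both are log-normal between subjects; each visit receives an additional
#' within-subject log-normal perturbation; follow-up truth is baseline truth
#' multiplied by the arm's configured effect ratio. Follow-up weight is
#' baseline weight times (1 + weight_change[arm]) with a small individual
#' spread. The true disposition index is proportional to `s_i * isr_amp`.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return List of class `trial_cohort` with elements `profiles` (one row per
#'   participant) and `truth` (one row per participant-visit: latent factors,
#'   visit weight, true basal endogenous glucose production, and the true
#'   normalized indices `isi_true`, `isr_norm_true`, `di_true`).
#' @export
generate_cohort <- function(config = trial_config(), seed = 1) {
  stopifnot(inherits(config, "trial_config"))
  n <- sum(config$n_per_arm)
  sb <- .sdlog(config$cv_between)
  sw <- .sdlog(config$cv_within)

  withr::with_seed(seed, {
    n_f <- round(config$female_prop * n)
    sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
    profiles <- tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      sex = sex,
      age = pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 30), 80),
      bmi = pmin(pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 27.1), 39.9),
      weight = pmin(pmax(
        rnorm(n, config$weight_mean + ifelse(sex == "M", 6, -11), config$weight_sd),
        55), 160),
      fasting_glucose = config$fasting_glucose * exp(rnorm(n, 0, .sdlog(0.12))),
      fasting_insulin = config$fasting_insulin * exp(rnorm(n, 0, .sdlog(0.25)))
    )
    # C-peptide is co-secreted with insulin: the fasting molar ratio is
    # tightly distributed around its configured value
    profiles$fasting_cpeptide <- profiles$fasting_insulin *
      (config$fasting_cpeptide / config$fasting_insulin) *
      exp(rnorm(n, 0, .sdlog(0.10)))
    profiles$height <- sqrt(profiles$weight / profiles$bmi)

    # fill arms exactly to the configured sizes by drawing the randomization
    # on the realized cohort (block randomization gives +-1 balance)
    alloc <- randomize_arms(profiles, block_size = 4, seed = sample.int(1e8, 1))
    profiles$group <- alloc$group[match(profiles$id, alloc$id)]

    # latent physiology; geometric means shared across arms at baseline
    s_i_gm <- .S_I_GM
    amp_gm <- 1.0
    base <- tibble::tibble(
      participant_id = profiles$id,
      group = profiles$group,
      s_i0 = s_i_gm * exp(rnorm(n, 0, sb)),
      amp0 = amp_gm * exp(rnorm(n, 0, sb)),
      egp_basal = config$egp_basal * exp(rnorm(n, 0, .sdlog(0.10)))
    )
    er_isi <- unname(config$effect_ratio$isi[as.character(base$group)])
    er_isr <- unname(config$effect_ratio$isr[as.character(base$group)])
    wc <- unname(config$weight_change[as.character(profiles$group)])

    truth <- dplyr::bind_rows(
      base %>% dplyr::mutate(
        visit = "baseline",
        s_i = s_i0 * exp(rnorm(n, 0, sw)),
        isr_amp = amp0 * exp(rnorm(n, 0, sw)),
        weight = profiles$weight
      ),
      base %>% dplyr::mutate(
        visit = "followup",
        s_i = s_i0 * er_isi * exp(rnorm(n, 0, sw)),
        isr_amp = amp0 * er_isr * exp(rnorm(n, 0, sw)),
        weight = profiles$weight * (1 + wc + rnorm(n, 0, 0.015))
      )
    )
  })

  fs <- .fasting_state(
    profiles$fasting_glucose[match(truth$participant_id, profiles$id)],
    profiles$fasting_insulin[match(truth$participant_id, profiles$id)],
    profiles$fasting_cpeptide[match(truth$participant_id, profiles$id)],
    truth$s_i, truth$isr_amp
  )
  truth$fg_v <- fs$fg
  truth$fi_v <- fs$fi
  truth$fc_v <- fs$fc

  truth <- truth %>%
    dplyr::mutate(
      isi_true = s_i,
      isr_norm_true = isr_amp,
      di_true = s_i * isr_amp
    ) %>%
    dplyr::select(participant_id, visit, group, s_i, isr_amp, egp_basal,
                  weight, fg_v, fi_v, fc_v, isi_true, isr_norm_true,
                  di_true) %>%
    dplyr::arrange(participant_id, visit)

  # the clamp targets the baseline absolute glucose level at both visits
  bl_fg <- truth$fg_v[truth$visit == "baseline"]
  names(bl_fg) <- truth$participant_id[truth$visit == "baseline"]
  truth$clamp_target <- unname(bl_fg[truth$participant_id]) +
    config$protocol$hyper_target_increment

  structure(list(profiles = profiles, truth = truth, config = config,
                 dropped = character(0)),
            class = "trial_cohort")
}

#' Remove follow-up visits completely at random
#'
#' Dropout is missing completely at random at the participant level: each
#' participant's follow-up visit is removed with probability `dropout_prob`,
#' independently of arm and of all outcome values. Baseline visits are never
#' removed.
#'
#' @param cohort A `trial_cohort` from [generate_cohort()].
#' @param dropout_prob Dropout probability (defaults to the cohort config).
#' @param seed Integer seed.
#' @return The cohort with dropped follow-up rows removed from `truth` and the
#'   dropped ids recorded in `$dropped`.
#' @export
apply_missingness <- function(cohort, dropout_prob = NULL, seed = 1) {
  stopifnot(inherits(cohort, "trial_cohort"))
  if (is.null(dropout_prob)) dropout_prob <- cohort$config$dropout_prob
  ids <- cohort$profiles$id
  withr::with_seed(seed, {
    drop <- ids[runif(length(ids)) < dropout_prob]
  })
  cohort$truth <- cohort$truth %>%
    dplyr::filter(!(participant_id %in% drop & visit == "followup"))
  cohort$dropped <- drop
  cohort
}

#' Outcome-level long dataset from a synthetic cohort
#'
#' Produces the trial-level analysis table directly from the cohort's latent
#' per-visit truth, adding multiplicative log-normal measurement noise with
#' geometric mean one. This is the fast route for statistical calibration
#' studies; the full trace-level route (simulate, deconvolve, index) is
#' exercised by [simulate_trial()] and [derive_indices()].
#'
#' @param cohort A `trial_cohort`.
#' @param outcome One of "di", "isi", "isr", "weight".
#' @param seed Integer seed for the measurement noise.
#' @return Tibble (LongDataset): `participant_id`, `visit` (0 baseline /
#'   1 follow-up), `group`, `sex`, `value`.
#' @export
simulate_outcome_data <- function(cohort, outcome = c("di", "isi", "isr", "weight"),
                                  seed = 1) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(cohort, "trial_cohort"))
  col <- switch(outcome, di = "di_true", isi = "isi_true",
                isr = "isr_norm_true", weight = "weight")
  sm <- .sdlog(cohort$config$cv_meas)
  tr <- cohort$truth
  withr::with_seed(seed, {
    noise <- exp(rnorm(nrow(tr), 0, sm))
  })
  tibble::tibble(
    participant_id = tr$participant_id,
    visit = ifelse(tr$visit == "baseline", 0L, 1L),
    group = tr$group,
    sex = cohort$profiles$sex[match(tr$participant_id, cohort$profiles$id)],
    value = tr[[col]] * if (outcome == "weight") 1 else noise
  )
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat("<trial_cohort> ", nrow(x$profiles), " participants, ",
      nrow(x$truth), " participant-visits",
      if (length(x$dropped)) paste0(" (", length(x$dropped), " dropped)"), "\n",
      sep = "")
  print(table(x$profiles$group, x$profiles$sex))
  invisible(x)
}
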
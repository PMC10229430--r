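# Orchestration: simulate -> derive -> analyze -> report, with CSV contracts
# between stages and a reproducibility manifest.

.long_format <- function(rec, analytes, units) {
  purrr::map(seq_along(analytes), function(i) {
    tibble::tibble(
      participant_id = rec$participant_id,
      visit = rec$visit,
      time_min = rec$time,
      analyte = analytes[i],
      value = rec[[analytes[i]]],
      unit = units[i]
    )
  }) %>% dplyr::bind_rows()
}

#' Derive all per-participant indices from simulated time series
#'
#' Runs the derivation layer over every participant-visit: C-peptide
#' deconvolution, clamp indices, Steele turnover window summaries and
#' meal-test indices, joined into one indices table.
#'
#' @param sim A `trial_sim` from [simulate_trial()].
#' @param lambda_reg Deconvolution penalty (see [deconvolve_isr()]).
#' @return List with `indices` (one row per participant-visit), `isr`
#'   (piecewise-constant secretion curves, long) and `turnover` (Ra/Rd/EGP
#'   series, long).
#' @export
derive_indices <- function(sim, lambda_reg = "auto") {
  stopifnot(inherits(sim, "trial_sim"))
  keys <- dplyr::distinct(sim$clamp, participant_id, visit)
  out <- purrr::map(seq_len(nrow(keys)), function(i) {
    pid <- keys$participant_id[i]; vis <- keys$visit[i]
    rec <- sim$clamp %>% dplyr::filter(participant_id == pid, visit == vis)
    prof <- sim$participants[sim$participants$id == pid, ]
    params <- cpeptide_population_params(prof$age, prof$sex, rec$weight_kg[1],
                                         prof$bmi, diabetic = TRUE)
    isr <- deconvolve_isr(rec$time, rec$cpeptide, params, rec$weight_kg[1],
                          lambda_reg = lambda_reg)
    ci <- clamp_indices(rec, isr = isr)
    to <- clamp_turnover(rec, sim$config$protocol)
    # basal summary over the equilibrated mid-basal window: the prime
    # transient (early) and the smoothing window crossing the start of
    # hyperglycemia (late) are excluded
    basal_egp <- egp_summary(to, c(-60, -20))
    late_egp <- egp_summary(to, c(90, 120))
    late_ra <- window_mean(to, "ra", c(90, 120))
    late_rd <- window_mean(to, "rd", c(90, 120))
    mrec <- sim$mmtt %>% dplyr::filter(participant_id == pid, visit == vis)
    mi <- mmtt_indices(mrec) %>% dplyr::select(-participant_id, -visit)
    list(
      indices = dplyr::bind_cols(
        ci,
        tibble::tibble(egp_basal = as.numeric(basal_egp),
                       egp_late = as.numeric(late_egp),
                       ra_late = late_ra, rd_late = late_rd),
        mi
      ),
      isr = dplyr::bind_cols(
        tibble::tibble(participant_id = pid, visit = vis),
        as_tibble(isr)
      ),
      turnover = to
    )
  })
  list(
    indices = dplyr::bind_rows(purrr::map(out, "indices")),
    isr = dplyr::bind_rows(purrr::map(out, "isr")),
    turnover = dplyr::bind_rows(purrr::map(out, "turnover"))
  )
}

#' Long analysis dataset for one outcome from the indices table
#'
#' @param indices Indices tibble from [derive_indices()].
#' @param participants Profiles tibble (for group and sex).
#' @param outcome Column of `indices` to analyze (e.g. `"di"`).
#' @return LongDataset tibble for [fit_clda()].
#' @export
outcome_dataset <- function(indices, participants, outcome = "di") {
  stopifnot(outcome %in% names(indices))
  tibble::tibble(
    participant_id = indices$participant_id,
    visit = ifelse(indices$visit == "baseline", 0L, 1L),
    group = participants$group[match(indices$participant_id, participants$id)],
    sex = participants$sex[match(indices$participant_id, participants$id)],
    value = indices[[outcome]]
  )
}

#' Full trial analysis of one outcome
#'
#' Fits the log-scale constrained-baseline model, the dose trend, and builds
#' the gatekeeping comparison report.
#'
#' @param indices,participants As for [outcome_dataset()].
#' @param outcome Outcome column.
#' @param log_scale Analyze on the log scale (default).
#' @return A `comparison_report` (see [gatekeep_report()]); the underlying
#'   fit is attached as attribute `fit`.
#' @export
analyze_trial <- function(indices, participants, outcome = "di",
                          log_scale = TRUE) {
  d <- outcome_dataset(indices, participants, outcome)
  fit <- fit_clda(d, log_scale = log_scale)
  tr <- trend_test(d, log_scale = log_scale)
  rep <- gatekeep_report(fit, trend = tr)
  attr(rep, "fit") <- fit
  rep
}

# medication-reduction binary endpoint: simulated per arm probability
.simulate_medication <- function(participants, config, seed) {
  withr::with_seed(seed, {
    pr <- config$med_reduction_prob[as.character(participants$group)]
    tibble::tibble(
      participant_id = participants$id,
      group = participants$group,
      med_reduction = rbinom(nrow(participants), 1, pr)
    )
  })
}

.medication_report <- function(med) {
  po <- .pair_order()
  arms <- strsplit(po$pair, " vs ")
  purrr::map(seq_along(arms), function(i) {
    a <- arms[[i]][1]; b <- arms[[i]][2]
    na <- sum(med$group == a); nb <- sum(med$group == b)
    ea <- sum(med$med_reduction[med$group == a])
    eb <- sum(med$med_reduction[med$group == b])
    dplyr::bind_cols(tibble::tibble(pair = po$pair[i], events_a = ea,
                                    n_a = na, events_b = eb, n_b = nb),
                     continuity_or(ea, na, eb, nb))
  }) %>% dplyr::bind_rows()
}

#' Run the complete pipeline and write all artifacts
#'
#' simulate -> derive -> analyze -> report as one reproducible run: writes
#' participants.csv, clamp.csv and mmtt.csv (long format), truth.csv, isr.csv,
#' indices.csv, turnover.csv, report_comparisons.csv (pairwise
#' geometric-mean-ratio report with global/trend/gatekeeping annotations for
#' the disposition index, sensitivity and secretion) and
#' report_medication.csv (continuity-corrected odds ratios), plus a JSON run
#' manifest with the config hash, seed, stage timings, row counts and output
#' hashes. Identical config and seed give identical outputs and manifest
#' hashes.
#'
#' @param config A [trial_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param outcomes Indices columns to analyze.
#' @return The manifest (invisibly), as a list.
#' @export
run_pipeline <- function(config = trial_config(), out_dir, seed = 1,
                         outcomes = c("di", "isi", "isr_norm")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list(); t0 <- Sys.time()
  tick <- function(nm) {
    timings[[nm]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  sim <- simulate_trial(config, seed = seed)
  tick("simulate")

  derived <- derive_indices(sim)
  tick("derive")

  med <- .simulate_medication(sim$participants, config, seed + 3L)
  reports <- purrr::map(outcomes, function(oc) {
    rep <- analyze_trial(derived$indices, sim$participants, outcome = oc)
    dplyr::bind_cols(tibble::tibble(outcome = oc), as_tibble(rep)) %>%
      dplyr::mutate(global_p = attr(rep, "global_p"),
                    trend_p = attr(rep, "trend_p"))
  }) %>% dplyr::bind_rows()
  med_report <- .medication_report(med)
  tick("analyze")

  files <- list(
    participants.csv = sim$participants,
    clamp.csv = .long_format(
      sim$clamp,
      c("glucose", "insulin", "cpeptide", "gir", "enrichment"),
      c("mmol/l", "pmol/l", "pmol/l", "mg/kg/min", "fraction")),
    mmtt.csv = .long_format(
      sim$mmtt,
      c("glucose", "insulin", "cpeptide", "glp1_total", "gip_total",
        "paracetamol"),
      c("mmol/l", "pmol/l", "pmol/l", "pmol/l", "pmol/l", "mmol/l")),
    truth.csv = sim$truth,
    isr.csv = derived$isr,
    indices.csv = derived$indices,
    turnover.csv = derived$turnover,
    report_comparisons.csv = reports,
    report_medication.csv = med_report
  )
  inventory <- purrr::imap(files, function(df, nm) {
    path <- file.path(out_dir, nm)
    readr::write_csv(df, path)
    tibble::tibble(file = nm, rows = nrow(df),
                   hash = rlang::hash(readr::read_file(path)))
  }) %>% dplyr::bind_rows()
  tick("write")

  manifest <- list(
    package_version = as.character(utils::packageVersion("dosedi")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_participants = nrow(sim$participants),
    dropped = sim$dropped,
    stage_timings_s = timings,
    outputs = purrr::transpose(inventory)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Deterministic micro-fixtures for unit tests
#'
#' A 4-participant micro-cohort with hand-checkable constant traces: clamp
#' glucose 13 mmol/l, insulin 500 pmol/l, GIR 2.6 mg/kg/min (so
#' ISI = 2.6 / (500 x 13)), constant C-peptide and enrichment, and constant
#' meal-test curves (so every iAUC is exactly 0).
#'
#' @param out_dir Optional directory; when given, the fixtures are written as
#'   CSV files.
#' @return List with `participants`, `clamp`, `mmtt`.
#' @export
make_fixtures <- function(out_dir = NULL) {
  participants <- tibble::tibble(
    id = sprintf("F%02d", 1:4),
    sex = c("F", "M", "F", "M"),
    age = c(55, 60, 58, 62),
    bmi = c(32, 33, 34, 31),
    weight = c(90, 100, 95, 105),
    height = sqrt(c(90, 100, 95, 105) / c(32, 33, 34, 31)),
    group = factor(c("CON", "DCON", "MED", "HED"),
                   levels = c("CON", "DCON", "MED", "HED")),
    fasting_glucose = 8, fasting_insulin = 70, fasting_cpeptide = 800
  )
  grid <- clamp_sampling_grid()
  clamp <- purrr::map(seq_len(4), function(i) {
    tibble::tibble(
      participant_id = participants$id[i],
      visit = "baseline",
      time = grid,
      glucose = 13, insulin = 500, cpeptide = 2000, gir = 2.6,
      enrichment = 0.01, urine_glucose_mmol = 10,
      weight_kg = participants$weight[i]
    )
  }) %>% dplyr::bind_rows()
  mt <- c(0, 10, 20, 30, 45, 60, 90, 120, 150, 180)
  mmtt <- purrr::map(seq_len(4), function(i) {
    tibble::tibble(
      participant_id = participants$id[i],
      visit = "baseline",
      time = mt,
      glucose = 8, insulin = 100, cpeptide = 900, glp1_total = 15,
      gip_total = 20, paracetamol = 0.05
    )
  }) %>% dplyr::bind_rows()
  out <- list(participants = participants, clamp = clamp, mmtt = mmtt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    purrr::iwalk(out, function(df, nm) {
      readr::write_csv(df, file.path(out_dir, paste0("fixture_", nm, ".csv")))
    })
  }
  out
}
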
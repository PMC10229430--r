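# shared builders for the statistical-layer tests

# complete balanced 4-arm long dataset with multiplicative arm effects on the
# follow-up; equal baseline geometric means by construction
make_long_data <- function(n_per_arm = 10, ratios = c(CON = 1, DCON = 1,
                                                      MED = 1, HED = 1),
                           sd_change = 0.3, sd_base = 0.4, rho = 0.6,
                           seed = 1, dropout = 0) {
  arms <- names(ratios)
  n <- n_per_arm * length(arms)
  withr::with_seed(seed, {
    grp <- factor(rep(arms, each = n_per_arm), levels = arms)
    sex <- sample(rep(c("F", "M"), length.out = n))
    u <- rnorm(n, 0, sd_base)                      # shared subject level
    e0 <- rnorm(n, 0, sd_change)
    e1 <- rnorm(n, 0, sd_change)
    y0 <- u + e0
    y1 <- u + e1 + log(ratios[as.character(grp)])
    keep_fu <- runif(n) >= dropout
  })
  d <- tibble::tibble(
    participant_id = rep(sprintf("S%03d", 1:n), 2),
    visit = rep(0:1, each = n),
    group = rep(grp, 2),
    sex = rep(sex, 2),
    value = exp(c(y0, y1))
  )
  d[d$visit == 0 | rep(keep_fu, 2), ]
}

# one simulated participant-visit pair (profile + baseline latent row)
make_participant <- function(seed = 4, visit = "baseline") {
  coh <- generate_cohort(trial_config(n_per_arm = 2), seed = seed)
  id <- coh$profiles$id[1]
  list(profile = coh$profiles[1, ],
       latent = coh$truth[coh$truth$participant_id == id &
                            coh$truth$visit == visit, ])
}

study_params <- cpeptide_params(4.52, 37, 0.78, 5.2)
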
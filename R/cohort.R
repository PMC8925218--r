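# Synthetic cohort generator: per-heel true parameters with the covariate
# and correlation structure of a healthy adult gait cohort measured at both
# time-zero (rested) and post-loading (fatigue) conditions.

#' Cohort sampling configuration
#'
#' Defaults are the package's `paper_defaults` calibration: per-condition
#' medians and dispersions of a published in-vivo heel-pad cohort of healthy
#' adults (time-zero vs post-loading), with latent linear regressions that
#' induce the reported correlation structure (thickness decreasing with age,
#' viscous modulus increasing with age and strongly coupled to the elastic
#' modulus). Post-loading shifts are multiplicative: the viscous modulus is
#' roughly halved, primary thickness slightly reduced, the elastic modulus
#' unchanged. See the methods vignette for the calibration arithmetic.
#'
#' @param n_subjects number of subjects (each contributes 2 sides x 2
#'   conditions = 4 heels).
#' @param age_range sampling range for age (years), uniform.
#' @param bmi_mean,bmi_sd,bmi_range body mass index distribution (kg/m^2),
#'   truncated normal.
#' @param h0_median cohort median unloaded thickness (mm) at time zero.
#' @param h0_age_slope change in h0 per year of age (mm/yr, negative).
#' @param h0_subject_sd,h0_side_sd between-subject / between-side thickness
#'   SD (mm).
#' @param h0_post_multiplier multiplicative post-loading thickness shift.
#' @param h0_condition_sd per-condition additive jitter SD (mm).
#' @param elastic_median cohort median elastic modulus E (kPa).
#' @param log_elastic_subject_sd,log_elastic_side_sd log-scale E dispersion.
#' @param elastic_post_multiplier post-loading E shift (1 = unchanged).
#' @param log_elastic_condition_sd per-condition log-scale E jitter (test-
#'   retest variability of the measurement).
#' @param eta_median cohort median viscous modulus (kPa s) at time zero.
#' @param eta_elastic_coupling,eta_age_coupling log-eta loadings on the
#'   subject elastic latent and on standardized age.
#' @param log_eta_side_sd residual log-eta SD per side.
#' @param eta_post_multiplier multiplicative post-loading eta shift (< 1:
#'   viscous modulus drops after sustained loading).
#' @param log_eta_condition_sd per-condition log-scale eta jitter.
#' @param peak_strain_median cohort median peak compressive strain.
#' @param peak_strain_subject_sd,peak_strain_side_sd additive dispersions.
#' @param peak_strain_post_shift additive post-loading shift.
#' @param peak_strain_condition_sd per-condition additive jitter.
#' @param stance_duration_mean,stance_duration_sd heel-contact duration (s).
#' @param noise_cv multiplicative stress measurement noise, coefficient of
#'   variation (0 disables).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10L,
                          age_range = c(23, 72),
                          bmi_mean = 24.6, bmi_sd = 3.5,
                          bmi_range = c(19.2, 31.9),
                          h0_median = 15.99,
                          h0_age_slope = -0.0717,
                          h0_subject_sd = 1.72,
                          h0_side_sd = 0.3,
                          h0_post_multiplier = 15.72 / 15.99,
                          h0_condition_sd = 0.05,
                          elastic_median = 192.55,
                          log_elastic_subject_sd = 0.15,
                          log_elastic_side_sd = 0.05,
                          elastic_post_multiplier = 1,
                          log_elastic_condition_sd = 0.06,
                          eta_median = 43.9,
                          eta_elastic_coupling = 0.29,
                          eta_age_coupling = 0.12,
                          log_eta_side_sd = 0.06,
                          eta_post_multiplier = 20.37 / 43.9,
                          log_eta_condition_sd = 0.08,
                          peak_strain_median = 0.685,
                          peak_strain_subject_sd = 0.015,
                          peak_strain_side_sd = 0.005,
                          peak_strain_post_shift = 0.005,
                          peak_strain_condition_sd = 0.005,
                          stance_duration_mean = 0.6,
                          stance_duration_sd = 0.04,
                          noise_cv = 0.01) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 0 || n_subjects != round(n_subjects))
    stopf("'n_subjects' must be a non-negative integer",
          class = "invalid_config_error")
  if (length(age_range) != 2L || age_range[1L] >= age_range[2L])
    stopf("'age_range' must be an increasing pair of ages",
          class = "invalid_config_error")
  for (nm in c("bmi_sd", "h0_subject_sd", "h0_side_sd", "h0_condition_sd",
               "log_elastic_subject_sd", "log_elastic_side_sd",
               "log_elastic_condition_sd", "log_eta_side_sd",
               "log_eta_condition_sd", "peak_strain_subject_sd",
               "peak_strain_side_sd", "peak_strain_condition_sd",
               "stance_duration_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("dispersion '%s' must be a positive number", nm,
            class = "invalid_config_error")
  }
  assert_number(h0_median, "h0_median", lower = 0, strict_lower = TRUE)
  assert_number(elastic_median, "elastic_median", lower = 0, strict_lower = TRUE)
  assert_number(eta_median, "eta_median", lower = 0)
  assert_number(peak_strain_median, "peak_strain_median",
                lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_number(stance_duration_mean, "stance_duration_mean",
                lower = 0, strict_lower = TRUE)
  assert_number(noise_cv, "noise_cv", lower = 0)
  assert_number(h0_post_multiplier, "h0_post_multiplier", lower = 0,
                strict_lower = TRUE)
  assert_number(eta_post_multiplier, "eta_post_multiplier", lower = 0)
  assert_number(elastic_post_multiplier, "elastic_post_multiplier", lower = 0,
                strict_lower = TRUE)
  structure(mget(names(formals(cohort_config))), class = "cohort_config")
}

#' Sample a synthetic heel cohort
#'
#' Draws per-heel true parameters for `n_subjects` subjects, each measured on
#' both sides under both loading conditions (4 heels per subject; covariates
#' shared within subject). All randomness flows from `seed` through
#' per-subject / per-side / per-condition sub-streams ([derive_seed()]), so
#' identical `(cfg, seed)` give byte-identical cohorts.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer master seed.
#' @return A data frame of class `heel_cohort`, one row per heel, with
#'   columns `subject_id`, `side`, `condition`, `age`, `bmi`, `h0_true` (mm),
#'   `E_true` (kPa), `eta_true` (kPa s), `peak_strain_true`,
#'   `stance_duration` (s), `noise_cv`, `trial_seed`.
#' @export
#' @examples
#' coh <- sample_cohort(cohort_config(n_subjects = 2), seed = 1)
#' nrow(coh) # 8 heels
sample_cohort <- function(cfg = cohort_config(), seed = 1L) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  assert_number(seed, "seed")
  n <- as.integer(cfg$n_subjects)
  sides <- c("left", "right")
  conditions <- c("time_zero", "post_loading")
  rows <- vector("list", n * 4L)
  age_mid <- mean(cfg$age_range)
  age_sd_u <- diff(cfg$age_range) / sqrt(12) # sd of the uniform age draw
  k <- 0L
  for (i in seq_len(n)) {
    sid <- sprintf("S%02d", i)
    subj <- with_seed(derive_seed(seed, "subject", sid), {
      list(age = runif(1, cfg$age_range[1L], cfg$age_range[2L]),
           bmi = rnorm_trunc(1, cfg$bmi_mean, cfg$bmi_sd,
                             cfg$bmi_range[1L], cfg$bmi_range[2L]),
           z_elastic = rnorm(1),
           h0_resid = rnorm(1, 0, cfg$h0_subject_sd),
           peak_resid = rnorm(1, 0, cfg$peak_strain_subject_sd))
    })
    z_age <- (subj$age - age_mid) / age_sd_u
    h0_subject <- cfg$h0_median + cfg$h0_age_slope * (subj$age - age_mid) +
      subj$h0_resid
    for (sd_ in sides) {
      sidevals <- with_seed(derive_seed(seed, "side", sid, sd_), {
        list(h0_side = rnorm(1, 0, cfg$h0_side_sd),
             logE_side = rnorm(1, 0, cfg$log_elastic_side_sd),
             logeta_side = rnorm(1, 0, cfg$log_eta_side_sd),
             peak_side = rnorm(1, 0, cfg$peak_strain_side_sd))
      })
      h0_heel <- max(h0_subject + sidevals$h0_side, 1)
      E_heel <- cfg$elastic_median *
        exp(cfg$log_elastic_subject_sd * subj$z_elastic + sidevals$logE_side)
      eta_heel <- cfg$eta_median *
        exp(cfg$eta_elastic_coupling * subj$z_elastic +
            cfg$eta_age_coupling * z_age + sidevals$logeta_side)
      peak_heel <- subj$peak_resid + sidevals$peak_side +
        cfg$peak_strain_median
      for (cond in conditions) {
        cv <- with_seed(derive_seed(seed, "condition", sid, sd_, cond), {
          list(h0_j = rnorm(1, 0, cfg$h0_condition_sd),
               logE_j = rnorm(1, 0, cfg$log_elastic_condition_sd),
               logeta_j = rnorm(1, 0, cfg$log_eta_condition_sd),
               peak_j = rnorm(1, 0, cfg$peak_strain_condition_sd),
               stance = rnorm_trunc(1, cfg$stance_duration_mean,
                                    cfg$stance_duration_sd,
                                    0.3, 2))
        })
        post <- cond == "post_loading"
        h0 <- max((if (post) h0_heel * cfg$h0_post_multiplier else h0_heel) +
                    cv$h0_j, 1)
        E <- E_heel * (if (post) cfg$elastic_post_multiplier else 1) *
          exp(cv$logE_j)
        eta <- eta_heel * (if (post) cfg$eta_post_multiplier else 1) *
          exp(cv$logeta_j)
        peak <- min(max(peak_heel + (if (post) cfg$peak_strain_post_shift else 0) +
                          cv$peak_j, 0.05), 0.95)
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = sid, side = sd_, condition = cond,
          age = subj$age, bmi = subj$bmi,
          h0_true = h0, E_true = E, eta_true = eta,
          peak_strain_true = peak, stance_duration = cv$stance,
          noise_cv = cfg$noise_cv,
          trial_seed = derive_seed(seed, "trial", sid, sd_, cond),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (k == 0L) data.frame(
    subject_id = character(), side = character(), condition = character(),
    age = numeric(), bmi = numeric(), h0_true = numeric(),
    E_true = numeric(), eta_true = numeric(), peak_strain_true = numeric(),
    stance_duration = numeric(), noise_cv = numeric(),
    trial_seed = integer(), stringsAsFactors = FALSE)
  else do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  class(out) <- c("heel_cohort", "data.frame")
  out
}
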
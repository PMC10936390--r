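#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of older adults with demographic covariates (age,
#' gender), physical performance (SPPB, 0-12) and cognition (MoCA, 0-30),
#' and a set of gait outcomes generated from a linear model in those
#' covariates plus Gaussian residuals. The true coefficients are returned
#' with the cohort so estimator recovery can be tested.
#'
#' `effects` is a named list: one entry per outcome, each a named numeric
#' vector with elements among `intercept`, `age`, `gender`, `sppb`, `moca`.
#'
#' @param n_subjects Number of subjects (>= 4: enough for a three-predictor
#'   regression).
#' @param age_range Length-2 years, e.g. `c(65, 85)`.
#' @param gender_mix Proportion of subjects coded `gender = 1`.
#' @param sppb_range,moca_range Length-2 integer score ranges.
#' @param effects Named list of true linear-model coefficients (see above).
#' @param noise_sd Residual SD: single number or named per outcome.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 24,
                          age_range = c(65, 85),
                          gender_mix = 0.5,
                          sppb_range = c(4, 12),
                          moca_range = c(10, 30),
                          effects = default_cohort_effects(),
                          noise_sd = 0.05,
                          seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 4)
  check_number(gender_mix, "gender_mix", lower = 0, upper = 1)
  for (nm in c("age_range", "sppb_range", "moca_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[2] <= r[1]) {
      abort(sprintf("`%s` must be a non-degenerate (low, high) range.", nm),
            class = "gaitmos_config_error")
    }
  }
  if (!is.list(effects) || is.null(names(effects))) {
    abort("`effects` must be a named list of coefficient vectors.",
          class = "gaitmos_config_error")
  }
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 gender_mix = gender_mix, sppb_range = sppb_range,
                 moca_range = moca_range, effects = effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort effect structure
#'
#' Effects emulating the directions reported for guided dual-task walking
#' in older adults: stride length increases with SPPB; dual-task increases
#' in stride-time variability decrease with MoCA; the dual-task/normal
#' ratio of the anteroposterior stability margin increases with MoCA.
#'
#' @return Named list of coefficient vectors (units: outcome units per
#'   covariate unit).
#' @export
default_cohort_effects <- function() {
  list(
    sl_mean_N = c(intercept = 1.45, age = -0.006, gender = 0.03, sppb = 0.02),
    sv_mean_N = c(intercept = 1.30, age = -0.006, gender = 0.02, sppb = 0.01),
    st_cv_dn = c(intercept = 6.0, age = 0.02, gender = 0.2, moca = -0.15),
    sv_cv_dn = c(intercept = 5.5, age = 0.02, gender = 0.2, moca = -0.12),
    mos_ap_ratio = c(intercept = 0.55, age = 0.002, gender = -0.02,
                     moca = 0.012))
}

#' Generate a synthetic cohort
#'
#' Draws covariates (uniform age, Bernoulli gender, uniform integer SPPB
#' and MoCA) and generates each configured outcome from its linear model
#' plus Gaussian residuals.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (tibble, one row per subject: `id`, `age`,
#'   `gender`, `sppb`, `moca`, one column per outcome) and `true_effects`
#'   (the coefficient list used).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().",
          class = "gaitmos_config_error")
  }
  set.seed(config$seed)
  n <- config$n_subjects
  cohort <- tibble::tibble(
    id = seq_len(n),
    age = runif(n, config$age_range[1], config$age_range[2]),
    gender = rbinom(n, 1, config$gender_mix),
    sppb = sample(seq(config$sppb_range[1], config$sppb_range[2]), n,
                  replace = TRUE),
    moca = sample(seq(config$moca_range[1], config$moca_range[2]), n,
                  replace = TRUE))
  sd_of <- function(nm) {
    if (length(config$noise_sd) == 1 && is.null(names(config$noise_sd))) {
      config$noise_sd
    } else {
      config$noise_sd[[nm]] %||% 0
    }
  }
  for (nm in names(config$effects)) {
    b <- config$effects[[nm]]
    mu <- rep(b[["intercept"]] %||% 0, n)
    for (cv in intersect(names(b), c("age", "gender", "sppb", "moca"))) {
      mu <- mu + b[[cv]] * cohort[[cv]]
    }
    cohort[[nm]] <- mu + rnorm(n, 0, sd_of(nm))
  }
  list(cohort = cohort, true_effects = config$effects)
}
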
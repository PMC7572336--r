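# Table-level synthetic cohort: covariates, regional WMH loads, cognition.

#' Dictionary of the 14 cognitive outcomes
#'
#' Score ranges, population means and SDs of the seven memory-binding
#' outcomes and seven WAIS-IV subtests, with their domain assignment.
#' Semantic proactive interference is a percentage. These values
#' parameterize the cohort generator and name the cognition columns
#' everywhere.
#'
#' @return A tibble with columns `measure`, `mean`, `sd`, `min`, `max`,
#'   `domain`.
#' @export
cognitive_measure_table <- function() {
  tibble::tribble(
    ~measure, ~mean, ~sd, ~min, ~max, ~domain,
    "total_paired_recall",            24.2,  4.5, 0,  32, "memory",
    "total_free_recall",              16.6,  5.2, 0,  32, "memory",
    "paired_recall_pairs",             9.2,  3.4, 0,  16, "memory",
    "total_delayed_free_recall",      16.9,  5.2, 0,  32, "memory",
    "total_delayed_paired_recall",    23.9,  4.6, 0,  32, "memory",
    "pairs_delayed_free_recall",       6.4,  3.1, 0,  16, "memory",
    "semantic_proactive_interference", 75.2, 18.6, 0, 200, "memory",
    "visual_puzzles",                 13.3,  4.2, 0,  26, "executive",
    "digit_span_forward",              8.5,  2.1, 0,  16, "executive",
    "digit_span_backward",             8.0,  2.1, 0,  16, "executive",
    "digit_span_sequencing",           8.4,  2.1, 0,  16, "executive",
    "matrix_reasoning",               16.3,  4.3, 0,  26, "executive",
    "similarities",                   22.6,  4.7, 0,  36, "executive",
    "coding",                         65.5, 15.0, 0, 135, "executive"
  )
}

# Default expected regional share of total load: periventricular layers and
# occipital/frontal lobes carry more, mirroring the reported pattern that
# periventricular and occipital areas are most affected.
default_region_share_means <- function() {
  lobe_w <- c(FR = 0.13, FL = 0.13, TR = 0.09, TL = 0.09,
              PR = 0.12, PL = 0.12, OR = 0.14, OL = 0.14, BG = 0.04)
  layer_w <- c(0.40, 0.25, 0.20, 0.15)
  x <- as.numeric(outer(layer_w, lobe_w))  # layer varies fastest: lobe-major
  x / sum(x)
}

#' Specify a synthetic cohort
#'
#' Parameters of the table-level generator. Defaults reproduce the reference
#' population: age 57.4 (7.5) years, 60.9% female, education 13.7 (3.5)
#' years, APOE-e4 allele count probabilities 49.0/38.3/12.6%, TIV median
#' 1.42e6 mm^3, and a right-skewed total WMH load with median 1.94e3 mm^3
#' and quartiles 1.13e3-3.69e3 mm^3 (log-normal). Regional loads are
#' Dirichlet shares of the total, which makes the regional sum exact and
#' induces inter-region correlation through the shared total.
#'
#' Planted load-cognition effects are given by `beta`, a 36 x 14 matrix
#' (regions in lobe-major order x measures in [cognitive_measure_table()]
#' order). `beta[r, m]` multiplies the standardized, age-adjusted log load
#' of region r in the latent score of measure m, so with the default
#' `noise_sd` of 0.9 a value of -0.3 plants a partial correlation of about
#' -0.3 (Spearman about -0.30) between that region's load and that outcome.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param age_mean,age_sd,female_fraction,education_mean,education_sd
#'   Covariate distribution parameters.
#' @param apoe_probs Probabilities of 0, 1, 2 APOE-e4 alleles (normalized).
#' @param tiv_meanlog,tiv_sdlog Log-normal total intracranial volume (mm^3).
#' @param total_load_meanlog,total_load_sdlog Log-normal total WMH load
#'   (mm^3); defaults match the reference median and IQR.
#' @param load_age_log_slope Increase in log total load per year of age.
#' @param region_share_means Length-36 expected regional shares (sum 1).
#' @param region_share_concentration Dirichlet concentration; larger means
#'   less subject-to-subject variation in the regional pattern.
#' @param beta 36 x 14 planted effect matrix (default all zero).
#' @param noise_sd Residual SD of the latent (z-scale) cognitive scores;
#'   scalar or length 14. Must be positive.
#' @param cognition_age_effect,cognition_education_effect,cognition_sex_effect
#'   Latent-scale covariate effects per SD of the covariate.
#' @param qc_meningioma_prob,qc_artifact_prob Exclusion-flag probabilities
#'   (defaults 10/608 and 37/608).
#' @param seed Integer seed; the cohort is a pure function of this spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 561L,
                        age_mean = 57.4, age_sd = 7.5,
                        female_fraction = 0.609,
                        education_mean = 13.7, education_sd = 3.5,
                        apoe_probs = c(0.490, 0.383, 0.126),
                        tiv_meanlog = log(1.42e6),
                        tiv_sdlog = log(1490 / 1330) / (2 * qnorm(0.75)),
                        total_load_meanlog = log(1940),
                        total_load_sdlog = log(3690 / 1130) / (2 * qnorm(0.75)),
                        load_age_log_slope = 0.07,
                        region_share_means = default_region_share_means(),
                        region_share_concentration = 50,
                        beta = NULL,
                        noise_sd = 0.9,
                        cognition_age_effect = -0.25,
                        cognition_education_effect = 0.30,
                        cognition_sex_effect = 0,
                        qc_meningioma_prob = 10 / 608,
                        qc_artifact_prob = 37 / 608,
                        seed = 1L) {
  meas <- cognitive_measure_table()
  if (is.null(beta)) {
    beta <- matrix(0, 36, nrow(meas), dimnames = list(NULL, meas$measure))
  }
  if (any(noise_sd <= 0)) {
    rlang::abort("noise_sd must be positive", class = "bullseye_parameter_error")
  }
  if (any(apoe_probs < 0) || sum(apoe_probs) <= 0) {
    rlang::abort("apoe_probs must be non-negative and sum to a positive value",
                 class = "bullseye_parameter_error")
  }
  if (n_subjects < 10L) {
    rlang::abort("n_subjects must be >= 10", class = "bullseye_parameter_error")
  }
  stopifnot(length(region_share_means) == 36L, all(region_share_means > 0),
            identical(dim(beta), c(36L, nrow(meas))))
  spec <- list(
    n_subjects = as.integer(n_subjects),
    age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction,
    education_mean = education_mean, education_sd = education_sd,
    apoe_probs = apoe_probs / sum(apoe_probs),
    tiv_meanlog = tiv_meanlog, tiv_sdlog = tiv_sdlog,
    total_load_meanlog = total_load_meanlog,
    total_load_sdlog = total_load_sdlog,
    load_age_log_slope = load_age_log_slope,
    region_share_means = region_share_means / sum(region_share_means),
    region_share_concentration = region_share_concentration,
    beta = beta,
    noise_sd = rep_len(noise_sd, nrow(meas)),
    cognition_age_effect = cognition_age_effect,
    cognition_education_effect = cognition_education_effect,
    cognition_sex_effect = cognition_sex_effect,
    qc_meningioma_prob = qc_meningioma_prob,
    qc_artifact_prob = qc_artifact_prob,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a subject-level cohort table
#'
#' Draws covariates, 36 regional WMH loads (plus their exact total),
#' 14 cognitive outcomes, generic extra confounder columns and QC flags
#' according to a [cohort_spec()]. Cognitive latent scores are
#' `covariate terms + sum_r beta[r, m] * standardized age-adjusted log
#' load_r + Gaussian noise`, mapped onto each measure's printed mean/SD and
#' clamped to its printed range. With `beta = 0`, loads and cognition are
#' independent given the covariates.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble, one row per subject, with columns `subject_id`, `age`,
#'   `sex` (1 = female), `education`, `apoe_e4_count`, `tiv`,
#'   `load_region_1` .. `load_region_36`, `load_total`, the 14 measures of
#'   [cognitive_measure_table()], `caide_like`, `depression_like`,
#'   `mta_like`, `qc_meningioma`, `qc_artifact`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 50, seed = 3))
#' dplyr::glimpse(coh[, 1:8])
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  meas <- cognitive_measure_table()
  with_seed(spec$seed, {
    age <- rnorm(n, spec$age_mean, spec$age_sd)
    sex <- rbinom(n, 1L, spec$female_fraction)
    education <- pmax(rnorm(n, spec$education_mean, spec$education_sd), 0)
    apoe <- sample(0:2, n, replace = TRUE, prob = spec$apoe_probs)
    tiv <- rlnorm(n, spec$tiv_meanlog, spec$tiv_sdlog)

    # total load: age raises the log-mean; the residual log SD is reduced so
    # the marginal spread still matches the specified sdlog
    age_term <- spec$load_age_log_slope * (age - spec$age_mean)
    resid_sdlog <- sqrt(max(
      spec$total_load_sdlog^2 - (spec$load_age_log_slope * spec$age_sd)^2,
      0.05^2))
    load_total <- exp(spec$total_load_meanlog + age_term +
                        rnorm(n, 0, resid_sdlog))
    alpha <- spec$region_share_means * spec$region_share_concentration
    g <- matrix(rgamma(n * 36L, shape = rep(alpha, each = n)), n, 36L)
    shares <- g / rowSums(g)
    loads <- shares * load_total
    colnames(loads) <- paste0("load_region_", 1:36)

    # planted effects act on the standardized age-adjusted log load
    log_loads <- log(loads)
    lam <- apply(log_loads, 2, function(v) {
      r <- lm.fit(cbind(1, age), v)$residuals
      as.numeric(scale(r))
    })
    z_age <- (age - spec$age_mean) / spec$age_sd
    z_edu <- (education - spec$education_mean) / spec$education_sd
    base_latent <- spec$cognition_age_effect * z_age +
      spec$cognition_education_effect * z_edu +
      spec$cognition_sex_effect * (sex - spec$female_fraction)
    cog <- matrix(NA_real_, n, nrow(meas), dimnames = list(NULL, meas$measure))
    for (m in seq_len(nrow(meas))) {
      latent <- base_latent + drop(lam %*% spec$beta[, m]) +
        rnorm(n, 0, spec$noise_sd[m])
      cog[, m] <- pmin(pmax(meas$mean[m] + meas$sd[m] * latent,
                            meas$min[m]), meas$max[m])
    }

    caide_like <- 0.5 * z_age + rnorm(n, 0, sqrt(1 - 0.25))
    depression_like <- rnorm(n)
    mta_like <- pmax(0.79 + 0.64 * (0.3 * z_age + rnorm(n, 0, sqrt(1 - 0.09))), 0)
    qc_meningioma <- rbinom(n, 1L, spec$qc_meningioma_prob) == 1L
    qc_artifact <- rbinom(n, 1L, spec$qc_artifact_prob) == 1L

    out <- dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("sub-%05d", seq_len(n)),
        age = age, sex = sex, education = education,
        apoe_e4_count = apoe, tiv = tiv
      ),
      tibble::as_tibble(loads),
      tibble::tibble(load_total = rowSums(loads)),
      tibble::as_tibble(cog),
      tibble::tibble(caide_like = caide_like,
                     depression_like = depression_like,
                     mta_like = mta_like,
                     qc_meningioma = qc_meningioma,
                     qc_artifact = qc_artifact)
    )
    attr(out, "cohort_spec") <- spec
    out
  })
}
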
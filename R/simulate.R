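#' Cohort simulation configuration
#'
#' Builds the configuration for the longitudinal cohort generator. Defaults
#' emulate a mid-century urban Polish growth study: 193 boys measured
#' annually at ages 8-18 and 199 girls at ages 8-16, APHV distributed as a
#' truncated normal (boys 14.06 +/- 1.11 years on [11.45, 17.34]; girls
#' 11.89 +/- 1.00 years on [9.03, 14.82]), occasional missed visits
#' weighted toward late adolescence, and occasional second visits falling
#' within the same chronological-age class.
#'
#' @param n_boys,n_girls Subjects per sex.
#' @param ages_boys,ages_girls Scheduled whole-year visit ages.
#' @param age_jitter_sd SD (years) of the Gaussian jitter around each
#'   scheduled age, so within-age-group decimal ages scatter realistically.
#' @param height_noise_sd,sitting_noise_sd,mass_noise_sd Measurement noise
#'   SDs (cm, cm, kg).
#' @param aphv_boys,aphv_girls Named vectors `c(mean, sd, min, max)` for
#'   the sex-specific truncated-normal APHV targets (years). The truncation
#'   window must contain mean +/- 2 sd.
#' @param missing_visit_rate Average per-visit probability of a missed
#'   examination (weighted toward the oldest ages).
#' @param duplicate_visit_rate Per-visit probability of a second
#'   observation within the same age class.
#' @param s0,s1 Named vectors `c(mean, sd)` for the PB1 rate constants.
#' @param h_adult_boys,h_adult_girls Named vectors `c(mean, sd)` for adult
#'   stature (cm).
#' @param h_delta Named vector `c(mean, sd)`: `h_theta = h_adult - delta`.
#' @param bmi_at8,bmi_at18,bmi_subject_sd Mass model: BMI linear in age
#'   between these anchors (kg/m^2) plus a subject-level random intercept.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_boys = 193, n_girls = 199,
                          ages_boys = 8:18, ages_girls = 8:16,
                          age_jitter_sd = 0.15,
                          height_noise_sd = 0.3,
                          sitting_noise_sd = 0.3,
                          mass_noise_sd = 1.0,
                          aphv_boys = c(mean = 14.06, sd = 1.11,
                                        min = 11.45, max = 17.34),
                          aphv_girls = c(mean = 11.89, sd = 1.00,
                                         min = 9.03, max = 14.82),
                          missing_visit_rate = 0.05,
                          duplicate_visit_rate = 0.03,
                          s0 = c(mean = 0.11, sd = 0.015),
                          s1 = c(mean = 1.2, sd = 0.2),
                          h_adult_boys = c(mean = 176, sd = 6.5),
                          h_adult_girls = c(mean = 164, sd = 6),
                          h_delta = c(mean = 13, sd = 2),
                          bmi_at8 = 16, bmi_at18 = 21,
                          bmi_subject_sd = 1.5,
                          seed = 1L) {
  cfg <- list(n_boys = n_boys, n_girls = n_girls,
              ages_boys = ages_boys, ages_girls = ages_girls,
              age_jitter_sd = age_jitter_sd,
              height_noise_sd = height_noise_sd,
              sitting_noise_sd = sitting_noise_sd,
              mass_noise_sd = mass_noise_sd,
              aphv_boys = aphv_boys, aphv_girls = aphv_girls,
              missing_visit_rate = missing_visit_rate,
              duplicate_visit_rate = duplicate_visit_rate,
              s0 = s0, s1 = s1,
              h_adult_boys = h_adult_boys, h_adult_girls = h_adult_girls,
              h_delta = h_delta,
              bmi_at8 = bmi_at8, bmi_at18 = bmi_at18,
              bmi_subject_sd = bmi_subject_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  rates <- c(cfg$missing_visit_rate, cfg$duplicate_visit_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "phvalid_config_error")
  }
  sds <- c(cfg$age_jitter_sd, cfg$height_noise_sd, cfg$sitting_noise_sd,
           cfg$mass_noise_sd)
  if (any(sds < 0)) {
    abort("noise sds must be non-negative", class = "phvalid_config_error")
  }
  for (a in list(cfg$aphv_boys, cfg$aphv_girls)) {
    if (a[["min"]] > a[["mean"]] - 2 * a[["sd"]] ||
        a[["max"]] < a[["mean"]] + 2 * a[["sd"]]) {
      abort("APHV truncation window must contain mean +/- 2 sd",
            class = "phvalid_config_error")
    }
  }
  invisible(cfg)
}

# offset of the velocity peak from theta; depends only on the rate
# constants because PB1 velocity is a function of t - theta. NA when the
# peak is not interior to theta +/- 4 (such draws are rejected upstream:
# the spurt would sit implausibly far from the timing parameter)
aphv_shift <- function(s0, s1) {
  p <- pb1_params(176, 163, s0, s1, 13)
  tryCatch(estimate_aphv(p)$aphv - 13, error = function(e) NA_real_)
}

rtruncnorm1 <- function(mean, sd, lo, hi, max_tries = 1000) {
  if (sd == 0) return(mean)
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  mean
}

#' Sample one subject's true PB1 parameters
#'
#' Draws a target APHV from the sex-specific truncated normal, then places
#' the timing parameter so the curve's velocity peaks exactly at that age:
#' since PB1 velocity depends on age only through `t - theta`, the peak sits
#' at `theta + delta(s0, s1)`, so `theta = APHV - delta`. Rate constants and
#' stature levels are drawn from the configured normals; draws violating the
#' parameter invariants are rejected and resampled (bounded retries).
#'
#' @param sex "M" or "F".
#' @param config A [cohort_config()].
#' @return A list: `params` ([pb1_params()]), `true_aphv`,
#'   `bmi_intercept`.
#' @export
sample_pb1_params <- function(sex, config) {
  a <- if (sex == "M") config$aphv_boys else config$aphv_girls
  ha <- if (sex == "M") config$h_adult_boys else config$h_adult_girls
  for (try in 1:100) {
    target <- rtruncnorm1(a[["mean"]], a[["sd"]], a[["min"]], a[["max"]])
    s0 <- rnorm(1, config$s0[["mean"]], config$s0[["sd"]])
    s1 <- rnorm(1, config$s1[["mean"]], config$s1[["sd"]])
    if (!(s0 > 0.03 && s1 > s0 + 0.3)) next
    h_adult <- rnorm(1, ha[["mean"]], ha[["sd"]])
    delta <- rnorm(1, config$h_delta[["mean"]], config$h_delta[["sd"]])
    if (delta < 5) next
    shift <- aphv_shift(s0, s1)
    if (is.na(shift)) next
    theta <- target - shift
    if (theta < 8 || theta > 18) next
    p <- tryCatch(pb1_params(h_adult, h_adult - delta, s0, s1, theta),
                  error = function(e) NULL)
    if (is.null(p)) next
    return(list(params = p, true_aphv = target,
                bmi_intercept = rnorm(1, 0, config$bmi_subject_sd)))
  }
  abort("could not sample valid PB1 parameters in 100 tries",
        class = "phvalid_config_error")
}

# sitting-height fraction of stature: logistic decline from ~0.535 in
# childhood to ~0.52 in adulthood, with a transient 0.005 dip centred half
# a year before the subject's APHV (legs peak before the trunk)
sitting_fraction <- function(t, aphv) {
  0.52 + 0.015 / (1 + exp((t - aphv) / 1.5)) -
    0.005 * exp(-(t - (aphv - 0.5))^2 / 2)
}

measure_at_age <- function(age, subj, config) {
  stature <- pb1_height(subj$params, age) +
    rnorm(length(age), 0, config$height_noise_sd)
  sitting <- stature * sitting_fraction(age, subj$true_aphv) +
    rnorm(length(age), 0, config$sitting_noise_sd)
  sitting <- pmin(sitting, stature - 1)  # plausibility guard
  bmi <- config$bmi_at8 +
    (config$bmi_at18 - config$bmi_at8) * (age - 8) / 10 +
    subj$bmi_intercept
  mass <- pmax(bmi * (stature / 100)^2 +
                 rnorm(length(age), 0, config$mass_noise_sd), 10)
  tibble(age_years = age, stature_cm = stature,
         sitting_height_cm = sitting, mass_kg = mass)
}

#' Generate one subject's visit records
#'
#' One record per scheduled whole-year age: decimal age is the schedule
#' plus Gaussian jitter; stature sits on the subject's PB1 curve plus
#' measurement noise; sitting height follows the sitting-height fraction
#' model; mass follows the BMI-by-age allometric model.
#'
#' @param sex "M" or "F".
#' @param subject_id Identifier copied into every record.
#' @param subj A draw from [sample_pb1_params()].
#' @param config A [cohort_config()].
#' @return A tibble of visits (before missingness/duplication).
#' @export
generate_subject <- function(sex, subject_id, subj, config) {
  sched <- if (sex == "M") config$ages_boys else config$ages_girls
  ages <- sched + rnorm(length(sched), 0, config$age_jitter_sd)
  measure_at_age(ages, subj, config) |>
    mutate(subject_id = subject_id, sex = sex, schedule_age = sched,
           .before = 1)
}

#' Apply visit missingness and same-age-class duplication
#'
#' Drops visits with an average probability of `missing_visit_rate`,
#' weighted linearly toward the oldest scheduled ages (late-adolescence
#' examinations are the ones youths miss), and, with probability
#' `duplicate_visit_rate` per visit, inserts a second measurement falling
#' within the same chronological-age class, drawn from the subject's true
#' growth curve with fresh measurement noise.
#'
#' @param visits One subject's visit tibble from [generate_subject()].
#' @param subj The same subject's draw from [sample_pb1_params()]
#'   (needed to synthesise duplicate measurements); may be `NULL` when
#'   `duplicate_visit_rate` is 0.
#' @param config A [cohort_config()].
#' @return The thinned/augmented visit tibble.
#' @export
apply_missingness <- function(visits, subj, config) {
  n <- nrow(visits)
  if (n == 0) return(visits)
  out <- visits
  if (config$missing_visit_rate > 0) {
    # per-visit drop probabilities proportional to age rank, mean equal to
    # the configured rate
    w <- rank(out$schedule_age, ties.method = "first")
    p <- pmin(config$missing_visit_rate * 2 * w / (n + 1), 1)
    out <- out[runif(n) >= p, , drop = FALSE]
  }
  if (config$duplicate_visit_rate > 0 && nrow(out) > 0) {
    dup_idx <- which(runif(nrow(out)) < config$duplicate_visit_rate)
    if (length(dup_idx) > 0) {
      if (is.null(subj)) {
        abort("subject parameters required to synthesise duplicate visits",
              class = "phvalid_config_error")
      }
      dups <- purrr::map_dfr(dup_idx, function(i) {
        cls <- floor(out$age_years[i] + 0.5)
        new_age <- cls + runif(1, -0.49, 0.49)
        measure_at_age(new_age, subj, config) |>
          mutate(subject_id = out$subject_id[i], sex = out$sex[i],
                 schedule_age = out$schedule_age[i], .before = 1)
      })
      out <- bind_rows(out, dups)
    }
  }
  arrange(out, .data$age_years)
}

#' Generate a full longitudinal cohort with ground truth
#'
#' Draws every subject's true PB1 parameters and APHV, generates annual
#' visit records, applies missingness and duplication, and returns both the
#' long-format visit table and the ground-truth registry. Deterministic
#' under the config seed: per-subject random substreams are derived from it,
#' so the same seed reproduces the same cohort byte for byte.
#'
#' @param config A [cohort_config()].
#' @return A list with `visits` (tibble: `subject_id`, `sex`,
#'   `age_years`, `stature_cm`, `sitting_height_cm`, `mass_kg`) and
#'   `registry` (tibble: subject, sex, true PB1 parameters, `true_aphv`,
#'   `bmi_intercept`).
#' @examples
#' cc <- cohort_config(n_boys = 5, n_girls = 5, seed = 7)
#' cohort <- generate_cohort(cc)
#' dplyr::count(cohort$registry, sex)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  subjects <- tibble(
    sex = c(rep("M", config$n_boys), rep("F", config$n_girls)),
    idx = c(seq_len(config$n_boys), seq_len(config$n_girls))) |>
    mutate(subject_id = sprintf("%s%03d", ifelse(.data$sex == "M", "B", "G"),
                                .data$idx))
  res <- purrr::pmap(subjects, function(sex, idx, subject_id) {
    # deterministic per-subject substream, reproducible and extensible
    set.seed((config$seed + 7919L * (idx + 10000L * (sex == "F"))) %%
               .Machine$integer.max)
    subj <- sample_pb1_params(sex, config)
    v <- generate_subject(sex, subject_id, subj, config)
    v <- apply_missingness(v, subj, config)
    reg <- tibble(subject_id = subject_id, sex = sex,
                  h_adult = subj$params$h_adult,
                  h_theta = subj$params$h_theta,
                  s0 = subj$params$s0, s1 = subj$params$s1,
                  theta = subj$params$theta,
                  true_aphv = subj$true_aphv,
                  bmi_intercept = subj$bmi_intercept)
    list(visits = v, registry = reg)
  })
  visits <- purrr::map_dfr(res, "visits") |>
    select("subject_id", "sex", "age_years", "stature_cm",
           "sitting_height_cm", "mass_kg")
  registry <- purrr::map_dfr(res, "registry")
  list(visits = visits, registry = registry)
}
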
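#' Chronological-age group of a decimal age
#'
#' The whole year is the midpoint of the range defining CA groups
#' (8.0 = 7.50-8.49 years), i.e. `floor(age + 0.5)`. The groups tile the
#' real line with no gaps or overlaps.
#'
#' @param age Decimal age, years. Vectorised.
#' @return Integer CA group.
#' @export
ca_group <- function(age) as.integer(floor(age + 0.5))

#' Years-from-PHV bin of a visit
#'
#' Bins `age - observed_aphv` by the same midpoint rule
#' (`0` = -0.50 to +0.49, `+1` = +0.50 to +1.49, ...), reported over the
#' window -3..+3; values outside [-3.50, +3.49] are excluded (`NA`).
#'
#' @param age Decimal age, years.
#' @param observed_aphv Observed age at PHV, years.
#' @return Integer bin in -3..+3, or `NA` when outside the window.
#' @export
phv_bin <- function(age, observed_aphv) {
  b <- as.integer(floor(age - observed_aphv + 0.5))
  b[b < -3L | b > 3L] <- NA_integer_
  b
}

#' Early/average/late maturity classification
#'
#' A subject is average maturing when observed APHV lies within
#' `band` years (inclusive) of the sex-specific mean observed APHV,
#' early when below the lower bound, late when above the upper bound.
#'
#' @param observed_aphv Observed age at PHV, years. Vectorised.
#' @param sex_mean_aphv Sex-specific mean observed APHV of the analysed
#'   sample, years.
#' @param band Half-width of the average band, years (default 1.0).
#' @return A tibble: `category` ("early"/"average"/"late"), `lower`,
#'   `upper`.
#' @export
classify_maturity <- function(observed_aphv, sex_mean_aphv, band = 1.0) {
  lower <- sex_mean_aphv - band
  upper <- sex_mean_aphv + band
  category <- ifelse(observed_aphv < lower, "early",
                     ifelse(observed_aphv > upper, "late", "average"))
  tibble(category = factor(category,
                           levels = c("early", "average", "late")),
         lower = lower, upper = upper)
}

#' Remove duplicate observations within an age class
#'
#' When a subject has two (or more) observations falling within the same CA
#' group, keeps the one whose decimal age is nearest the group midpoint
#' (the whole year); exact ties keep the earlier age.
#'
#' @param visits Visit data frame with `subject_id` and `age_years`.
#' @return The visits with at most one row per (subject, CA group).
#' @export
dedupe_age_class <- function(visits) {
  visits |>
    as_tibble() |>
    mutate(.ca = ca_group(.data$age_years),
           .dist = abs(.data$age_years - .data$.ca)) |>
    group_by(.data$subject_id, .data$.ca) |>
    arrange(.data$.dist, .data$age_years, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".ca", -".dist") |>
    arrange(.data$subject_id, .data$age_years)
}

#' Binned summaries of offsets, predicted APHV and differences
#'
#' The descriptive core of the validation battery: per bin (CA group or
#' years-from-PHV) and per equation, the count and the mean/SD of the
#' actual maturity offset (CA minus observed APHV), the predicted offset,
#' the predicted APHV and the difference predicted minus observed APHV.
#' SDs are reported only when n >= 2.
#'
#' @param predictions Long prediction table from
#'   [add_offset_predictions()], augmented with a column `observed_aphv`.
#' @param bin_kind `"ca"` (chronological-age groups) or `"phv"`
#'   (years-from-PHV bins; visits outside -3..+3 are excluded).
#' @param boot_se Add bootstrap standard errors of the mean difference
#'   (`diff_mean_se`, 200 resamples)? Off by default.
#' @return A tibble keyed by (`sex`, `bin`, `equation`).
#' @export
summarize_by_bin <- function(predictions, bin_kind = c("ca", "phv"),
                             boot_se = FALSE) {
  bin_kind <- match.arg(bin_kind)
  stopifnot("observed_aphv" %in% names(predictions))
  d <- predictions |>
    as_tibble() |>
    mutate(bin = if (bin_kind == "ca") ca_group(.data$age_years)
           else phv_bin(.data$age_years, .data$observed_aphv),
           actual_offset = .data$age_years - .data$observed_aphv,
           diff = .data$predicted_aphv - .data$observed_aphv) |>
    filter(!is.na(.data$bin))
  sd2 <- function(x) if (length(x) >= 2) sd(x) else NA_real_
  out <- d |>
    group_by(.data$sex, .data$bin, .data$equation) |>
    summarise(n = n(),
              actual_offset_mean = mean(.data$actual_offset),
              actual_offset_sd = sd2(.data$actual_offset),
              pred_offset_mean = mean(.data$offset),
              pred_offset_sd = sd2(.data$offset),
              pred_aphv_mean = mean(.data$predicted_aphv),
              pred_aphv_sd = sd2(.data$predicted_aphv),
              obs_aphv_mean = mean(.data$observed_aphv),
              obs_aphv_sd = sd2(.data$observed_aphv),
              diff_mean = mean(.data$diff),
              diff_sd = sd2(.data$diff),
              .groups = "drop")
  if (boot_se) {
    se <- d |>
      group_by(.data$sex, .data$bin, .data$equation) |>
      summarise(diff_mean_se = {
        x <- .data$diff
        if (length(x) < 2) NA_real_ else
          sd(vapply(1:200, function(i)
            mean(sample(x, replace = TRUE)), numeric(1)))
      }, .groups = "drop")
    out <- left_join(out, se, by = c("sex", "bin", "equation"))
  }
  out
}

#' Percentage of predictions within a band of the observed value
#'
#' `100 * count(|predicted - observed| <= band) / n`, boundary inclusive.
#'
#' @param predicted,observed Paired predicted and observed APHV, years.
#' @param band Half-width, years (default 0.5, approximating the prediction
#'   equations' standard errors).
#' @return Percentage in `[0, 100]`.
#' @export
pct_within_band <- function(predicted, observed, band = 0.5) {
  if (length(predicted) == 0 || length(predicted) != length(observed)) {
    abort("predicted and observed must be non-empty and equal length",
          class = "phvalid_input_error")
  }
  100 * mean(abs(predicted - observed) <= band)
}

#' Bland-Altman agreement regression
#'
#' Ordinary least squares of the difference `d = predicted - observed` on
#' the mean `m = (predicted + observed) / 2`, plus the classical limits of
#' agreement `mean(d) +/- 1.96 sd(d)`. The slope estimates proportional
#' bias; a negative slope means predictions compress toward the centre.
#'
#' @param predicted,observed Paired predicted and observed APHV, years
#'   (at least 3 pairs).
#' @return A list of class `"ba_fit"`: `intercept`, `slope`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, and the fitted points.
#' @export
bland_altman <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3) {
    abort("bland_altman needs at least 3 paired values",
          class = "phvalid_input_error")
  }
  d <- predicted - observed
  m <- (predicted + observed) / 2
  fit <- lm(d ~ m)
  out <- list(intercept = unname(coef(fit)[1]),
              slope = unname(coef(fit)[2]),
              mean_diff = mean(d), sd_diff = sd(d),
              loa_low = mean(d) - 1.96 * sd(d),
              loa_high = mean(d) + 1.96 * sd(d),
              n = length(d),
              points = tibble(mean = m, diff = d))
  class(out) <- "ba_fit"
  out
}

#' @export
print.ba_fit <- function(x, ...) {
  cat(sprintf("Bland-Altman fit (n = %d)\n", x$n))
  cat(sprintf("  diff = %.3f %+.3f x mean;  bias %.3f, LoA [%.3f, %.3f]\n",
              x$intercept, x$slope, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @method tidy ba_fit
#' @export
tidy.ba_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @method glance ba_fit
#' @export
glance.ba_fit <- function(x, ...) {
  tibble(intercept = x$intercept, slope = x$slope,
         mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Intra-individual spread of predicted APHV
#'
#' For each subject and equation, the minimum, maximum and range of the
#' predicted APHV across that subject's visits. Single-visit subjects get
#' range 0 and are flagged low-information.
#'
#' @param predictions Long prediction table from
#'   [add_offset_predictions()].
#' @return A tibble: `subject_id`, `sex`, `equation`, `n_visits`, `min`,
#'   `max`, `range`, `low_information`.
#' @export
intra_individual_spread <- function(predictions) {
  predictions |>
    as_tibble() |>
    group_by(.data$subject_id, .data$sex, .data$equation) |>
    summarise(n_visits = n(),
              min = min(.data$predicted_aphv),
              max = max(.data$predicted_aphv),
              range = max(.data$predicted_aphv) - min(.data$predicted_aphv),
              .groups = "drop") |>
    mutate(low_information = .data$n_visits < 2)
}

ba_by_bin <- function(predictions, bin_kind) {
  d <- predictions |>
    mutate(bin = if (bin_kind == "ca") ca_group(.data$age_years)
           else phv_bin(.data$age_years, .data$observed_aphv)) |>
    filter(!is.na(.data$bin))
  d |>
    group_by(.data$sex, .data$bin, .data$equation) |>
    group_modify(function(g, key) {
      if (nrow(g) < 3) {
        return(tibble(intercept = NA_real_, slope = NA_real_,
                      mean_diff = NA_real_, sd_diff = NA_real_,
                      loa_low = NA_real_, loa_high = NA_real_,
                      n = nrow(g)))
      }
      glance(bland_altman(g$predicted_aphv, g$observed_aphv))
    }) |>
    ungroup()
}

#' Run the full validation battery on a cohort
#'
#' End-to-end orchestration: fits PB1 per subject to estimate observed
#' APHV, excludes non-converged fits and fits whose APHV falls outside the
#' subject's measurement span, removes duplicate observations within an age
#' class, classifies subjects early/average/late around the analysed
#' cohort's own sex-specific mean APHV, applies every sex-appropriate
#' prediction equation at every retained visit, and assembles the
#' descriptive tables, hit-rate tables, Bland-Altman regressions and
#' intra-individual spread statistics. Deterministic given its input.
#'
#' @param visits Long visit table (`subject_id`, `sex`, `age_years`,
#'   `stature_cm`, `sitting_height_cm`, `mass_kg`).
#' @param band_maturity Half-width of the average-maturity band, years.
#' @param band_hit Half-width of the hit-rate band, years.
#' @param predictor Function `(visits, subjects)` mapping the deduped visit
#'   table (and the per-subject APHV table) to the long prediction table;
#'   defaults to [add_offset_predictions()] applied to the visits. Exposed
#'   so an oracle predictor (e.g. predicted = observed) can exercise the
#'   pipeline end to end.
#' @return A list of class `"phv_validation"`: `fits`, `subjects`
#'   (per-subject APHV + maturity class), `predictions`, summary tables
#'   `by_ca` / `by_phv` (total sample), `by_ca_maturity` / `by_phv_maturity`
#'   (stratified), hit-rate tables `hits_ca` / `hits_phv`, Bland-Altman
#'   tables `ba_ca` / `ba_phv`, `spread`, and a `log` of counts.
#' @export
run_validation <- function(visits, band_maturity = 1.0, band_hit = 0.5,
                           predictor = NULL) {
  if (is.null(predictor)) {
    predictor <- function(visits, subjects) add_offset_predictions(visits)
  }
  fits <- fit_pb1_cohort(visits)
  excluded_nonconv <- sum(!fits$converged)
  excluded_span <- sum(fits$converged & !fits$aphv_in_span)
  kept <- fits |> filter(.data$converged, .data$aphv_in_span)

  sex_means <- kept |>
    group_by(.data$sex) |>
    summarise(mean_aphv = mean(.data$aphv), sd_aphv = sd(.data$aphv),
              .groups = "drop")

  subjects <- kept |>
    left_join(sex_means, by = "sex") |>
    mutate(classify_maturity(.data$aphv, .data$mean_aphv,
                             band = band_maturity)) |>
    select("subject_id", "sex", observed_aphv = "aphv", "mean_aphv",
           "category", "lower", "upper")

  deduped <- visits |>
    as_tibble() |>
    semi_join(subjects, by = "subject_id") |>
    dedupe_age_class()

  predictions <- predictor(deduped, subjects) |>
    left_join(subjects |>
                select("subject_id", "observed_aphv", "category"),
              by = "subject_id")

  hits <- function(d, bin_kind) {
    d |>
      mutate(bin = if (bin_kind == "ca") ca_group(.data$age_years)
             else phv_bin(.data$age_years, .data$observed_aphv)) |>
      filter(!is.na(.data$bin)) |>
      group_by(.data$sex, .data$category, .data$bin, .data$equation) |>
      summarise(n = n(),
                pct_within = pct_within_band(.data$predicted_aphv,
                                             .data$observed_aphv,
                                             band = band_hit),
                .groups = "drop")
  }

  out <- list(
    fits = fits,
    subjects = subjects,
    predictions = predictions,
    by_ca = summarize_by_bin(predictions, "ca"),
    by_phv = summarize_by_bin(predictions, "phv"),
    by_ca_maturity = predictions |>
      group_by(.data$category) |>
      group_modify(~ summarize_by_bin(.x, "ca")) |> ungroup(),
    by_phv_maturity = predictions |>
      group_by(.data$category) |>
      group_modify(~ summarize_by_bin(.x, "phv")) |> ungroup(),
    hits_ca = hits(predictions, "ca"),
    hits_phv = hits(predictions, "phv"),
    ba_ca = ba_by_bin(predictions, "ca"),
    ba_phv = ba_by_bin(predictions, "phv"),
    spread = intra_individual_spread(predictions),
    log = tibble(
      n_subjects_input = dplyr::n_distinct(visits$subject_id),
      n_analysed = nrow(subjects),
      n_excluded_nonconverged = excluded_nonconv,
      n_excluded_aphv_outside_span = excluded_span))
  class(out) <- "phv_validation"
  out
}

#' @export
print.phv_validation <- function(x, ...) {
  cat("PHV prediction-equation validation\n")
  cat(sprintf("  %d subjects analysed (%d excluded: %d non-converged, %d APHV outside span)\n",
              x$log$n_analysed,
              x$log$n_excluded_nonconverged + x$log$n_excluded_aphv_outside_span,
              x$log$n_excluded_nonconverged,
              x$log$n_excluded_aphv_outside_span))
  tab <- dplyr::count(x$subjects, .data$sex, .data$category)
  print(tab, n = Inf)
  invisible(x)
}
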
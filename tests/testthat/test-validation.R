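test_that("CA groups follow the midpoint rule and tile the line", {
  expect_equal(ca_group(7.50), 8L)
  expect_equal(ca_group(8.49), 8L)
  expect_equal(ca_group(8.50), 9L)
  expect_equal(ca_group(14.0), 14L)
  # no gaps, no overlaps: group changes exactly at the half-year
  ages <- seq(6, 20, by = 0.01)
  g <- ca_group(ages)
  expect_true(all(diff(g) %in% c(0L, 1L)))
  expect_equal(sort(unique(g)), 6:20)
})

test_that("years-from-PHV bins reproduce the printed range endpoints", {
  aphv <- 14
  expect_equal(phv_bin(13.0, aphv), -1L)       # x = -1.0
  expect_equal(phv_bin(14.5, aphv), 1L)        # x = +0.50 opens bin +1
  expect_equal(phv_bin(13.5, aphv), 0L)        # x = -0.50 closes bin 0
  # printed interval ends for every bin -3..+3
  expect_equal(phv_bin(aphv - 3.50, aphv), -3L)
  expect_equal(phv_bin(aphv - 2.51, aphv), -3L)
  expect_equal(phv_bin(aphv - 2.50, aphv), -2L)
  expect_equal(phv_bin(aphv - 1.51, aphv), -2L)
  expect_equal(phv_bin(aphv - 1.50, aphv), -1L)
  expect_equal(phv_bin(aphv - 0.51, aphv), -1L)
  expect_equal(phv_bin(aphv + 0.49, aphv), 0L)
  expect_equal(phv_bin(aphv + 1.49, aphv), 1L)
  expect_equal(phv_bin(aphv + 2.49, aphv), 2L)
  expect_equal(phv_bin(aphv + 3.49, aphv), 3L)
  # outside the reporting window
  expect_true(is.na(phv_bin(17.6, aphv)))      # x = +3.6
  expect_true(is.na(phv_bin(aphv - 3.51, aphv)))
})

test_that("maturity classification uses the inclusive +/- 1 year band", {
  expect_equal(as.character(classify_maturity(12.5, 14.06)$category), "early")
  expect_equal(as.character(classify_maturity(13.0, 11.89)$category), "late")
  expect_equal(as.character(classify_maturity(14.06, 14.06)$category),
               "average")
  # inclusive at both ends of the band
  expect_equal(as.character(classify_maturity(13.06, 14.06)$category),
               "average")
  expect_equal(as.character(classify_maturity(15.06, 14.06)$category),
               "average")
  cl <- classify_maturity(12.5, 14.06)
  expect_equal(cl$lower, 13.06)
  expect_equal(cl$upper, 15.06)
})

test_that("duplicate age-class observations resolve to the nearest-midpoint visit", {
  v <- tibble::tibble(subject_id = "a", sex = "M",
                      age_years = c(13.95, 14.40), stature_cm = c(160, 162))
  expect_equal(dedupe_age_class(v)$age_years, 13.95)
  # exact tie keeps the earlier age
  v2 <- tibble::tibble(subject_id = "a", sex = "M",
                       age_years = c(13.8, 14.2), stature_cm = c(160, 162))
  expect_equal(dedupe_age_class(v2)$age_years, 13.8)
  # no duplicates: identity (up to ordering)
  v3 <- tiny_visits()
  expect_equal(dedupe_age_class(v3), dplyr::arrange(v3, subject_id, age_years))
})

test_that("binned summaries match hand arithmetic and the mean identity", {
  pred <- tibble::tibble(
    subject_id = c("a", "b", "c"), sex = "M",
    age_years = c(13.9, 14.1, 14.3), equation = "moore1_boys",
    offset = c(-0.2, 0.1, 0.4),
    predicted_aphv = c(14.1, 14.0, 13.9),
    observed_aphv = c(14.5, 13.8, 14.2))
  s <- summarize_by_bin(pred, "ca")
  expect_equal(nrow(s), 1)
  expect_equal(s$n, 3L)
  expect_equal(s$pred_aphv_mean, mean(c(14.1, 14.0, 13.9)))
  expect_equal(s$pred_aphv_sd, sd(c(14.1, 14.0, 13.9)))
  expect_equal(s$actual_offset_mean,
               mean(c(13.9 - 14.5, 14.1 - 13.8, 14.3 - 14.2)))
  expect_equal(s$diff_mean, s$pred_aphv_mean - s$obs_aphv_mean)

  # single observation: mean defined, sd absent
  s1 <- summarize_by_bin(pred[1, ], "ca")
  expect_equal(s1$pred_aphv_mean, 14.1)
  expect_true(is.na(s1$pred_aphv_sd))

  # phv binning drops out-of-window visits
  pred2 <- pred
  pred2$observed_aphv <- c(14.5, 13.8, 10.0)  # third visit sits at +4.3
  s2 <- summarize_by_bin(pred2, "phv")
  expect_equal(sum(s2$n), 2L)

  # optional bootstrap SE of the mean difference
  s3 <- summarize_by_bin(pred, "ca", boot_se = TRUE)
  expect_true("diff_mean_se" %in% names(s3))
  expect_gt(s3$diff_mean_se, 0)
})

test_that("percentage within band counts the boundary as inside", {
  expect_equal(pct_within_band(c(14, 13, 15), c(14, 13, 15)), 100)
  expect_equal(pct_within_band(c(14.2, 13.4, 14.5), c(14, 14, 14)),
               100 * 2 / 3)
  expect_error(pct_within_band(numeric(0), numeric(0)),
               class = "phvalid_input_error")
})

test_that("Bland-Altman regression matches the closed-form OLS oracle", {
  # constant difference: slope 0, intercept at the constant
  ba <- bland_altman(c(10.3, 12.3, 14.3), c(10, 12, 14))
  expect_equal(ba$slope, 0, tolerance = 1e-12)
  expect_equal(ba$intercept, 0.3, tolerance = 1e-12)
  expect_equal(ba$mean_diff, 0.3)
  expect_equal(ba$loa_low, ba$loa_high, tolerance = 1e-12)

  # 3-point fixture with means 10, 12, 14 and diffs 0.2, 0.0, -0.2:
  # hand OLS gives slope -0.1 and intercept 1.2
  pred <- c(10.1, 12.0, 13.9)
  obs <- c(9.9, 12.0, 14.1)
  ba2 <- bland_altman(pred, obs)
  expect_equal(ba2$slope, -0.1, tolerance = 1e-10)
  expect_equal(ba2$intercept, 1.2, tolerance = 1e-10)

  # random data: agreement with the independent closed-form oracle
  set.seed(33)
  p <- rnorm(50, 13, 1); o <- p + rnorm(50, 0, 0.5)
  ba3 <- bland_altman(p, o)
  ref <- ols_oracle((p + o) / 2, p - o)
  expect_equal(ba3$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  expect_equal(ba3$slope, unname(ref["slope"]), tolerance = 1e-10)
  expect_true(ba3$loa_low <= ba3$mean_diff && ba3$mean_diff <= ba3$loa_high)

  expect_error(bland_altman(1:2, 1:2), class = "phvalid_input_error")

  gl <- glance(ba3)
  expect_named(gl, c("intercept", "slope", "mean_diff", "sd_diff",
                     "loa_low", "loa_high", "n"))
})

test_that("Bland-Altman slope is centred on zero under symmetric noise", {
  # when predicted and observed carry equal independent noise around a
  # common truth, the difference is uncorrelated with the mean; noise on
  # one side alone would tilt the slope by construction
  set.seed(71)
  slopes <- replicate(200, {
    truth <- rnorm(100, 14, 1)
    pred <- truth + rnorm(100, 0, 0.5)
    obs <- truth + rnorm(100, 0, 0.5)
    bland_altman(pred, obs)$slope
  })
  expect_lt(abs(mean(slopes)), 0.02)
})

test_that("intra-individual spread summarises per subject and equation", {
  pred <- tibble::tibble(
    subject_id = c("a", "a", "a", "b"), sex = "M",
    equation = "moore1_boys",
    predicted_aphv = c(13.2, 13.9, 14.6, 14.0))
  sp <- intra_individual_spread(pred)
  expect_equal(sp$range[sp$subject_id == "a"], 1.4)
  expect_equal(sp$range[sp$subject_id == "b"], 0)
  expect_true(sp$low_information[sp$subject_id == "b"])
  # constant predictions give zero range
  sp2 <- intra_individual_spread(
    tibble::tibble(subject_id = "c", sex = "F", equation = "moore1_girls",
                   predicted_aphv = rep(12.2, 4)))
  expect_equal(sp2$range, 0)
})

test_that("end-to-end null case: an exact predictor yields perfect agreement", {
  ch <- generate_cohort(cohort_config(n_boys = 30, n_girls = 30, seed = 41))
  oracle_predictor <- function(visits, subjects) {
    visits |>
      dplyr::left_join(subjects |>
                         dplyr::select(subject_id, oracle = observed_aphv),
                       by = "subject_id") |>
      dplyr::mutate(equation = "oracle",
                    offset = age_years - oracle,
                    predicted_aphv = oracle,
                    age_out_of_range = FALSE) |>
      dplyr::select(-oracle)
  }
  vr <- run_validation(ch$visits, predictor = oracle_predictor)
  expect_true(all(abs(vr$by_ca$diff_mean) < 1e-10))
  expect_true(all(vr$hits_ca$pct_within == 100))
  expect_true(all(abs(vr$ba_ca$slope) < 1e-8, na.rm = TRUE))
  expect_true(all(abs(vr$ba_phv$slope) < 1e-8, na.rm = TRUE))
})

test_that("validation partitions subjects and visits exactly once", {
  ch <- generate_cohort(cohort_config(n_boys = 40, n_girls = 40, seed = 43))
  vr <- run_validation(ch$visits)
  # every analysed subject in exactly one maturity class
  expect_equal(nrow(vr$subjects),
               dplyr::n_distinct(vr$subjects$subject_id))
  expect_false(any(is.na(vr$subjects$category)))
  # every retained visit maps to one CA group; per-equation row counts in
  # the CA tables sum to the per-sex retained visit counts
  pred1 <- vr$predictions |> dplyr::filter(equation == "moore1_boys")
  expect_equal(sum(vr$by_ca$n[vr$by_ca$equation == "moore1_boys"]),
               nrow(pred1))
  # at most one visit per subject per CA group after deduplication
  dup <- vr$predictions |>
    dplyr::distinct(subject_id, age_years) |>
    dplyr::mutate(ca = ca_group(age_years)) |>
    dplyr::count(subject_id, ca)
  expect_true(all(dup$n == 1))
  # exclusions are logged
  expect_equal(vr$log$n_analysed + vr$log$n_excluded_nonconverged +
                 vr$log$n_excluded_aphv_outside_span,
               vr$log$n_subjects_input)
})
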
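#' Preece-Baines Model 1 parameter set
#'
#' Bundles and validates the five parameters of the Preece-Baines Model 1
#' (PB1) growth curve,
#' \deqn{h(t) = h_1 - \frac{2\,(h_1 - h_\theta)}{\exp(s_0 (t-\theta)) +
#'   \exp(s_1 (t-\theta))},}
#' where `h_adult` (\eqn{h_1}) is adult stature, `h_theta` the stature at the
#' timing parameter `theta`, and `s0 < s1` are the slow and fast rate
#' constants (1/years). The curve's velocity has a single interior maximum
#' (the adolescent spurt) whenever the two rate constants differ.
#'
#' @param h_adult Adult stature in cm; must exceed `h_theta`.
#' @param h_theta Stature at age `theta`, cm; positive.
#' @param s0,s1 Rate constants, 1/years; `0 < s0 < s1`.
#' @param theta Timing parameter, years, in `[8, 18]`.
#'
#' @return A list of class `"pb1_params"`.
#' @examples
#' p <- pb1_params(176, 163, 0.11, 1.2, 14.3)
#' pb1_height(p, 14.3) # equals h_theta
#' @export
pb1_params <- function(h_adult, h_theta, s0, s1, theta) {
  stopifnot(is.numeric(h_adult), is.numeric(h_theta), is.numeric(s0),
            is.numeric(s1), is.numeric(theta))
  if (!(h_adult > h_theta && h_theta > 0)) {
    abort("invalid PB1 parameters: need h_adult > h_theta > 0",
          class = "phvalid_param_error")
  }
  if (!(s0 > 0 && s0 < s1)) {
    abort("invalid PB1 parameters: need 0 < s0 < s1 (s0 = s1 has no spurt)",
          class = "phvalid_param_error")
  }
  if (theta < 8 || theta > 18) {
    abort("invalid PB1 parameters: theta must lie in [8, 18]",
          class = "phvalid_param_error")
  }
  structure(list(h_adult = h_adult, h_theta = h_theta,
                 s0 = s0, s1 = s1, theta = theta),
            class = "pb1_params")
}

as_pb1_params <- function(x) {
  if (inherits(x, "pb1_params")) return(x)
  pb1_params(x$h_adult, x$h_theta, x$s0, x$s1, x$theta)
}

#' PB1 model stature
#'
#' Evaluates the Preece-Baines Model 1 curve at ages `t`. The value is
#' strictly below `h_adult` for finite `t` and approaches it as
#' `t` grows.
#'
#' @param params A [pb1_params()] object (or list with the same fields).
#' @param t Ages in years (vectorised).
#' @return Stature in cm, same length as `t`.
#' @export
pb1_height <- function(params, t) {
  p <- as_pb1_params(params)
  p$h_adult - 2 * (p$h_adult - p$h_theta) /
    (exp(p$s0 * (t - p$theta)) + exp(p$s1 * (t - p$theta)))
}

#' PB1 growth velocity
#'
#' Analytic first derivative of [pb1_height()] with respect to age:
#' \deqn{v(t) = 2\,(h_1 - h_\theta)\,
#'   \frac{s_0 e_0 + s_1 e_1}{(e_0 + e_1)^2}, \quad
#'   e_i = \exp(s_i (t - \theta)).}
#'
#' @inheritParams pb1_height
#' @return Velocity in cm/year, same length as `t`.
#' @export
pb1_velocity <- function(params, t) {
  p <- as_pb1_params(params)
  e0 <- exp(p$s0 * (t - p$theta))
  e1 <- exp(p$s1 * (t - p$theta))
  2 * (p$h_adult - p$h_theta) * (p$s0 * e0 + p$s1 * e1) / (e0 + e1)^2
}

#' Age at peak height velocity of a PB1 curve
#'
#' Maximises the analytic velocity by bounded scalar optimisation
#' (Brent's method via [stats::optimize()]) over a bracket that, for any
#' valid parameter set, contains the interior velocity peak. Agreement with
#' an exhaustive 0.001-year grid search to within 0.002 years is part of
#' the test contract.
#'
#' @inheritParams pb1_height
#' @param search_lo,search_hi Bracket in years; defaults `theta - 4` and
#'   `theta + 4`.
#' @return A tibble of class `"phv_estimate"` with columns `aphv` (years),
#'   `peak_velocity` (cm/year), `residual_se` (NA here; filled by
#'   [fit_pb1()]), `n_points` and `converged`.
#' @export
estimate_aphv <- function(params, search_lo = NULL, search_hi = NULL) {
  p <- as_pb1_params(params)
  lo <- search_lo %||% (p$theta - 4)
  hi <- search_hi %||% (p$theta + 4)
  # PB1 stature (hence velocity) diverges as t -> -infinity, so the global
  # maximum over a wide bracket can sit at the left edge rather than at the
  # adolescent spurt. Locate the interior local maximum by a coarse scan,
  # then polish it with Brent's method inside the scan cell.
  xs <- seq(lo, hi, length.out = 257)
  vs <- pb1_velocity(p, xs)
  k <- length(xs)
  is_peak <- c(FALSE, vs[2:(k - 1)] > vs[1:(k - 2)] &
                 vs[2:(k - 1)] >= vs[3:k], FALSE)
  if (!any(is_peak)) {
    abort("no interior velocity maximum in [search_lo, search_hi]",
          class = "phvalid_bracket_error")
  }
  i <- which(is_peak)[which.max(vs[is_peak])]
  opt <- optimize(function(t) pb1_velocity(p, t),
                  c(xs[i - 1], xs[i + 1]), maximum = TRUE, tol = 1e-6)
  structure(tibble(aphv = opt$maximum, peak_velocity = opt$objective,
                   residual_se = NA_real_, n_points = NA_integer_,
                   converged = TRUE),
            class = c("phv_estimate", "tbl_df", "tbl", "data.frame"))
}

# Starting values: adult stature a little above the tallest observation,
# theta candidates at the empirical velocity peaks from first differences.
# First differences of jittered annual data are noisy, so several theta
# candidates are proposed (the two largest empirical-velocity midpoints
# plus a coarse grid) and the caller keeps the best resulting fit.
pb1_start_candidates <- function(ages, heights) {
  v_emp <- diff(heights) / diff(ages)
  mid <- (head(ages, -1) + ages[-1]) / 2
  ord <- order(v_emp, decreasing = TRUE)
  cand <- c(mid[ord[seq_len(min(2, length(ord)))]], 11, 13.5, 15.5)
  cand <- pmin(pmax(cand, 8.5), 17.5)
  # drop near-duplicates, preserving priority order
  keep <- c()
  for (x in cand) if (all(abs(x - keep) > 0.7)) keep <- c(keep, x)
  lapply(keep, function(theta0)
    list(h_adult = max(heights) + 2,
         h_theta = heights[which.min(abs(ages - theta0))],
         s0 = 0.1, s1 = 1.0, theta = theta0))
}

#' Fit PB1 to one subject's serial heights
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()])
#' of the PB1 curve to one subject's (age, height) series. PB1 fits are
#' sensitive to starting values, so a deterministic ladder of up to
#' `restarts` perturbed starts is tried and the fit with the lowest
#' residual sum of squares kept (deterministic: no randomness is consumed,
#' so repeated runs on the same data are identical). Convergence is
#' reported honestly in the result; a failed fit is flagged, never
#' silently replaced.
#'
#' @param ages Strictly increasing ages in years; at least 6 values.
#' @param heights Stature in cm, same length.
#' @param init Optional [pb1_params()] starting values.
#' @param restarts Maximum additional starts tried beyond the primary one.
#' @return A list of class `"pb1_fit"` with elements `params`
#'   ([pb1_params()] or `NULL`), `estimate` (a `phv_estimate` tibble),
#'   `residual_se`, `n_points`, `converged`, and `data`.
#' @examples
#' p <- pb1_params(176, 163, 0.11, 1.2, 14.3)
#' ages <- 8:18
#' fit <- fit_pb1(ages, pb1_height(p, ages))
#' fit$estimate$aphv
#' @export
fit_pb1 <- function(ages, heights, init = NULL, restarts = 5) {
  if (length(ages) < 6) {
    abort("fit_pb1 needs at least 6 (age, height) pairs",
          class = "phvalid_input_error")
  }
  if (length(heights) != length(ages) || any(diff(ages) <= 0)) {
    abort("ages must be strictly increasing and match heights in length",
          class = "phvalid_input_error")
  }
  starts <- if (is.null(init)) pb1_start_candidates(ages, heights)
            else list(unclass(init))

  fit_once <- function(st) {
    df <- data.frame(t = ages, y = heights)
    tryCatch({
      m <- minpack.lm::nlsLM(
        y ~ h1 - 2 * (h1 - hth) / (exp(s0 * (t - th)) + exp(s1 * (t - th))),
        data = df,
        start = list(h1 = st$h_adult, hth = st$h_theta,
                     s0 = st$s0, s1 = st$s1, th = st$theta),
        lower = c(h1 = 100, hth = 80, s0 = 1e-4, s1 = 0.2, th = 8),
        upper = c(h1 = 230, hth = 220, s0 = 0.5, s1 = 5, th = 18),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-10, ptol = 1e-10))
      cf <- coef(m)
      p <- pb1_params(cf[["h1"]], cf[["hth"]], cf[["s0"]], cf[["s1"]],
                      cf[["th"]])
      list(params = p, rss = sum(residuals(m)^2))
    }, error = function(e) NULL)
  }

  # widen the ladder with rate-constant variants of the primary start
  if (is.null(init)) {
    s1_var <- lapply(c(0.7, 2), function(s1) {
      st <- starts[[1]]; st$s1 <- s1; st
    })
    starts <- c(starts, s1_var)
  }
  starts <- starts[seq_len(min(1 + restarts, length(starts)))]
  fits <- lapply(starts, fit_once)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  res <- if (length(fits) == 0) NULL else
    fits[[which.min(vapply(fits, function(f) f$rss, numeric(1)))]]

  n <- length(ages)
  if (is.null(res)) {
    est <- tibble(aphv = NA_real_, peak_velocity = NA_real_,
                  residual_se = NA_real_, n_points = n, converged = FALSE)
    out <- list(params = NULL, estimate = est, residual_se = NA_real_,
                n_points = n, converged = FALSE,
                data = tibble(age = ages, height = heights))
    class(out) <- "pb1_fit"
    return(out)
  }

  rse <- sqrt(res$rss / max(n - 5, 1))
  est <- tryCatch(estimate_aphv(res$params), error = function(e) NULL)
  converged <- !is.null(est)
  if (is.null(est)) {
    est <- tibble(aphv = NA_real_, peak_velocity = NA_real_,
                  residual_se = rse, n_points = n, converged = FALSE)
  } else {
    est$residual_se <- rse
    est$n_points <- n
  }
  out <- list(params = res$params, estimate = est, residual_se = rse,
              n_points = n, converged = converged,
              data = tibble(age = ages, height = heights))
  class(out) <- "pb1_fit"
  out
}

#' @export
print.pb1_fit <- function(x, ...) {
  cat("Preece-Baines Model 1 fit\n")
  if (x$converged) {
    p <- x$params
    cat(sprintf("  h_adult %.1f cm, h_theta %.1f cm, s0 %.4f, s1 %.3f, theta %.2f y\n",
                p$h_adult, p$h_theta, p$s0, p$s1, p$theta))
    cat(sprintf("  APHV %.2f y, peak velocity %.2f cm/y, residual SE %.2f cm (n = %d)\n",
                x$estimate$aphv, x$estimate$peak_velocity, x$residual_se,
                x$n_points))
  } else {
    cat("  did not converge (n =", x$n_points, ")\n")
  }
  invisible(x)
}

#' @method tidy pb1_fit
#' @export
tidy.pb1_fit <- function(x, ...) {
  if (!x$converged || is.null(x$params)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = c("h_adult", "h_theta", "s0", "s1", "theta"),
         estimate = unlist(x$params, use.names = FALSE))
}

#' @method glance pb1_fit
#' @export
glance.pb1_fit <- function(x, ...) {
  tibble(aphv = x$estimate$aphv,
         peak_velocity = x$estimate$peak_velocity,
         residual_se = x$residual_se,
         n_points = x$n_points,
         converged = x$converged)
}

#' Fit PB1 across a visit table
#'
#' Applies [fit_pb1()] to every subject in a long-format visit table and
#' returns one row per subject with fitted parameters, observed APHV and
#' diagnostics. Subjects with fewer than 6 visits are returned unconverged
#' rather than dropped, so exclusion accounting stays with the caller.
#'
#' @param visits Data frame with columns `subject_id`, `sex`, `age_years`,
#'   `stature_cm`.
#' @return A tibble, one row per subject: fitted parameters, `aphv`,
#'   `peak_velocity`, `residual_se`, `n_points`, `converged`, and
#'   `aphv_in_span` (whether the fitted APHV lies strictly inside that
#'   subject's measured age range).
#' @export
fit_pb1_cohort <- function(visits) {
  stopifnot(all(c("subject_id", "sex", "age_years", "stature_cm")
                %in% names(visits)))
  visits |>
    as_tibble() |>
    arrange(.data$subject_id, .data$age_years) |>
    group_by(.data$subject_id, .data$sex) |>
    group_modify(function(d, key) {
      if (nrow(d) < 6 || any(duplicated(d$age_years))) {
        d <- d[!duplicated(d$age_years), ]
      }
      if (nrow(d) < 6) {
        return(tibble(h_adult = NA_real_, h_theta = NA_real_, s0 = NA_real_,
                      s1 = NA_real_, theta = NA_real_, aphv = NA_real_,
                      peak_velocity = NA_real_, residual_se = NA_real_,
                      n_points = nrow(d), converged = FALSE,
                      aphv_in_span = FALSE))
      }
      f <- fit_pb1(d$age_years, d$stature_cm)
      pr <- if (is.null(f$params)) {
        list(h_adult = NA_real_, h_theta = NA_real_, s0 = NA_real_,
             s1 = NA_real_, theta = NA_real_)
      } else unclass(f$params)
      tibble(h_adult = pr$h_adult, h_theta = pr$h_theta, s0 = pr$s0,
             s1 = pr$s1, theta = pr$theta,
             aphv = f$estimate$aphv,
             peak_velocity = f$estimate$peak_velocity,
             residual_se = f$residual_se, n_points = f$n_points,
             converged = f$converged,
             aphv_in_span = isTRUE(f$converged) &&
               f$estimate$aphv > min(d$age_years) &&
               f$estimate$aphv < max(d$age_years))
    }) |>
    ungroup()
}
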
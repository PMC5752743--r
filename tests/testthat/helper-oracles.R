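# Independent test oracles. These deliberately avoid the code paths they
# check: the APHV oracle uses a 0.001-year grid over central finite
# differences of the height curve (no analytic velocity, no optimiser),
# and the OLS oracle is the closed two-variable form.

grid_aphv_oracle <- function(params, lo = params$theta - 4,
                             hi = params$theta + 4, step = 0.001) {
  g <- seq(lo, hi, by = step)
  h <- 1e-5
  v <- (pb1_height(params, g + h) - pb1_height(params, g - h)) / (2 * h)
  # the spurt is the interior local maximum (the curve diverges far to the
  # left of the bracket, so a bare argmax could catch the edge)
  k <- length(g)
  peak <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] >= v[3:k],
            FALSE)
  if (!any(peak)) return(NA_real_)
  cand <- which(peak)
  g[cand[which.max(v[cand])]]
}

ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

random_valid_params <- function(n, seed = 42) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    s0 <- runif(1, 0.07, 0.16)
    s1 <- runif(1, max(0.6, s0 + 0.3), 2.2)
    h_adult <- runif(1, 150, 195)
    h_theta <- h_adult - runif(1, 8, 18)
    theta <- runif(1, 10, 16)
    p <- tryCatch(pb1_params(h_adult, h_theta, s0, s1, theta),
                  error = function(e) NULL)
    if (is.null(p)) next
    # keep only parameter sets whose velocity peak is interior
    a <- tryCatch(estimate_aphv(p), error = function(e) NULL)
    if (is.null(a)) next
    out[[length(out) + 1]] <- p
  }
  out
}

# small deterministic visit fixture: two subjects, built in code
tiny_visits <- function() {
  tibble::tibble(
    subject_id = rep(c("b1", "g1"), each = 3),
    sex = rep(c("M", "F"), each = 3),
    age_years = c(13.1, 14.0, 15.2, 11.0, 12.1, 13.0),
    stature_cm = c(152, 160, 168, 144, 152, 157),
    sitting_height_cm = c(78, 82, 87, 76, 80, 83),
    mass_kg = c(42, 50, 56, 36, 40, 45))
}
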
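#' Plot a fitted PB1 growth curve
#'
#' Distance curve over the observations, with the estimated APHV marked.
#'
#' @param object A `"pb1_fit"` from [fit_pb1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb1_fit
#' @export
autoplot.pb1_fit <- function(object, ...) {
  if (!object$converged) {
    abort("cannot plot a non-converged fit", class = "phvalid_input_error")
  }
  rng <- range(object$data$age)
  grid <- tibble(age = seq(rng[1], rng[2], length.out = 200))
  grid$height <- pb1_height(object$params, grid$age)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$height)) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(y = .data$height), shape = 1) +
    ggplot2::geom_vline(xintercept = object$estimate$aphv,
                        linetype = "dashed") +
    ggplot2::labs(x = "age (years)", y = "stature (cm)",
                  title = sprintf("PB1 fit: APHV %.2f y, peak %.1f cm/y",
                                  object$estimate$aphv,
                                  object$estimate$peak_velocity))
}

#' Bland-Altman plot
#'
#' Difference against mean with the bias line, limits of agreement and the
#' fitted proportional-bias regression.
#'
#' @param object A `"ba_fit"` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_fit
#' @export
autoplot.ba_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "red") +
    ggplot2::labs(x = "mean of predicted and observed APHV (years)",
                  y = "predicted - observed APHV (years)")
}

#' Intra-individual spread of predicted APHV
#'
#' One vertical array of predicted APHV per subject (ordered by observed
#' APHV), with the observed value marked — makes the within-subject
#' instability of the predictions visible.
#'
#' @param predictions Long prediction table carrying `observed_aphv`
#'   (e.g. `run_validation(...)$predictions`).
#' @param which_sex "M" or "F".
#' @param equation_id One equation id to display.
#' @param max_subjects Cap on subjects displayed.
#' @return A ggplot object.
#' @export
plot_individual_predictions <- function(predictions, which_sex = "M",
                                        equation_id = NULL,
                                        max_subjects = 60) {
  d <- predictions |> filter(.data$sex == which_sex)
  if (!is.null(equation_id)) d <- d |> filter(.data$equation == equation_id)
  ord <- d |> distinct(.data$subject_id, .data$observed_aphv) |>
    arrange(.data$observed_aphv)
  keep <- head(ord$subject_id, max_subjects)
  d <- d |> filter(.data$subject_id %in% keep) |>
    mutate(subject_id = factor(.data$subject_id, levels = keep))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject_id)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted_aphv),
                        shape = 1, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_aphv),
                        shape = 4, colour = "red") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "subjects (ordered by observed APHV)",
                  y = "age at PHV (years)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
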
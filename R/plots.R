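#' Plot a classification result
#'
#' Per-residue `delta_R` at 12 min with its error bar, coloured by the final
#' call (orange = accelerated, blue = decelerated), faceted by condition
#' when several are present. The shaded band is the unchanged zone
#' `|delta_R| <= Error(delta_R)` of each residue.
#'
#' @param object A `thz_classification` tibble.
#' @param timepoint Which `delta_R` to show (6 or 12; default 12).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.thz_classification <- function(object, timepoint = 12, ...) {
  stopifnot(timepoint %in% c(6, 12))
  dcol <- paste0("delta_r_", timepoint)
  ecol <- paste0("error_delta_r_", timepoint)
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    residue = factor(.data$residue_number),
    delta = .data[[dcol]],
    err = .data[[ecol]]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta - .data$err,
                   ymax = .data$delta + .data$err),
      width = 0.3, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::scale_colour_manual(values = c(
      accelerated = "#d55e00", unchanged = "grey55", decelerated = "#0072b2"
    )) +
    ggplot2::labs(
      x = "residue", colour = NULL,
      y = bquote(Delta * R[.(timepoint) * " min"])
    ) +
    ggplot2::theme_minimal()
  if ("condition" %in% names(df) && length(unique(df$condition)) > 1) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Plot an HDX decay fit
#'
#' @param object An `hdx_fit`.
#' @param ... Unused.
#' @return A ggplot of the data with the fitted exponential.
#' @exportS3Method ggplot2::autoplot
autoplot.hdx_fit <- function(object, ...) {
  est <- stats::coef(object$fit)
  grid <- tibble::tibble(
    time_h = seq(min(object$data$time_h), max(object$data$time_h),
                 length.out = 200)
  )
  grid$intensity <- est[["A"]] * exp(-est[["k"]] * grid$time_h)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$intensity)) +
    ggplot2::geom_line(data = grid, colour = "#0072b2") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "normalised intensity",
                  subtitle = sprintf("k = %.3g h^-1", est[["k"]])) +
    ggplot2::theme_minimal()
}

#' Plot a phase schedule
#'
#' Temperature profile of the protocol on a square-root time axis (so the
#' minutes-scale exposure and the hours-scale storage are both visible).
#'
#' @param object A `phase_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_schedule <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$end <- cumsum(df$duration_min)
  df$start <- df$end - df$duration_min
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = sqrt(.data$start), xmax = sqrt(.data$end),
                   ymin = .data$temperature_c - 0.3,
                   ymax = .data$temperature_c + 0.3,
                   fill = .data$label)
    ) +
    ggplot2::labs(x = expression(sqrt("time (min)")),
                  y = "temperature (°C)", fill = "phase") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
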
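#' Perturbed-to-control intensity ratio
#'
#' The effect of a perturbation on HDX at time point t is read from the
#' ratio of the perturbed normalised amide intensity to the matched
#' general-control one, \eqn{R_t = I_{pert,t} / I_{GC,t}}. Accelerated
#' exchange gives R < 1, decelerated exchange R > 1.
#'
#' @param i_pert,i_gc Normalised amide intensities; `i_gc` must be positive.
#' @return `R_t`, vectorised.
#' @export
ratio_r <- function(i_pert, i_gc) {
  if (any(i_gc <= 0)) stop("control intensity must be positive", call. = FALSE)
  i_pert / i_gc
}

#' Propagated error of an intensity ratio
#'
#' First-order propagation of independent relative noise on the two
#' intensities: \eqn{Error(R_t) = R_t \sqrt{SNR_{pert}^{-2} + SNR_{gc}^{-2}}}.
#'
#' @param r The ratio.
#' @param snr_pert,snr_gc Signal-to-noise ratios of the two peaks; positive
#'   (`Inf` allowed, contributing zero error).
#' @return `Error(R_t)`, vectorised.
#' @examples
#' error_r(1, 33.3, 33.3) # sqrt(2)/33.3 ~ 0.0425
#' @export
error_r <- function(r, snr_pert, snr_gc) {
  if (any(snr_pert <= 0) || any(snr_gc <= 0)) {
    stop("SNR values must be positive", call. = FALSE)
  }
  r * sqrt(snr_pert^-2 + snr_gc^-2)
}

#' Ratio change from the post-equilibration reference
#'
#' Because the perturbation-induced temperature settles within ~3 min, the
#' 3-min ratio serves as reference and effects are judged from
#' \eqn{\Delta R = R_t - R_{3min}} at t = 6 and 12 min.
#'
#' @param r_t Ratio at t (6 or 12 min).
#' @param r_ref Ratio at the 3-min reference.
#' @return `delta_R`, vectorised.
#' @export
delta_r <- function(r_t, r_ref) r_t - r_ref

#' Error of the ratio change
#'
#' The printed definition of the combined error is typographically ambiguous
#' between a plain sum and other readings; the default combines the two
#' time-point errors in quadrature (standard propagation for a difference of
#' independent measurements), with the literal readings `"sum"` and
#' `"half_sum"` selectable.
#'
#' @param e_t,e_ref Errors of `R_t` and of the 3-min reference ratio; >= 0.
#' @param method `"quadrature"` (default), `"sum"`, or `"half_sum"`.
#' @return `Error(delta_R)`, vectorised.
#' @export
error_delta_r <- function(e_t, e_ref,
                          method = c("quadrature", "sum", "half_sum")) {
  method <- match.arg(method)
  if (any(e_t < 0) || any(e_ref < 0)) {
    stop("errors must be non-negative", call. = FALSE)
  }
  switch(method,
    quadrature = sqrt(e_t^2 + e_ref^2),
    sum = e_t + e_ref,
    half_sum = (e_t + e_ref) / 2
  )
}

classification_levels <- c("accelerated", "unchanged", "decelerated")

#' Classify a ratio change against its error
#'
#' One-sigma decision rule with strict inequalities:
#' accelerated iff `delta + error < 0`; decelerated iff `delta - error > 0`;
#' otherwise unchanged.
#'
#' @param delta `delta_R` value(s).
#' @param error `Error(delta_R)` value(s); >= 0.
#' @return Character vector over
#'   `c("accelerated", "unchanged", "decelerated")`.
#' @export
classify_delta <- function(delta, error) {
  if (any(error < 0)) stop("`error` must be non-negative", call. = FALSE)
  dplyr::case_when(
    delta + error < 0 ~ "accelerated",
    delta - error > 0 ~ "decelerated",
    .default = "unchanged"
  )
}

#' Combine the 6- and 12-min calls into one label and onset tier
#'
#' The same non-unchanged call at both time points gives a strong
#' (`at_6_and_12`) call; a call present only at 12 min is weak (`only_12`);
#' no call at 12 min means unchanged. Conflicting directions at the two time
#' points collapse to unchanged with a warning (a conservative policy; the
#' measurement design never produced such a case).
#'
#' @param label_6,label_12 Classification at 6 and 12 min.
#' @return Tibble with columns `label` and `onset`
#'   (`at_6_and_12`, `only_12`, `none`), one row per input pair.
#' @export
combine_timepoints <- function(label_6, label_12) {
  stopifnot(length(label_6) == length(label_12))
  conflict <- label_6 != "unchanged" & label_12 != "unchanged" &
    label_6 != label_12
  if (any(conflict)) {
    warning("conflicting 6- and 12-min calls collapsed to unchanged",
            call. = FALSE)
  }
  label <- dplyr::case_when(
    conflict ~ "unchanged",
    label_12 == "unchanged" ~ "unchanged",
    .default = label_12
  )
  onset <- dplyr::case_when(
    conflict | label_12 == "unchanged" ~ "none",
    label_6 == label_12 ~ "at_6_and_12",
    .default = "only_12"
  )
  tibble::tibble(label = label, onset = onset)
}

#' Normalise amide intensities by the methyl internal standards
#'
#' Each sample's amide intensities are divided by the mean height of that
#' same sample's non-exchangeable methyl resonances, cancelling
#' sample-to-sample concentration differences. SNR values are left untouched
#' (a ratio of like-scaled quantities).
#'
#' @param peaks Tibble of peak records (possibly several samples; a sample is
#'   one `condition` x `timepoint_min` combination) with columns `signal_id`,
#'   `kind`, `intensity`, `snr`, `condition`, `timepoint_min`.
#' @return The amide records with an added `intensity_norm` column.
#' @export
normalize_intensities <- function(peaks) {
  stopifnot(all(c("signal_id", "kind", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  grouped <- peaks |>
    dplyr::group_by(.data$condition, .data$timepoint_min)
  key <- dplyr::group_keys(grouped)
  norm <- grouped |>
    dplyr::group_map(function(df, key) {
      methyl <- df$intensity[df$kind == "methyl"]
      if (!length(methyl)) {
        stop("sample ", key$condition, "/t=", key$timepoint_min,
             " has no methyl internal standards", call. = FALSE)
      }
      m <- mean(methyl)
      if (m <= 0) {
        stop("sample ", key$condition, "/t=", key$timepoint_min,
             " has non-positive methyl mean", call. = FALSE)
      }
      df |>
        dplyr::filter(.data$kind == "amide") |>
        dplyr::mutate(condition = key$condition,
                      timepoint_min = key$timepoint_min,
                      intensity_norm = .data$intensity / m)
    }) |>
    dplyr::bind_rows()
  norm
}

#' Compute perturbed-to-control ratios for every residue and time point
#'
#' Normalises all samples by their methyl standards, pairs each perturbed
#' condition with the control at the same time point, and returns the ratio
#' with its SNR-propagated error.
#'
#' @param peaks Long tibble of peak records covering the control and at
#'   least one perturbed condition at matched time points.
#' @param control Name of the control condition (default `"GC"`).
#' @return A `thz_ratios` tibble: `condition`, `residue_number`,
#'   `timepoint_min`, `r`, `error_r`, `snr_pert`, `snr_gc`.
#' @export
compute_ratios <- function(peaks, control = "GC") {
  norm <- normalize_intensities(peaks)
  if (!control %in% norm$condition) {
    stop("control condition '", control, "' not present", call. = FALSE)
  }
  gc <- norm |>
    dplyr::filter(.data$condition == control) |>
    dplyr::select(residue_number = "signal_id", "timepoint_min",
                  i_gc = "intensity_norm", snr_gc = "snr")
  pert <- norm |>
    dplyr::filter(.data$condition != control) |>
    dplyr::select("condition", residue_number = "signal_id",
                  "timepoint_min", i_pert = "intensity_norm",
                  snr_pert = "snr")
  out <- pert |>
    dplyr::inner_join(gc, by = c("residue_number", "timepoint_min")) |>
    dplyr::mutate(
      r = ratio_r(.data$i_pert, .data$i_gc),
      error_r = error_r(.data$r, .data$snr_pert, .data$snr_gc)
    ) |>
    dplyr::select("condition", "residue_number", "timepoint_min", "r",
                  "error_r", "snr_pert", "snr_gc") |>
    dplyr::arrange(.data$condition, .data$residue_number,
                   .data$timepoint_min)
  class(out) <- c("thz_ratios", class(out))
  out
}

#' Classify every residue from its ratio time course
#'
#' Forms `delta_R` at 6 and 12 min against the 3-min reference, propagates
#' errors with the chosen combiner, applies the one-sigma rule at each time
#' point and merges the two calls into a label and onset tier.
#'
#' @param ratios A `thz_ratios` tibble from [compute_ratios()] containing
#'   the 3-, 6- and 12-min time points.
#' @param method Error combiner for `Error(delta_R)`; see [error_delta_r()].
#' @param reference_min Reference time point (minutes; default 3).
#' @return A `thz_classification` tibble with per-residue ratios, errors,
#'   `delta_r_6/12`, `error_delta_r_6/12`, per-time-point labels, the final
#'   `label` and `onset`.
#' @export
classify_residues <- function(ratios, method = "quadrature",
                              reference_min = 3) {
  needed <- c(reference_min, 6, 12)
  wide <- ratios |>
    dplyr::filter(.data$timepoint_min %in% needed) |>
    tidyr::pivot_wider(
      id_cols = c("condition", "residue_number"),
      names_from = "timepoint_min",
      values_from = c("r", "error_r")
    )
  cols <- c(paste0("r_", needed), paste0("error_r_", needed))
  missing <- setdiff(cols, names(wide))
  if (length(missing)) {
    stop("ratios lack required time points: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rref <- wide[[paste0("r_", reference_min)]]
  eref <- wide[[paste0("error_r_", reference_min)]]
  out <- wide |>
    dplyr::mutate(
      delta_r_6 = delta_r(.data$r_6, rref),
      delta_r_12 = delta_r(.data$r_12, rref),
      error_delta_r_6 = error_delta_r(.data$error_r_6, eref, method),
      error_delta_r_12 = error_delta_r(.data$error_r_12, eref, method),
      label_6 = classify_delta(.data$delta_r_6, .data$error_delta_r_6),
      label_12 = classify_delta(.data$delta_r_12, .data$error_delta_r_12)
    )
  out <- dplyr::bind_cols(out, combine_timepoints(out$label_6, out$label_12))
  class(out) <- c("thz_classification", class(out))
  out
}

#' Residue selection by observability
#'
#' Excludes residues that cannot support the ratio analysis:
#' `fast_exchanger` — the control amide at the first time point has already
#' decayed below `floor_multiple` times the noise rms (equivalently its SNR
#' is below `floor_multiple`), meaning the proton exchanged during cold
#' storage; `low_snr` — any peak of the residue falls below the SNR
#' threshold (3% relative noise at the default 33.3); `overlap` — the peak
#' overlaps another signal.
#'
#' @param peaks Long tibble of peak records (amide rows are used).
#' @param snr_min SNR threshold (default 33.3).
#' @param floor_multiple Intensity floor in units of noise rms (default 3).
#' @param control Control condition name.
#' @return Tibble `residue_number`, `included`, `reason` (`NA` when
#'   included; otherwise `fast_exchanger`, `low_snr` or `overlap`).
#' @export
select_residues <- function(peaks, snr_min = 33.3, floor_multiple = 3,
                            control = "GC") {
  amide <- dplyr::filter(peaks, .data$kind == "amide")
  if (!nrow(amide)) stop("no amide records", call. = FALSE)
  if (snr_min <= 0) stop("`snr_min` must be positive", call. = FALSE)
  first_tp <- min(amide$timepoint_min)
  amide |>
    dplyr::group_by(residue_number = .data$signal_id) |>
    dplyr::summarise(
      fast = any(.data$condition == control &
                   .data$timepoint_min == first_tp &
                   .data$snr < floor_multiple),
      low_snr = any(.data$snr < snr_min),
      overlap = any(.data$overlap),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        fast ~ "fast_exchanger",
        low_snr ~ "low_snr",
        overlap ~ "overlap",
        .default = NA_character_
      ),
      included = is.na(.data$reason)
    ) |>
    dplyr::select("residue_number", "included", "reason")
}

#' Fit a single-exponential HDX decay
#'
#' Nonlinear least squares of `I(t) = A * exp(-k * t)` on the linear
#' intensity scale (additive-noise model; a log transform would distort the
#' errors at low intensity), with `k` constrained to be non-negative.
#' Standard errors come from the fit covariance.
#'
#' @param data Data frame of the time series.
#' @param time,intensity Columns (tidy-eval) holding time in hours and
#'   normalised intensity.
#' @return An `hdx_fit` object; use [generics::tidy()] / [generics::glance()]
#'   or `coef()` to extract `A` and `k` (h^-1).
#' @examples
#' d <- data.frame(t = 0:5 * 2, i = 1.1 * exp(-0.05 * 0:5 * 2))
#' fit <- fit_hdx_rate(d, t, i)
#' tidy(fit)
#' @export
fit_hdx_rate <- function(data, time, intensity) {
  t <- dplyr::pull(data, {{ time }})
  i <- dplyr::pull(data, {{ intensity }})
  if (length(t) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(i <= 0)) stop("intensities must be positive", call. = FALSE)
  if (length(unique(t)) < 2) {
    stop("degenerate series: all time points equal", call. = FALSE)
  }
  # log-linear starting values; slope clamped into the feasible region
  lmfit <- stats::lm(log(i) ~ t)
  k0 <- max(-unname(stats::coef(lmfit)[2]), 1e-8)
  a0 <- max(i)
  df <- data.frame(t = t, i = i)
  # port reports degenerate already-converged cases (e.g. an exactly constant
  # series) as a "singular convergence" warning; the solution is still valid
  fit <- tryCatch(
    withCallingHandlers(
      stats::nls(i ~ A * exp(-k * t), data = df,
                 start = list(A = a0, k = k0),
                 algorithm = "port", lower = c(A = 0, k = 0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      warning = function(w) {
        if (grepl("Convergence failure", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) {
      minpack.lm::nlsLM(i ~ A * exp(-k * t), data = df,
                        start = list(A = a0, k = k0),
                        lower = c(A = 0, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  )
  structure(list(fit = fit, data = tibble::tibble(time_h = t, intensity = i)),
            class = "hdx_fit")
}

#' @export
coef.hdx_fit <- function(object, ...) stats::coef(object$fit)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_hdx_rate
#' @param x,object An `hdx_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hdx_fit <- function(x, ...) {
  est <- stats::coef(x$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(x$fit))),
                 error = function(e) rep(NA_real_, length(est)))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se))
}

#' @rdname fit_hdx_rate
#' @exportS3Method generics::glance
glance.hdx_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    sigma = s$sigma,
    df.residual = stats::df.residual(x$fit),
    nobs = nrow(x$data),
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}

#' @export
print.hdx_fit <- function(x, ...) {
  est <- stats::coef(x$fit)
  cat(sprintf("<hdx_fit> I(t) = %.4g * exp(-%.4g t), n = %d\n",
              est[["A"]], est[["k"]], nrow(x$data)))
  invisible(x)
}
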
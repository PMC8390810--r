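#' Simulate one measurement (one tube, one summed spectrum set)
#'
#' Generates the peak table of a single sample: per-residue amide intensities
#' decayed by the protonated fraction surviving the protocol, plus 37
#' non-exchangeable methyl internal standards. A per-sample concentration
#' jitter multiplies every peak (motivating the methyl normalisation), each
#' of `n_spectra` spectra receives independent homoscedastic Gaussian noise
#' with rms `amplitude / nominal_snr`, and the spectra are summed; reported
#' SNR is summed intensity over summed-noise rms (so summation improves SNR
#' by `sqrt(n_spectra)`).
#'
#' @param residues Residue table (see [default_ubiquitin_fixture()]).
#' @param design An [experiment_design()]; its `seed` makes the sample
#'   bit-reproducible.
#' @param scenario A `perturbation_scenario` applied during the perturbation
#'   window ([gc_scenario()] for the control).
#' @param rate_model An [intrinsic_rate_model()] (reference pH/temperature
#'   and activation energy).
#' @param amplitude Full-intensity peak height `C` (arbitrary units).
#' @param conc_jitter_sd Standard deviation of the per-sample relative
#'   concentration jitter (default 2%).
#' @param n_methyl Number of methyl internal-standard resonances.
#' @param quench_kch_mult Cold-storage quench multiplier on `k_ch`.
#' @return A `peak_table`: a tibble with one row per peak (`signal_id`,
#'   `kind`, `intensity`, `snr`, `overlap`, `condition`, `timepoint_min`)
#'   carrying the summed-noise rms and the design as attributes.
#' @export
simulate_experiment <- function(residues, design, scenario = gc_scenario(),
                                rate_model = intrinsic_rate_model(),
                                amplitude = 1000, conc_jitter_sd = 0.02,
                                n_methyl = 37, quench_kch_mult = 0.05) {
  stopifnot(inherits(design, "experiment_design"))
  check_residue_table(residues)
  set.seed(design$seed)

  storage_hours <- design$storage_hours %||% 8
  if (length(storage_hours) == 2) {
    storage_hours <- stats::runif(1, storage_hours[1], storage_hours[2])
  }
  schedule <- build_schedule(design, scenario, storage_hours = storage_hours,
                             quench_kch_mult = quench_kch_mult)
  frac <- protonated_fraction(schedule, residues, rate_model)
  frac <- frac[match(residues$residue_number, frac$residue_number), ]

  eps <- stats::rnorm(1, 0, conc_jitter_sd)
  conc <- amplitude * (1 + eps)
  noisy <- is.finite(design$nominal_snr)
  rms1 <- if (noisy) amplitude / design$nominal_snr else 0

  n_res <- nrow(residues)
  true_sig <- c(conc * frac$fraction, rep(conc, n_methyl))
  summed <- design$n_spectra * true_sig
  if (noisy) {
    noise <- stats::rnorm(length(true_sig) * design$n_spectra, 0, rms1)
    summed <- summed + rowSums(matrix(noise, nrow = length(true_sig)))
  }
  summed <- pmax(summed, 0)
  rms_summed <- sqrt(design$n_spectra) * rms1

  overlap <- residues$overlap_flag %||% rep(FALSE, n_res)
  out <- tibble::tibble(
    signal_id = c(residues$residue_number, seq_len(n_methyl)),
    kind = rep(c("amide", "methyl"), c(n_res, n_methyl)),
    intensity = summed,
    snr = if (noisy) summed / rms_summed else rep(Inf, length(summed)),
    overlap = c(overlap, rep(FALSE, n_methyl)),
    condition = design$condition,
    timepoint_min = design$timepoint_min
  )
  new_peak_table(out, noise_rms = rms_summed, design = design)
}

new_peak_table <- function(x, noise_rms, design = NULL) {
  structure(x,
            class = c("peak_table", class(tibble::tibble())),
            noise_rms = noise_rms, design = design)
}

#' Summed-noise rms of a peak table
#' @param table A `peak_table`.
#' @export
noise_rms <- function(table) attr(table, "noise_rms")

#' Simulate a full paired run (perturbed condition + matched controls)
#'
#' One sample per (condition, time point): the perturbed condition and the
#' general control, each at 3, 6 and 12 min. Per-sample seeds are derived
#' deterministically from `seed`.
#'
#' @param residues Residue table.
#' @param scenario Perturbation scenario for the non-control condition.
#' @param condition Label of the perturbed condition.
#' @param timepoints Perturbation durations / time-point labels (minutes).
#' @param nominal_snr Per-spectrum SNR (Inf for noise off).
#' @param seed Run seed.
#' @param ... Passed to [simulate_experiment()].
#' @inheritParams simulate_experiment
#' @return A tibble of all peak records (both conditions, all time points).
#' @export
simulate_run <- function(residues, scenario,
                         condition = c("THz_low", "THz_high", "TC"),
                         timepoints = c(3, 6, 12), nominal_snr = 100,
                         seed = 1L, rate_model = intrinsic_rate_model(), ...) {
  condition <- match.arg(condition)
  grid <- tidyr::expand_grid(
    cond = c(condition, "GC"),
    tp = timepoints
  )
  tabs <- purrr::pmap(grid, function(cond, tp) {
    i <- which(grid$cond == cond & grid$tp == tp)
    des <- experiment_design(
      condition = cond, timepoint_min = tp, nominal_snr = nominal_snr,
      seed = seed * 1009L + i
    )
    scen <- if (cond == "GC") gc_scenario() else scenario
    simulate_experiment(residues, des, scen, rate_model = rate_model, ...)
  })
  dplyr::bind_rows(tabs)
}

peak_table_columns <- c("signal_id", "kind", "intensity", "snr", "overlap",
                        "condition", "timepoint_min")

#' Write / read a peak table (TSV)
#'
#' Plain TSV with header `signal_id kind intensity snr overlap condition
#' timepoint_min`, UTF-8, decimal point; lines starting with `#` are
#' comments. The summed-noise rms is preserved in a `# noise_rms = <value>`
#' comment so that write-then-read is lossless.
#'
#' @param table A `peak_table` (or any tibble with the peak-table columns).
#' @param path File path.
#' @return `read_peak_table()` returns a `peak_table`;
#'   `write_peak_table()` returns `path` invisibly.
#' @export
write_peak_table <- function(table, path) {
  missing <- setdiff(peak_table_columns, names(table))
  if (length(missing)) {
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rms <- attr(table, "noise_rms")
  header <- c(
    "# thzhdx peak table",
    sprintf("# noise_rms = %s", format(rms %||% NA_real_, digits = 17))
  )
  writeLines(header, path)
  readr::write_tsv(tibble::as_tibble(table)[peak_table_columns], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rms_line <- grep("^#\\s*noise_rms\\s*=", lines, value = TRUE)
  rms <- if (length(rms_line)) {
    as.numeric(sub("^#\\s*noise_rms\\s*=\\s*", "", rms_line[1]))
  } else {
    NA_real_
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(body)) stop("empty peak table: ", path, call. = FALSE)
  header_cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(peak_table_columns, header_cols)
  if (length(missing)) {
    stop("peak table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      signal_id = readr::col_integer(),
      kind = readr::col_character(),
      intensity = readr::col_double(),
      snr = readr::col_double(),
      overlap = readr::col_logical(),
      condition = readr::col_character(),
      timepoint_min = readr::col_double()
    )
  )
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    stop("malformed peak table at line(s) ",
         paste(unique(probs$row), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  if (any(tab$intensity < 0)) {
    stop("peak table ", path, " contains negative intensities", call. = FALSE)
  }
  new_peak_table(tab[peak_table_columns], noise_rms = rms)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
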
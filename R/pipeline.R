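#' Read and validate a run configuration (YAML)
#'
#' A run config drives [run_thz_hdx()]. Recognised keys:
#' \describe{
#'   \item{mode}{`"simulate"` (generate peak tables, then analyse) or
#'     `"analyze"` (read peak tables from `peak_table_dir`).}
#'   \item{seed}{Integer; required in simulate mode.}
#'   \item{condition}{Perturbed condition (`THz_low`, `THz_high`, `TC`).}
#'   \item{scenario}{List: `type` (`thz`/`heat`/`gc`) plus the matching
#'     factors (`f_kop_up`, `f_kch_down`, `power`, `delta_t_c`,
#'     `f_kop_down`).}
#'   \item{nominal_snr, timepoints, conc_jitter_sd}{Generator settings.}
#'   \item{snr_min, floor_multiple, errdr_method}{Statistics settings.}
#'   \item{peak_table_dir}{Input directory (analyze mode).}
#'   \item{pdb, chain}{Optional coordinate file for structure annotation.}
#'   \item{beam}{Optional list `power_density`, `reflection_loss`, `alpha`,
#'     `pathlength_cm` for the dose report.}
#'   \item{out}{Output directory.}
#' }
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `thz_run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list with the keys above.
#' @export
validate_run_config <- function(cfg) {
  known <- c("mode", "seed", "condition", "scenario", "nominal_snr",
             "timepoints", "conc_jitter_sd", "snr_min", "floor_multiple",
             "errdr_method", "peak_table_dir", "pdb", "chain", "beam", "out")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$mode <- cfg$mode %||% "simulate"
  if (!cfg$mode %in% c("simulate", "analyze")) {
    stop("`mode` must be 'simulate' or 'analyze'", call. = FALSE)
  }
  if (cfg$mode == "simulate" && is.null(cfg$seed)) {
    stop("`seed` is required in simulate mode", call. = FALSE)
  }
  if (cfg$mode == "analyze" && is.null(cfg$peak_table_dir)) {
    stop("`peak_table_dir` is required in analyze mode", call. = FALSE)
  }
  cfg$condition <- cfg$condition %||% "THz_low"
  cfg$scenario <- cfg$scenario %||% list(type = "thz")
  cfg$nominal_snr <- cfg$nominal_snr %||% 100
  cfg$timepoints <- cfg$timepoints %||% c(3, 6, 12)
  cfg$conc_jitter_sd <- cfg$conc_jitter_sd %||% 0.02
  cfg$snr_min <- cfg$snr_min %||% 33.3
  if (cfg$snr_min <= 0) stop("`snr_min` must be positive", call. = FALSE)
  cfg$floor_multiple <- cfg$floor_multiple %||% 3
  cfg$errdr_method <- cfg$errdr_method %||% "quadrature"
  cfg$chain <- cfg$chain %||% "A"
  cfg$out <- cfg$out %||% "thzhdx-run"
  structure(cfg, class = "thz_run_config")
}

scenario_from_config <- function(sc) {
  type <- sc$type %||% "thz"
  switch(type,
    thz = thz_scenario(
      f_kop_up = sc$f_kop_up %||% 6,
      f_kch_down = sc$f_kch_down %||% 0.1,
      power = sc$power %||% "low",
      delta_t_c = sc$delta_t_c
    ),
    heat = heat_scenario(
      delta_t_c = sc$delta_t_c %||% 5,
      f_kop_down = sc$f_kop_down %||% 0.5
    ),
    gc = gc_scenario(),
    stop("unknown scenario type '", type, "'", call. = FALSE)
  )
}

#' Run the full pipeline
#'
#' Simulate (or load) peak tables, normalise by the methyl standards, select
#' observable residues, compute ratios and errors, classify, and write the
#' artifacts: per-sample peak tables (simulate mode), a results TSV, a JSON
#' run summary (config hash, seed, label counts, optional dose), and an
#' annotated PDB when coordinates are supplied. Identical config and seed
#' reproduce identical artifacts; on failure, partially written output is
#' removed.
#'
#' @param cfg A `thz_run_config` (from [read_run_config()] or
#'   [validate_run_config()]).
#' @param residues Residue table (defaults to the ubiquitin fixture).
#' @return Invisibly, a list with the classification tibble, the selection
#'   table and the output paths.
#' @export
run_thz_hdx <- function(cfg, residues = default_ubiquitin_fixture()) {
  stopifnot(inherits(cfg, "thz_run_config"))
  out_dir <- cfg$out
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)

  if (cfg$mode == "simulate") {
    scen <- scenario_from_config(cfg$scenario)
    grid <- tidyr::expand_grid(cond = c(cfg$condition, "GC"),
                               tp = cfg$timepoints)
    tabs <- purrr::pmap(
      list(grid$cond, grid$tp, seq_len(nrow(grid))),
      function(cond, tp, i) {
        des <- experiment_design(
          condition = cond, timepoint_min = tp,
          nominal_snr = cfg$nominal_snr, seed = cfg$seed * 1009L + i
        )
        simulate_experiment(
          residues, des,
          scenario = if (cond == "GC") gc_scenario() else scen,
          conc_jitter_sd = cfg$conc_jitter_sd
        )
      }
    )
    for (tab in tabs) {
      f <- file.path(out_dir, sprintf("peaks_%s_t%02d.tsv",
                                      tab$condition[1], tab$timepoint_min[1]))
      write_peak_table(tab, f)
    }
    peaks <- dplyr::bind_rows(tabs)
  } else {
    files <- list.files(cfg$peak_table_dir, pattern = "^peaks_.*\\.tsv$",
                        full.names = TRUE)
    if (!length(files)) {
      stop("no peak tables found in ", cfg$peak_table_dir, call. = FALSE)
    }
    peaks <- dplyr::bind_rows(lapply(files, read_peak_table))
  }

  selection <- select_residues(peaks, snr_min = cfg$snr_min,
                               floor_multiple = cfg$floor_multiple)
  kept <- selection$residue_number[selection$included]
  peaks_kept <- dplyr::filter(
    peaks, .data$kind == "methyl" | .data$signal_id %in% kept
  )
  cls <- peaks_kept |>
    compute_ratios() |>
    classify_residues(method = cfg$errdr_method)

  results_path <- file.path(out_dir, "results.tsv")
  write_results(cls, selection, results_path)

  paths <- list(results = results_path)
  if (!is.null(cfg$pdb)) {
    paths$annotated_pdb <- file.path(out_dir, "annotated.pdb")
    paths$attributes <- file.path(out_dir, "residue_attributes.tsv")
    annotate_structure(cls, cfg$pdb, chain = cfg$chain,
                       out_pdb = paths$annotated_pdb,
                       out_attr = paths$attributes)
  }

  summary <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    mode = cfg$mode,
    condition = cfg$condition,
    n_residues = nrow(selection),
    n_included = sum(selection$included),
    label_counts = as.list(table(cls$label))
  )
  if (!is.null(cfg$beam)) {
    b <- cfg$beam
    summary$dose <- beam_summary(
      power_density = b$power_density,
      duration_min = max(cfg$timepoints),
      reflection_loss = b$reflection_loss %||% 0.40,
      alpha = b$alpha %||% 83,
      pathlength_cm = b$pathlength_cm %||% 0.039
    )
  }
  paths$summary <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  ok <- TRUE
  invisible(list(classification = cls, selection = selection, paths = paths))
}

#' Write the per-residue results table (TSV)
#'
#' Columns: `residue R3 err3 R6 err6 R12 err12 dR6 errdR6 dR12 errdR12
#' label onset exclusion_reason`; excluded residues appear with their
#' exclusion reason and empty statistics.
#'
#' @param classification A `thz_classification` tibble.
#' @param selection Selection table from [select_residues()] (optional).
#' @param path Output path.
#' @export
write_results <- function(classification, selection = NULL, path) {
  res <- classification |>
    dplyr::transmute(
      residue = .data$residue_number,
      R3 = .data$r_3, err3 = .data$error_r_3,
      R6 = .data$r_6, err6 = .data$error_r_6,
      R12 = .data$r_12, err12 = .data$error_r_12,
      dR6 = .data$delta_r_6, errdR6 = .data$error_delta_r_6,
      dR12 = .data$delta_r_12, errdR12 = .data$error_delta_r_12,
      label = .data$label, onset = .data$onset
    )
  if (!is.null(selection)) {
    res <- selection |>
      dplyr::transmute(residue = .data$residue_number,
                       exclusion_reason = .data$reason) |>
      dplyr::left_join(res, by = "residue") |>
      dplyr::relocate("exclusion_reason", .after = dplyr::last_col())
  } else {
    res$exclusion_reason <- NA_character_
  }
  readr::write_tsv(res, path)
  invisible(path)
}
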
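#' Validate a residue table
#'
#' @noRd
check_residue_table <- function(residues) {
  needed <- c("residue_number", "hydropathy_class", "K_op", "k_ch_ref")
  missing <- setdiff(needed, names(residues))
  if (length(missing)) {
    stop("residue table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(residues$K_op <= 0)) stop("`K_op` must be positive", call. = FALSE)
  if (any(residues$k_ch_ref < 0)) {
    stop("`k_ch_ref` must be non-negative", call. = FALSE)
  }
  invisible(residues)
}

#' Hydropathy classes used by the perturbation scenarios
#' @export
hydropathy_classes <- function() {
  c("interior_helix", "hydrophobic_surface", "hydrophilic_surface")
}

#' Default ubiquitin residue fixture
#'
#' The 15 slow-exchanging ubiquitin amides for which a perturbation response
#' direction is established: the inner helical surface (V26, I30), the
#' hydrophobic beta-sheet surface (I3, F4, L15, V17, I44, V70, plus the slow
#' beta3 set Q41, R42, L43 and L69), and the hydrophilic surface loop /
#' 3-10 helix (D21, Y59, I61).
#'
#' Ground-truth kinetic parameters are fixed, not sampled: opening equilibria
#' span `K_op` of 1e-7 to 1e-3 — smallest for the rigid interior, largest for
#' solvent-exposed loops — and the per-residue intrinsic rate `k_ch_ref`
#' (h^-1, at reference pH and temperature) is chosen so that every
#' control-condition EX2 rate `K_op * k_ch_ref` stays at or below the 0.1 h^-1
#' bound established for the selected slow exchangers.
#'
#' @return Tibble with columns `residue_number`, `amino_acid` (one-letter
#'   code), `hydropathy_class`, `K_op`, `k_ch_ref`, `overlap_flag`,
#'   `fast_exchanger`.
#' @examples
#' fx <- default_ubiquitin_fixture()
#' all(fx$K_op * fx$k_ch_ref <= 0.1)
#' @export
default_ubiquitin_fixture <- function() {
  # K_op and the target control-condition rate k_ex = K_op * k_ch_ref (h^-1)
  spec <- tibble::tribble(
    ~residue_number, ~amino_acid, ~hydropathy_class,     ~K_op,  ~k_ex_gc,
    3L,  "I", "hydrophobic_surface", 1.0e-6, 0.040,
    4L,  "F", "hydrophobic_surface", 2.0e-6, 0.050,
    15L, "L", "hydrophobic_surface", 1.5e-6, 0.045,
    17L, "V", "hydrophobic_surface", 3.0e-6, 0.055,
    21L, "D", "hydrophilic_surface", 2.0e-4, 0.100,
    26L, "V", "interior_helix",      2.0e-7, 0.020,
    30L, "I", "interior_helix",      3.0e-7, 0.025,
    41L, "Q", "hydrophobic_surface", 5.0e-7, 0.030,
    42L, "R", "hydrophobic_surface", 6.0e-7, 0.030,
    43L, "L", "hydrophobic_surface", 8.0e-7, 0.035,
    44L, "I", "hydrophobic_surface", 2.5e-6, 0.060,
    59L, "Y", "hydrophilic_surface", 1.0e-4, 0.090,
    61L, "I", "hydrophilic_surface", 3.0e-4, 0.095,
    69L, "L", "hydrophobic_surface", 4.0e-6, 0.050,
    70L, "V", "hydrophobic_surface", 5.0e-6, 0.065
  )
  spec |>
    dplyr::mutate(
      k_ch_ref = .data$k_ex_gc / .data$K_op,
      overlap_flag = FALSE,
      fast_exchanger = FALSE
    ) |>
    dplyr::select(-"k_ex_gc") |>
    dplyr::arrange(.data$residue_number)
}
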
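#' Observed exchange rate of the two-state opening model
#'
#' Backbone amide hydrogens exchange with solvent deuterons through a
#' transient structural opening:
#' closed (k_op) <-> (k_cl) open --(k_ch)--> exchanged.
#' Under native conditions opening is rare (`k_op << k_cl`) and the observed
#' first-order exchange rate is the pre-equilibrium Linderstrom-Lang
#' expression
#' \deqn{k_{ex} = \frac{k_{op}\,k_{ch}}{k_{cl} + k_{ch}},}
#' which reduces to the EX2 product `K_op * k_ch` when closing outruns
#' chemistry (`k_cl >> k_ch`) and to the opening rate `k_op` in the EX1 limit
#' (`k_ch >> k_cl`).
#'
#' @param k_op Opening rate (h^-1), non-negative.
#' @param k_cl Closing rate (h^-1), non-negative.
#' @param k_ch Intrinsic chemical exchange rate in the open state (h^-1),
#'   non-negative.
#' @return Observed exchange rate (h^-1). Vectorised over its arguments.
#' @seealso [ex2_rate()] for the EX2 limit.
#' @examples
#' exchange_rate_general(k_op = 1, k_cl = 1e4, k_ch = 1) # ~1e-4 (EX2 regime)
#' exchange_rate_general(k_op = 0.01, k_cl = 1, k_ch = 1e6) # ~0.01 (EX1)
#' @export
exchange_rate_general <- function(k_op, k_cl, k_ch) {
  if (any(k_op < 0) || any(k_cl < 0) || any(k_ch < 0)) {
    stop("rates `k_op`, `k_cl`, `k_ch` must be non-negative", call. = FALSE)
  }
  denom <- k_cl + k_ch
  out <- ifelse(denom == 0, k_op * (k_ch > 0), k_op * k_ch / denom)
  # denom == 0 means k_cl == k_ch == 0: nothing exchanges
  ifelse(k_ch == 0, 0, out)
}

#' EX2-limit exchange rate
#'
#' In the EX2 limit the exchange rate is the intrinsic chemical rate weighted
#' by the opening equilibrium constant: `k_ex = K_op * k_ch`.
#'
#' @param K_op Opening equilibrium constant (dimensionless, > 0).
#' @param k_ch Intrinsic chemical exchange rate (h^-1, >= 0).
#' @return Exchange rate (h^-1). Vectorised.
#' @examples
#' ex2_rate(K_op = 1e-4, k_ch = 1e3) # 0.1 h^-1
#' @export
ex2_rate <- function(K_op, k_ch) {
  if (any(K_op <= 0)) stop("`K_op` must be positive", call. = FALSE)
  if (any(k_ch < 0)) stop("`k_ch` must be non-negative", call. = FALSE)
  K_op * k_ch
}

#' Intrinsic-rate reference model
#'
#' Bundles the reference value of the intrinsic chemical exchange rate with
#' the conditions it refers to and the knobs used to rescale it: pure base
#' catalysis in pH (a 10-fold change per pH unit) and an Arrhenius activation
#' energy in temperature.
#'
#' @param k_ref Intrinsic rate (h^-1) at the reference conditions; > 0.
#' @param ph_ref Reference pH (unitless).
#' @param t_ref_c Reference temperature (degrees C).
#' @param ea_kj_mol Activation energy (kJ/mol) for Arrhenius temperature
#'   scaling; >= 0. Default 60 kJ/mol, a typical magnitude for base-catalysed
#'   amide exchange; tune per system.
#' @return An object of class `intrinsic_rate_model`.
#' @export
intrinsic_rate_model <- function(k_ref = 1, ph_ref = 5.6, t_ref_c = 25,
                                 ea_kj_mol = 60) {
  stopifnot(is.numeric(k_ref), length(k_ref) == 1, is.finite(k_ref))
  if (k_ref <= 0) stop("`k_ref` must be positive", call. = FALSE)
  if (ea_kj_mol < 0) stop("`ea_kj_mol` must be non-negative", call. = FALSE)
  structure(
    list(k_ref = k_ref, ph_ref = ph_ref, t_ref_c = t_ref_c,
         ea_kj_mol = ea_kj_mol),
    class = "intrinsic_rate_model"
  )
}

#' @export
print.intrinsic_rate_model <- function(x, ...) {
  cat("<intrinsic_rate_model>\n")
  cat(sprintf("  k_ref: %g h^-1 at pH %g, %g degC (Ea = %g kJ/mol)\n",
              x$k_ref, x$ph_ref, x$t_ref_c, x$ea_kj_mol))
  invisible(x)
}

#' pH scaling of the intrinsic exchange rate
#'
#' Base-catalysed amide exchange above pH ~4 scales 10-fold per pH unit;
#' with a pH-independent opening equilibrium this carries through to the EX2
#' rate. Acid- and water-catalysed terms are deliberately omitted (see the
#' methods vignette).
#'
#' @param model An [intrinsic_rate_model()].
#' @param ph Target pH; finite.
#' @return Rate (h^-1): `k_ref * 10^(ph - ph_ref)`. Vectorised over `ph`.
#' @examples
#' m <- intrinsic_rate_model(k_ref = 1, ph_ref = 5.6)
#' scale_kch_ph(m, 6.6) # 10
#' scale_kch_ph(m, 7.2) # 10^1.6 ~ 39.8
#' @export
scale_kch_ph <- function(model, ph) {
  stopifnot(inherits(model, "intrinsic_rate_model"))
  if (any(!is.finite(ph))) stop("`ph` must be finite", call. = FALSE)
  model$k_ref * 10^(ph - model$ph_ref)
}

#' Arrhenius temperature scaling of the intrinsic exchange rate
#'
#' @param model An [intrinsic_rate_model()].
#' @param temperature_c Target temperature (degrees C); must be above
#'   absolute zero.
#' @return Rate (h^-1): `k_ref * exp(-Ea/R * (1/T - 1/T_ref))` with
#'   temperatures in kelvin. Vectorised over `temperature_c`.
#' @examples
#' m <- intrinsic_rate_model(k_ref = 1, t_ref_c = 25, ea_kj_mol = 60)
#' scale_kch_temperature(m, 30) # ~1.49
#' @export
scale_kch_temperature <- function(model, temperature_c) {
  stopifnot(inherits(model, "intrinsic_rate_model"))
  t_k <- temperature_c + 273.15
  if (any(t_k <= 0)) stop("temperature must be above absolute zero", call. = FALSE)
  R_gas <- 8.31446261815324e-3 # kJ/(mol K)
  t_ref_k <- model$t_ref_c + 273.15
  model$k_ref * exp(-(model$ea_kj_mol / R_gas) * (1 / t_k - 1 / t_ref_k))
}

#' Combined pH/temperature factor relative to reference conditions
#'
#' Multiplicative factor applied to a residue's reference intrinsic rate for
#' a phase at the given pH and temperature. Internal helper shared by the
#' protocol integrator.
#'
#' @noRd
kch_condition_factor <- function(model, ph, temperature_c) {
  (scale_kch_ph(model, ph) / model$k_ref) *
    (scale_kch_temperature(model, temperature_c) / model$k_ref)
}

#' Build one protocol phase
#'
#' A phase is a contiguous stretch of the exposure protocol with constant
#' temperature, pH and per-class kinetic multipliers. Multipliers are named
#' by hydropathy class; classes absent from a map default to 1.
#'
#' @param duration_min Duration in minutes, >= 0 and finite.
#' @param temperature_c Temperature (degrees C).
#' @param ph pH during the phase.
#' @param kop_mult,kch_mult Named numeric vectors mapping hydropathy class to
#'   a positive multiplicative factor on `K_op` / `k_ch`.
#' @param label Optional phase label.
#' @return A one-row tibble usable as a row of a phase schedule.
#' @export
protocol_phase <- function(duration_min, temperature_c = 25, ph = 5.6,
                           kop_mult = numeric(), kch_mult = numeric(),
                           label = NA_character_) {
  if (!is.finite(duration_min) || duration_min < 0) {
    stop("`duration_min` must be finite and non-negative", call. = FALSE)
  }
  if (length(kop_mult) && (is.null(names(kop_mult)) || any(kop_mult <= 0))) {
    stop("`kop_mult` must be a named vector of positive factors", call. = FALSE)
  }
  if (length(kch_mult) && (is.null(names(kch_mult)) || any(kch_mult <= 0))) {
    stop("`kch_mult` must be a named vector of positive factors", call. = FALSE)
  }
  tibble::tibble(
    label = label,
    duration_min = duration_min,
    temperature_c = temperature_c,
    ph = ph,
    kop_mult = list(kop_mult),
    kch_mult = list(kch_mult)
  )
}

#' Assemble a phase schedule
#'
#' @param ... One-row tibbles from [protocol_phase()] (or complete schedule
#'   tibbles to concatenate).
#' @return A `phase_schedule` tibble; phases are contiguous by construction
#'   (each starts where the previous one ends) and total duration must be
#'   positive.
#' @export
phase_schedule <- function(...) {
  sched <- dplyr::bind_rows(...)
  if (nrow(sched) == 0 || sum(sched$duration_min) <= 0) {
    stop("a phase schedule needs at least one phase of positive duration",
         call. = FALSE)
  }
  class(sched) <- c("phase_schedule", class(sched))
  sched
}

# "*" applies to every class, combined with any class-specific factor
mult_for_class <- function(map, cls) {
  out <- rep(1, length(cls))
  if (length(map)) {
    base <- if ("*" %in% names(map)) unname(map[["*"]]) else 1
    hit <- match(cls, names(map))
    out[!is.na(hit)] <- map[hit[!is.na(hit)]]
    out <- out * base
  }
  out
}

#' Per-phase EX2 exchange rates for a residue set
#'
#' For each phase and residue, the effective EX2 rate is
#' `K_op * kop_mult(class) * k_ch_ref * f(pH) * f(T) * kch_mult(class)`,
#' with pH and temperature factors taken relative to the reference model.
#'
#' @param schedule A [phase_schedule()].
#' @param residues Tibble of residues (see [default_ubiquitin_fixture()] for
#'   the required columns `residue_number`, `hydropathy_class`, `K_op`,
#'   `k_ch_ref`).
#' @param rate_model An [intrinsic_rate_model()] giving the reference pH,
#'   temperature and activation energy (its `k_ref` is only a carrier for the
#'   scaling laws; per-residue `k_ch_ref` supplies the magnitude).
#' @return Tibble with one row per phase x residue: `residue_number`,
#'   `phase`, `duration_min`, `k_ex` (h^-1).
#' @export
phase_rates <- function(schedule, residues,
                        rate_model = intrinsic_rate_model()) {
  stopifnot(inherits(schedule, "phase_schedule"))
  check_residue_table(residues)
  purrr::imap_dfr(seq_len(nrow(schedule)), function(i, ...) {
    ph_i <- schedule$ph[i]
    t_i <- schedule$temperature_c[i]
    cond <- kch_condition_factor(rate_model, ph_i, t_i)
    tibble::tibble(
      residue_number = residues$residue_number,
      phase = i,
      duration_min = schedule$duration_min[i],
      k_ex = ex2_rate(
        residues$K_op * mult_for_class(schedule$kop_mult[[i]],
                                       residues$hydropathy_class),
        residues$k_ch_ref * cond *
          mult_for_class(schedule$kch_mult[[i]], residues$hydropathy_class)
      )
    )
  })
}

#' Protonated fraction after a piecewise protocol
#'
#' Exchange into excess D2O is first order and irreversible, so over a
#' piecewise-constant protocol the surviving protonated fraction is the
#' product of per-phase exponentials
#' \deqn{f = \prod_i \exp(-k_{ex,i}\,\Delta t_i).}
#'
#' @inheritParams phase_rates
#' @return Tibble `residue_number`, `fraction` with `fraction` in (0, 1];
#'   non-increasing as phases are appended and invariant under subdividing a
#'   phase.
#' @export
protonated_fraction <- function(schedule, residues,
                                rate_model = intrinsic_rate_model()) {
  rates <- phase_rates(schedule, residues, rate_model)
  rates |>
    dplyr::group_by(.data$residue_number) |>
    dplyr::summarise(
      fraction = exp(-sum(.data$k_ex * .data$duration_min / 60)),
      .groups = "drop"
    )
}

#' Apparent pH order of an exchange rate
#'
#' Decades of rate change per pH unit between two measurements. Ideal EX2
#' exchange with a pH-independent opening equilibrium gives exactly 1; rigid,
#' opening-limited residues fall below 1.
#'
#' @param k_ex_ph1,k_ex_ph2 Exchange rates (h^-1) at `ph1` and `ph2`; > 0.
#' @param ph1,ph2 The two pH values; must differ.
#' @return Apparent order, `log10(k2/k1) / (ph2 - ph1)`.
#' @examples
#' ph_sensitivity(0.1, 0.1 * 10^1.6, 5.6, 7.2) # 1 (ideal EX2)
#' @export
ph_sensitivity <- function(k_ex_ph1, k_ex_ph2, ph1, ph2) {
  if (any(k_ex_ph1 <= 0) || any(k_ex_ph2 <= 0)) {
    stop("exchange rates must be positive", call. = FALSE)
  }
  if (any(ph1 == ph2)) stop("`ph1` and `ph2` must differ", call. = FALSE)
  log10(k_ex_ph2 / k_ex_ph1) / (ph2 - ph1)
}
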
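#' Energy-balance weight-model parameters
#'
#' Simplified steady-state energy-balance rule: a sustained change of
#' `kj_per_kg` kilojoules per day in energy intake moves steady-state
#' body weight by one kilogram (default 100 kJ/day per kg). The approach
#' to the new steady state is exponential, calibrated so that
#' `attainment_fraction` of the full change is reached at
#' `horizon_years` (defaults: 95% at 3 years). Height is held constant,
#' so the BMI change is the weight change divided by height squared.
#'
#' @param kj_per_kg Steady-state constant, kJ/day per kg; `> 0`.
#' @param attainment_fraction Fraction of the steady-state change reached
#'   at the horizon, in `(0, 1]`.
#' @param horizon_years Calibration horizon in years; `> 0`.
#' @param kcal_to_kj Thermochemical conversion, kJ per kcal.
#' @param min_weight_kg Physiologic floor applied after the change.
#' @return A list of class `weight_model_params` with the inputs plus
#'   `tau_years`, the calibrated exponential time constant
#'   (`1 - exp(-horizon/tau) == attainment_fraction` exactly; infinite
#'   when `attainment_fraction = 1`, meaning the steady state itself).
#' @export
weight_model_params <- function(kj_per_kg = 100,
                                attainment_fraction = 0.95,
                                horizon_years = 3,
                                kcal_to_kj = 4.184,
                                min_weight_kg = 30) {
  check_number(kj_per_kg, "kj_per_kg", min = 0, allow_zero = FALSE)
  check_number(attainment_fraction, "attainment_fraction", min = 0, max = 1,
               allow_zero = FALSE)
  check_number(horizon_years, "horizon_years", min = 0, allow_zero = FALSE)
  check_number(kcal_to_kj, "kcal_to_kj", min = 0, allow_zero = FALSE)
  check_number(min_weight_kg, "min_weight_kg", min = 0)
  tau <- if (attainment_fraction >= 1) {
    0  # sentinel: interpret as instantaneous attainment of steady state
  } else {
    -horizon_years / log(1 - attainment_fraction)
  }
  structure(list(kj_per_kg = kj_per_kg,
                 attainment_fraction = attainment_fraction,
                 horizon_years = horizon_years,
                 kcal_to_kj = kcal_to_kj,
                 min_weight_kg = min_weight_kg,
                 tau_years = tau),
            class = "weight_model_params")
}

#' Steady-state weight change from a sustained energy-intake change
#'
#' `delta_w = delta_e * kcal_to_kj / kj_per_kg`: with the defaults, a
#' sustained -100 kJ/day (about -23.9 kcal/day) maps to -1 kg of
#' steady-state body weight. Linear and sign-preserving.
#'
#' @param delta_e_kcal Signed energy-intake change, kcal/day (vectorised).
#' @param params A [weight_model_params()].
#' @return Signed steady-state weight change, kg.
#' @examples
#' steady_state_weight_change(-100 / 4.184)  # exactly -1 kg
#' @export
steady_state_weight_change <- function(delta_e_kcal,
                                       params = weight_model_params()) {
  stopifnot(inherits(params, "weight_model_params"))
  delta_e_kcal * params$kcal_to_kj / params$kj_per_kg
}

#' Weight change attained after a given time
#'
#' Exponential approach to the new steady state,
#' `delta_w(t) = delta_w_ss * (1 - exp(-t / tau))`, with `tau` calibrated
#' in [weight_model_params()] so that the attainment fraction is hit
#' exactly at the configured horizon (default: 95% at 3 years).
#'
#' @param delta_w_ss Steady-state weight change, kg (vectorised).
#' @param t_years Elapsed time, years; `>= 0`.
#' @param params A [weight_model_params()].
#' @return Attained weight change at `t_years`, kg.
#' @examples
#' weight_change_at_horizon(-1, 3)  # -0.95 kg
#' @export
weight_change_at_horizon <- function(delta_w_ss, t_years,
                                     params = weight_model_params()) {
  stopifnot(inherits(params, "weight_model_params"))
  check_number(t_years, "t_years", min = 0)
  if (params$tau_years == 0) {
    frac <- if (t_years > 0) 1 else 0
  } else {
    frac <- 1 - exp(-t_years / params$tau_years)
  }
  delta_w_ss * frac
}

#' Apply a weight change to individuals, holding height constant
#'
#' @param individuals Data frame with `height_m` and `weight_kg`
#'   (typically `pop$individuals`).
#' @param delta_w_kg Signed weight change, kg (length 1 or one per row).
#' @param params A [weight_model_params()]; supplies the physiologic
#'   weight floor. Individuals pushed below the floor are clamped and
#'   counted in the `clamped` attribute with a warning.
#' @return A tibble with `delta_w_kg` (after clamping), `weight_post_kg`,
#'   `bmi_pre`, `bmi_post`.
#' @export
apply_weight_change <- function(individuals, delta_w_kg,
                                params = weight_model_params()) {
  h <- individuals$height_m
  w <- individuals$weight_kg
  if (any(!is.finite(h)) || any(h <= 0)) abort("`height_m` must be positive.")
  if (any(!is.finite(w)) || any(w <= 0)) abort("`weight_kg` must be positive.")
  w_post <- w + delta_w_kg
  # The floor only binds for individuals at or above it at baseline; anyone
  # already below is left where the energy change puts them (never raised),
  # guarded only against nonpositive weight.
  floor_kg <- ifelse(w >= params$min_weight_kg, params$min_weight_kg,
                     pmin(w, 1))
  clamped <- w_post < floor_kg
  n_clamped <- sum(clamped)
  if (n_clamped > 0) {
    warn(sprintf("%d individual(s) clamped at the %g kg weight floor.",
                 n_clamped, params$min_weight_kg))
    w_post[clamped] <- floor_kg[clamped]
  }
  out <- tibble::tibble(
    delta_w_kg = w_post - w,
    weight_post_kg = w_post,
    bmi_pre = w / h^2,
    bmi_post = w_post / h^2
  )
  attr(out, "clamped") <- n_clamped
  out
}
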
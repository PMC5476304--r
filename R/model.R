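#' Fixed biophysical constants of the PD neuron clamp model
#'
#' Constants that are held fixed during fitting: membrane capacitance, the
#' sigmoid slope factors of the three gating variables, the half-activation
#' voltage of the H current, the gating exponents, the voltage dependence of
#' the H-current activation time constant, and the reversal potentials.
#'
#' The reversal potentials are not constrained by the impedance attributes
#' alone; the defaults are typical crustacean stomatogastric values. Fitted
#' maximal conductances trade off against the chosen driving forces, so they
#' are comparable across analyses only for a fixed set of reversal potentials.
#'
#' @param C_m membrane capacitance (nF).
#' @param k_mCa,k_hCa slope factors (mV) of the Ca activation and
#'   inactivation sigmoids; activation slopes are negative (increasing in V),
#'   the inactivation slope positive.
#' @param k_mH slope factor (mV) of the H activation sigmoid.
#' @param V_half_mH half-activation voltage (mV) of the H current. The default
#'   -70 mV follows crab measurements; -96 mV is the lobster variant.
#' @param p_Ca,q_Ca,p_H,q_H integer gating exponents; the calcium current is
#'   \eqn{\bar g_{Ca} m^3 h (V - E_{Ca})}, the H current \eqn{\bar g_H m (V - E_H)}.
#' @param tauH_shift,tauH_slope voltage shift (mV) and slope (mV) of the
#'   H-activation time constant \eqn{\tau_{mH}(V) = \tau_{mH}^{max} /
#'   [1 + \exp((V + 110)/(-13))]}.
#' @param E_L,E_Ca,E_H reversal potentials (mV) of leak, Ca and H currents.
#' @return An object of class `"mpr_constants"` (named list).
#' @export
#' @examples
#' cc <- fixed_constants()
#' cc$V_half_mH
fixed_constants <- function(C_m = 1, k_mCa = -8, k_hCa = 6, k_mH = -7,
                            V_half_mH = -70, p_Ca = 3L, q_Ca = 1L,
                            p_H = 1L, q_H = 0L,
                            tauH_shift = 110, tauH_slope = -13,
                            E_L = -60, E_Ca = 120, E_H = -20) {
  stopifnot(C_m > 0, k_mCa < 0, k_hCa > 0, k_mH < 0, tauH_slope < 0)
  p_Ca <- as.integer(p_Ca); q_Ca <- as.integer(q_Ca)
  p_H <- as.integer(p_H); q_H <- as.integer(q_H)
  stopifnot(p_Ca >= 0, q_Ca >= 0, p_H >= 0, q_H == 0L)
  structure(list(C_m = C_m, k_mCa = k_mCa, k_hCa = k_hCa, k_mH = k_mH,
                 V_half_mH = V_half_mH, p_Ca = p_Ca, q_Ca = q_Ca,
                 p_H = p_H, q_H = q_H,
                 tauH_shift = tauH_shift, tauH_slope = tauH_slope,
                 E_L = E_L, E_Ca = E_Ca, E_H = E_H),
            class = "mpr_constants")
}

#' Allowed ranges of the eight free model parameters
#'
#' Lower and upper limits used both to validate candidate parameter sets and
#' as the sampling box of the evolutionary search. Conductances in uS,
#' time constants in ms, half-(in)activation voltages in mV.
#'
#' @return A numeric matrix with one row per parameter (in canonical order)
#'   and columns `low`, `high`.
#' @export
param_bounds <- function() {
  m <- rbind(
    g_L        = c(0, 0.15),
    g_H        = c(0, 0.35),
    g_Ca       = c(0, 0.35),
    tau_mH_max = c(0, 3000),
    V_half_mCa = c(-75, -30),
    tau_mCa    = c(0, 100),
    V_half_hCa = c(-75, -30),
    tau_hCa    = c(0, 1000)
  )
  colnames(m) <- c("low", "high")
  m
}

#' Names of the eight free model parameters, in canonical order
#' @return Character vector of length 8.
#' @export
param_names <- function() rownames(param_bounds())

#' Construct a validated model parameter set
#'
#' @param g_L,g_H,g_Ca maximal conductances (uS) of leak, H and Ca currents.
#' @param tau_mH_max maximal H-activation time constant (ms); the
#'   voltage-dependent time constant is `tau_mH_max` scaled by a sigmoid of V.
#' @param V_half_mCa,V_half_hCa half-activation / half-inactivation voltages
#'   (mV) of the Ca current.
#' @param tau_mCa,tau_hCa Ca activation / inactivation time constants (ms).
#' @param bounds bounds matrix as from [param_bounds()]; set to `NULL` to skip
#'   the range check.
#' @return Named numeric vector of class `"mpr_params"`.
#' @export
#' @examples
#' p <- model_params(g_L = 0.1, g_H = 0.2, g_Ca = 0.15, tau_mH_max = 2000,
#'                   V_half_mCa = -50, tau_mCa = 60, V_half_hCa = -65,
#'                   tau_hCa = 400)
model_params <- function(g_L, g_H, g_Ca, tau_mH_max, V_half_mCa, tau_mCa,
                         V_half_hCa, tau_hCa, bounds = param_bounds()) {
  p <- c(g_L = g_L, g_H = g_H, g_Ca = g_Ca, tau_mH_max = tau_mH_max,
         V_half_mCa = V_half_mCa, tau_mCa = tau_mCa,
         V_half_hCa = V_half_hCa, tau_hCa = tau_hCa)
  as_model_params(p, bounds = bounds)
}

#' Coerce a named numeric vector to a model parameter set
#' @param x named numeric vector containing all entries of [param_names()].
#' @param bounds bounds matrix, or `NULL` to skip the range check.
#' @return Named numeric vector of class `"mpr_params"`, in canonical order.
#' @export
as_model_params <- function(x, bounds = param_bounds()) {
  nm <- param_names()
  if (!all(nm %in% names(x)))
    stop("missing parameters: ", paste(setdiff(nm, names(x)), collapse = ", "))
  p <- as.numeric(x[nm]); names(p) <- nm
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (!is.null(bounds)) {
    bad <- p < bounds[, "low"] | p > bounds[, "high"]
    if (any(bad))
      stop("parameter(s) outside allowed bounds: ",
           paste(nm[bad], collapse = ", "))
  }
  structure(p, class = "mpr_params")
}

#' Population-median parameter set of the fitted PD models
#'
#' The median of each parameter across a large population of optimal models;
#' a convenient resonant reference model for examples and synthetic targets.
#' @return Object of class `"mpr_params"`.
#' @export
pd_median_params <- function() {
  model_params(g_L = 0.096, g_H = 0.164, g_Ca = 0.172, tau_mH_max = 2179,
               V_half_mCa = -51, tau_mCa = 70, V_half_hCa = -67, tau_hCa = 458)
}

#' Sigmoid steady-state activation/inactivation curve
#'
#' \eqn{x_\infty(V) = 1 / [1 + \exp((V - V_{1/2}) / k)]}. A negative slope
#' factor `k` gives a curve increasing in V (activation), a positive one a
#' decreasing curve (inactivation).
#'
#' @param V membrane voltage (mV), vectorized.
#' @param V_half half-maximum voltage (mV).
#' @param k slope factor (mV), nonzero.
#' @return Steady-state gating value(s) in (0, 1).
#' @export
#' @examples
#' gate_steady_state(-51, -51, -8) # 0.5 at the midpoint
gate_steady_state <- function(V, V_half, k) {
  if (!is.finite(k) || k == 0) stop("slope factor k must be nonzero")
  1 / (1 + exp((V - V_half) / k))
}

#' Voltage-dependent H-current activation time constant
#'
#' \eqn{\tau_{mH}(V) = \tau_{mH}^{max} / [1 + \exp((V + 110)/(-13))]}; the
#' shift and slope live in [fixed_constants()].
#'
#' @param V membrane voltage (mV), vectorized.
#' @param tau_mH_max maximal time constant (ms).
#' @param consts fixed constants, see [fixed_constants()].
#' @return Time constant(s) in ms, in (0, `tau_mH_max`).
#' @export
tau_mH_of_V <- function(V, tau_mH_max, consts = fixed_constants()) {
  stopifnot(tau_mH_max >= 0)
  tau_mH_max / (1 + exp((V + consts$tauH_shift) / consts$tauH_slope))
}

#' @export
print.mpr_params <- function(x, digits = 4, ...) {
  cat("PD clamp model parameters:\n")
  print(round(unclass(x), digits))
  invisible(x)
}
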
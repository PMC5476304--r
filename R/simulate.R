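# Precompute the voltage-dependent arrays shared by every candidate model for
# a fixed command waveform: H-gate steady state and tau scale (their midpoint
# and slopes are fixed constants) and exp(V/k) for the two Ca gates, whose
# model-specific midpoints enter later as scalar factors.
stim_precompute <- function(V, consts) {
  list(
    minfH = gate_steady_state(V, consts$V_half_mH, consts$k_mH),
    tauHscale = 1 / (1 + exp((V + consts$tauH_shift) / consts$tauH_slope)),
    expVm = exp(V / consts$k_mCa),
    expVh = exp(V / consts$k_hCa)
  )
}

# Minimal-allocation evaluation path used by the evolutionary search: returns
# only the total clamp current for a parameter vector in canonical order.
eval_current <- function(p, pre, V, dVdt, dt, consts) {
  if (is.null(names(p))) names(p) <- param_names()
  simulate_clamp_cpp(V, dVdt, dt,
                     p[["g_L"]], p[["g_H"]], p[["g_Ca"]],
                     p[["tau_mH_max"]],
                     exp(-p[["V_half_mCa"]] / consts$k_mCa), p[["tau_mCa"]],
                     exp(-p[["V_half_hCa"]] / consts$k_hCa), p[["tau_hCa"]],
                     consts$E_L, consts$E_Ca, consts$E_H, consts$C_m,
                     consts$p_Ca, consts$q_Ca, consts$p_H, consts$q_H,
                     pre$minfH, pre$tauHscale, pre$expVm, pre$expVh,
                     FALSE)$I_total
}

#' Simulate the voltage-clamp model along a command waveform
#'
#' Integrates the three gating variables (m_H, m_Ca, h_Ca) along the clamped
#' voltage with Heun's explicit trapezoidal method (the classical "modified
#' Euler" predictor-corrector) and reconstructs the clamp current
#' decomposition \eqn{I_{clamp} = I_{Cm} + I_L + I_{Ca} + I_H}. With the unit
#' system mV / ms / uS / nF all currents come out in nA. Gating variables are
#' initialized at their steady state for the first command voltage.
#'
#' The capacitive current uses the analytic derivative of the command when the
#' `dVdt` column is present (all commands generated by this package carry it),
#' and a centered finite difference otherwise.
#'
#' @param params model parameters, see [model_params()].
#' @param command a `"clamp_command"` data frame (columns `t` in ms, `V` in mV,
#'   optionally `dVdt` in mV/ms) on a uniform time grid.
#' @param consts fixed constants, see [fixed_constants()].
#' @return A data frame of class `"clamp_trace"` with columns `t`, `V`,
#'   `I_total`, `I_Cm`, `I_L`, `I_Ca`, `I_H` (nA) and the gating trajectories
#'   `m_H`, `m_Ca`, `h_Ca`. Command attributes are carried over.
#' @export
#' @examples
#' tr <- simulate_clamp(pd_median_params(), sine_voltage(1, n_cycles = 3))
#' stopifnot(max(abs(tr$I_total - (tr$I_Cm + tr$I_L + tr$I_Ca + tr$I_H))) < 1e-12)
simulate_clamp <- function(params, command, consts = fixed_constants()) {
  params <- as_model_params(params)
  t <- command$t; V <- command$V
  if (any(!is.finite(V))) stop("command voltage must be finite")
  dts <- diff(t)
  dt <- dts[1]
  if (!(dt > 0) || any(abs(dts - dt) > 1e-8 * dt))
    stop("command must be on a uniform time grid")
  dVdt <- command$dVdt
  if (is.null(dVdt)) {
    n <- length(V)
    dVdt <- c(V[2] - V[1], (V[3:n] - V[1:(n - 2)]) / 2, V[n] - V[n - 1]) / dt
  }
  tau_min <- min(params[["tau_mCa"]], params[["tau_hCa"]],
                 tau_mH_of_V(max(V), params[["tau_mH_max"]], consts))
  if (dt > tau_min / 2)
    warning("time step dt = ", dt, " ms exceeds half the smallest time ",
            "constant (", signif(tau_min, 3), " ms); integration may be inaccurate")
  pre <- stim_precompute(V, consts)
  sim <- simulate_clamp_cpp(V, dVdt, dt,
                            params[["g_L"]], params[["g_H"]], params[["g_Ca"]],
                            params[["tau_mH_max"]],
                            exp(-params[["V_half_mCa"]] / consts$k_mCa),
                            params[["tau_mCa"]],
                            exp(-params[["V_half_hCa"]] / consts$k_hCa),
                            params[["tau_hCa"]],
                            consts$E_L, consts$E_Ca, consts$E_H, consts$C_m,
                            consts$p_Ca, consts$q_Ca, consts$p_H, consts$q_H,
                            pre$minfH, pre$tauHscale, pre$expVm, pre$expVh,
                            TRUE)
  out <- data.frame(t = t, V = V, I_total = sim$I_total, I_Cm = sim$I_Cm,
                    I_L = sim$I_L, I_Ca = sim$I_Ca, I_H = sim$I_H,
                    m_H = sim$m_H, m_Ca = sim$m_Ca, h_Ca = sim$h_Ca)
  for (a in c("t_sweep_start", "config", "frequency"))
    attr(out, a) <- attr(command, a)
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  class(out) <- c("clamp_trace", "data.frame")
  out
}

#' Steady-state response to a constant-frequency sinusoidal clamp
#'
#' Convenience wrapper: simulates `n_cycles` of a sinusoidal command and flags
#' the final cycle, which is taken as the steady-state response (earlier
#' cycles carry the equilibration transient). Used to build current-phase
#' diagrams of the ionic currents.
#'
#' @inheritParams simulate_clamp
#' @inheritParams sine_voltage
#' @return A `"clamp_trace"` with attribute `final_cycle` holding the index
#'   range of the last full cycle.
#' @export
sine_probe <- function(params, f, v0 = -45, v1 = 15, n_cycles = 5, dt = 0.2,
                       consts = fixed_constants()) {
  cmd <- sine_voltage(f, v0 = v0, v1 = v1, n_cycles = n_cycles, dt = dt)
  tr <- simulate_clamp(params, cmd, consts = consts)
  period_ms <- 1000 / f
  i_end <- nrow(tr)
  i_start <- which.min(abs(tr$t - (tr$t[i_end] - period_ms)))
  attr(tr, "final_cycle") <- c(i_start, i_end)
  tr
}

#' Extract the steady-state cycle of a sinusoidal clamp trace
#'
#' @param trace a trace from [sine_probe()].
#' @return The final-cycle subset of the trace with an added `phase` column
#'   (cycle phase in \[0, 1\] = elapsed time within the cycle times frequency);
#'   the command voltage peaks at phase 0.5.
#' @export
steady_cycle <- function(trace) {
  fc <- attr(trace, "final_cycle")
  f <- attr(trace, "frequency")
  if (is.null(fc) || is.null(f)) stop("trace does not come from sine_probe()")
  out <- trace[fc[1]:fc[2], , drop = FALSE]
  ph <- (out$t - out$t[1]) * f / 1000
  # the command is v0 + v1 sin(2 pi f t): shift so the voltage peak sits at 0.5
  out$phase <- (ph + 0.25) %% 1
  out[order(out$phase), , drop = FALSE]
}
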
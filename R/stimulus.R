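#' Configuration of the logarithmic ZAP voltage-clamp command
#'
#' The command is \eqn{V(t) = v_0 + v_1 \sin(2\pi F(t))} with the logarithmic
#' sweep \eqn{F(t) = f_{lo}\, t\, (f_{hi}/f_{lo})^{t/T}} (t in seconds),
#' preceded by `n_precycles` cycles of a plain sinusoid at `f_lo` that
#' transition smoothly (continuously and with matching derivative) into the
#' sweep. The logarithmic sweep spends more time at low frequencies, which is
#' what makes the cycle-by-cycle impedance measurement well conditioned there.
#'
#' @param v0 voltage offset (mV); the command oscillates about this value.
#' @param v1 half-amplitude (mV); the command spans `v0 - v1` to `v0 + v1`.
#' @param f_lo,f_hi nominal lowest/highest swept frequencies (Hz).
#' @param T duration of the swept segment (s).
#' @param n_precycles number of equilibration sine cycles at `f_lo` preceding
#'   the sweep; they are excluded from impedance analysis.
#' @param dt sample interval (ms).
#' @return Object of class `"zap_config"`.
#' @export
#' @examples
#' cfg <- zap_config()         # -60 to -30 mV, 0.1 to 4 Hz, 130 s in total
zap_config <- function(v0 = -45, v1 = 15, f_lo = 0.1, f_hi = 4, T = 100,
                       n_precycles = 3, dt = 0.2) {
  stopifnot(f_lo > 0, f_hi > f_lo, T > 0, v1 > 0, dt > 0, n_precycles >= 0)
  structure(list(v0 = v0, v1 = v1, f_lo = f_lo, f_hi = f_hi, T = T,
                 n_precycles = n_precycles, dt = dt),
            class = "zap_config")
}

#' Re-centre a ZAP configuration on a new voltage range
#'
#' @param base base configuration.
#' @param V_low,V_high new lower/upper voltage bounds (mV), `V_high > V_low`.
#' @return A `"zap_config"` with `v0 = (V_low + V_high)/2` and
#'   `v1 = (V_high - V_low)/2`; all other fields unchanged.
#' @export
#' @examples
#' shifted_range_config(zap_config(), -70, -30) # v0 = -50, v1 = 20
shifted_range_config <- function(base, V_low, V_high) {
  stopifnot(inherits(base, "zap_config"))
  if (!(V_high > V_low)) stop("V_high must exceed V_low")
  base$v0 <- (V_low + V_high) / 2
  base$v1 <- (V_high - V_low) / 2
  base
}

# Phase argument F (in cycles) and its time derivative (in Hz) of the full
# waveform (pre-cycles + sweep), as functions of time in seconds.
zap_phase <- function(t_s, config) {
  t0 <- config$n_precycles / config$f_lo
  r <- config$f_hi / config$f_lo
  pre <- t_s <= t0
  ph <- numeric(length(t_s))
  ph[pre] <- config$f_lo * t_s[pre]
  ts <- t_s[!pre] - t0
  ph[!pre] <- config$f_lo * ts * r^(ts / config$T)
  ph
}

zap_phase_deriv <- function(t_s, config) {
  t0 <- config$n_precycles / config$f_lo
  r <- config$f_hi / config$f_lo
  pre <- t_s <= t0
  d <- numeric(length(t_s))
  d[pre] <- config$f_lo
  ts <- t_s[!pre] - t0
  d[!pre] <- config$f_lo * r^(ts / config$T) * (1 + ts * log(r) / config$T)
  d
}

#' Generate the ZAP command voltage
#'
#' @param config a [zap_config()].
#' @return A data frame of class `"clamp_command"` with columns `t` (ms),
#'   `V` (mV) and `dVdt` (mV/ms, the analytic derivative). The start time of
#'   the swept segment is stored in attribute `t_sweep_start` (ms) and the
#'   configuration in attribute `config`.
#' @export
#' @examples
#' cmd <- zap_voltage(zap_config())
#' range(cmd$V)        # -60 ... -30 mV
zap_voltage <- function(config = zap_config()) {
  stopifnot(inherits(config, "zap_config"))
  total_s <- config$n_precycles / config$f_lo + config$T
  t_ms <- seq(0, total_s * 1000, by = config$dt)
  t_s <- t_ms / 1000
  ph <- zap_phase(t_s, config)
  V <- config$v0 + config$v1 * sin(2 * pi * ph)
  dVdt <- config$v1 * 2 * pi * zap_phase_deriv(t_s, config) *
    cos(2 * pi * ph) / 1000 # mV/ms
  out <- data.frame(t = t_ms, V = V, dVdt = dVdt)
  attr(out, "t_sweep_start") <- config$n_precycles / config$f_lo * 1000
  attr(out, "config") <- config
  class(out) <- c("clamp_command", "data.frame")
  out
}

#' Analytic time derivative of the ZAP command
#'
#' @param config a [zap_config()].
#' @return Data frame with columns `t` (ms) and `dVdt` (mV/ms).
#' @export
zap_derivative <- function(config = zap_config()) {
  cmd <- zap_voltage(config)
  data.frame(t = cmd$t, dVdt = cmd$dVdt)
}

#' Generate a constant-frequency sinusoidal clamp command
#'
#' @param f frequency (Hz), positive.
#' @param v0 voltage offset (mV).
#' @param v1 half-amplitude (mV).
#' @param n_cycles number of cycles (the first cycles carry the transient;
#'   steady-state measures should use the last one).
#' @param dt sample interval (ms).
#' @return A `"clamp_command"` data frame with columns `t`, `V`, `dVdt`.
#' @export
sine_voltage <- function(f, v0 = -45, v1 = 15, n_cycles = 5, dt = 0.2) {
  if (!(f > 0)) stop("frequency must be positive")
  stopifnot(n_cycles >= 2, dt > 0, v1 > 0)
  t_ms <- seq(0, n_cycles / f * 1000, by = dt)
  t_s <- t_ms / 1000
  V <- v0 + v1 * sin(2 * pi * f * t_s)
  dVdt <- v1 * 2 * pi * f * cos(2 * pi * f * t_s) / 1000
  out <- data.frame(t = t_ms, V = V, dVdt = dVdt)
  attr(out, "frequency") <- f
  class(out) <- c("clamp_command", "data.frame")
  out
}
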
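# wrap an angle to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Delimit the oscillation cycles of a clamp command
#'
#' Cycles are delimited trough-to-trough on the command voltage; the per-cycle
#' frequency is the reciprocal of the measured cycle period. Cycles that end
#' before `exclude_before` (by default the start of the swept ZAP segment, so
#' that the equilibration pre-cycles are dropped) are excluded.
#'
#' @param x a `"clamp_command"` or `"clamp_trace"` data frame with columns
#'   `t` (ms) and `V` (mV).
#' @param exclude_before time (ms) before which cycles are discarded; defaults
#'   to the `t_sweep_start` attribute when present, else 0.
#' @return Data frame with columns `start`, `end` (row indices of consecutive
#'   troughs) and `f` (Hz).
#' @export
segment_cycles <- function(x, exclude_before = NULL) {
  t <- x$t; V <- x$V
  if (is.null(exclude_before)) {
    exclude_before <- attr(x, "t_sweep_start")
    if (is.null(exclude_before)) exclude_before <- 0
  }
  n <- length(V)
  if (n < 3) stop("too few samples to delimit cycles")
  core <- V[2:(n - 1)]
  is_trough <- core < V[1:(n - 2)] & core <= V[3:n]
  troughs <- which(is_trough) + 1L
  # collapse runs of equal samples flagged together
  if (length(troughs) > 1)
    troughs <- troughs[c(TRUE, diff(troughs) > 1)]
  if (length(troughs) < 2) stop("fewer than 3 cycles detected in command")
  start <- troughs[-length(troughs)]
  end <- troughs[-1]
  keep <- t[end] > exclude_before
  start <- start[keep]; end <- end[keep]
  if (length(start) < 3) stop("fewer than 3 cycles detected in command")
  data.frame(start = start, end = end, f = 1000 / (t[end] - t[start]))
}

#' Impedance amplitude and phase of a single cycle
#'
#' Amplitude is the ratio of the voltage and current peak-to-peak amplitudes
#' (mV / nA = MOhm). Phase is measured from the time difference between the
#' command-voltage peak and the current peak within the cycle,
#' \eqn{\varphi = 2\pi f (t_{peak I} - t_{peak V})}, wrapped to \eqn{(-\pi,\pi]}:
#' a current that peaks before the voltage (capacitive lead) has negative
#' phase.
#'
#' @param Vcycle,Icycle one full cycle of command voltage (mV) and clamp
#'   current (nA).
#' @param f cycle frequency (Hz).
#' @param t sample times (ms) of the cycle; defaults to a uniform grid, only
#'   differences matter.
#' @return Named list with `f`, `Z` (MOhm) and `phi` (rad).
#' @export
cycle_impedance <- function(Vcycle, Icycle, f, t = seq_along(Vcycle)) {
  dI <- max(Icycle) - min(Icycle)
  if (dI <= 0) stop("zero current peak-to-peak amplitude in cycle")
  Z <- (max(Vcycle) - min(Vcycle)) / dI
  tI <- refine_peak_time(Icycle, t, which.max(Icycle))
  tV <- refine_peak_time(Vcycle, t, which.max(Vcycle))
  list(f = f, Z = Z, phi = wrap_angle(2 * pi * f * (tI - tV) / 1000))
}

#' Cycle-by-cycle impedance profile of a clamp trace
#'
#' Applies [cycle_impedance()] to every retained cycle of the command and
#' returns the Z- and phi-profiles ordered by frequency. Near the end of the
#' printed logarithmic sweep the instantaneous frequency exceeds the nominal
#' ceiling; measured cycles above `f_max` are truncated so the profile covers
#' the nominal analysis band.
#'
#' @param trace a `"clamp_trace"` from [simulate_clamp()].
#' @param cycles optional precomputed cycle table from [segment_cycles()].
#' @param f_max highest retained cycle frequency (Hz); defaults to 1.15 times
#'   the configured `f_hi` (or of 4 Hz if the trace has no configuration).
#' @return Data frame of class `"impedance_profile"` with columns `f` (Hz),
#'   `Z` (MOhm), `phi` (rad), frequencies strictly increasing.
#' @export
#' @examples
#' cmd <- zap_voltage(zap_config(dt = 1))
#' tr <- simulate_clamp(pd_median_params(), cmd)
#' prof <- impedance_profile(tr)
impedance_profile <- function(trace, cycles = NULL, f_max = NULL) {
  if (is.null(cycles)) cycles <- segment_cycles(trace)
  if (is.null(f_max)) {
    cfg <- attr(trace, "config")
    f_max <- if (is.null(cfg)) 4 * 1.15 else cfg$f_hi * 1.15
  }
  prof <- profile_from_cycles(trace$V, trace$I_total, trace$t, cycles, f_max)
  class(prof) <- c("impedance_profile", "data.frame")
  attr(prof, "config") <- attr(trace, "config")
  prof
}

# Sub-sample refinement of a peak time: parabola through the sample maximum
# and its neighbours. Removes the dt quantization of peak-based phases.
refine_peak_time <- function(y, t, idx) {
  n <- length(y)
  i <- pmin(pmax(idx, 2L), n - 1L)
  d2 <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  off <- ifelse(abs(d2) > 0, 0.5 * (y[i - 1L] - y[i + 1L]) / d2, 0)
  off <- pmin(pmax(off, -1), 1)
  dt <- t[2] - t[1]
  t[i] + off * dt
}

# shared fast path: per-cycle Z and phi from precomputed cycle boundaries
profile_from_cycles <- function(V, I, t, cycles, f_max) {
  keep <- cycles$f <= f_max
  cyc <- cycles[keep, , drop = FALSE]
  sv <- cycle_stats_cpp(V, cyc$start, cyc$end)
  si <- cycle_stats_cpp(I, cyc$start, cyc$end)
  dI <- si$max - si$min
  Z <- (sv$max - sv$min) / dI
  tV <- refine_peak_time(V, t, sv$imax)
  tI <- refine_peak_time(I, t, si$imax)
  phi <- wrap_angle(2 * pi * cyc$f * (tI - tV) / 1000)
  out <- data.frame(f = cyc$f, Z = Z, phi = phi)
  out <- out[order(out$f), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vertex of the parabola through three points; falls back to the middle point
# when the curvature is not negative (degenerate discrete maximum)
quad_vertex <- function(x, y) {
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d32 - d21) / (x[3] - x[1])
  if (!is.finite(a) || a >= 0) return(c(x[2], y[2]))
  b <- d21 - a * (x[1] + x[2])
  xv <- -b / (2 * a)
  if (xv < x[1] || xv > x[3]) return(c(x[2], y[2]))
  cc <- y[1] - a * x[1]^2 - b * x[1]
  c(xv, a * xv^2 + b * xv + cc)
}

#' Scalar attributes of an impedance profile
#'
#' Reduces a Z/phi profile to the ten-point attribute description used as
#' fitting targets: on the amplitude side the impedance at the band edges
#' (`Z0` at `f0`, `Z_f1` at `f1`), the resonance peak (`f_res`, `Z_max`) with
#' resonance power `Q_Z = Z_max - Z0`, and the two half-height frequencies
#' where `Z = Z0 + Q_Z/2` whose separation is the bandwidth `Lambda_half`; on
#' the phase side the phase at `f0` and at 2 Hz, the maximal phase advance
#' (`f_phimax`, `phi_max`), the zero-phase (phasonant) frequency `f_phi0`,
#' and the maximal phase delay (`f_phimin`, `phi_min`).
#'
#' Peak locations come from a local quadratic fit around the discrete
#' extremum; crossings and fixed-frequency values from linear interpolation
#' between cycle points. A profile without an interior maximum is flagged
#' `resonant = FALSE` (then `f_res = f0`, `Q_Z = 0` and the bandwidth is
#' undefined); a profile whose phase never crosses zero downward is flagged
#' `has_phi0 = FALSE`.
#'
#' @param profile an `"impedance_profile"` data frame (`f`, `Z`, `phi`).
#' @param f0,f1 band-edge frequencies (Hz) at which `Z0`, `Z_f1`, `phi_f0`
#'   are read.
#' @param f_phi_fix fixed frequency (Hz) for the phase attribute `phi_f2`.
#' @return Object of class `"mpr_attributes"`: a named list of the scalar
#'   attributes plus the logical flags `resonant` and `has_phi0`.
#' @export
extract_attributes <- function(profile, f0 = 0.1, f1 = 4, f_phi_fix = 2) {
  f <- profile$f; Z <- profile$Z; phi <- profile$phi
  n <- length(f)
  if (n < 3) stop("profile has too few cycles")
  # Values at fixed frequencies by linear interpolation. The retained cycles
  # start slightly above f0 (the equilibration pre-cycles are excluded and
  # the sweep accelerates immediately), so f0 itself is reached by local
  # linear extrapolation from the first two cycles rather than by clamping,
  # which would read the rising flank of a resonant profile as its f0 value.
  at <- function(y, x0) {
    if (x0 < f[1])
      return(y[1] + (y[2] - y[1]) / (f[2] - f[1]) * (x0 - f[1]))
    if (x0 > f[n])
      return(y[n] + (y[n] - y[n - 1]) / (f[n] - f[n - 1]) * (x0 - f[n]))
    stats::approx(f, y, xout = x0, ties = "ordered")$y
  }
  Z0 <- at(Z, f0); Z_f1 <- at(Z, f1)
  phi_f0 <- at(phi, f0); phi_f2 <- at(phi, f_phi_fix)

  j <- which.max(Z)
  resonant <- j > 1 && j < n
  if (resonant) {
    v <- quad_vertex(f[(j - 1):(j + 1)], Z[(j - 1):(j + 1)])
    f_res <- v[1]; Z_max <- max(v[2], Z[j])
  } else {
    f_res <- f0; Z_max <- Z0
  }
  Q_Z <- max(Z_max - Z0, 0)
  Z_half <- Z0 + Q_Z / 2
  f_half_lo <- f_half_hi <- Lambda_half <- NA_real_
  if (resonant && Q_Z > 0) {
    cross <- function(i) {
      # linear interpolation of Z = Z_half between points i, i+1
      f[i] + (Z_half - Z[i]) * (f[i + 1] - f[i]) / (Z[i + 1] - Z[i])
    }
    lo <- which(Z[seq_len(j - 1)] <= Z_half & Z[2:j] > Z_half)
    if (length(lo)) f_half_lo <- cross(max(lo)) else f_half_lo <- f[1]
    hi <- which(Z[j:(n - 1)] > Z_half & Z[(j + 1):n] <= Z_half)
    if (length(hi)) f_half_hi <- cross(j + min(hi) - 1) else f_half_hi <- f[n]
    Lambda_half <- f_half_hi - f_half_lo
  }

  jmax <- which.max(phi)
  if (jmax > 1 && jmax < n) {
    v <- quad_vertex(f[(jmax - 1):(jmax + 1)], phi[(jmax - 1):(jmax + 1)])
    f_phimax <- v[1]; phi_max <- max(v[2], phi[jmax])
  } else {
    f_phimax <- f[jmax]; phi_max <- phi[jmax]
  }
  jmin <- which.min(phi)
  if (jmin > 1 && jmin < n) {
    v <- quad_vertex(f[(jmin - 1):(jmin + 1)], -phi[(jmin - 1):(jmin + 1)])
    f_phimin <- v[1]; phi_min <- min(-v[2], phi[jmin])
  } else {
    f_phimin <- f[jmin]; phi_min <- phi[jmin]
  }

  f_phi0 <- NA_real_; has_phi0 <- FALSE
  if (jmax < n) {
    idx <- which(phi[jmax:(n - 1)] > 0 & phi[(jmax + 1):n] <= 0)
    if (length(idx)) {
      i <- jmax + min(idx) - 1
      f_phi0 <- f[i] + (0 - phi[i]) * (f[i + 1] - f[i]) / (phi[i + 1] - phi[i])
      has_phi0 <- TRUE
    }
  }

  structure(list(f0 = f0, Z0 = Z0, f_res = f_res, Z_max = Z_max, Q_Z = Q_Z,
                 Z_half = Z_half, f_half_lo = f_half_lo, f_half_hi = f_half_hi,
                 Lambda_half = Lambda_half, f1 = f1, Z_f1 = Z_f1,
                 phi_f0 = phi_f0, f_phimax = f_phimax, phi_max = phi_max,
                 f_phi0 = f_phi0, f_phi_fix = f_phi_fix, phi_f2 = phi_f2,
                 f_phimin = f_phimin, phi_min = phi_min,
                 resonant = resonant, has_phi0 = has_phi0),
            class = "mpr_attributes")
}

#' The biological PD neuron target attribute set
#'
#' The ten target points measured from a representative PD neuron Z/phi
#' profile, used as the fitting objectives. Amplitude points (Hz, MOhm):
#' (0.1, 8.2), (1, 13.7) at resonance, the half-height points (0.4, 11.65)
#' and (2.5, 11.65), and (4, 9.6). Phase points (Hz, rad): (0.1, 0),
#' (0.4, 0.5) at maximal advance, (1.05, 0) at phasonance, (2, `phi_f2`) and
#' (4, -0.4) at maximal delay.
#'
#' The printed half-height points are kept literally as objective targets even
#' though they sit slightly above `Z0 + Q_Z/2` computed from the printed `Z0`
#' and `Z_max`. The printed phase value at 2 Hz is not a valid angle (its
#' magnitude exceeds pi) and is taken to be -0.25 rad by default; it can be
#' overridden.
#'
#' @param phi_f2 target phase at 2 Hz (rad).
#' @return Object of class `"mpr_attributes"`.
#' @export
pd_target <- function(phi_f2 = -0.25) {
  stopifnot(phi_f2 > -pi, phi_f2 <= pi)
  structure(list(f0 = 0.1, Z0 = 8.2, f_res = 1, Z_max = 13.7,
                 Q_Z = 13.7 - 8.2, Z_half = 11.65,
                 f_half_lo = 0.4, f_half_hi = 2.5, Lambda_half = 2.5 - 0.4,
                 f1 = 4, Z_f1 = 9.6,
                 phi_f0 = 0, f_phimax = 0.4, phi_max = 0.5,
                 f_phi0 = 1.05, f_phi_fix = 2, phi_f2 = phi_f2,
                 f_phimin = 4, phi_min = -0.4,
                 resonant = TRUE, has_phi0 = TRUE),
            class = "mpr_attributes")
}

#' @export
print.mpr_attributes <- function(x, digits = 3, ...) {
  cat("Impedance profile attributes:\n")
  num <- vapply(x, is.numeric, logical(1))
  print(round(unlist(x[num]), digits))
  if (!isTRUE(x$resonant)) cat("  [no interior impedance maximum]\n")
  if (!isTRUE(x$has_phi0)) cat("  [no phase zero crossing]\n")
  invisible(x)
}

#' Ten objective scores of an attribute set against a target
#'
#' Each objective is the Euclidean distance between a measured attribute point
#' and the corresponding target point, after normalizing each coordinate by
#' the target's scale: frequency coordinates by the target frequency, Z
#' coordinates by the target Z value, and phase coordinates by `phi_scale`
#' (the magnitude of the target's maximal phase advance). For attributes
#' pinned to a fixed frequency the objective is the normalized absolute value
#' difference. An attribute undefined on the measured profile (no resonance,
#' no phase zero crossing) receives the penalty score.
#'
#' @param attrs measured attributes ([extract_attributes()]).
#' @param target target attributes (e.g. [pd_target()]).
#' @param phi_scale normalization scale (rad) for phase coordinates.
#' @param penalty score assigned to undefined attributes.
#' @return Named numeric vector of 10 non-negative scores: `z0`, `z_res`,
#'   `z_half_lo`, `z_half_hi`, `z_f1`, `phi0`, `phi_max`, `f_phi0`, `phi_2`,
#'   `phi_min`.
#' @export
#' @examples
#' objective_vector(pd_target(), pd_target()) # all zeros
objective_vector <- function(attrs, target = pd_target(), phi_scale = 0.5,
                             penalty = 1e6) {
  a <- attrs; tg <- target
  dist2 <- function(df, dv) sqrt(df^2 + dv^2)
  ok <- function(...) all(is.finite(c(...)))
  sc <- c(
    z0 = if (ok(a$Z0)) abs(a$Z0 - tg$Z0) / tg$Z0 else penalty,
    z_res = if (isTRUE(a$resonant) && ok(a$f_res, a$Z_max))
      dist2((a$f_res - tg$f_res) / tg$f_res, (a$Z_max - tg$Z_max) / tg$Z_max)
      else penalty,
    z_half_lo = if (isTRUE(a$resonant) && ok(a$f_half_lo, a$Z_half))
      dist2((a$f_half_lo - tg$f_half_lo) / tg$f_half_lo,
            (a$Z_half - tg$Z_half) / tg$Z_half) else penalty,
    z_half_hi = if (isTRUE(a$resonant) && ok(a$f_half_hi, a$Z_half))
      dist2((a$f_half_hi - tg$f_half_hi) / tg$f_half_hi,
            (a$Z_half - tg$Z_half) / tg$Z_half) else penalty,
    z_f1 = if (ok(a$Z_f1)) abs(a$Z_f1 - tg$Z_f1) / tg$Z_f1 else penalty,
    phi0 = if (ok(a$phi_f0)) abs(a$phi_f0 - tg$phi_f0) / phi_scale else penalty,
    phi_max = if (ok(a$f_phimax, a$phi_max))
      dist2((a$f_phimax - tg$f_phimax) / tg$f_phimax,
            (a$phi_max - tg$phi_max) / phi_scale) else penalty,
    f_phi0 = if (isTRUE(a$has_phi0) && ok(a$f_phi0))
      abs(a$f_phi0 - tg$f_phi0) / tg$f_phi0 else penalty,
    phi_2 = if (ok(a$phi_f2)) abs(a$phi_f2 - tg$phi_f2) / phi_scale else penalty,
    phi_min = if (ok(a$f_phimin, a$phi_min))
      dist2((a$f_phimin - tg$f_phimin) / tg$f_phimin,
            (a$phi_min - tg$phi_min) / phi_scale) else penalty
  )
  pmin(sc, penalty)
}

#' Per-attribute acceptance errors against a target
#'
#' Relative error of every acceptance-relevant scalar attribute with respect
#' to its target value. The attribute list follows the ten-point profile
#' characterization: on the amplitude side `Z0`, the resonance peak (`f_res`
#' and `Z_max`), the two half-height frequencies and `Z(f1)`; on the phase
#' side the phase at `f0`, the phasonant frequency, the phase at 2 Hz and
#' the maximal delay `phi_min` (a value — the frequency where the delay
#' peaks is not itself an attribute). Attributes whose target is zero cannot
#' carry a relative error: the phase at the lowest frequency is reported as
#' an absolute error in rad (`phi_f0_abs`), and phasonance is assessed
#' through its frequency `f_phi0`. The maximal phase advance is excluded
#' from acceptance and does not appear here. Undefined attributes
#' (non-resonant profile, missing zero crossing) give `Inf`.
#'
#' @inheritParams objective_vector
#' @return Named numeric vector of errors: `z0`, `f_res`, `z_max`,
#'   `f_half_lo`, `f_half_hi`, `z_f1`, `phi_f0_abs`, `f_phi0`, `phi_2`,
#'   `phi_min`.
#' @export
attribute_errors <- function(attrs, target = pd_target()) {
  a <- attrs; tg <- target
  rel <- function(v, t) if (is.finite(v)) abs(v - t) / abs(t) else Inf
  c(z0 = rel(a$Z0, tg$Z0),
    f_res = if (isTRUE(a$resonant)) rel(a$f_res, tg$f_res) else Inf,
    z_max = if (isTRUE(a$resonant)) rel(a$Z_max, tg$Z_max) else Inf,
    f_half_lo = rel(a$f_half_lo, tg$f_half_lo),
    f_half_hi = rel(a$f_half_hi, tg$f_half_hi),
    z_f1 = rel(a$Z_f1, tg$Z_f1),
    phi_f0_abs = if (is.finite(a$phi_f0)) abs(a$phi_f0 - tg$phi_f0) else Inf,
    f_phi0 = if (isTRUE(a$has_phi0)) rel(a$f_phi0, tg$f_phi0) else Inf,
    phi_2 = rel(a$phi_f2, tg$phi_f2),
    phi_min = rel(a$phi_min, tg$phi_min))
}

#' Acceptance test of an attribute set against a target
#'
#' A model is accepted when every acceptance-relevant attribute lies within
#' `tol` relative error of its target (see [attribute_errors()]); the phase
#' at the lowest frequency, whose target is zero, must satisfy
#' `|phi(f0)| <= tol` rad; the maximal phase advance is excluded from
#' acceptance. The profile must be resonant and have a phase zero crossing.
#'
#' @inheritParams objective_vector
#' @param tol acceptance radius (relative error; also rad for the phase-at-f0
#'   rule). The conventional value is 0.05.
#' @param errors optional precomputed vector from [attribute_errors()].
#' @return Logical.
#' @export
is_accepted <- function(attrs, target = pd_target(), tol = 0.05,
                        errors = NULL) {
  if (!isTRUE(attrs$resonant) || !isTRUE(attrs$has_phi0)) return(FALSE)
  if (is.null(errors)) errors <- attribute_errors(attrs, target)
  all(errors <= tol)
}
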
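# Analytic oracles and shared lightweight fixtures.

# Closed-form impedance of the passive RC membrane in the package's unit
# system (mV / ms / uS / nF): omega in rad/ms, so Z in MOhm and phase in rad.
rc_impedance <- function(f_hz, g_l, c_m = 1) {
  w <- 2 * pi * f_hz * 1e-3
  list(Z = 1 / sqrt(g_l^2 + (w * c_m)^2), phi = -atan(w * c_m / g_l))
}

# A purely passive parameter set (leak only).
passive_params <- function(g_l = 0.096) {
  model_params(g_L = g_l, g_H = 0, g_Ca = 0, tau_mH_max = 1000,
               V_half_mCa = -51, tau_mCa = 70, V_half_hCa = -67,
               tau_hCa = 458)
}

# Brute-force O(n^2 d) Pareto front partition used as an oracle for
# non_dominated_sort().
brute_fronts <- function(obj) {
  n <- nrow(obj)
  left <- seq_len(n)
  fronts <- list()
  while (length(left)) {
    nd <- left[vapply(left, function(i) {
      !any(vapply(left, function(j) {
        if (i == j) return(FALSE)
        d <- obj[j, ] - obj[i, ]
        all(d <= 0) && any(d < 0)
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1]] <- nd
    left <- setdiff(left, nd)
  }
  fronts
}

# Coarse but fast ZAP configuration for unit tests that only need the
# machinery, not the full measurement resolution.
coarse_zap <- function(dt = 1) zap_config(dt = dt)
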
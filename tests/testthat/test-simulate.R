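test_that("current decomposition sums exactly and units are consistent", {
  tr <- simulate_clamp(pd_median_params(), sine_voltage(1, n_cycles = 3))
  expect_lt(max(abs(tr$I_total - (tr$I_Cm + tr$I_L + tr$I_Ca + tr$I_H))),
            1e-12)
  expect_true(all(tr$m_H >= 0 & tr$m_H <= 1))
  expect_true(all(tr$m_Ca >= 0 & tr$m_Ca <= 1))
  expect_true(all(tr$h_Ca >= 0 & tr$h_Ca <= 1))
})

test_that("passive model reproduces the analytic RC impedance", {
  # with g_Ca = g_H = 0 the membrane is a linear RC circuit; amplitude and
  # phase of the simulated impedance must match the closed form to < 1%
  cmd <- zap_voltage(zap_config())
  tr <- simulate_clamp(passive_params(0.096), cmd)
  prof <- impedance_profile(tr)
  an <- rc_impedance(prof$f, 0.096)
  expect_lt(max(abs(prof$Z - an$Z) / an$Z), 0.01)
  expect_lt(max(abs(prof$phi - an$phi)), 0.01)
})

test_that("a long constant hold settles on the steady-state current", {
  p <- pd_median_params()
  cc <- fixed_constants()
  V0 <- -40
  cmd <- data.frame(t = seq(0, 20000, by = 0.2), V = V0)
  tr <- simulate_clamp(p, cmd, consts = cc)
  minf <- gate_steady_state(V0, cc$V_half_mH, cc$k_mH)
  mca <- gate_steady_state(V0, p[["V_half_mCa"]], cc$k_mCa)
  hca <- gate_steady_state(V0, p[["V_half_hCa"]], cc$k_hCa)
  I_eq <- p[["g_L"]] * (V0 - cc$E_L) +
    p[["g_Ca"]] * mca^3 * hca * (V0 - cc$E_Ca) +
    p[["g_H"]] * minf * (V0 - cc$E_H)
  expect_equal(tail(tr$I_total, 1), I_eq, tolerance = 1e-6)
})

test_that("gating stays in [0,1] for random bounded commands", {
  set.seed(11)
  for (k in 1:5) {
    p <- as_model_params(sample_params(1)[1, ], bounds = NULL)
    f <- runif(1, 0.2, 3)
    cmd <- sine_voltage(f, v0 = runif(1, -60, -40), v1 = runif(1, 5, 20),
                        n_cycles = 3, dt = 0.5)
    tr <- suppressWarnings(simulate_clamp(p, cmd))
    expect_true(all(tr$m_H >= 0 & tr$m_H <= 1))
    expect_true(all(tr$m_Ca >= 0 & tr$m_Ca <= 1))
    expect_true(all(tr$h_Ca >= 0 & tr$h_Ca <= 1))
    expect_true(all(is.finite(tr$I_total)))
  }
})

test_that("refining the time step leaves every attribute within tolerance", {
  # validates both the halved step (0.4 -> 0.2) and the coarse fast-mode step
  # (0.5) against the reference dt = 0.2 ms
  p <- pd_median_params()
  a_ref <- extract_attributes(impedance_profile(
    simulate_clamp(p, zap_voltage(zap_config(dt = 0.2)))))
  for (dt in c(0.4, 0.5)) {
    a <- extract_attributes(impedance_profile(
      simulate_clamp(p, zap_voltage(zap_config(dt = dt)))))
    for (nm in c("Z0", "f_res", "Z_max", "Q_Z", "Z_f1", "f_half_lo",
                 "f_half_hi", "f_phi0", "f_phimin"))
      expect_lt(abs(a[[nm]] - a_ref[[nm]]) / abs(a_ref[[nm]]), 0.005)
    for (nm in c("phi_f0", "phi_max", "phi_f2", "phi_min"))
      expect_lt(abs(a[[nm]] - a_ref[[nm]]), 0.005) # rad
  }
})

test_that("a time step large relative to the gating kinetics warns", {
  p <- model_params(g_L = 0.1, g_H = 0.1, g_Ca = 0.1, tau_mH_max = 2000,
                    V_half_mCa = -50, tau_mCa = 0.3, V_half_hCa = -65,
                    tau_hCa = 400)
  expect_warning(simulate_clamp(p, sine_voltage(1, n_cycles = 2)),
                 "time step")
})

test_that("non-uniform time grids are rejected", {
  cmd <- data.frame(t = c(0, 1, 3, 4), V = -50)
  expect_error(simulate_clamp(pd_median_params(), cmd), "uniform")
})

test_that("passive sine response has capacitive lead and leak in phase", {
  p <- passive_params(0.096)
  tr <- sine_probe(p, 1, n_cycles = 4)
  cyc <- steady_cycle(tr)
  # leak tracks the voltage: peak exactly where V peaks (cycle phase 0.5)
  expect_equal(cyc$phase[which.max(cyc$I_L)], 0.5, tolerance = 0.01)
  # capacitive current = C dV/dt peaks a quarter cycle before the voltage
  expect_equal(cyc$phase[which.max(cyc$I_Cm)], 0.25, tolerance = 0.01)
  # leak current vs cycle phase is frequency independent
  cyc4 <- steady_cycle(sine_probe(p, 4, n_cycles = 4))
  il1 <- approx(cyc$phase, cyc$I_L, xout = seq(0.05, 0.95, by = 0.05),
                ties = "ordered")$y
  il4 <- approx(cyc4$phase, cyc4$I_L, xout = seq(0.05, 0.95, by = 0.05),
                ties = "ordered")$y
  expect_equal(il1, il4, tolerance = 1e-3)
})
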
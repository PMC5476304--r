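test_that("default ZAP waveform has the prescribed duration and range", {
  cmd <- zap_voltage(zap_config()) # dt = 0.2 ms
  # three 10-s pre-cycles + 100-s sweep = 130 s inclusive of both endpoints
  expect_identical(nrow(cmd), 650001L)
  expect_equal(max(cmd$t), 130000)
  expect_equal(min(cmd$V), -60, tolerance = 1e-6)
  expect_equal(max(cmd$V), -30, tolerance = 1e-6)
  # sweep onset: phase argument restarts at zero, so V = v0 there
  i0 <- which(cmd$t == attr(cmd, "t_sweep_start"))
  expect_equal(cmd$V[i0], -45, tolerance = 1e-9)
})

test_that("waveform and derivative are smooth across the junction", {
  cfg <- zap_config(dt = 0.5)
  cmd <- zap_voltage(cfg)
  n <- nrow(cmd)
  fd <- (cmd$V[3:n] - cmd$V[1:(n - 2)]) / (2 * cfg$dt)
  # analytic derivative matches a centered difference to O(dt^2) everywhere,
  # including the pre-cycle/sweep junction; the bound reflects the curvature
  # of the fastest cycles at the end of the sweep (~(2 pi f dt)^2 / 6)
  expect_lt(max(abs(cmd$dVdt[2:(n - 1)] - fd)), 2e-3 * max(abs(cmd$dVdt)))
  # left and right derivatives agree at the junction: the pre-cycle sine value
  i0 <- which(cmd$t == attr(cmd, "t_sweep_start"))
  expect_equal(cmd$dVdt[i0], 2 * pi * 0.1 * 15 / 1000, tolerance = 1e-12)
  expect_equal(cmd$dVdt[i0 + 1], cmd$dVdt[i0], tolerance = 1e-3)
  # pre-cycle derivative amplitude is that of a 0.1 Hz sine (mV/ms)
  pre <- cmd$t < attr(cmd, "t_sweep_start")
  expect_equal(max(abs(cmd$dVdt[pre])), 2 * pi * 0.1 * 15 / 1000,
               tolerance = 1e-4)
})

test_that("measured cycle frequencies increase and span the band", {
  cmd <- zap_voltage(zap_config(dt = 0.5))
  cyc <- segment_cycles(cmd)
  # within the analysis band (up to the 15% truncation margin) the measured
  # periods strictly decrease; beyond it, dt quantization of the very short
  # cycles is allowed to produce ties
  band <- cyc$f <= 4.6
  expect_true(all(diff(cyc$f[band]) > 0))
  expect_true(all(cyc$f[band] >= 0.095))
  expect_lt(min(cyc$f), 0.12) # coverage near f_lo
  expect_gt(max(cyc$f), 4)    # coverage beyond f_hi (printed chirp overshoot)
})

test_that("re-centring a configuration on a voltage range", {
  base <- zap_config()
  sh <- shifted_range_config(base, -70, -30)
  expect_equal(sh$v0, -50); expect_equal(sh$v1, 20)
  sh2 <- shifted_range_config(base, -60, -30)
  expect_equal(sh2$v0, -45); expect_equal(sh2$v1, 15)
  expect_error(shifted_range_config(base, -50, -50))
})

test_that("configuration validation rejects degenerate sweeps", {
  expect_error(zap_config(f_lo = 0))
  expect_error(zap_config(f_hi = 0.05))
  expect_error(zap_config(v1 = -1))
  expect_error(sine_voltage(0))
})
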
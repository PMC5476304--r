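test_that("cycle segmentation recovers exact sine periods", {
  cmd <- sine_voltage(1, n_cycles = 7, dt = 0.5)
  cyc <- segment_cycles(cmd, exclude_before = 0)
  expect_gte(nrow(cyc), 5)
  expect_equal(cyc$f, rep(1, nrow(cyc)), tolerance = 1e-3)
  expect_error(segment_cycles(data.frame(t = 0:100, V = -50)), "cycles")
})

test_that("single-cycle impedance matches the RC closed form", {
  p <- passive_params(0.096)
  tr <- sine_probe(p, 0.1, n_cycles = 3)
  fc <- attr(tr, "final_cycle")
  idx <- fc[1]:fc[2]
  m <- cycle_impedance(tr$V[idx], tr$I_total[idx], 0.1, tr$t[idx])
  an <- rc_impedance(0.1, 0.096)
  expect_equal(m$Z, an$Z, tolerance = 0.005)
  expect_equal(m$phi, an$phi, tolerance = 0.005)
  expect_error(cycle_impedance(rep(-50, 10), rep(1, 10), 1), "peak-to-peak")
})

test_that("capacitive lead drives the phase toward -pi/2 at high frequency", {
  p <- passive_params(0.096)
  tr <- sine_probe(p, 100, n_cycles = 4, dt = 0.01)
  fc <- attr(tr, "final_cycle")
  idx <- fc[1]:fc[2]
  m <- cycle_impedance(tr$V[idx], tr$I_total[idx], 100, tr$t[idx])
  expect_lt(m$phi, -1.4)
  expect_gt(m$phi, -pi / 2 - 0.05)
})

test_that("per-cycle amplitude is invariant to time reversal", {
  tr <- simulate_clamp(pd_median_params(), zap_voltage(coarse_zap()))
  prof <- impedance_profile(tr)
  rev_tr <- tr
  rev_tr$V <- rev(tr$V); rev_tr$I_total <- rev(tr$I_total)
  cyc <- segment_cycles(tr)
  n <- nrow(tr)
  rev_cyc <- data.frame(start = n + 1 - cyc$end, end = n + 1 - cyc$start,
                        f = cyc$f)
  prof_rev <- impedance_profile(rev_tr, cycles = rev_cyc)
  expect_equal(sort(prof_rev$Z), sort(prof$Z), tolerance = 1e-12)
})

test_that("attribute extraction recovers a known analytic peak", {
  # parabola through (1, 13.7) sampled at the measured ZAP cycle frequencies
  cmd <- zap_voltage(coarse_zap())
  f <- segment_cycles(cmd)$f
  f <- f[f <= 4.6]
  Z <- 13.7 - 5.5 * (f - 1)^2
  phi <- 0.5 - 0.5 * f # linear phase, zero crossing exactly at 1 Hz
  prof <- structure(data.frame(f = f, Z = Z, phi = phi),
                    class = c("impedance_profile", "data.frame"))
  a <- extract_attributes(prof)
  expect_true(a$resonant)
  expect_equal(a$f_res, 1, tolerance = 0.01)
  expect_equal(a$Z_max, 13.7, tolerance = 0.001)
  expect_equal(a$f_phi0, 1, tolerance = 0.01)
  # half-height frequencies: Z = Z0 + Q/2 on the parabola
  Z0 <- a$Z0
  expect_equal(a$Z_half, Z0 + a$Q_Z / 2, tolerance = 1e-9)
  expect_equal(a$f_half_lo, 1 - sqrt((13.7 - a$Z_half) / 5.5), tolerance = 0.02)
  expect_equal(a$f_half_hi, 1 + sqrt((13.7 - a$Z_half) / 5.5), tolerance = 0.02)
  expect_equal(a$Lambda_half, a$f_half_hi - a$f_half_lo)
})

test_that("a monotonically decreasing profile is flagged non-resonant", {
  f <- seq(0.1, 4.5, by = 0.1)
  prof <- structure(data.frame(f = f, Z = 10 - f, phi = -0.1 * f),
                    class = c("impedance_profile", "data.frame"))
  a <- extract_attributes(prof)
  expect_false(a$resonant)
  expect_equal(a$Q_Z, 0)
  expect_equal(a$f_res, 0.1)
  expect_true(is.na(a$Lambda_half))
})

test_that("objective scores are zero at the target and scale as constructed", {
  tg <- pd_target()
  expect_equal(unname(objective_vector(tg, tg)), rep(0, 10))
  a <- tg
  a$Z_max <- 1.05 * tg$Z_max
  sc <- objective_vector(a, tg)
  expect_equal(unname(sc["z_res"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(sc[names(sc) != "z_res"]), rep(0, 9))
  # undefined attributes draw the penalty
  b <- tg; b$resonant <- FALSE
  expect_equal(unname(objective_vector(b, tg)["z_res"]), 1e6)
})

test_that("acceptance demands every relevant attribute within tolerance", {
  tg <- pd_target()
  expect_true(is_accepted(tg, tg))
  a <- tg; a$Z_f1 <- tg$Z_f1 * 1.06
  expect_false(is_accepted(a, tg)) # one attribute at 6% error is rejected
  a <- tg; a$Z_f1 <- tg$Z_f1 * 1.04
  expect_true(is_accepted(a, tg))
  # the maximal phase advance is exempt from acceptance
  a <- tg; a$phi_max <- 2 * tg$phi_max
  expect_true(is_accepted(a, tg))
  # phase at f0 is judged in absolute radians
  a <- tg; a$phi_f0 <- 0.04
  expect_true(is_accepted(a, tg))
  a$phi_f0 <- 0.06
  expect_false(is_accepted(a, tg))
  # losing resonance or phasonance is disqualifying
  a <- tg; a$resonant <- FALSE
  expect_false(is_accepted(a, tg))
})

test_that("dominance relations survive the objective construction", {
  tg <- pd_target()
  worse <- tg; worse$Z0 <- tg$Z0 * 1.1; worse$Z_f1 <- tg$Z_f1 * 1.1
  mid <- tg; mid$Z0 <- tg$Z0 * 1.05
  obj <- rbind(objective_vector(tg, tg), objective_vector(mid, tg),
               objective_vector(worse, tg))
  nds <- non_dominated_sort(obj)
  expect_equal(nds$rank, c(1, 2, 3))
})
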
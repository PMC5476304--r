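# Synthetic attribute closures: sensitivity machinery must recover known
# exponents exactly, independent of the simulation pipeline.
power_attr <- function(param, expo, c0 = 3) {
  function(params) c0 * params[[param]]^expo
}

test_that("1D sensitivity recovers power-law exponents exactly", {
  p <- pd_median_params()
  s1 <- sensitivity_1d(p, "g_Ca", power_attr("g_Ca", 1))
  expect_equal(s1$slope, 1, tolerance = 1e-6)
  expect_gte(s1$r_squared, 0.98)
  s2 <- sensitivity_1d(p, "tau_mCa", power_attr("tau_mCa", 2, c0 = 0.01))
  expect_equal(s2$slope, 2, tolerance = 0.01)
  s3 <- sensitivity_1d(p, "tau_hCa", power_attr("tau_hCa", -1.5))
  expect_equal(s3$slope, -1.5, tolerance = 0.01)
})

test_that("the multiplicative step schedule starts at 0.001 and grows by 1.15", {
  p <- pd_median_params()
  s <- sensitivity_1d(p, "g_Ca", power_attr("g_Ca", 1))
  dps <- sort(unique(round(abs(s$points$dp[s$points$dp != 0]), 10)))
  expect_equal(dps[1], 0.001, tolerance = 1e-9)
  expect_equal(dps[2], 0.00115, tolerance = 1e-9)
  expect_equal(dps[3], 0.001 * 1.15^2, tolerance = 1e-9)
})

test_that("additive voltage midpoints move in 0.5 mV increments", {
  p <- pd_median_params()
  s <- sensitivity_1d(p, "V_half_mCa", function(q) exp(0.1 * (q[["V_half_mCa"]] + 51)))
  # log-attribute change per mV is exactly 0.1
  expect_equal(s$slope, 0.1, tolerance = 1e-9)
  steps <- sort(unique(abs(s$points$dp[s$points$dp != 0])))
  expect_equal(steps[1:2], c(0.5, 1.0))
})

test_that("expansion stops when the response stops being linear", {
  p <- pd_median_params()
  p0 <- p[["g_Ca"]]
  kinked <- function(q) {
    x <- q[["g_Ca"]] / p0
    # linear in log until +-2%, then strongly curved
    exp(log(x) + ifelse(abs(log(x)) > 0.02, 40 * (abs(log(x)) - 0.02)^2, 0))
  }
  s <- sensitivity_1d(p, "g_Ca", kinked)
  expect_gte(s$r_squared, 0.98)
  expect_equal(s$slope, 1, tolerance = 0.05)
  expect_lt(max(abs(s$points$dp)), 0.2) # did not run to the schedule cap
})

test_that("degenerate baselines are rejected", {
  p <- pd_median_params()
  expect_error(sensitivity_1d(p, "g_Ca", function(q) NA_real_), "baseline")
  p0 <- p; p0[["g_Ca"]] <- 0
  expect_error(sensitivity_1d(p0, "g_Ca", power_attr("g_Ca", 1)), "zero")
})

test_that("correlation lines: slope 1 yields perpendicular slope -1", {
  set.seed(41)
  u <- runif(80, 0.05, 0.15)
  pop <- as.data.frame(sample_params(80))
  pop$g_Ca <- u
  pop$g_H <- u # identical values: median-normalized slope exactly 1
  fam <- correlation_line_family(pop, c("g_Ca", "g_H"), n_models = 10,
                                 require_significant = FALSE)
  expect_equal(fam$slope, 1, tolerance = 1e-9)
  # all sampled parallel lines share the fitted slope by construction;
  # the perpendicular in normalized space is the negative reciprocal
  expect_equal(-1 / fam$slope, -1)
})

test_that("an uncorrelated pair fails the line-family guard", {
  set.seed(42)
  pop <- as.data.frame(sample_params(100))
  expect_error(correlation_line_family(pop, c("g_L", "tau_hCa"),
                                       n_models = 5, n_perms = 400),
               "not significantly correlated")
})

test_that("an attribute invariant along the correlation line has zero parallel slope", {
  set.seed(43)
  u <- seq(0.05, 0.15, length.out = 101) # symmetric: median exactly 0.1
  pop <- as.data.frame(sample_params(101))
  pop$g_Ca <- u
  pop$g_H <- 0.2 - u # negative covariation, equal medians -> slope -1
  fam <- correlation_line_family(pop, c("g_Ca", "g_H"), n_models = 5,
                                 require_significant = FALSE)
  expect_equal(fam$slope, -1, tolerance = 1e-9)
  sum_attr <- function(q) q[["g_Ca"]] + q[["g_H"]] + 1
  p <- as_model_params(pop[3, param_names()], bounds = NULL)
  s_par <- sensitivity_2d(p, fam, sum_attr, "parallel")
  expect_lt(abs(s_par$slope), 1e-6)
  # perpendicular movement changes the sum: d(log a)/d(log p1) = 2 p1 / a
  s_per <- sensitivity_2d(p, fam, sum_attr, "perpendicular")
  expect_equal(s_per$slope, 2 * p[["g_Ca"]] / sum_attr(p), tolerance = 0.1)
})

test_that("2D machinery reduces to 1D when the line is axis-aligned", {
  fam <- structure(list(pair = c("g_Ca", "g_H"), slope = 0, scale = c(1, 1),
                        models = NULL, R = 1), class = "mpr_line_family")
  p <- pd_median_params()
  s2 <- sensitivity_2d(p, fam, power_attr("g_Ca", 2, c0 = 5), "parallel")
  s1 <- sensitivity_1d(p, "g_Ca", power_attr("g_Ca", 2, c0 = 5))
  expect_equal(s2$slope, s1$slope, tolerance = 1e-9)
})
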
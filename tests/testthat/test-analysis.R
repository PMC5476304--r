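make_pop <- function(n = 60, seed = 31) {
  set.seed(seed)
  as.data.frame(sample_params(n))
}

test_that("a perfect linear relation gives R = 1 and tiny permutation p", {
  pop <- make_pop()
  pop$g_H <- 2 * pop$g_L
  set.seed(1)
  r <- pearson_permutation(pop, "g_L", "g_H", n_subsets = 50, n_perms = 200)
  expect_equal(r$R, 1, tolerance = 1e-12)
  expect_lt(r$p_perm, 0.01)
  expect_equal(r$pct_significant, 100)
  expect_equal(r$slope, 2, tolerance = 1e-12)
})

test_that("permutation p-values are valid under the null", {
  set.seed(2)
  reps <- 200
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    pop <- data.frame(g_L = runif(20), g_H = runif(20))
    r <- pearson_permutation(pop, "g_L", "g_H", subset_size = 20,
                             n_subsets = 0, n_perms = 200)
    p[i] <- r$p_perm
  }
  # P(p <= alpha) ~ alpha for a valid test (binomial tolerance)
  expect_lt(mean(p <= 0.05), 0.11)
  expect_gt(mean(p <= 0.5), 0.35)
  expect_lt(mean(p <= 0.5), 0.65)
})

test_that("permutation p agrees with the analytic t-test for Gaussian data", {
  set.seed(3)
  n <- 80
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  pop <- data.frame(g_L = x, g_H = y)
  r <- pearson_permutation(pop, "g_L", "g_H", n_subsets = 0, n_perms = 4000)
  p_t <- cor.test(x, y)$p.value
  expect_lt(abs(r$p_perm - p_t), 0.03)
})

test_that("zero-variance parameters are flagged, not silently correlated", {
  pop <- make_pop()
  pop$g_Ca <- 0.1
  expect_error(pearson_permutation(pop, "g_L", "g_Ca", n_subsets = 0),
               "zero-variance")
  expect_error(pearson_permutation(make_pop(10), "g_L", "g_H",
                                   subset_size = 20), "smaller")
})

test_that("g_Ca partition is exhaustive, disjoint and uses the tie rule", {
  pop <- make_pop()
  pop$g_Ca[1] <- 0.04   # below threshold
  pop$g_Ca[2] <- 0.172  # population median of the fitted models
  pop$g_Ca[3] <- 0.05   # boundary
  lab <- partition_gca(pop)
  expect_identical(as.character(lab$group[1]), "low")
  expect_identical(as.character(lab$group[2]), "high")
  expect_identical(as.character(lab$group[3]), "high")
  expect_false(any(is.na(lab$group)))
  expect_warning(partition_gca(transform(pop, g_Ca = g_Ca + 1)), "empty")
})

test_that("correlation p matrix carries groups in separate triangles", {
  pop <- make_pop(80)
  pop$g_H <- 2 * pop$g_L + rnorm(80, 0, 1e-3) # strong in both groups
  pop <- partition_gca(pop)
  set.seed(4)
  m <- correlation_p_matrix(pop, n_perms = 200)
  expect_true(is.na(m["g_L", "g_L"]))
  expect_lt(m["g_H", "g_L"], 0.05) # lower triangle: low group
  expect_lt(m["g_L", "g_H"], 0.05) # upper triangle: high group
})

test_that("a passive model is flagged in the voltage-floor comparison", {
  pop <- as.data.frame(t(unclass(passive_params(0.096))))
  sh <- vlow_shift(pop, zap = coarse_zap())
  expect_false(sh$ok[1])
})

test_that("the intermediate filter keeps self-consistent shifts only", {
  p <- pd_median_params()
  pop <- as.data.frame(t(unclass(p)))
  sh <- vlow_shift(pop, zap = coarse_zap())
  expect_true(sh$ok[1])
  # a target manufactured from the model's own response at the lowered range
  tg <- pd_target()
  tg$Z_max <- sh$Z_max_new
  tg$f_res <- sh$f_res_new + 0.24
  kept <- intermediate_filter(pop, target = tg, zap = coarse_zap())
  expect_equal(nrow(kept), 1)
  # a 30% mismatch in the expected peak impedance excludes the model
  tg$Z_max <- sh$Z_max_new * 1.3
  expect_warning(kept2 <- intermediate_filter(pop, target = tg,
                                              zap = coarse_zap()))
  expect_equal(nrow(kept2), 0)
})
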
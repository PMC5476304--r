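test_that("non-dominated sorting matches hand and brute-force oracles", {
  obj <- rbind(c(1, 1), c(1, 2), c(2, 2))
  nds <- non_dominated_sort(obj)
  expect_equal(nds$fronts, list(1L, 2L, 3L))
  # identical vectors form a single front
  same <- matrix(1, nrow = 4, ncol = 3)
  expect_equal(non_dominated_sort(same)$rank, rep(1L, 4))
  # random instances against the O(n^2 d) oracle
  set.seed(5)
  for (k in 1:3) {
    obj <- matrix(sample(1:5, 50 * 10, replace = TRUE), nrow = 50)
    got <- non_dominated_sort(obj)$fronts
    want <- brute_fronts(obj)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("crowding distance rewards boundary and spread", {
  expect_equal(crowding_distance(rbind(c(1, 1), c(2, 2))), c(Inf, Inf))
  # three evenly spaced collinear points: the middle one spans one full
  # normalized gap per objective
  cd <- crowding_distance(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(cd[2], 2)
  expect_true(all(is.infinite(cd[c(1, 3)])))
  # duplicated objective values must not divide by zero
  cd2 <- crowding_distance(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(is.finite(cd2) | is.infinite(cd2)))
  expect_true(all(cd2 >= 0))
})

test_that("SBX keeps children in bounds and preserves the parent mean", {
  b <- param_bounds()
  # interior parents: away from the bounds so clipping never interferes with
  # the mean-preservation identity c1 + c2 = p1 + p2
  p1 <- as_model_params(b[, "low"] + 0.25 * (b[, "high"] - b[, "low"]),
                        bounds = NULL)
  p2 <- as_model_params(b[, "low"] + 0.60 * (b[, "high"] - b[, "low"]),
                        bounds = NULL)
  # identical parents are a fixed point
  set.seed(4)
  kids <- sbx_crossover(p1, p1, bounds = b)
  expect_equal(as.numeric(kids[[1]]), as.numeric(p1))
  expect_equal(as.numeric(kids[[2]]), as.numeric(p1))
  # eta -> infinity concentrates children on the parents
  set.seed(4)
  kids <- sbx_crossover(p1, p2, eta = 1e9, bounds = b, p_pair = 1, p_gene = 1)
  expect_equal(unclass(kids[[1]]), unclass(p1), tolerance = 1e-6)
  # Monte-Carlo: per-gene child mean equals parent mean within 3 SE
  set.seed(6)
  n <- 4000
  devs <- matrix(0, nrow = n, ncol = length(p1))
  for (i in seq_len(n)) {
    k <- sbx_crossover(p1, p2, bounds = b, p_pair = 1, p_gene = 1)
    devs[i, ] <- (k[[1]] + k[[2]]) / 2 - (p1 + p2) / 2
  }
  se <- apply(devs, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(devs)) <= 3 * pmax(se, 1e-12)))
  # in-bounds after clipping
  expect_true(all(k[[1]] >= b[, "low"] & k[[1]] <= b[, "high"]))
})

test_that("polynomial mutation respects bounds, rate 0 and symmetry", {
  b <- param_bounds()
  p <- as_model_params(sample_params(1)[1, ], bounds = NULL)
  expect_identical(polynomial_mutation(p, rate = 0, bounds = b), p)
  # a gene on its lower bound can only move inward
  p0 <- p; p0[["g_Ca"]] <- 0
  set.seed(8)
  moved <- replicate(500, polynomial_mutation(p0, rate = 1, bounds = b)[["g_Ca"]])
  expect_true(all(moved >= 0))
  expect_gt(max(moved), 0)
  # perturbations of a centered gene are symmetric about zero
  pc <- p; pc[["V_half_mCa"]] <- mean(b["V_half_mCa", ])
  set.seed(9)
  d <- replicate(4000, polynomial_mutation(pc, rate = 1,
                                           bounds = b)[["V_half_mCa"]]) -
    pc[["V_half_mCa"]]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("evolution is deterministic given the seed and honours gens = 0", {
  zap <- zap_config(dt = 2)
  set.seed(21)
  e1 <- nsga2_evolve(pop_size = 8, generations = 2, zap = zap)
  set.seed(21)
  e2 <- nsga2_evolve(pop_size = 8, generations = 2, zap = zap)
  expect_identical(e1$params, e2$params)
  expect_identical(e1$objectives, e2$objectives)
  set.seed(22)
  e0 <- nsga2_evolve(pop_size = 8, generations = 0, zap = zap)
  expect_equal(nrow(e0$params), 8)
  expect_true(all(is.finite(e0$objectives)))
})

test_that("elitism: per-objective best scores never increase", {
  zap <- zap_config(dt = 2)
  set.seed(23)
  ev <- nsga2_evolve(pop_size = 20, generations = 15, zap = zap)
  mins <- ev$objective_minima
  expect_true(all(diff(mins) <= 1e-12))
})

test_that("failed simulations receive penalty scores but stay in the pool", {
  # a collapsed g_L bound with zero conductances everywhere yields flat
  # current profiles whose attributes are undefined -> penalties, not errors
  b <- param_bounds()
  b["g_L", ] <- c(0, 1e-9); b["g_H", ] <- c(0, 1e-9); b["g_Ca", ] <- c(0, 1e-9)
  set.seed(24)
  ev <- nsga2_evolve(pop_size = 4, generations = 1, bounds = b,
                     zap = zap_config(dt = 2))
  expect_equal(nrow(ev$params), 4)
  expect_true(all(is.finite(ev$objectives)))
})

test_that("the acceptance filter keeps exact matches and deduplicates", {
  zap <- zap_config(dt = 2)
  set.seed(25)
  ev <- nsga2_evolve(pop_size = 8, generations = 1, zap = zap)
  # force one individual's stored errors to zero: it must be kept
  ev$attributes[1, grep("^err_", names(ev$attributes))] <- 0
  ev$attributes[1, c("resonant", "has_phi0")] <- 1
  # duplicate it
  ev$params[2, ] <- ev$params[1, ]
  ev$attributes[2, ] <- ev$attributes[1, ]
  out <- suppressWarnings(filter_optimal(ev))
  expect_equal(nrow(out), 1)
  # a 6% error on a single attribute is rejected
  ev$attributes[1, "err_z_f1"] <- 0.06
  out2 <- suppressWarnings(filter_optimal(ev))
  expect_equal(nrow(out2), 1) # only the duplicate row (errors all zero)
})
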
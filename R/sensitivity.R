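# Which parameters vary multiplicatively (conductances, time constants) and
# which additively (voltage midpoints)?
is_multiplicative <- function(param) {
  !param %in% c("V_half_mCa", "V_half_hCa")
}

#' Build an attribute-evaluation closure for sensitivity analysis
#'
#' Returns a function mapping a parameter vector to one scalar impedance
#' attribute (typically `f_res` or `Q_Z`), evaluated through the full ZAP
#' simulation pipeline with the stimulus precomputed once.
#'
#' @param attribute name of the attribute scalar to return.
#' @param zap ZAP configuration.
#' @param consts fixed constants.
#' @return Function `f(params) -> numeric(1)` (NA when the attribute is
#'   undefined for the parameter set).
#' @export
make_attr_fn <- function(attribute = "f_res", zap = zap_config(),
                         consts = fixed_constants()) {
  ev <- make_evaluator(pd_target(), zap, consts)
  function(params) {
    row <- ev(params)$row
    if (attribute %in% c("f_res", "Z_max", "Q_Z", "Lambda_half") &&
        !isTRUE(row[["resonant"]] > 0)) return(NA_real_)
    unname(row[[attribute]])
  }
}

# The step schedule: multiplicative parameters move on a log scale with
# geometrically growing offsets 0.001 * 1.15^n; additive voltage midpoints
# move in 0.5 mV increments.
step_value <- function(p0, param, n, sign) {
  if (is_multiplicative(param)) p0 * exp(sign * 0.001 * 1.15^n)
  else p0 + sign * 0.5 * (n + 1)
}

# Relative change used in the regression. Multiplicative parameters and the
# (positive) attributes are compared on the log scale, log(value / baseline),
# so that a pure power law has a constant slope equal to its exponent and a
# slope of 1 means a 2-fold parameter change doubles the attribute; for small
# changes this is the ordinary fractional change. Additive voltage midpoints
# enter as plain differences in mV.
rel_param_change <- function(p, p0, param) {
  if (is_multiplicative(param)) log(p / p0) else p - p0
}

#' One-dimensional sensitivity of an impedance attribute to a parameter
#'
#' Starting from a baseline model, the parameter is stepped away from its
#' value in both directions — multiplicative parameters on a log scale with
#' geometrically growing offsets (first offsets 0.001, 0.00115, ...),
#' additive voltage midpoints in 0.5 mV increments — and the relative change
#' of the attribute is regressed on the relative parameter change (for
#' additive parameters, on the change in mV). Points are added until the
#' linear fit's R-squared drops below `r2_min` or until a bound / step cap
#' is hit; the sensitivity is the slope of the final fit, whose retained
#' points all satisfy the R-squared rule.
#'
#' A sensitivity of 1 means a given fractional parameter change produces the
#' same fractional attribute change.
#'
#' @param params baseline parameter set (attribute must be defined there).
#' @param param name of the parameter to vary.
#' @param attr_fn function mapping a parameter vector to the scalar
#'   attribute, e.g. from [make_attr_fn()].
#' @param r2_min minimum R-squared of the linear fit.
#' @param max_steps cap on the number of step indices explored per side.
#' @param bounds bounds matrix; exploration never leaves it.
#' @return Object of class `"mpr_sensitivity"`: list with `param`,
#'   `attribute` (as named by `attr_fn`, informational), `slope`,
#'   `r_squared`, `n_points`, `direction = "single"`, and the explored
#'   `points` data frame.
#' @export
sensitivity_1d <- function(params, param, attr_fn, r2_min = 0.98,
                           max_steps = 40, bounds = param_bounds()) {
  params <- as_model_params(params, bounds = NULL)
  p0 <- params[[param]]
  if (is_multiplicative(param) && p0 == 0)
    stop("multiplicative parameter is zero at baseline")
  a0 <- attr_fn(params)
  if (!is.finite(a0) || a0 <= 0) stop("attribute undefined at baseline")
  eval_at <- function(p) {
    q <- params; q[[param]] <- p
    attr_fn(q)
  }
  sens_expand(p0, a0, param, eval_at, r2_min, max_steps, bounds[param, ],
              direction = "single")
}

# shared expansion loop for 1D and 2D sensitivity: explore steps n = 0, 1,
# ... on both sides, growing the fit until R^2 falls below r2_min
sens_expand <- function(p0, a0, param, eval_at, r2_min, max_steps, bnd,
                        direction) {
  pts <- data.frame(dp = 0, da = 0) # origin
  fit_ok <- NULL
  for (n in 0:max_steps) {
    added <- FALSE
    for (sgn in c(-1, 1)) {
      p <- step_value(p0, param, n, sgn)
      if (p < bnd[["low"]] || p > bnd[["high"]]) next
      a <- eval_at(p)
      if (!is.finite(a) || a <= 0) next
      pts <- rbind(pts, data.frame(dp = rel_param_change(p, p0, param),
                                   da = log(a / a0)))
      added <- TRUE
    }
    if (!added && n > 0) break
    if (nrow(pts) >= 3) {
      fit <- stats::lm(da ~ dp, data = pts)
      # near-exact fits trip summary.lm's reliability warning; R^2 is still valid
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (!is.finite(r2)) r2 <- 1 # attribute numerically flat at tiny steps
      if (r2 < r2_min) break
      fit_ok <- list(slope = unname(stats::coef(fit)[2]), r2 = r2,
                     pts = pts)
    }
  }
  if (is.null(fit_ok)) stop("fewer than 3 valid points for the sensitivity fit")
  structure(list(param = param, slope = fit_ok$slope,
                 r_squared = fit_ok$r2, n_points = nrow(fit_ok$pts),
                 direction = direction, points = fit_ok$pts),
            class = "mpr_sensitivity")
}

#' @export
print.mpr_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity (%s) to %s: slope = %.4g (R^2 = %.4f, %d points)\n",
              x$direction, paste(x$param, collapse = "-"), x$slope,
              x$r_squared, x$n_points))
  invisible(x)
}

#' Families of lines parallel and perpendicular to a parameter correlation
#'
#' Fits a line through the population's values of a correlated parameter
#' pair and shifts it through `n_models` randomly sampled models, giving a
#' family of parallel lines; each sampled model also gets the perpendicular
#' line through its point. Because the two parameters may carry different
#' units, the fit and the perpendicular are taken in a normalized space:
#' multiplicative parameters are divided by their population median,
#' additive voltage midpoints enter in raw mV.
#'
#' @param pop population data frame (e.g. accepted models, possibly
#'   restricted to one g_Ca group).
#' @param pair character vector of the two parameter names (p1 drives, p2
#'   follows the line).
#' @param n_models number of models sampled (without replacement when
#'   possible).
#' @param require_significant abort unless the pair is significantly
#'   correlated in the population (permutation p < 0.05).
#' @param n_perms permutations for the significance guard.
#' @return Object of class `"mpr_line_family"`: list with `pair`, `slope`
#'   (fitted, in normalized space), `scale` (normalization divisors),
#'   `models` (sampled parameter rows), `R` of the pooled correlation.
#' @export
correlation_line_family <- function(pop, pair, n_models = 50,
                                    require_significant = TRUE,
                                    n_perms = 1000) {
  pop <- as_population(pop)
  x <- pop[[pair[1]]]; y <- pop[[pair[2]]]
  if (require_significant) {
    r <- pearson_permutation(pop, pair[1], pair[2], n_subsets = 0,
                             n_perms = n_perms)
    if (r$p_perm >= 0.05)
      stop("parameter pair is not significantly correlated (permutation p = ",
           signif(r$p_perm, 3), ")")
    R <- r$R
  } else R <- stats::cor(x, y)
  sx <- if (is_multiplicative(pair[1])) abs(stats::median(x)) else 1
  sy <- if (is_multiplicative(pair[2])) abs(stats::median(y)) else 1
  if (sx == 0 || sy == 0) stop("degenerate normalization (zero median)")
  fit <- stats::lm(I(y / sy) ~ I(x / sx))
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || abs(b) < 1e-12)
    stop("degenerate correlation line (flat or vertical fit)")
  idx <- sample.int(nrow(pop), min(n_models, nrow(pop)))
  structure(list(pair = pair, slope = b, scale = c(sx, sy),
                 models = pop[idx, , drop = FALSE], R = R),
            class = "mpr_line_family")
}

#' Two-dimensional sensitivity along a correlation line
#'
#' Co-varies a correlated parameter pair along a line through the baseline
#' model — either parallel to the population correlation line or
#' perpendicular to it (in the normalized space of
#' [correlation_line_family()]) — and regresses the relative attribute
#' change on the relative change of the driving parameter `p1`, with the 1D
#' step schedule and the same R-squared expansion rule. Steps where either
#' parameter would leave its bounds are truncated.
#'
#' @param params baseline parameter set (one sampled model).
#' @param family an `"mpr_line_family"` for the pair.
#' @param attr_fn attribute closure from [make_attr_fn()].
#' @param direction `"parallel"` or `"perpendicular"`.
#' @inheritParams sensitivity_1d
#' @return An `"mpr_sensitivity"` with `direction` set accordingly.
#' @export
sensitivity_2d <- function(params, family, attr_fn,
                           direction = c("parallel", "perpendicular"),
                           r2_min = 0.98, max_steps = 40,
                           bounds = param_bounds()) {
  direction <- match.arg(direction)
  params <- as_model_params(params, bounds = NULL)
  pair <- family$pair
  sx <- family$scale[1]; sy <- family$scale[2]
  b <- if (direction == "parallel") family$slope else -1 / family$slope
  p10 <- params[[pair[1]]]; p20 <- params[[pair[2]]]
  a0 <- attr_fn(params)
  if (!is.finite(a0) || a0 <= 0) stop("attribute undefined at baseline")
  if (is_multiplicative(pair[1]) && p10 == 0)
    stop("driving parameter is zero at baseline")
  b2 <- bounds[pair[2], ]
  eval_at <- function(p1) {
    # follow the line in normalized space: y/sy = y0/sy + b (x/sx - x0/sx)
    p2 <- (p20 / sy + b * (p1 - p10) / sx) * sy
    if (p2 < b2[["low"]] || p2 > b2[["high"]]) return(NA_real_)
    q <- params; q[[pair[1]]] <- p1; q[[pair[2]]] <- p2
    attr_fn(q)
  }
  out <- sens_expand(p10, a0, pair[1], eval_at, r2_min, max_steps,
                     bounds[pair[1], ], direction = direction)
  out$param <- pair
  out
}

#' Paired parallel-versus-perpendicular sensitivity comparison
#'
#' For each sampled model of a line family, computes the 2D sensitivity of
#' an attribute along the parallel and the perpendicular line and compares
#' the slope magnitudes with a paired Wilcoxon signed-rank test. A
#' correlation line that preserves the attribute shows systematically
#' smaller parallel than perpendicular slope magnitudes.
#'
#' @param family an `"mpr_line_family"`.
#' @param attr_fn attribute closure from [make_attr_fn()].
#' @inheritParams sensitivity_1d
#' @return List with `slopes` (data frame of per-model parallel /
#'   perpendicular slopes), `median_parallel`, `median_perpendicular`, and
#'   `p_wilcoxon` for |parallel| < |perpendicular|.
#' @export
compare_line_sensitivity <- function(family, attr_fn, r2_min = 0.98,
                                     max_steps = 40,
                                     bounds = param_bounds()) {
  models <- family$models
  rows <- lapply(seq_len(nrow(models)), function(i) {
    p <- as_model_params(models[i, ], bounds = NULL)
    par_s <- tryCatch(sensitivity_2d(p, family, attr_fn, "parallel",
                                     r2_min, max_steps, bounds)$slope,
                      error = function(e) NA_real_)
    per_s <- tryCatch(sensitivity_2d(p, family, attr_fn, "perpendicular",
                                     r2_min, max_steps, bounds)$slope,
                      error = function(e) NA_real_)
    c(parallel = par_s, perpendicular = per_s)
  })
  sl <- as.data.frame(do.call(rbind, rows))
  ok <- stats::complete.cases(sl)
  sl <- sl[ok, , drop = FALSE]
  if (nrow(sl) < 3) stop("too few models with valid sensitivities")
  pw <- stats::wilcox.test(abs(sl$parallel), abs(sl$perpendicular),
                           paired = TRUE, alternative = "less",
                           exact = FALSE)$p.value
  list(slopes = sl,
       median_parallel = stats::median(sl$parallel),
       median_perpendicular = stats::median(sl$perpendicular),
       p_wilcoxon = pw)
}
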
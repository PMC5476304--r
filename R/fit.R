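#' Fit a population of conductance-based clamp models to a resonance target
#'
#' The central fitting function of the package. Runs the NSGA-II
#' multi-objective search ([nsga2_evolve()]) `n_runs` times with distinct
#' seeds, pools the final populations, and keeps the accepted models — those
#' whose every acceptance-relevant impedance attribute lies within
#' `tolerance` of the target ([filter_optimal()]). The result describes the
#' family of parameter combinations compatible with the target Z- and
#' phi-profiles, not a single best model.
#'
#' @param target target attribute set; by default the representative PD
#'   neuron target [pd_target()]. Pass the `target` element of a
#'   [make_target()] object for synthetic parameter-recovery problems.
#' @param n_runs number of independent NSGA-II runs pooled.
#' @param pop_size population size per run.
#' @param generations generations per run.
#' @param tolerance acceptance radius on the attribute errors.
#' @param seed integer seed; run `k` uses `seed + k - 1`.
#' @inheritParams nsga2_evolve
#' @param ... further arguments passed to [nsga2_evolve()]
#'   (`eta_crossover`, `eta_mutation`, `p_crossover`, `mutation_rate`,
#'   `penalty`, `trace_every`).
#' @return Object of class `"mpr_fit"`: a list with `population` (all pooled
#'   final individuals), `optimal` (the accepted subset, one row per model),
#'   `target`, `runs` (the individual `"mpr_evolution"` objects), and the
#'   configuration. Methods: [print.mpr_fit()], [summary.mpr_fit()],
#'   [coef.mpr_fit()], [plot.mpr_fit()], [predict.mpr_fit()],
#'   [residuals.mpr_fit()].
#' @export
#' @examples
#' \donttest{
#' fit <- mpr_fit(pop_size = 20, generations = 10, n_runs = 1,
#'                zap = zap_config(dt = 1), seed = 1)
#' print(fit)
#' }
mpr_fit <- function(target = pd_target(), n_runs = 3, pop_size = 100,
                    generations = 200, tolerance = 0.05, seed = 1,
                    bounds = param_bounds(), zap = zap_config(),
                    consts = fixed_constants(), ...) {
  stopifnot(n_runs >= 1)
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(seed + k - 1L)
    runs[[k]] <- nsga2_evolve(target = target, pop_size = pop_size,
                              generations = generations, bounds = bounds,
                              zap = zap, consts = consts, ...)
  }
  population <- do.call(rbind, lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    cbind(as.data.frame(r$params), obj_columns(r$objectives),
          r$attributes, run = k)
  }))
  optimal <- suppressWarnings(filter_optimal(runs, target, tol = tolerance))
  structure(list(population = population, optimal = optimal, target = target,
                 runs = runs, tolerance = tolerance, seed = seed,
                 bounds = bounds, zap = zap, consts = consts,
                 pop_size = pop_size, generations = generations,
                 n_runs = n_runs),
            class = "mpr_fit")
}

#' @export
print.mpr_fit <- function(x, ...) {
  cat("Population fit of the PD clamp model to impedance attributes\n")
  cat(sprintf("  %d run(s) x %d generations, population %d (seed %d)\n",
              x$n_runs, x$generations, x$pop_size, x$seed))
  cat(sprintf("  pooled individuals: %d\n", nrow(x$population)))
  cat(sprintf("  accepted models (all attribute errors <= %g%%): %d\n",
              100 * x$tolerance, nrow(x$optimal)))
  if (nrow(x$optimal)) {
    med <- apply(x$optimal[, param_names()], 2, stats::median)
    cat("  accepted-parameter medians:\n")
    print(signif(med, 3))
  }
  invisible(x)
}

#' Summarize an mpr_fit: parameter spread and dispersion of accepted models
#'
#' @param object an `"mpr_fit"`.
#' @param ... unused.
#' @return Object of class `"summary.mpr_fit"` containing a per-parameter
#'   table (median, min, max, CoV = SD of the median-normalized values) of
#'   the accepted models, and the acceptance counts.
#' @export
summary.mpr_fit <- function(object, ...) {
  opt <- object$optimal
  tab <- NULL
  if (nrow(opt)) {
    P <- as.matrix(opt[, param_names()])
    tab <- t(apply(P, 2, function(v) {
      md <- stats::median(v)
      c(median = md, min = min(v), max = max(v),
        CoV = if (md != 0) stats::sd(v / md) else NA_real_)
    }))
  }
  structure(list(params = tab, n_accepted = nrow(opt),
                 n_pooled = nrow(object$population),
                 tolerance = object$tolerance),
            class = "summary.mpr_fit")
}

#' @export
print.summary.mpr_fit <- function(x, ...) {
  cat(sprintf("Accepted models: %d of %d pooled (tolerance %g%%)\n",
              x$n_accepted, x$n_pooled, 100 * x$tolerance))
  if (!is.null(x$params)) {
    cat("Parameter spread across accepted models:\n")
    print(signif(x$params, 3))
  }
  invisible(x)
}

#' Parameter sets of the accepted models
#'
#' @param object an `"mpr_fit"`.
#' @param ... unused.
#' @return Numeric matrix, one row per accepted model, eight parameter
#'   columns in canonical order.
#' @export
coef.mpr_fit <- function(object, ...) {
  as.matrix(object$optimal[, param_names()])
}

#' Objective scores of the accepted models
#'
#' @param object an `"mpr_fit"`.
#' @param ... unused.
#' @return Numeric matrix of the ten normalized objective scores, one row
#'   per accepted model.
#' @export
residuals.mpr_fit <- function(object, ...) {
  nm <- paste0("obj_", names(objective_vector(object$target, object$target)))
  out <- as.matrix(object$optimal[, nm])
  colnames(out) <- sub("^obj_", "", colnames(out))
  out
}

#' Impedance attributes for new parameter sets under the fitted stimulus
#'
#' Runs the full simulate / profile / attribute pipeline of the fit for each
#' row of `newdata`.
#'
#' @param object an `"mpr_fit"`.
#' @param newdata matrix or data frame of parameter sets (columns named as
#'   [param_names()]); defaults to the accepted models.
#' @param ... unused.
#' @return Data frame of attribute scalars, one row per parameter set.
#' @export
predict.mpr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- coef(object)
  newdata <- as.matrix(as.data.frame(newdata)[, param_names()])
  ev <- make_evaluator(object$target, object$zap, object$consts)
  rows <- lapply(seq_len(nrow(newdata)), function(i) ev(newdata[i, ])$row)
  out <- as.data.frame(do.call(rbind, rows))
  out[, !grepl("^err_", names(out))]
}

#' Plot the impedance profiles of accepted models against the target
#'
#' Re-simulates up to `n_show` accepted models under the fitted ZAP command
#' and draws their Z(f) and phi(f) profiles with the target attribute points
#' overlaid.
#'
#' @param x an `"mpr_fit"`.
#' @param n_show maximum number of accepted models drawn.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.mpr_fit <- function(x, n_show = 20, ...) {
  opt <- x$optimal
  if (!nrow(opt)) stop("no accepted models to plot")
  idx <- seq_len(min(n_show, nrow(opt)))
  cmd <- zap_voltage(x$zap)
  cycles <- segment_cycles(cmd)
  pre <- stim_precompute(cmd$V, x$consts)
  profs <- lapply(idx, function(i) {
    I <- eval_current(as.numeric(opt[i, param_names()]), pre, cmd$V, cmd$dVdt,
                      x$zap$dt, x$consts)
    profile_from_cycles(cmd$V, I, cmd$t, cycles, x$zap$f_hi * 1.15)
  })
  tg <- x$target
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  zlim <- range(unlist(lapply(profs, `[[`, "Z")), tg$Z0, tg$Z_max, tg$Z_f1)
  graphics::plot(NA, xlim = c(x$zap$f_lo, x$zap$f_hi), ylim = zlim, log = "x",
                 xlab = "f (Hz)", ylab = "Z (MOhm)")
  for (p in profs) graphics::lines(p$f, p$Z, col = grDevices::adjustcolor("steelblue", 0.5))
  graphics::points(c(tg$f0, tg$f_res, tg$f_half_lo, tg$f_half_hi, tg$f1),
                   c(tg$Z0, tg$Z_max, tg$Z_half, tg$Z_half, tg$Z_f1),
                   pch = 19, col = "red")
  plim <- range(unlist(lapply(profs, `[[`, "phi")), tg$phi_max, tg$phi_min)
  graphics::plot(NA, xlim = c(x$zap$f_lo, x$zap$f_hi), ylim = plim, log = "x",
                 xlab = "f (Hz)", ylab = "phi (rad)")
  graphics::abline(h = 0, lty = 3)
  for (p in profs) graphics::lines(p$f, p$phi, col = grDevices::adjustcolor("steelblue", 0.5))
  graphics::points(c(tg$f0, tg$f_phimax, tg$f_phi0, tg$f_phi_fix, tg$f_phimin),
                   c(tg$phi_f0, tg$phi_max, 0, tg$phi_f2, tg$phi_min),
                   pch = 19, col = "red")
  invisible(x)
}
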
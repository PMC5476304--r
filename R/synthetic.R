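#' Sample random parameter sets within the allowed bounds
#'
#' Uniform independent draws per parameter, the same distribution the
#' evolutionary search uses for its initial population. Uses R's RNG.
#'
#' @param n number of parameter sets.
#' @param bounds bounds matrix ([param_bounds()]).
#' @return Numeric matrix, `n` rows by 8 parameter columns.
#' @export
sample_params <- function(n = 1, bounds = param_bounds()) {
  stopifnot(n >= 1)
  npar <- nrow(bounds)
  matrix(stats::runif(n * npar, rep(bounds[, "low"], each = n),
                      rep(bounds[, "high"], each = n)),
         nrow = n, dimnames = list(NULL, rownames(bounds)))
}

#' Build a synthetic fitting target from a known ground-truth model
#'
#' Simulates the ground-truth parameter set under the ZAP command, extracts
#' its impedance attributes and returns them as a fitting target in the same
#' form as [pd_target()]. With `noise_level > 0`, multiplicative Gaussian
#' noise is applied to the impedance and phase attribute values (never to
#' the frequency coordinates), emulating measurement variability of the
#' attribute points. When `truth` is omitted, random parameter sets are
#' drawn until one yields a well-posed resonant profile
#' (`Q_Z / Z0 >= min_qz_ratio`).
#'
#' @param truth ground-truth parameters, or `NULL` to sample one.
#' @param zap ZAP configuration used to measure the target.
#' @param consts fixed constants.
#' @param noise_level relative SD of the multiplicative attribute noise.
#' @param min_qz_ratio resonance prominence required of a sampled truth.
#' @param max_tries resampling budget before giving up.
#' @param bounds bounds for sampling and validation.
#' @return Object of class `"mpr_synthetic_target"`: list with `truth`
#'   (parameters), `target` (attributes, class `"mpr_attributes"`),
#'   `clean` (the noise-free attributes) and `noise_level`.
#' @export
#' @examples
#' \donttest{
#' tg <- make_target(pd_median_params(), zap = zap_config(dt = 1))
#' tg$target$f_res
#' }
make_target <- function(truth = NULL, zap = zap_config(),
                        consts = fixed_constants(), noise_level = 0,
                        min_qz_ratio = 0.1, max_tries = 200,
                        bounds = param_bounds()) {
  cmd <- zap_voltage(zap)
  cycles <- segment_cycles(cmd)
  pre <- stim_precompute(cmd$V, consts)
  measure <- function(p) {
    I <- eval_current(as_model_params(p, bounds = NULL), pre,
                      cmd$V, cmd$dVdt, zap$dt, consts)
    prof <- profile_from_cycles(cmd$V, I, cmd$t, cycles, zap$f_hi * 1.15)
    extract_attributes(prof, f0 = zap$f_lo, f1 = zap$f_hi)
  }
  if (is.null(truth)) {
    for (k in seq_len(max_tries)) {
      cand <- as_model_params(sample_params(1, bounds)[1, ], bounds = NULL)
      a <- measure(cand)
      if (isTRUE(a$resonant) && isTRUE(a$has_phi0) &&
          a$Q_Z / a$Z0 >= min_qz_ratio) {
        truth <- cand
        break
      }
    }
    if (is.null(truth)) stop("no resonant ground truth found in ", max_tries,
                             " draws")
  } else {
    truth <- as_model_params(truth, bounds = bounds)
    a <- measure(truth)
    if (!isTRUE(a$resonant) || !isTRUE(a$has_phi0))
      stop("ground-truth model is not resonant under this stimulus")
  }
  clean <- a
  target <- a
  if (noise_level > 0) {
    value_fields <- c("Z0", "Z_max", "Z_half", "Z_f1",
                      "phi_f0", "phi_max", "phi_f2", "phi_min")
    for (f in value_fields)
      target[[f]] <- target[[f]] * (1 + stats::rnorm(1, 0, noise_level))
    target$Q_Z <- target$Z_max - target$Z0
  }
  structure(list(truth = truth, target = target, clean = clean,
                 noise_level = noise_level),
            class = "mpr_synthetic_target")
}

#' @export
print.mpr_synthetic_target <- function(x, ...) {
  cat("Synthetic resonance target (noise level ", x$noise_level, ")\n", sep = "")
  cat(sprintf("  truth: f_res = %.3f Hz, Z_max = %.2f MOhm, Q_Z = %.2f MOhm\n",
              x$clean$f_res, x$clean$Z_max, x$clean$Q_Z))
  invisible(x)
}

#' Parameter-recovery summary of a fitted population against a known truth
#'
#' For every parameter, reports whether the ground-truth value lies within
#' the range spanned by the accepted models, together with the coefficient
#' of variation of the median-normalized values. Attributes constrain some
#' parameters tightly (small CoV, narrow range around the truth) while
#' others are recovered only up to their correlation manifolds (large CoV).
#'
#' @param truth ground-truth parameter set.
#' @param fitted an `"mpr_fit"`, or a data frame / matrix of accepted
#'   parameter sets.
#' @return Data frame, one row per parameter: `truth`, `min`, `max`,
#'   `median`, `contains_truth`, `CoV`.
#' @export
recovery_report <- function(truth, fitted) {
  truth <- as_model_params(truth)
  P <- as.matrix(as_population(fitted)[, param_names()])
  if (!nrow(P)) stop("empty fitted set")
  rows <- lapply(param_names(), function(nm) {
    v <- P[, nm]
    md <- stats::median(v)
    data.frame(param = nm, truth = truth[[nm]], min = min(v), max = max(v),
               median = md,
               contains_truth = truth[[nm]] >= min(v) & truth[[nm]] <= max(v),
               CoV = if (md != 0) stats::sd(v / md) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
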
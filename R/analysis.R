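# coerce an mpr_fit / evolution / data frame / matrix to a data frame of
# accepted-model parameters (plus any attribute columns it carries)
as_population <- function(pop, optimal = TRUE) {
  if (inherits(pop, "mpr_fit")) pop <- if (optimal) pop$optimal else pop$population
  if (inherits(pop, "mpr_evolution"))
    pop <- cbind(as.data.frame(pop$params), pop$attributes)
  as.data.frame(pop)
}

#' Pearson correlation of two parameters with a subset permutation test
#'
#' Computes the pooled-population Pearson coefficient, its permutation
#' p-value, the regression slope with its t-test p-value, and the stability
#' screen used for population-level claims: `n_subsets` random subsets of
#' `subset_size` models are drawn, each subset's correlation is tested by
#' permutation, and `pct_significant` reports the percentage of subsets with
#' a permutation p-value below `alpha`.
#'
#' The permutation p-value is the fraction of `n_perms` shuffles of `y`
#' whose correlation magnitude meets or exceeds the observed one (two-sided
#' on |R| by default; set `two_sided = FALSE` for the one-sided version).
#'
#' @param pop population: an `"mpr_fit"`, an evolution result, or a data
#'   frame / matrix with parameter columns.
#' @param param_x,param_y names of the two parameters (columns).
#' @param subset_size models per subset repetition.
#' @param n_subsets number of subset repetitions (0 skips the screen).
#' @param n_perms permutations per test.
#' @param alpha significance level of the subset screen.
#' @param two_sided permutation test sidedness.
#' @return Object of class `"mpr_correlation"`: list with `pair`, `n`, `R`,
#'   `p_perm`, `slope`, `slope_p`, `pct_significant`.
#' @export
pearson_permutation <- function(pop, param_x, param_y, subset_size = 20,
                                n_subsets = 2000, n_perms = 1000,
                                alpha = 0.01, two_sided = TRUE) {
  pop <- as_population(pop)
  x <- pop[[param_x]]; y <- pop[[param_y]]
  n <- length(x)
  if (n_subsets > 0 && n < subset_size)
    stop("population smaller than subset_size")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance parameter: correlation undefined")
  R <- stats::cor(x, y)
  cnt <- perm_cor_count_cpp(x, y, n_perms, two_sided)
  p_perm <- (cnt + 1) / (n_perms + 1)
  fit <- stats::lm(y ~ x)
  sl <- suppressWarnings(summary(fit))$coefficients # exact fits are legitimate
  pct <- NA_real_
  if (n_subsets > 0) {
    hits <- 0L
    for (b in seq_len(n_subsets)) {
      idx <- sample.int(n, subset_size)
      cs <- perm_cor_count_cpp(x[idx], y[idx], n_perms, two_sided)
      if (!is.na(cs) && (cs + 1) / (n_perms + 1) < alpha) hits <- hits + 1L
    }
    pct <- 100 * hits / n_subsets
  }
  structure(list(pair = c(param_x, param_y), n = n, R = R, p_perm = p_perm,
                 slope = sl["x", "Estimate"], slope_p = sl["x", "Pr(>|t|)"],
                 pct_significant = pct),
            class = "mpr_correlation")
}

#' @export
print.mpr_correlation <- function(x, ...) {
  cat(sprintf("%s - %s (n = %d): R = %.3f, permutation p = %.4g\n",
              x$pair[1], x$pair[2], x$n, x$R, x$p_perm))
  cat(sprintf("  slope = %.4g (t-test p = %.4g)", x$slope, x$slope_p))
  if (is.finite(x$pct_significant))
    cat(sprintf("; %.1f%% of size-20 subsets significant", x$pct_significant))
  cat("\n")
  invisible(x)
}

#' Pairwise correlation table of a model population
#'
#' Applies [pearson_permutation()] to every parameter pair (or a selection)
#' and optionally appends Benjamini-Hochberg adjusted p-values. The BH
#' column is an extension beyond the conventional raw p < 0.01 screen and is
#' labelled as such.
#'
#' @inheritParams pearson_permutation
#' @param pairs `"all"` or a 2-column character matrix of parameter pairs.
#' @param bh add a Benjamini-Hochberg adjusted p-value column.
#' @return Data frame with one row per pair: `param_x`, `param_y`, `R`,
#'   `p_perm`, `slope`, `slope_p`, `pct_significant`, optionally `p_bh`.
#' @export
param_correlations <- function(pop, pairs = "all", subset_size = 20,
                               n_subsets = 0, n_perms = 1000, alpha = 0.01,
                               bh = FALSE) {
  pop <- as_population(pop)
  if (identical(pairs, "all")) {
    nm <- param_names()
    pairs <- t(utils::combn(nm, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- pearson_permutation(pop, pairs[i, 1], pairs[i, 2],
                             subset_size = subset_size,
                             n_subsets = n_subsets, n_perms = n_perms,
                             alpha = alpha)
    data.frame(param_x = pairs[i, 1], param_y = pairs[i, 2], R = r$R,
               p_perm = r$p_perm, slope = r$slope, slope_p = r$slope_p,
               pct_significant = r$pct_significant)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p_perm, method = "BH")
  out
}

#' Partition a population by calcium conductance
#'
#' Labels each model `"low"` when its maximal calcium conductance is below
#' `threshold` and `"high"` otherwise (a model exactly at the threshold is
#' assigned to the high group).
#'
#' @param pop population (see [pearson_permutation()]).
#' @param threshold split value (uS).
#' @return The population data frame with an added `group` factor column.
#' @export
partition_gca <- function(pop, threshold = 0.05) {
  pop <- as_population(pop)
  pop$group <- factor(ifelse(pop$g_Ca < threshold, "low", "high"),
                      levels = c("low", "high"))
  for (g in levels(pop$group))
    if (!any(pop$group == g)) warning("empty ", g, " g_Ca group")
  pop
}

#' Table-layout per-group correlation p-values
#'
#' Square matrix of permutation p-values with the low-group pairs in the
#' lower triangle and the high-group pairs in the upper triangle, mirroring
#' the conventional presentation of per-group pairwise tests.
#'
#' @param pop population with a `group` column from [partition_gca()].
#' @param n_perms permutations per pair.
#' @return Numeric matrix with parameter names on both dimensions.
#' @export
correlation_p_matrix <- function(pop, n_perms = 1000) {
  pop <- as_population(pop)
  stopifnot("group" %in% names(pop))
  nm <- param_names()
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) next
    g <- if (i > j) "low" else "high" # lower triangle: low group
    sub <- pop[pop$group == g, ]
    if (nrow(sub) < 3) next
    r <- tryCatch(pearson_permutation(sub, nm[min(i, j)], nm[max(i, j)],
                                      n_subsets = 0, n_perms = n_perms),
                  error = function(e) NULL)
    if (!is.null(r)) m[i, j] <- r$p_perm
  }
  m
}

#' Shift of resonance under a lowered oscillation floor
#'
#' Re-profiles each model with the ZAP command spanning
#' (`V_low_new`, `V_high`) instead of the base range and reports the change
#' in resonant frequency and peak impedance,
#' `delta = value(new range) - value(base range)`. Models that lose
#' resonance at either range are flagged (`ok = FALSE`) and should be
#' excluded from group means.
#'
#' @param pop population (fit, evolution result, data frame or parameter
#'   matrix).
#' @param zap base ZAP configuration.
#' @param V_low_new new lower voltage bound (mV).
#' @param V_high upper voltage bound (mV); defaults to the base
#'   configuration's upper bound.
#' @param consts fixed constants.
#' @return Data frame per model: `f_res_base`, `Z_max_base`, `f_res_new`,
#'   `Z_max_new`, `d_f_res`, `d_Z_max`, `ok`.
#' @export
vlow_shift <- function(pop, zap = zap_config(), V_low_new = -70,
                       V_high = NULL, consts = fixed_constants()) {
  pop <- as_population(pop)
  P <- as.matrix(pop[, param_names()])
  if (is.null(V_high)) V_high <- zap$v0 + zap$v1
  zap_new <- shifted_range_config(zap, V_low_new, V_high)
  base_attrs <- batch_attributes(P, zap, consts)
  new_attrs <- batch_attributes(P, zap_new, consts)
  out <- data.frame(
    f_res_base = base_attrs$f_res, Z_max_base = base_attrs$Z_max,
    f_res_new = new_attrs$f_res, Z_max_new = new_attrs$Z_max,
    d_f_res = new_attrs$f_res - base_attrs$f_res,
    d_Z_max = new_attrs$Z_max - base_attrs$Z_max,
    ok = base_attrs$resonant > 0 & new_attrs$resonant > 0
  )
  cbind(pop, out)
}

# attributes of many parameter sets under one stimulus (shared precompute)
batch_attributes <- function(P, zap, consts) {
  ev <- make_evaluator(pd_target(), zap, consts)
  rows <- lapply(seq_len(nrow(P)), function(i) ev(as.numeric(P[i, param_names_idx(P)]))$row)
  as.data.frame(do.call(rbind, rows))
}

param_names_idx <- function(P) {
  if (!is.null(colnames(P))) match(param_names(), colnames(P)) else seq_len(8)
}

#' Filter models that reproduce the resonance shift at a lowered floor
#'
#' Keeps the models whose attributes at the lowered voltage range match a
#' shifted target — resonant frequency reduced by `delta_f_res`, peak
#' impedance unchanged — within `tol` relative error. This selects the
#' subset (the "intermediate" calcium-conductance group) that reproduces the
#' biological response to a lowered oscillation floor; the emergent
#' correlation structure of the subset (notably g_Ca against g_H) can then
#' be examined with [param_correlations()].
#'
#' @param pop population of accepted models.
#' @param target base target attribute set.
#' @param delta_f_res shift of the resonant frequency at the lowered range
#'   (Hz; negative = slower resonance). The default is the experimentally
#'   observed -0.24 Hz.
#' @param tol relative tolerance on `f_res` and `Z_max` at the new range.
#' @inheritParams vlow_shift
#' @return The subset data frame, with the [vlow_shift()] columns appended.
#' @export
intermediate_filter <- function(pop, target = pd_target(),
                                delta_f_res = -0.24, tol = 0.05,
                                zap = zap_config(), V_low_new = -70,
                                consts = fixed_constants()) {
  sh <- vlow_shift(pop, zap = zap, V_low_new = V_low_new, consts = consts)
  f_target <- target$f_res + delta_f_res
  z_target <- target$Z_max
  keep <- sh$ok &
    abs(sh$f_res_new - f_target) / abs(f_target) <= tol &
    abs(sh$Z_max_new - z_target) / abs(z_target) <= tol
  out <- sh[keep, , drop = FALSE]
  if (!nrow(out)) warning("no models pass the intermediate filter")
  rownames(out) <- NULL
  out
}
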
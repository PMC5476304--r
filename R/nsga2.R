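#' Non-dominated sorting of objective vectors
#'
#' Partitions a set of objective vectors (rows; all objectives minimized)
#' into Pareto fronts. A solution dominates another if it is no worse in
#' every objective and strictly better in at least one. Front 1 is the
#' non-dominated set; each subsequent front is non-dominated once earlier
#' fronts are removed.
#'
#' @param obj numeric matrix, one row per solution, one column per objective.
#' @return List with `fronts` (list of integer row-index vectors) and `rank`
#'   (integer vector, front index of each solution, starting at 1).
#' @export
non_dominated_sort <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  dominated_by <- vector("list", n) # solutions that i dominates
  n_dom <- integer(n)               # number of solutions dominating i
  for (i in seq_len(n)) {
    oi <- obj[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      d <- oi - obj[j, ]
      if (all(d <= 0) && any(d < 0)) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (all(d >= 0) && any(d > 0)) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  rank <- integer(n)
  fronts <- list()
  current <- which(n_dom == 0L)
  k <- 0L
  remaining <- n_dom
  while (length(current)) {
    k <- k + 1L
    rank[current] <- k
    fronts[[k]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        remaining[j] <- remaining[j] - 1L
        if (remaining[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within one Pareto front
#'
#' Boundary solutions of every objective get infinite distance; interior
#' solutions accumulate, over objectives, the gap between their neighbours
#' normalized by the objective's span in the front. Objectives with zero
#' span contribute nothing (no division by zero).
#'
#' @param obj numeric matrix of the front's objective vectors (rows).
#' @return Numeric vector of non-negative (possibly infinite) distances.
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    span <- obj[o[n], m] - obj[o[1], m]
    d[o[1]] <- d[o[n]] <- Inf
    if (span > 0) {
      mid <- o[2:(n - 1)]
      d[mid] <- d[mid] + (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / span
    }
  }
  d
}

#' Simulated binary crossover (SBX)
#'
#' Per-gene SBX with distribution index `eta`: children are spread around the
#' parents with the classic polynomial kernel, so the expected child mean
#' equals the parent mean per gene; larger `eta` concentrates children near
#' the parents. Each gene recombines with probability `p_gene` (otherwise it
#' is copied), and the whole pair recombines with probability `p_pair`.
#' Children are clipped to the bounds. Uses R's RNG.
#'
#' @param p1,p2 parent parameter vectors (within bounds).
#' @param eta distribution index (> 0).
#' @param bounds bounds matrix (`low`, `high` columns) matching the vectors.
#' @param p_pair probability that the pair recombines at all.
#' @param p_gene per-gene recombination probability.
#' @return List of two children.
#' @export
sbx_crossover <- function(p1, p2, eta = 20, bounds = param_bounds(),
                          p_pair = 0.9, p_gene = 0.5) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= p_pair) {
    for (g in seq_along(p1)) {
      if (stats::runif(1) > p_gene) next
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
              else (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[g] <- 0.5 * ((1 + beta) * p1[g] + (1 - beta) * p2[g])
      c2[g] <- 0.5 * ((1 - beta) * p1[g] + (1 + beta) * p2[g])
    }
    c1 <- pmin(pmax(c1, bounds[, "low"]), bounds[, "high"])
    c2 <- pmin(pmax(c2, bounds[, "low"]), bounds[, "high"])
  }
  list(c1, c2)
}

#' Bounded polynomial mutation
#'
#' Deb's bounded polynomial mutation with distribution index `eta`: each gene
#' mutates with probability `rate`; the perturbation is drawn from a
#' polynomial kernel whose support is exactly the gene's feasible interval,
#' so a gene sitting on a bound can only move inward and no clipping is
#' needed. Uses R's RNG.
#'
#' @param p parameter vector within bounds.
#' @param eta distribution index (> 0).
#' @param rate per-gene mutation probability; 0 returns `p` unchanged.
#' @param bounds bounds matrix matching `p`.
#' @return Mutated parameter vector.
#' @export
polynomial_mutation <- function(p, eta = 20, rate = 1 / length(p),
                                bounds = param_bounds()) {
  if (rate <= 0) return(p)
  for (g in seq_along(p)) {
    if (stats::runif(1) > rate) next
    lo <- bounds[g, "low"]; hi <- bounds[g, "high"]
    span <- hi - lo
    if (span <= 0) next
    d1 <- (p[g] - lo) / span
    d2 <- (hi - p[g]) / span
    u <- stats::runif(1)
    mpow <- 1 / (eta + 1)
    if (u < 0.5) {
      dq <- (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^mpow - 1
    } else {
      dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^mpow
    }
    p[g] <- min(max(p[g] + dq * span, lo), hi)
  }
  p
}

# Binary tournament: lower front rank wins; among equal ranks the candidate
# closer to the target (smaller normalized objective norm) wins, with
# crowding distance as the final tie-break. With ten objectives almost every
# candidate is non-dominated after a few generations, so dominance alone
# carries no selection pressure; guiding ties toward the target point (the
# origin of objective space) restores convergence while the dominance rank
# and crowding diversity of NSGA-II are retained.
tournament <- function(rank, gdist, crowd) {
  n <- length(rank)
  a <- sample.int(n, 1); b <- sample.int(n, 1)
  if (rank[a] != rank[b]) return(if (rank[a] < rank[b]) a else b)
  if (gdist[a] != gdist[b]) return(if (gdist[a] < gdist[b]) a else b)
  if (crowd[a] > crowd[b]) a else b
}

# (mu + lambda) environmental selection down to pop_size: whole fronts are
# taken in rank order; an overflowing front is truncated to its per-objective
# minima (preserving single-objective elitism) plus the members closest to
# the target. The guidance distance `gdist` is the worst acceptance-attribute
# error (Chebyshev norm): the goal region is the box where every acceptance
# error is below tolerance, and the Chebyshev scalarization points straight
# at it. When it is not supplied the normalized objective norm is used.
environmental_selection <- function(obj, pop_size, gdist_all = NULL) {
  nds <- non_dominated_sort(obj)
  if (is.null(gdist_all)) gdist_all <- sqrt(rowSums(pmin(obj, 1e6)^2))
  keep <- integer(0)
  crowd_all <- numeric(nrow(obj))
  for (fr in nds$fronts) {
    crowd_all[fr] <- crowding_distance(obj[fr, , drop = FALSE])
    if (length(keep) + length(fr) <= pop_size) {
      keep <- c(keep, fr)
    } else {
      need <- pop_size - length(keep)
      if (need > 0) {
        elite <- unique(fr[apply(obj[fr, , drop = FALSE], 2, which.min)])
        elite <- elite[seq_len(min(length(elite), need))]
        rest <- setdiff(fr[order(gdist_all[fr])], elite)
        keep <- c(keep, elite, rest[seq_len(need - length(elite))])
      }
      break
    }
  }
  list(keep = keep, rank = nds$rank, crowd = crowd_all, gdist = gdist_all)
}

#' Evolve a population of clamp models toward a target attribute set
#'
#' One NSGA-II run: a population of parameter vectors sampled uniformly
#' within bounds is evolved by binary tournament selection, SBX crossover,
#' polynomial mutation and (mu + lambda) elitist survival by (front rank,
#' crowding distance). Every candidate is evaluated through the full
#' pipeline: ZAP clamp simulation, cycle-by-cycle impedance profile,
#' attribute extraction and the ten normalized objective scores against the
#' target. Candidates whose simulation fails or whose attributes are
#' undefined receive a large finite penalty on the affected objectives and
#' remain in the sorting machinery, keeping the population size fixed.
#'
#' Randomness is drawn from R's RNG; seed with `set.seed()` for
#' reproducibility. The evaluation stimulus (command waveform, derivative and
#' cycle boundaries) is precomputed once per call.
#'
#' @param target target attribute set (e.g. [pd_target()] or the target of a
#'   [make_target()] synthetic problem).
#' @param pop_size population size (even).
#' @param generations number of generations; 0 returns the evaluated initial
#'   random population.
#' @param eta_crossover,eta_mutation SBX / mutation distribution indices.
#' @param p_crossover probability that a parent pair recombines.
#' @param mutation_rate per-gene mutation probability.
#' @param bounds parameter bounds matrix ([param_bounds()]).
#' @param zap ZAP command configuration ([zap_config()]); its `dt` field sets
#'   the integration step.
#' @param consts fixed constants ([fixed_constants()]). Setting `g_H = 0` in
#'   a model is equivalent to removing the H current; to fit without it, pass
#'   bounds with a collapsed `g_H` row.
#' @param penalty objective score assigned to failed evaluations.
#' @param tol acceptance radius used for the archive of accepted models
#'   encountered during the run.
#' @param trace_every if positive, print best/median total score every so
#'   many generations.
#' @return List of class `"mpr_evolution"`: `params` (pop_size x 8 matrix),
#'   `objectives` (pop_size x 10), `attributes` (data frame of per-model
#'   attribute scalars and acceptance errors), `rank`, `crowding`, `log`
#'   (per-generation best/median of the summed objective scores),
#'   `objective_minima` (per-generation minimum of each objective), `archive`
#'   (every accepted individual encountered during the run, or `NULL`), plus
#'   the configuration used.
#'
#' @details With ten objectives the population becomes almost entirely
#'   mutually non-dominated within a few generations, and the classic
#'   crowding-only tie-break then spreads the population along the front
#'   instead of closing in on the target. Selection here therefore breaks
#'   equal-rank ties toward the target point (the origin of objective space)
#'   before falling back on crowding, and front truncation always retains the
#'   per-objective minima, so the best value of every single objective is
#'   non-increasing across generations. Accepted models found at any
#'   generation are accumulated in the archive, mirroring how large pooled
#'   populations of optimal models are collected across runs.
#' @export
nsga2_evolve <- function(target = pd_target(), pop_size = 100,
                         generations = 200, eta_crossover = 20,
                         eta_mutation = 20, p_crossover = 0.9,
                         mutation_rate = 1 / 8, bounds = param_bounds(),
                         zap = zap_config(), consts = fixed_constants(),
                         penalty = 1e6, tol = 0.05, trace_every = 0) {
  stopifnot(pop_size >= 2, pop_size %% 2 == 0, generations >= 0,
            eta_crossover > 0, eta_mutation > 0)
  ev <- make_evaluator(target, zap, consts, penalty)
  archive <- list()
  archive_accepted <- function(par_mat, obj_mat, att_mat) {
    err <- att_mat[, grep("^err_", colnames(att_mat)), drop = FALSE]
    err[is.na(err)] <- Inf
    ok <- att_mat[, "resonant"] > 0 & att_mat[, "has_phi0"] > 0 &
      apply(err <= tol, 1, all)
    if (any(ok))
      archive[[length(archive) + 1L]] <<-
        cbind(as.data.frame(par_mat[ok, , drop = FALSE]),
              obj_columns(obj_mat[ok, , drop = FALSE]),
              as.data.frame(att_mat[ok, , drop = FALSE]))
    invisible(NULL)
  }

  npar <- nrow(bounds)
  pop <- matrix(stats::runif(pop_size * npar, rep(bounds[, "low"], each = pop_size),
                             rep(bounds[, "high"], each = pop_size)),
                nrow = pop_size, dimnames = list(NULL, rownames(bounds)))
  worst_err <- function(att_mat) {
    err <- att_mat[, grep("^err_", colnames(att_mat)), drop = FALSE]
    err[!is.finite(err)] <- penalty
    pmin(apply(err, 1, max), penalty)
  }

  evals <- lapply(seq_len(pop_size), function(i) ev(pop[i, ]))
  obj <- do.call(rbind, lapply(evals, `[[`, "scores"))
  att <- do.call(rbind, lapply(evals, `[[`, "row"))
  archive_accepted(pop, obj, att)

  sel <- environmental_selection(obj, pop_size, worst_err(att))
  rank <- sel$rank; crowd <- sel$crowd; gdist <- sel$gdist
  log <- matrix(NA_real_, nrow = generations, ncol = 2,
                dimnames = list(NULL, c("best", "median")))
  obj_min <- matrix(NA_real_, nrow = generations, ncol = ncol(obj),
                    dimnames = list(NULL, colnames(obj)))

  gen <- 0L
  while (gen < generations) {
    gen <- gen + 1L
    # variation: children from binary tournaments
    child <- matrix(NA_real_, nrow = pop_size, ncol = npar,
                    dimnames = list(NULL, rownames(bounds)))
    i <- 1L
    while (i < pop_size) {
      pa <- tournament(rank, gdist, crowd); pb <- tournament(rank, gdist, crowd)
      kids <- sbx_crossover(pop[pa, ], pop[pb, ], eta = eta_crossover,
                            bounds = bounds, p_pair = p_crossover)
      child[i, ] <- polynomial_mutation(kids[[1]], eta = eta_mutation,
                                        rate = mutation_rate, bounds = bounds)
      child[i + 1L, ] <- polynomial_mutation(kids[[2]], eta = eta_mutation,
                                             rate = mutation_rate, bounds = bounds)
      i <- i + 2L
    }
    cevals <- lapply(seq_len(pop_size), function(i) ev(child[i, ]))
    cobj <- do.call(rbind, lapply(cevals, `[[`, "scores"))
    catt <- do.call(rbind, lapply(cevals, `[[`, "row"))
    archive_accepted(child, cobj, catt)

    pool <- rbind(pop, child)
    pool_obj <- rbind(obj, cobj)
    pool_att <- rbind(att, catt)
    sel <- environmental_selection(pool_obj, pop_size, worst_err(pool_att))
    keep <- sel$keep
    pop <- pool[keep, , drop = FALSE]
    obj <- pool_obj[keep, , drop = FALSE]
    att <- pool_att[keep, , drop = FALSE]
    rank <- sel$rank[keep]; crowd <- sel$crowd[keep]
    gdist <- sel$gdist[keep]

    tot <- rowSums(obj)
    log[gen, ] <- c(min(tot), stats::median(tot))
    obj_min[gen, ] <- apply(obj, 2, min)
    if (trace_every > 0 && gen %% trace_every == 0)
      message(sprintf("generation %d: best %.4g, median %.4g",
                      gen, log[gen, 1], log[gen, 2]))
  }

  archive <- if (length(archive)) do.call(rbind, archive) else NULL
  structure(list(params = pop, objectives = obj,
                 attributes = as.data.frame(att),
                 rank = rank, crowding = crowd, log = log,
                 objective_minima = obj_min, archive = archive,
                 target = target, bounds = bounds, zap = zap,
                 consts = consts, pop_size = pop_size,
                 generations = generations, tol = tol),
            class = "mpr_evolution")
}

# objective scores as population-table columns, prefixed so they cannot
# shadow the attribute columns of the same name (f_phi0, phi_max, phi_min)
obj_columns <- function(obj_mat) {
  df <- as.data.frame(obj_mat)
  names(df) <- paste0("obj_", names(df))
  df
}

# Build the evaluation closure: parameter vector -> list(scores, row) where
# row holds the attribute scalars and acceptance errors stored with the
# population. The stimulus and its cycle boundaries are precomputed here.
make_evaluator <- function(target, zap, consts, penalty = 1e6) {
  cmd <- zap_voltage(zap)
  cycles <- segment_cycles(cmd)
  pre <- stim_precompute(cmd$V, consts)
  V <- cmd$V; dVdt <- cmd$dVdt; t <- cmd$t; dt <- zap$dt
  f_max <- zap$f_hi * 1.15
  attr_names <- c("Z0", "f_res", "Z_max", "Q_Z", "Z_half", "f_half_lo",
                  "f_half_hi", "Lambda_half", "Z_f1", "phi_f0", "f_phimax",
                  "phi_max", "f_phi0", "phi_f2", "f_phimin", "phi_min")
  err_names <- c("z0", "f_res", "z_max", "f_half_lo", "f_half_hi",
                 "z_f1", "phi_f0_abs", "f_phi0", "phi_2", "phi_min")
  n_row <- length(attr_names) + length(err_names) + 2L
  row_names <- c(attr_names, paste0("err_", err_names), "resonant", "has_phi0")
  fail_row <- stats::setNames(rep(NA_real_, n_row), row_names)
  fail_row["resonant"] <- 0; fail_row["has_phi0"] <- 0
  fail_scores <- stats::setNames(rep(penalty, 10),
                                 names(objective_vector(target, target)))
  function(p) {
    if (is.null(names(p))) names(p) <- param_names()
    res <- tryCatch({
      I <- eval_current(p, pre, V, dVdt, dt, consts)
      prof <- profile_from_cycles(V, I, t, cycles, f_max)
      a <- extract_attributes(prof, f0 = zap$f_lo, f1 = zap$f_hi)
      sc <- pmin(objective_vector(a, target, penalty = penalty), penalty)
      er <- attribute_errors(a, target)
      row <- stats::setNames(c(unlist(a[attr_names], use.names = FALSE),
                               er, as.numeric(a$resonant),
                               as.numeric(a$has_phi0)), row_names)
      list(scores = sc, row = row)
    }, error = function(e) NULL)
    if (is.null(res)) res <- list(scores = fail_scores, row = fail_row)
    res
  }
}

#' Pool evolution runs and keep the accepted, deduplicated models
#'
#' Combines the final populations and accepted-model archives of one or more
#' NSGA-II runs, keeps the individuals whose every acceptance-relevant
#' attribute is within `tol` of the target (see [is_accepted()]), and removes
#' near-identical parameter vectors (agreement to ~7 significant digits in
#' every parameter).
#'
#' @param runs a single `"mpr_evolution"` or a list of them (pooled).
#' @param target target attribute set; defaults to the target stored in the
#'   first run.
#' @param tol acceptance radius.
#' @return Data frame with one row per accepted model: the 8 parameters, the
#'   10 objective scores, the attribute scalars, acceptance errors and the
#'   originating `run` index. Zero rows (with a warning) when nothing passes.
#' @export
filter_optimal <- function(runs, target = NULL, tol = 0.05) {
  if (inherits(runs, "mpr_evolution")) runs <- list(runs)
  if (is.null(target)) target <- runs[[1]]$target
  pop <- do.call(rbind, lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    final <- cbind(as.data.frame(r$params), obj_columns(r$objectives),
                   r$attributes)
    all_rows <- if (!is.null(r$archive)) rbind(r$archive, final) else final
    cbind(all_rows, run = k)
  }))
  err_cols <- grep("^err_", names(pop), value = TRUE)
  errs <- as.matrix(pop[, err_cols])
  errs[is.na(errs)] <- Inf
  ok <- pop$resonant > 0 & pop$has_phi0 > 0 & apply(errs <= tol, 1, all)
  out <- pop[ok, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no models pass the acceptance filter")
    return(out)
  }
  key <- apply(signif(as.matrix(out[, param_names()]), 7), 1, paste,
               collapse = "|")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
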
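#' Cohort coreness container
#'
#' Stacks the per-subject coreness vectors of two groups into matrices with
#' one row per subject and one column per node. This is the substrate of
#' the Fisher separation criterion and of the group statistics.
#'
#' @param group_a,group_b numeric matrices (`subjects x nodes`) with entries
#'   in `[0, 1]`; both groups must share the node dimension.
#' @param node_labels optional node labels.
#' @return an object of class `"cohort_coreness"`.
#' @export
cohort_coreness <- function(group_a, group_b, node_labels = NULL) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b))
    stop("both groups must share the same number of nodes")
  if (nrow(group_a) < 2L || nrow(group_b) < 2L)
    stop("each group needs at least 2 subjects")
  if (min(group_a, group_b) < 0 || max(group_a, group_b) > 1)
    stop("coreness values must lie in [0, 1]")
  if (is.null(node_labels)) {
    node_labels <- colnames(group_a)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(ncol(group_a)))
  }
  structure(list(group_a = group_a, group_b = group_b,
                 node_labels = node_labels),
            class = "cohort_coreness")
}

#' Fisher separation criterion between two groups of coreness vectors
#'
#' `F = ||mean_A - mean_B||^2 / (s_A^2 + s_B^2)` where the means are the
#' elementwise group averages of the subject coreness vectors and
#' `s_Pop^2 = sum_s ||I_s - mean_Pop||^2` is the summed within-group
#' dispersion. Large `F` means the two groups are well separated relative
#' to their internal scatter. `F` is invariant to a positive rescaling of
#' the layer coefficients used to compute the coreness vectors.
#'
#' @param study a [cohort_coreness()] object.
#' @return a nonnegative scalar; 0 when the group means coincide.
#' @export
fisher_criterion <- function(study) {
  stopifnot(inherits(study, "cohort_coreness"))
  ma <- colMeans(study$group_a)
  mb <- colMeans(study$group_b)
  num <- sum((ma - mb)^2)
  if (num == 0) return(0)
  sa <- sum(sweep(study$group_a, 2L, ma)^2)
  sb <- sum(sweep(study$group_b, 2L, mb)^2)
  if (sa + sb == 0)
    stop("degenerate cohort: zero within-group dispersion with distinct means")
  num / (sa + sb)
}

#' Bundle a raw multiplex cohort for repeated coreness evaluation
#'
#' Builds the per-subject density-sweep caches once so that candidate layer
#' coefficient vectors can be scored cheaply during optimization.
#'
#' @param subjects a list of normalized `multiplex` objects sharing nodes
#'   and layers.
#' @param group a factor (or vector) of length `length(subjects)` with
#'   exactly two levels; the first level is treated as group A (reference).
#' @return an object of class `"mcp_cohort"`.
#' @export
mcp_cohort <- function(subjects, group) {
  if (!length(subjects) || !all(vapply(subjects, inherits, TRUE, "multiplex")))
    stop("'subjects' must be a list of multiplex objects")
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("'group' must have exactly two levels")
  if (length(group) != length(subjects))
    stop("'group' length must match the number of subjects")
  nodes <- subjects[[1L]]$nodes
  layers <- subjects[[1L]]$layers
  for (s in subjects) {
    if (!identical(s$nodes, nodes) || !identical(s$layers, layers))
      stop("all subjects must share node labels and layer names")
  }
  caches <- lapply(subjects, coreness_cache)
  structure(list(caches = caches, group = group, nodes = nodes,
                 layers = layers, N = length(nodes), M = length(layers)),
            class = "mcp_cohort")
}

# Coreness matrices (subjects x nodes) of both groups for a coefficient
# vector, from the precomputed caches.
cohort_coreness_at <- function(cohort, c) {
  cv <- as_coefficient_values(c)
  X <- t(vapply(cohort$caches,
                function(ca) coreness_from_cache(ca, cv)$coreness,
                numeric(cohort$N)))
  colnames(X) <- cohort$nodes
  lev <- levels(cohort$group)
  cohort_coreness(X[cohort$group == lev[1L], , drop = FALSE],
                  X[cohort$group == lev[2L], , drop = FALSE],
                  node_labels = cohort$nodes)
}

#' Score a candidate angle vector on a cohort
#'
#' Composes [angles_to_coefficients()], the per-subject coreness sweep and
#' [fisher_criterion()]. The per-subject caches of the cohort are reused, so
#' the cost per candidate is one sweep per subject.
#'
#' @param cohort an [mcp_cohort()] object.
#' @param phi numeric vector of `M - 1` hypersphere angles in `[0, pi/2]`.
#' @return the nonnegative Fisher criterion value.
#' @export
evaluate_candidate <- function(cohort, phi) {
  stopifnot(inherits(cohort, "mcp_cohort"))
  c <- angles_to_coefficients(phi)
  if (length(c$values) != cohort$M)
    stop("'phi' must have length M - 1 = ", cohort$M - 1L)
  fisher_criterion(cohort_coreness_at(cohort, c))
}

#' Particle swarm configuration
#'
#' Standard constriction-coefficient settings: inertia 0.729 with cognitive
#' and social acceleration 1.49 each. The search space is the angle box
#' `[0, pi/2]^(M-1)`; velocities are reflected at the bounds. The swarm
#' stops at `max_iterations` or when the best criterion value has improved
#' by less than `tolerance` over the last `stall_window` iterations.
#'
#' @param swarm_size number of particles; default `min(100, 10 * (M - 1))`,
#'   resolved when `NULL` at fit time.
#' @param max_iterations iteration cap.
#' @param inertia,cognitive,social PSO velocity-update constants.
#' @param tolerance minimal improvement counted as progress.
#' @param stall_window number of stagnant iterations tolerated.
#' @param seed integer seed for reproducibility (`NULL` = leave RNG alone).
#' @return an object of class `"pso_config"`.
#' @export
pso_config <- function(swarm_size = NULL, max_iterations = 200L,
                       inertia = 0.729, cognitive = 1.49, social = 1.49,
                       tolerance = 1e-6, stall_window = 20L, seed = NULL) {
  if (!is.null(swarm_size) && swarm_size < 2L)
    stop("'swarm_size' must be at least 2")
  if (max_iterations < 1L) stop("'max_iterations' must be positive")
  if (tolerance <= 0) stop("'tolerance' must be positive")
  structure(list(swarm_size = swarm_size,
                 max_iterations = as.integer(max_iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 tolerance = tolerance,
                 stall_window = as.integer(stall_window),
                 seed = seed),
            class = "pso_config")
}

#' Particle swarm maximization of the Fisher criterion
#'
#' Searches the positive unit hypersphere of layer coefficient vectors —
#' parametrized by `M - 1` angles — for the vector that maximizes the
#' Fisher separation of the two groups' coreness. Fully seeded and
#' reproducible; the best-so-far trace is non-decreasing by construction.
#'
#' @param cohort an [mcp_cohort()] object.
#' @param config a [pso_config()].
#' @return an object of class `"pso_fit"`: list with `coefficients` (a
#'   [layer_coefficients()] named by the cohort's layers), `F_star`,
#'   `trace` (per-iteration best `F`), `iterations` and `converged`.
#' @export
pso_optimize <- function(cohort, config = pso_config()) {
  stopifnot(inherits(cohort, "mcp_cohort"), inherits(config, "pso_config"))
  D <- cohort$M - 1L
  if (D < 1L)
    stop("layer-weight optimization needs at least 2 layers")
  np <- config$swarm_size
  if (is.null(np)) np <- min(100L, 10L * D)
  np <- max(2L, as.integer(np))
  if (!is.null(config$seed)) set.seed(config$seed)
  lo <- 0; hi <- pi / 2
  X <- matrix(stats::runif(np * D, lo, hi), np, D)
  V <- matrix(stats::runif(np * D, -(hi - lo), hi - lo) * 0.25, np, D)
  fitness <- apply(X, 1L, function(p) evaluate_candidate(cohort, p))
  Pbest <- X; pbest_f <- fitness
  gi <- which.max(pbest_f)
  gbest <- Pbest[gi, ]; gbest_f <- pbest_f[gi]
  trace <- numeric(config$max_iterations)
  it <- 0L; stall <- 0L; converged <- FALSE
  while (it < config$max_iterations) {
    it <- it + 1L
    r1 <- matrix(stats::runif(np * D), np, D)
    r2 <- matrix(stats::runif(np * D), np, D)
    V <- config$inertia * V +
      config$cognitive * r1 * (Pbest - X) +
      config$social * r2 * sweep(X, 2L, gbest, function(x, g) g - x)
    X <- X + V
    # reflect at the box bounds
    below <- X < lo; X[below] <- lo + (lo - X[below]); V[below] <- -V[below]
    above <- X > hi; X[above] <- hi - (X[above] - hi); V[above] <- -V[above]
    X[X < lo] <- lo; X[X > hi] <- hi  # guard against double overshoot
    fitness <- apply(X, 1L, function(p) evaluate_candidate(cohort, p))
    improved <- fitness > pbest_f
    Pbest[improved, ] <- X[improved, , drop = FALSE]
    pbest_f[improved] <- fitness[improved]
    gi <- which.max(pbest_f)
    if (pbest_f[gi] > gbest_f + config$tolerance) {
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (pbest_f[gi] > gbest_f) {
      gbest_f <- pbest_f[gi]
      gbest <- Pbest[gi, ]
    }
    trace[it] <- gbest_f
    if (stall >= config$stall_window) { converged <- TRUE; break }
  }
  coef <- angles_to_coefficients(gbest, layer_names = cohort$layers)
  structure(list(coefficients = coef, F_star = gbest_f,
                 trace = trace[seq_len(it)], iterations = it,
                 converged = converged, swarm_size = np),
            class = "pso_fit")
}

#' @export
print.pso_fit <- function(x, ...) {
  cat("Particle swarm fit: F* =", format(x$F_star, digits = 6),
      "after", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  print(round(x$coefficients$values, 4))
  invisible(x)
}
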
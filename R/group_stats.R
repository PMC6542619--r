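#' Coreness disruption index
#'
#' Regresses the node-wise difference between a target and a reference mean
#' coreness profile on the reference profile; the ordinary least-squares
#' slope is the coreness disruption index `kappa`. A negative `kappa` means
#' that nodes with high reference coreness lose proportionally more
#' coreness in the target — preferential weakening of the core.
#'
#' @param mean_reference numeric length-`N` reference profile (e.g. the
#'   control-group mean coreness); must not be constant.
#' @param mean_target numeric length-`N` target profile.
#' @return an object of class `"disruption_index"`: list with `kappa`,
#'   `intercept`, `p_value` (two-sided, slope != 0) and `per_node_diff`.
#' @examples
#' ref <- seq(0.1, 0.9, length.out = 10)
#' coreness_disruption_index(ref, 0.8 * ref)$kappa   # exactly -0.2
#' @export
coreness_disruption_index <- function(mean_reference, mean_target) {
  x <- as.numeric(mean_reference)
  y <- as.numeric(mean_target)
  if (length(x) != length(y))
    stop("reference and target profiles must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("profiles must be finite")
  if (stats::sd(x) == 0)
    stop("degenerate reference profile: constant coreness")
  d <- y - x
  # closed-form simple OLS of d on x with the usual t test on the slope
  n <- length(x)
  mx <- mean(x); md <- mean(d)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (d - md)) / sxx
  intercept <- md - slope * mx
  rss <- sum((d - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) {
    if (slope == 0) 1 else 0  # exact (anti)proportional profiles
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  structure(list(kappa = slope, intercept = intercept, p_value = p,
                 per_node_diff = d),
            class = "disruption_index")
}

#' @export
print.disruption_index <- function(x, ...) {
  cat(sprintf("Coreness disruption index kappa = %.4f (p = %.3g)\n",
              x$kappa, x$p_value))
  invisible(x)
}

#' Per-subject coreness disruption index
#'
#' Same regression as [coreness_disruption_index()] with a single subject's
#' coreness vector as the target — used to attach one `kappa` to each
#' patient for behavioral correlation.
#'
#' @param subject_coreness numeric length-`N` coreness of one subject.
#' @param mean_reference reference profile (reference-group mean coreness).
#' @return a `"disruption_index"` object.
#' @export
individual_disruption <- function(subject_coreness, mean_reference) {
  coreness_disruption_index(mean_reference, subject_coreness)
}

# Welch t statistic; returns 0/Inf-safe value (NaN when both variances 0).
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / na + stats::var(b) / nb)
}

#' Permutation t test
#'
#' Two-sided test of a group difference using the Welch t statistic and a
#' permutation null: group labels are reshuffled and the achieved
#' significance is `p = (1 + #{ |t*| >= |t_obs| }) / (1 + n_perm)` (add-one
#' correction, so `p` is never 0 and the test is exact-level). With
#' `exact = TRUE` all distinct group assignments are enumerated instead and
#' `p` is the exact proportion of assignments with `|t*| >= |t_obs|`.
#'
#' @param values_a,values_b numeric vectors (>= 2 observations each).
#' @param n_perm number of random permutations.
#' @param seed optional integer seed.
#' @param exact enumerate all `choose(na + nb, na)` assignments (only
#'   sensible for small samples).
#' @return the p value in `(0, 1]`.
#' @export
permutation_ttest <- function(values_a, values_b, n_perm = 10000L,
                              seed = NULL, exact = FALSE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  if (stats::var(pooled) == 0) {
    warning("zero pooled variance; returning p = 1")
    return(1)
  }
  t_obs <- abs(welch_t(a, b))
  if (is.nan(t_obs)) t_obs <- 0  # equal means, zero variances
  if (exact) {
    idx <- utils::combn(n, na)
    tstar <- apply(idx, 2L, function(ia) {
      abs(welch_t(pooled[ia], pooled[-ia]))
    })
    tstar[is.nan(tstar)] <- 0
    return(mean(tstar >= t_obs - 1e-12))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    ia <- sample.int(n, na)
    ts <- abs(welch_t(pooled[ia], pooled[-ia]))
    if (is.nan(ts)) ts <- 0
    if (ts >= t_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Rough false-discovery-rate threshold
#'
#' The approximate FDR correction for `n` simultaneous tests thresholds the
#' per-test p values at `alpha * (n + 1) / (2 * n)` — close to `alpha / 2`
#' for large `n` (0.025 at `alpha = 0.05`, `n = 68`).
#'
#' @param alpha nominal level in (0, 1).
#' @param n_tests number of post hoc tests (>= 1).
#' @return the corrected threshold.
#' @export
rough_fdr_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n_tests < 1) stop("'n_tests' must be >= 1")
  alpha * (n_tests + 1) / (2 * n_tests)
}

#' Spearman correlation with a behavioral score
#'
#' Rank correlation between a per-subject network statistic (e.g. the
#' individual disruption index) and a behavioral score, with pairwise
#' deletion of missing scores. At least 4 complete pairs are required.
#'
#' @param per_subject_stat numeric vector.
#' @param scores numeric vector of the same length (may contain `NA`).
#' @return list with `rho`, `p` (two-sided) and `n` (pairs used).
#' @export
behavior_correlations <- function(per_subject_stat, scores) {
  x <- as.numeric(per_subject_stat); y <- as.numeric(scores)
  if (length(x) != length(y))
    stop("statistic and scores must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L)
    stop("fewer than 4 complete pairs after missing-value removal")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Statistical configuration for the regional comparison
#'
#' @param alpha nominal level (default 0.05); the node-level threshold is
#'   the rough FDR correction `alpha * (N + 1) / (2 N)`.
#' @param n_permutations permutations per node-level test.
#' @param seed integer seed.
#' @return an object of class `"stats_config"`.
#' @export
stats_config <- function(alpha = 0.05, n_permutations = 10000L, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n_permutations < 1L) stop("'n_permutations' must be positive")
  structure(list(alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "stats_config")
}

#' Node-wise permutation comparison of two coreness groups
#'
#' Runs a two-sided Welch-statistic permutation test at every node and
#' flags nodes whose p value falls below the rough FDR threshold. A single
#' set of label permutations is shared across nodes (the tests are run on
#' the same subjects), which also makes the procedure fast.
#'
#' @param cohort a [cohort_coreness()] object (group A is the reference).
#' @param config a [stats_config()].
#' @return a data frame with one row per node: `node`, `mean_a`, `mean_b`,
#'   `diff` (`mean_b - mean_a`), `p`, `significant`; the FDR threshold is
#'   attached as attribute `"alpha_fdr"`.
#' @export
regional_comparison <- function(cohort, config = stats_config()) {
  stopifnot(inherits(cohort, "cohort_coreness"),
            inherits(config, "stats_config"))
  A <- cohort$group_a; B <- cohort$group_b
  na <- nrow(A); nb <- nrow(B)
  X <- rbind(A, B)
  n <- na + nb
  N <- ncol(X)
  col_welch <- function(ia) {
    Xa <- X[ia, , drop = FALSE]; Xb <- X[-ia, , drop = FALSE]
    ma <- colMeans(Xa); mb <- colMeans(Xb)
    va <- colSums(sweep(Xa, 2L, ma)^2) / (nrow(Xa) - 1L)
    vb <- colSums(sweep(Xb, 2L, mb)^2) / (nrow(Xb) - 1L)
    t <- (ma - mb) / sqrt(va / nrow(Xa) + vb / nrow(Xb))
    t[is.nan(t)] <- 0
    abs(t)
  }
  t_obs <- col_welch(seq_len(na))
  if (!is.null(config$seed)) set.seed(config$seed)
  hits <- integer(N)
  for (p in seq_len(config$n_permutations)) {
    ia <- sample.int(n, na)
    hits <- hits + (col_welch(ia) >= t_obs - 1e-12)
  }
  pvals <- (1 + hits) / (1 + config$n_permutations)
  alpha_fdr <- rough_fdr_threshold(config$alpha, N)
  out <- data.frame(node = cohort$node_labels,
                    mean_a = colMeans(A),
                    mean_b = colMeans(B),
                    diff = colMeans(B) - colMeans(A),
                    p = pvals,
                    significant = pvals < alpha_fdr,
                    row.names = NULL)
  attr(out, "alpha_fdr") <- alpha_fdr
  out
}
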
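#' Multiplex richness profile
#'
#' For a density-filtered multiplex, the richness of node `i` is the layer
#' weighted sum of its per-layer strengths, `mu_i = sum_m c_m * s_i[m]`,
#' where `s_i[m]` is the sum of the retained link weights of node `i` in
#' layer `m`. Splitting each strength into links towards nodes ranked
#' strictly above `i` in richness (`s_i[m]+`) and the rest gives the
#' richness towards richer nodes, `mu_i+ = sum_m c_m * s_i[m]+`, whose
#' maximum along the richness ranking marks the rich-core boundary.
#'
#' Nodes are ranked by decreasing `mu` with ties broken by ascending node
#' index; tied nodes do not count as "richer", so ties contribute to `s-`.
#'
#' @param net a filtered `multiplex` object.
#' @param c a [layer_coefficients()] object or nonnegative numeric vector of
#'   length `M`.
#' @return an object of class `"richness_profile"`: a list with `mu`,
#'   `mu_plus` (length-`N` vectors), `per_layer_strength`,
#'   `per_layer_strength_plus` (`M x N` matrices) and `rank_order` (node
#'   indices in decreasing richness).
#' @export
multiplex_richness <- function(net, c) {
  stopifnot(inherits(net, "multiplex"))
  cv <- as_coefficient_values(c)
  M <- n_layers(net)
  N <- n_nodes(net)
  if (length(cv) != M)
    stop("coefficient vector has length ", length(cv),
         " but the multiplex has ", M, " layers")
  s <- matrix(0, M, N)
  for (m in seq_len(M)) s[m, ] <- colSums(net$W[, , m])
  mu <- as.numeric(cv %*% s)
  rank_order <- order(-mu, seq_len(N))
  pos <- integer(N)
  pos[rank_order] <- seq_len(N)
  # richer[i, j] is TRUE when j is ranked strictly above i
  richer <- outer(pos, pos, `>`)
  s_plus <- matrix(0, M, N)
  for (m in seq_len(M)) s_plus[m, ] <- rowSums(net$W[, , m] * richer)
  mu_plus <- as.numeric(cv %*% s_plus)
  structure(list(mu = mu, mu_plus = mu_plus,
                 per_layer_strength = s,
                 per_layer_strength_plus = s_plus,
                 rank_order = rank_order,
                 nodes = net$nodes),
            class = "richness_profile")
}

#' Detect the rich core from a richness profile
#'
#' Walks the nodes in decreasing richness order and places the core boundary
#' at the first rank position where the richness-towards-richer-nodes
#' `mu+` attains its maximum; all nodes up to and including the boundary
#' node form the core. The rule is fully deterministic. When every `mu+`
#' is zero (e.g. an empty multiplex) the core is empty.
#'
#' @param profile a `"richness_profile"` object.
#' @return a logical vector of core membership, in node order.
#' @export
detect_core <- function(profile) {
  stopifnot(inherits(profile, "richness_profile"))
  mup <- profile$mu_plus[profile$rank_order]
  N <- length(mup)
  core <- logical(N)
  if (all(mup == 0)) return(core)
  rstar <- which.max(mup)  # first occurrence of the maximum
  core[profile$rank_order[seq_len(rstar)]] <- TRUE
  core
}

#' Per-node coreness over the density sweep
#'
#' The rich-core of a single filtered multiplex is deterministic, so a
#' probabilistic notion of core membership is obtained by sweeping the
#' density threshold: for every target mean degree `k = 1 .. N-1` the
#' multiplex is filtered, the richness profile computed, and the rich core
#' detected. The coreness of node `i` is the fraction of thresholds at
#' which it fell inside the core,
#' `C_i = (1 / (N - 1)) * sum_k delta_i[k]`, a value in `[0, 1]`.
#'
#' @param net a normalized `multiplex` object.
#' @param c layer coefficients (see [multiplex_richness()]).
#' @param engine `"cpp"` (fast path used throughout the package) or
#'   `"reference"` (plain-R composition of [filter_by_mean_degree()],
#'   [multiplex_richness()] and [detect_core()]).
#' @return an object of class `"coreness"`: list with `coreness` (named
#'   length-`N` vector) and `indicator` (`(N-1) x N` 0/1 matrix of
#'   per-threshold core membership).
#' @examples
#' set.seed(1)
#' W <- matrix(runif(36), 6, 6); W <- (W + t(W)) / 2; diag(W) <- 0
#' net <- normalize_multiplex(multiplex(list(W)))
#' coreness(net, 1)$coreness
#' @export
coreness <- function(net, c, engine = c("cpp", "reference")) {
  stopifnot(inherits(net, "multiplex"))
  engine <- match.arg(engine)
  cv <- as_coefficient_values(c)
  if (length(cv) == 1L && n_layers(net) > 1L)
    stop("coefficient vector has length 1 but the multiplex has ",
         n_layers(net), " layers")
  if (length(cv) != n_layers(net))
    stop("coefficient vector has length ", length(cv),
         " but the multiplex has ", n_layers(net), " layers")
  N <- n_nodes(net)
  if (engine == "cpp") {
    cache <- coreness_cache(net)
    return(coreness_from_cache(cache, cv))
  }
  K <- N - 1L
  delta <- matrix(0L, K, N)
  for (k in seq_len(K)) {
    filt <- filter_by_mean_degree(net, k)
    prof <- multiplex_richness(filt, cv)
    delta[k, ] <- as.integer(detect_core(prof))
  }
  C <- colSums(delta) / K
  names(C) <- net$nodes
  structure(list(coreness = C, indicator = delta, nodes = net$nodes),
            class = "coreness")
}

#' @export
print.coreness <- function(x, ...) {
  cat("Coreness over", nrow(x$indicator), "density thresholds\n")
  print(round(x$coreness, 3))
  invisible(x)
}

#' Precompute the density-sweep cache of a multiplex
#'
#' Stores, per layer, the positive links sorted by decreasing weight (ties
#' broken lexicographically). Because the retained link set at mean degree
#' `k` is a prefix of this ordering, the whole `k = 1..N-1` sweep for any
#' coefficient vector can then be evaluated without re-thresholding —
#' the kernel behind repeated evaluations during layer-weight optimization.
#'
#' @param net a normalized `multiplex` object.
#' @return an object of class `"coreness_cache"`.
#' @export
coreness_cache <- function(net) {
  stopifnot(inherits(net, "multiplex"))
  M <- n_layers(net)
  ei <- ej <- vector("list", M)
  ew <- vector("list", M)
  for (m in seq_len(M)) {
    E <- sorted_edges(net$W[, , m])
    ei[[m]] <- E[, 1L]; ej[[m]] <- E[, 2L]; ew[[m]] <- E[, 3L]
  }
  off <- c(0L, cumsum(vapply(ei, length, integer(1))))
  structure(list(ei = as.integer(unlist(ei)) - 1L,
                 ej = as.integer(unlist(ej)) - 1L,
                 ew = as.numeric(unlist(ew)),
                 off = as.integer(off),
                 N = n_nodes(net), M = M, nodes = net$nodes),
            class = "coreness_cache")
}

#' Evaluate the coreness sweep from a precomputed cache
#'
#' @param cache a [coreness_cache()] object.
#' @param c layer coefficients.
#' @return a `"coreness"` object (see [coreness()]).
#' @export
coreness_from_cache <- function(cache, c) {
  stopifnot(inherits(cache, "coreness_cache"))
  cv <- as_coefficient_values(c)
  if (length(cv) != cache$M)
    stop("coefficient vector has length ", length(cv),
         " but the cache has ", cache$M, " layers")
  res <- coreness_sweep_cpp(cache$ei, cache$ej, cache$ew, cache$off,
                            cache$N, cache$M, cv)
  C <- res$coreness
  names(C) <- cache$nodes
  structure(list(coreness = C, indicator = res$indicator,
                 nodes = cache$nodes),
            class = "coreness")
}
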
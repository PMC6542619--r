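#' Construct a multiplex network
#'
#' A multiplex network is a set of `M` weighted undirected layers sharing the
#' same `N` nodes, with no interlayer links. Each layer is an `N x N`
#' symmetric nonnegative matrix with a zero diagonal, typically one
#' connectivity modality (e.g. DWI tractography counts, fMRI correlation,
#' band-specific MEG coherence).
#'
#' @param layers a list of `N x N` symmetric numeric matrices, or a 3-D array
#'   with dimensions `N x N x M`.
#' @param nodes character vector of node labels (defaults to the dimnames of
#'   the first layer, or `"n1"..."nN"`).
#' @param layer_names character vector of layer names (defaults to list names
#'   or `"layer1"..."layerM"`).
#' @param tol tolerance for the symmetry check.
#' @return an object of class `"multiplex"`: a list with elements `W`
#'   (`N x N x M` array), `nodes` and `layers`.
#' @examples
#' W <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' net <- multiplex(list(a = W, b = 2 * W))
#' net
#' @export
multiplex <- function(layers, nodes = NULL, layer_names = NULL, tol = 1e-9) {
  if (is.array(layers) && length(dim(layers)) == 3L) {
    layers <- lapply(seq_len(dim(layers)[3L]),
                     function(m) layers[, , m, drop = TRUE])
  }
  if (!is.list(layers) || length(layers) < 1L)
    stop("'layers' must be a nonempty list of matrices or an N x N x M array")
  M <- length(layers)
  if (is.null(layer_names)) {
    layer_names <- names(layers)
    if (is.null(layer_names) || any(!nzchar(layer_names)))
      layer_names <- paste0("layer", seq_len(M))
  }
  first <- layers[[1L]]
  N <- nrow(first)
  if (is.null(nodes)) {
    nodes <- rownames(first)
    if (is.null(nodes)) nodes <- paste0("n", seq_len(N))
  }
  if (N < 3L) stop("a multiplex needs N >= 3 nodes, got N = ", N)
  W <- array(0, dim = c(N, N, M), dimnames = list(nodes, nodes, layer_names))
  for (m in seq_len(M)) {
    Wm <- as.matrix(layers[[m]])
    validate_layer(Wm, tol = tol, what = paste0("layer '", layer_names[m], "'"))
    if (nrow(Wm) != N)
      stop("layer '", layer_names[m], "' has ", nrow(Wm),
           " nodes; expected ", N)
    dimnames(Wm) <- NULL
    W[, , m] <- Wm
  }
  structure(list(W = W, nodes = nodes, layers = layer_names),
            class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat("Multiplex network: ", n_nodes(x), " nodes x ", n_layers(x),
      " layers\n", sep = "")
  cat("  layers: ", paste(x$layers, collapse = ", "), "\n", sep = "")
  rng <- range(x$W)
  cat(sprintf("  weight range: [%.4g, %.4g]\n", rng[1L], rng[2L]))
  invisible(x)
}

#' Number of nodes / layers of a multiplex
#' @param net a `multiplex` object.
#' @return an integer.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_layers <- function(net) length(net$layers)

# Validate a single layer matrix: square, symmetric, finite, nonnegative,
# zero diagonal. Errors name the first offending entry.
validate_layer <- function(W, tol = 1e-9, what = "layer") {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop(what, " is not a square matrix")
  if (nrow(W) < 3L)
    stop(what, " has fewer than 3 nodes")
  bad <- which(!is.finite(W))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(W))
    stop(what, " has a non-finite entry at (", ij[1L], ",", ij[2L], ")")
  }
  bad <- which(W < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(W))
    stop(what, " has a negative weight at (", ij[1L], ",", ij[2L], "): ",
         W[bad[1L]])
  }
  asym <- abs(W - t(W))
  if (max(asym) > tol) {
    ij <- arrayInd(which.max(asym), dim(W))
    stop(what, " is asymmetric beyond tolerance at (", ij[1L], ",", ij[2L],
         "): ", W[ij[1L], ij[2L]], " vs ", W[ij[2L], ij[1L]])
  }
  if (any(diag(W) != 0))
    stop(what, " has nonzero diagonal entries")
  invisible(TRUE)
}

#' Min-max normalize a connectivity layer
#'
#' Linearly rescales the off-diagonal weights of one layer to `[0, 1]`:
#' `w <- (w - w_min) / (w_max - w_min)`, with `w_min`/`w_max` taken over the
#' off-diagonal entries. This makes weights comparable across modalities that
#' live on different scales (fiber counts, correlations, coherences). A
#' constant layer (`w_max == w_min`) is mapped to all zeros with a warning.
#'
#' @param W a square symmetric nonnegative matrix with zero diagonal.
#' @param tol symmetry tolerance.
#' @return the rescaled matrix; the diagonal stays zero.
#' @examples
#' W <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3)
#' normalize_layer(W)   # off-diagonal weights become 0, 0.5, 1
#' @export
normalize_layer <- function(W, tol = 1e-9) {
  validate_layer(W, tol = tol)
  off <- row(W) != col(W)
  wmin <- min(W[off])
  wmax <- max(W[off])
  if (wmax == wmin) {
    warning("constant layer (w_max == w_min): all off-diagonal weights set to 0")
    W[off] <- 0
    return(W)
  }
  W[off] <- (W[off] - wmin) / (wmax - wmin)
  diag(W) <- 0
  W
}

#' Normalize every layer of a multiplex
#'
#' Applies [normalize_layer()] to each layer independently, once, at
#' multiplex construction time (not re-applied during the density sweep).
#'
#' @param net a `multiplex` object.
#' @return a `multiplex` with all weights in `[0, 1]`.
#' @export
normalize_multiplex <- function(net) {
  stopifnot(inherits(net, "multiplex"))
  for (m in seq_len(n_layers(net)))
    net$W[, , m] <- normalize_layer(net$W[, , m])
  net
}

# Edge list of one layer: columns i, j (i < j), w, restricted to w > 0,
# sorted by decreasing weight with ties broken by lexicographic (i, j).
sorted_edges <- function(Wm) {
  N <- nrow(Wm)
  ut <- which(upper.tri(Wm) & Wm > 0)
  if (!length(ut))
    return(cbind(i = integer(0), j = integer(0), w = numeric(0)))
  ij <- arrayInd(ut, dim(Wm))
  w <- Wm[ut]
  ord <- order(-w, ij[, 1L], ij[, 2L])
  cbind(i = ij[ord, 1L], j = ij[ord, 2L], w = w[ord])
}

# Number of links retained at mean binary degree k (half-up rounding).
links_at_degree <- function(N, k) as.integer(floor(N * k / 2 + 0.5))

#' Density-filter a multiplex at a target mean degree
#'
#' Per layer independently, retains the `round(N * k / 2)` strongest links
#' (so that the average binary node degree is `k` where exact) and removes
#' the rest. Surviving links keep their weights: the filtered multiplex is
#' sparse but still weighted. Weight ties at the retention boundary are
#' broken by lexicographic node-index order, so the operation is
#' deterministic. Zero-weight links are never counted as retained; a layer
#' with fewer positive links than the quota keeps them all, and its realized
#' mean degree is then below `k`.
#'
#' @param net a `multiplex` object (weights assumed normalized).
#' @param k target average node degree, an integer in `1..N-1`.
#' @return the filtered `multiplex`.
#' @export
filter_by_mean_degree <- function(net, k) {
  stopifnot(inherits(net, "multiplex"))
  N <- n_nodes(net)
  if (length(k) != 1L || !is.finite(k) || k != as.integer(k) ||
      k < 1L || k > N - 1L)
    stop("'k' must be an integer in 1..N-1 (N = ", N, "), got ", k)
  L <- links_at_degree(N, k)
  for (m in seq_len(n_layers(net))) {
    E <- sorted_edges(net$W[, , m])
    keep <- E[seq_len(min(L, nrow(E))), , drop = FALSE]
    Wm <- matrix(0, N, N)
    if (nrow(keep)) {
      Wm[cbind(keep[, 1L], keep[, 2L])] <- keep[, 3L]
      Wm[cbind(keep[, 2L], keep[, 1L])] <- keep[, 3L]
    }
    net$W[, , m] <- Wm
  }
  net
}
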
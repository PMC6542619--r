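#' Layer contribution coefficients
#'
#' The vector `c` weights the contribution of each layer to the multiplex
#' richness. Its components must be nonnegative; since the core-periphery
#' analysis is invariant to a positive rescaling of `c`, the vector is
#' conventionally constrained to the positive section of the unit
#' hypersphere and can be parametrized by `M - 1` angles in `[0, pi/2]`.
#'
#' @param values numeric vector of `M` nonnegative layer weights.
#' @param angles optional numeric vector of `M - 1` hypersphere angles; when
#'   supplied it must reproduce `values` (stored for round-tripping).
#' @param layer_names optional names for the components.
#' @return an object of class `"layer_coefficients"`.
#' @seealso [angles_to_coefficients()], [coefficients_to_angles()]
#' @export
layer_coefficients <- function(values, angles = NULL, layer_names = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("layer coefficients must be finite and nonnegative")
  if (all(values == 0))
    stop("layer coefficients cannot be all zero")
  if (!is.null(layer_names)) {
    if (length(layer_names) != length(values))
      stop("'layer_names' length does not match 'values'")
    names(values) <- layer_names
  }
  if (!is.null(angles)) {
    if (length(angles) != length(values) - 1L)
      stop("'angles' must have length M - 1")
    nrm <- sqrt(sum(values^2))
    if (abs(nrm - 1) > 1e-9)
      stop("coefficients constructed from angles must have unit norm")
  }
  structure(list(values = values, angles = angles),
            class = "layer_coefficients")
}

#' @export
print.layer_coefficients <- function(x, ...) {
  cat("Layer coefficients (M = ", length(x$values), "):\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

# Coerce a bare numeric vector for internal use.
as_coefficient_values <- function(c) {
  if (inherits(c, "layer_coefficients")) c$values else as.numeric(c)
}

#' Map hypersphere angles to layer coefficients
#'
#' Parametrizes the positive section of the unit `M`-sphere by `M - 1`
#' angles `phi` in `[0, pi/2]` using nested sine/cosine products:
#' `c_1 = sin(phi_1) ... sin(phi_{M-1})`,
#' `c_j = sin(phi_1) ... sin(phi_{M-j}) * cos(phi_{M-j+1})` for `j >= 2`,
#' down to `c_M = cos(phi_1)`. All components are nonnegative and the
#' Euclidean norm is 1 by construction. Searching over angles rather than
#' raw coefficients removes the redundant scale dimension.
#'
#' @param phi numeric vector of angles in `[0, pi/2]`.
#' @param layer_names optional component names.
#' @return a [layer_coefficients()] object with unit norm.
#' @examples
#' angles_to_coefficients(rep(0, 8))$values      # one-hot on the last layer
#' angles_to_coefficients(rep(pi / 2, 8))$values # one-hot on the first layer
#' @export
angles_to_coefficients <- function(phi, layer_names = NULL) {
  phi <- as.numeric(phi)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > pi / 2))
    stop("all angles must lie in [0, pi/2]")
  M <- length(phi) + 1L
  if (M == 1L)
    return(layer_coefficients(1, angles = numeric(0),
                              layer_names = layer_names))
  vals <- numeric(M)
  # running product sin(phi_1)...sin(phi_k)
  run <- cumprod(sin(phi))
  vals[M] <- cos(phi[1L])
  if (M > 2L)
    for (j in 2:(M - 1L)) vals[j] <- run[M - j] * cos(phi[M - j + 1L])
  vals[1L] <- run[M - 1L]
  vals[vals < 0 & vals > -1e-15] <- 0  # clamp -0 style round-off
  layer_coefficients(vals, angles = phi, layer_names = layer_names)
}

#' Recover hypersphere angles from nonnegative unit coefficients
#'
#' Inverse of [angles_to_coefficients()] on the closed positive octant.
#' Where the running sine product vanishes the remaining angles are
#' unidentified and set to 0.
#'
#' @param c a [layer_coefficients()] object or nonnegative numeric vector of
#'   unit Euclidean norm.
#' @return numeric vector of `M - 1` angles in `[0, pi/2]`.
#' @export
coefficients_to_angles <- function(c) {
  v <- as_coefficient_values(c)
  nrm <- sqrt(sum(v^2))
  if (abs(nrm - 1) > 1e-6)
    stop("coefficients must have unit Euclidean norm")
  M <- length(v)
  phi <- numeric(M - 1L)
  run <- 1
  for (k in seq_len(M - 1L)) {
    if (run <= 1e-300) {
      phi[k] <- 0
    } else {
      arg <- min(1, max(-1, v[M - k + 1L] / run))
      phi[k] <- acos(arg)
      phi[k] <- min(pi / 2, max(0, phi[k]))
      run <- run * sin(phi[k])
    }
  }
  phi
}
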
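#' Attack configuration
#'
#' Parameters of the targeted disconnection process: a fraction of the
#' distinct node pairs carrying weight in any layer is attacked; each
#' attacked pair has its weight reduced by the fraction `reduction`
#' (multiplicatively, `w <- w * (1 - R)`) in every layer simultaneously.
#' Pairs are drawn by sampling two endpoints with probability proportional
#' to node coreness (`mode = "core"`) or its complement
#' (`mode = "periphery"`).
#'
#' @param link_fraction fraction of eligible pairs to attack, in `[0, 1]`.
#' @param reduction fractional weight decrease `R` in `[0, 1]`.
#' @param mode `"core"` or `"periphery"`.
#' @param n_rand number of randomized replicates (used by
#'   [disruption_sweep()]).
#' @param seed integer seed.
#' @return an object of class `"attack_config"`.
#' @export
attack_config <- function(link_fraction, reduction = 0.75,
                          mode = c("core", "periphery"),
                          n_rand = 3L, seed = NULL) {
  mode <- match.arg(mode)
  if (link_fraction < 0 || link_fraction > 1)
    stop("'link_fraction' must be in [0, 1]")
  if (reduction < 0 || reduction > 1)
    stop("'reduction' must be in [0, 1]")
  if (n_rand < 1L) stop("'n_rand' must be positive")
  structure(list(link_fraction = link_fraction, reduction = reduction,
                 mode = mode, n_rand = as.integer(n_rand), seed = seed),
            class = "attack_config")
}

#' Node attack probabilities
#'
#' Converts a coreness vector into the endpoint-sampling distribution of
#' the disconnection process: proportional to `C_i` in core mode and to
#' `1 - C_i` in periphery mode. If every weight is zero (e.g. all-zero
#' coreness in core mode) a uniform distribution is used with a warning.
#'
#' @param coreness a `"coreness"` object or numeric vector in `[0, 1]`.
#' @param mode `"core"` or `"periphery"`.
#' @return a probability vector summing to 1.
#' @export
node_attack_probabilities <- function(coreness, mode = c("core", "periphery")) {
  mode <- match.arg(mode)
  C <- if (inherits(coreness, "coreness")) coreness$coreness else
    as.numeric(coreness)
  if (any(C < 0) || any(C > 1)) stop("coreness values must lie in [0, 1]")
  w <- if (mode == "core") C else 1 - C
  s <- sum(w)
  if (s == 0) {
    warning("all attack weights are zero; falling back to uniform sampling")
    return(rep(1 / length(C), length(C)))
  }
  unname(w / s)
}

#' Targeted disconnection of a multiplex
#'
#' Stochastic attack process: `L = round(link_fraction * P)` distinct node
#' pairs are selected, where `P` is the number of distinct pairs with
#' nonzero weight in at least one layer. Each selection draws endpoint `i`
#' and then `j` with the node attack probabilities (draws with `i == j` or
#' an already attacked pair are rejected and redrawn), the pair's weight is
#' multiplied by `1 - reduction` in every layer (or in the `layers` subset)
#' and the pair is excluded from re-selection. After the loop each layer is
#' min-max renormalized. Seeded and bit-reproducible.
#'
#' @param net a normalized `multiplex` object.
#' @param coreness the subject's coreness (vector or `"coreness"` object).
#' @param config an [attack_config()].
#' @param layers optional character/integer subset of layers whose weights
#'   are reduced (pair selection is unaffected); default all layers.
#' @param renormalize re-apply [normalize_layer()] per layer after the
#'   attack (the process's final step); set `FALSE` to inspect raw reduced
#'   weights.
#' @return an object of class `"attack_result"`: list with
#'   `attacked_multiplex`, `attacked_pairs` (`L x 2` index matrix) and
#'   `kappa_after` (`NA` unless both `coefficients` and `reference_mean`
#'   are supplied).
#' @param coefficients,reference_mean optional layer coefficients and
#'   reference mean-coreness profile; when both are given the attacked
#'   subject's disruption index against the reference is computed.
#' @export
attack_multiplex <- function(net, coreness, config, layers = NULL,
                             renormalize = TRUE,
                             coefficients = NULL, reference_mean = NULL) {
  stopifnot(inherits(net, "multiplex"), inherits(config, "attack_config"))
  N <- n_nodes(net)
  M <- n_layers(net)
  if (is.null(layers)) {
    lidx <- seq_len(M)
  } else if (is.character(layers)) {
    lidx <- match(layers, net$layers)
    if (anyNA(lidx)) stop("unknown layer name(s): ",
                          paste(layers[is.na(lidx)], collapse = ", "))
  } else lidx <- as.integer(layers)
  p <- node_attack_probabilities(coreness, config$mode)
  # eligible pair count: distinct pairs with weight > 0 in any layer
  any_w <- apply(net$W, c(1L, 2L), max) > 0
  P <- sum(any_w[upper.tri(any_w)])
  L <- as.integer(floor(config$link_fraction * P + 0.5))
  # pairs samplable at all: both endpoints must have positive probability
  support <- which(p > 0)
  n_avail <- length(support) * (length(support) - 1L) / 2L
  if (L > n_avail) {
    warning("requested ", L, " pairs but only ", n_avail,
            " are reachable; attacking ", n_avail)
    L <- n_avail
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  attacked <- matrix(0L, L, 2L)
  excluded <- matrix(FALSE, N, N)
  count <- 0L
  while (count < L) {
    i <- sample.int(N, 1L, prob = p)
    j <- sample.int(N, 1L, prob = p)
    if (i == j || excluded[i, j]) next
    excluded[i, j] <- excluded[j, i] <- TRUE
    count <- count + 1L
    attacked[count, ] <- c(min(i, j), max(i, j))
    for (m in lidx) {
      net$W[i, j, m] <- net$W[i, j, m] * (1 - config$reduction)
      net$W[j, i, m] <- net$W[i, j, m]
    }
  }
  if (renormalize) {
    for (m in seq_len(M)) {
      Wm <- net$W[, , m]
      off <- Wm[row(Wm) != col(Wm)]
      if (max(off) > min(off))
        net$W[, , m] <- normalize_layer(Wm)
      # constant layers are left untouched (nothing to rescale)
    }
  }
  kappa_after <- NA_real_
  if (!is.null(coefficients) && !is.null(reference_mean)) {
    Ck <- coreness(net, coefficients)$coreness
    kappa_after <- coreness_disruption_index(reference_mean, Ck)$kappa
  }
  structure(list(attacked_multiplex = net, attacked_pairs = attacked,
                 kappa_after = kappa_after),
            class = "attack_result")
}

#' Disruption index under increasing attack fractions
#'
#' For every subject of a reference cohort, every replicate and every
#' attack fraction, runs the targeted disconnection, recomputes the
#' coreness of the attacked multiplex, and measures its disruption index
#' against the unattacked cohort mean coreness. This traces how fast the
#' core-periphery structure degrades under core- versus
#' periphery-targeted damage.
#'
#' @param reference_cohort list of normalized `multiplex` objects.
#' @param c layer coefficients used for every coreness computation.
#' @param fractions numeric grid of link fractions.
#' @param reduction fractional weight decrease per attacked pair.
#' @param mode `"core"` or `"periphery"`.
#' @param n_rand randomized replicates per subject and fraction.
#' @param seed integer seed for the whole sweep.
#' @return a data frame with columns `fraction`, `replicate`, `subject`,
#'   `kappa` (`length(fractions) * n_rand * length(reference_cohort)` rows).
#' @export
disruption_sweep <- function(reference_cohort, c,
                             fractions = seq(0.05, 0.40, by = 0.05),
                             reduction = 0.75,
                             mode = c("core", "periphery"),
                             n_rand = 3L, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(reference_cohort) ||
      !all(vapply(reference_cohort, inherits, TRUE, "multiplex")))
    stop("'reference_cohort' must be a nonempty list of multiplex objects")
  if (!is.null(seed)) set.seed(seed)
  cv <- as_coefficient_values(c)
  base <- lapply(reference_cohort, function(net) coreness(net, cv)$coreness)
  ref_mean <- colMeans(do.call(rbind, base))
  rows <- vector("list", length(fractions) * n_rand * length(reference_cohort))
  ri <- 0L
  for (f in fractions) {
    for (r in seq_len(n_rand)) {
      for (s in seq_along(reference_cohort)) {
        cfg <- attack_config(link_fraction = f, reduction = reduction,
                             mode = mode)
        res <- attack_multiplex(reference_cohort[[s]], base[[s]], cfg)
        Ck <- coreness(res$attacked_multiplex, cv)$coreness
        ri <- ri + 1L
        rows[[ri]] <- data.frame(fraction = f, replicate = r, subject = s,
                                 kappa = coreness_disruption_index(
                                   ref_mean, Ck)$kappa)
      }
    }
  }
  do.call(rbind, rows)
}
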
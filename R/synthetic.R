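#' Synthetic cohort configuration
#'
#' Describes a seeded two-group cohort of multiplex networks with a planted
#' core: a graded node-prominence gradient (expected link weight scales
#' with the endpoints' prominences, which decline from the planted core
#' to the periphery), three layer
#' families emulating DWI (sparse, heavy-tailed), fMRI (dense) and MEG
#' band coherence (seven bands sharing a latent template, hence
#' inter-layer redundancy), patient networks derived from control-like
#' networks by a core-targeted disconnection restricted to a subset of
#' affected layers, and behavior scores that decrease with the planted
#' disruption severity.
#'
#' @param n_nodes number of nodes (default 68).
#' @param layer_spec named character vector mapping layer name to family
#'   (`"meg_like"`, `"fmri_like"`, `"dwi_like"`); default 7 MEG bands +
#'   fMRI + DWI, 9 layers.
#' @param n_core planted core size (default 14).
#' @param n_hc,n_ad group sizes (defaults 26 controls, 23 patients).
#' @param affected_layers layers carrying the group effect (default
#'   `c("dwi", "fmri", "alpha1")`).
#' @param severity_range interval within `[0, 1]` from which patient
#'   severities are drawn uniformly.
#' @param attack_reduction fractional weight decrease of attacked links.
#' @param behavior_noise_sd Gaussian noise on the behavior scores.
#' @param seed integer seed for the whole cohort.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_nodes = 68L,
                             layer_spec = c(
                               delta = "meg_like", theta = "meg_like",
                               alpha1 = "meg_like", alpha2 = "meg_like",
                               beta1 = "meg_like", beta2 = "meg_like",
                               gamma = "meg_like", fmri = "fmri_like",
                               dwi = "dwi_like"),
                             n_core = 14L, n_hc = 26L, n_ad = 23L,
                             affected_layers = c("dwi", "fmri", "alpha1"),
                             severity_range = c(0.25, 1),
                             attack_reduction = 0.75,
                             behavior_noise_sd = 1,
                             seed = NULL) {
  if (n_core >= n_nodes) stop("'n_core' must be below 'n_nodes'")
  if (n_hc < 2L || n_ad < 2L) stop("group sizes must be at least 2")
  if (!all(layer_spec %in% c("meg_like", "fmri_like", "dwi_like")))
    stop("unknown layer family in 'layer_spec'")
  if (is.null(names(layer_spec)) || any(!nzchar(names(layer_spec))))
    stop("'layer_spec' must be a named vector")
  if (!all(affected_layers %in% names(layer_spec)))
    stop("'affected_layers' must be a subset of the layer names")
  if (length(severity_range) != 2L || severity_range[1L] > severity_range[2L] ||
      severity_range[1L] < 0 || severity_range[2L] > 1)
    stop("'severity_range' must be an interval within [0, 1]")
  structure(list(n_nodes = as.integer(n_nodes), layer_spec = layer_spec,
                 n_core = as.integer(n_core), n_hc = as.integer(n_hc),
                 n_ad = as.integer(n_ad),
                 affected_layers = affected_layers,
                 severity_range = severity_range,
                 attack_reduction = attack_reduction,
                 behavior_noise_sd = behavior_noise_sd, seed = seed),
            class = "synthetic_config")
}

# Node prominence gradient: expected link weight of a pair scales with the
# product of its endpoints' prominences, declining linearly from 1 at the
# top-ranked node to 0.4 at the weakest. This plants a graded rich core (the
# first n_core nodes) while keeping ranks labile enough that disruption can
# reorder them, as in measured connectomes.
node_prominence <- function(N) seq(1, 0.4, length.out = N)

# Symmetric prominence-modulated weight draw.
gradient_weights <- function(N, q) {
  W <- matrix(0, N, N)
  ut <- which(upper.tri(W))
  ij <- arrayInd(ut, dim(W))
  W[ut] <- stats::rbeta(length(ut), 2, 2) * q[ij[, 1L]] * q[ij[, 2L]]
  W + t(W)
}

# Deterministic per-pair uniform in [0, 1); the same for every subject and
# seed, used for structural skeletons shared across a cohort.
pair_hash <- function(i, j) {
  (sin(i * 12.9898 + j * 78.233) * 43758.5453123) %% 1
}

# Entrywise multiplicative lognormal jitter (symmetric).
jitter_weights <- function(W, sdlog = 0.1) {
  N <- nrow(W)
  ut <- upper.tri(W)
  W[ut] <- W[ut] * stats::rlnorm(sum(ut), 0, sdlog)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

#' Generate one control-like multiplex subject
#'
#' Draws the prominence-gradient layers described in [synthetic_config()]:
#' every layer's expected pair weight scales with the product of its
#' endpoints' prominences (declining from the planted core to the
#' periphery), with a subject-level lognormal perturbation of the
#' prominences so individual rankings vary around the population gradient.
#' MEG-like layers mix a shared latent template with band-specific noise,
#' the fMRI-like layer is dense, and the DWI-like layer is sparsified over
#' a fixed structural skeleton common to all subjects (pair retention
#' probability increasing with prominence) with heavy-tailed multiplicative
#' weights. Every layer gets entrywise multiplicative noise and is min-max
#' normalized. Uses the current RNG state; seed with `set.seed()` or via
#' [generate_cohort()].
#'
#' @param config a [synthetic_config()].
#' @return a normalized `multiplex` object; the planted core indices are
#'   attached as attribute `"core"`.
#' @export
generate_hc_subject <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  N <- config$n_nodes
  core_idx <- seq_len(config$n_core)
  nodes <- paste0("roi", formatC(seq_len(N), width = 2, flag = "0"))
  q_pop <- node_prominence(N)
  q <- q_pop * exp(stats::rnorm(N, 0, 0.1))  # subject-level rank lability
  ut <- which(upper.tri(matrix(0, N, N)))
  ij <- arrayInd(ut, c(N, N))
  template <- gradient_weights(N, q)
  layers <- vector("list", length(config$layer_spec))
  names(layers) <- names(config$layer_spec)
  for (li in seq_along(config$layer_spec)) {
    fam <- config$layer_spec[[li]]
    if (fam == "meg_like") {
      Wm <- 0.65 * template + 0.35 * gradient_weights(N, q)
    } else if (fam == "fmri_like") {
      Wm <- gradient_weights(N, q)
    } else {  # dwi_like: sparse and heavy-tailed before normalization
      Wm <- gradient_weights(N, q)
      # the binary skeleton is a fixed function of the node pair, shared by
      # every subject: anatomical backbones are largely common across
      # individuals, and only the streamline weights vary
      keep_p <- 0.15 + 0.7 * q_pop[ij[, 1L]] * q_pop[ij[, 2L]]
      keep <- pair_hash(ij[, 1L], ij[, 2L]) < keep_p
      Wm[ut] <- Wm[ut] * keep * stats::rlnorm(length(ut), 0, 0.5)
      Wm[lower.tri(Wm)] <- t(Wm)[lower.tri(Wm)]
    }
    Wm <- jitter_weights(Wm, sdlog = 0.1)
    diag(Wm) <- 0
    layers[[li]] <- Wm
  }
  net <- normalize_multiplex(multiplex(layers, nodes = nodes))
  attr(net, "core") <- core_idx
  net
}

#' Generate one patient-like multiplex subject
#'
#' Draws a control-like subject, then applies the core-targeted
#' disconnection of [attack_multiplex()] with
#' `link_fraction = 0.4 * severity` and the configured weight reduction,
#' restricted to the affected layers. The attacked pairs are returned as
#' ground truth for recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param severity disruption severity within the configured range.
#' @return a list with `net` (the attacked, renormalized multiplex) and
#'   `ground_truth` (list with `severity` and `attacked_pairs`).
#' @export
generate_ad_subject <- function(config, severity) {
  stopifnot(inherits(config, "synthetic_config"))
  if (severity < 0 || severity > 1)
    stop("'severity' must be in [0, 1]")
  net <- generate_hc_subject(config)
  if (severity == 0)
    return(list(net = net,
                ground_truth = list(severity = 0,
                                    attacked_pairs = matrix(0L, 0L, 2L))))
  C <- coreness(net, rep(1 / sqrt(n_layers(net)), n_layers(net)))
  cfg <- attack_config(link_fraction = 0.4 * severity,
                       reduction = config$attack_reduction, mode = "core")
  res <- attack_multiplex(net, C, cfg, layers = config$affected_layers)
  out <- res$attacked_multiplex
  attr(out, "core") <- attr(net, "core")
  list(net = out,
       ground_truth = list(severity = severity,
                           attacked_pairs = res$attacked_pairs))
}

#' Generate behavior scores tied to disruption severity
#'
#' MMSE-like global cognition: `30 - 12 * severity + noise`, clipped to
#' `[18, 30]` (patients at or above the inclusion floor of 18). Immediate
#' and free recall (FCSRT-like, 0-48 scale): `48 - 24 * severity` and
#' `40 - 24 * severity` plus twice the noise, clipped to `[0, 48]`.
#' Controls score near ceiling on all three.
#'
#' @param severities numeric vector, one severity per patient.
#' @param config a [synthetic_config()].
#' @return a data frame with columns `subject_id`, `group`, `mmse`,
#'   `recall_immediate`, `recall_free` (controls first).
#' @export
generate_behavior <- function(severities, config) {
  stopifnot(inherits(config, "synthetic_config"))
  sdn <- config$behavior_noise_sd
  n_hc <- config$n_hc
  n_ad <- length(severities)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  hc <- data.frame(
    subject_id = sprintf("hc%02d", seq_len(n_hc)),
    group = "hc",
    mmse = clip(29 + stats::rnorm(n_hc, 0, 0.5 * sdn), 18, 30),
    recall_immediate = clip(46 + stats::rnorm(n_hc, 0, sdn), 0, 48),
    recall_free = clip(38 + stats::rnorm(n_hc, 0, sdn), 0, 48))
  ad <- data.frame(
    subject_id = sprintf("ad%02d", seq_len(n_ad)),
    group = "ad",
    mmse = clip(30 - 12 * severities + stats::rnorm(n_ad, 0, sdn), 18, 30),
    recall_immediate = clip(48 - 24 * severities +
                              stats::rnorm(n_ad, 0, 2 * sdn), 0, 48),
    recall_free = clip(40 - 24 * severities +
                         stats::rnorm(n_ad, 0, 2 * sdn), 0, 48))
  rbind(hc, ad)
}

#' Generate a full synthetic two-group study
#'
#' Draws `n_hc` control-like and `n_ad` patient-like subjects (severities
#' uniform over the configured range), behavior scores, and the ground
#' truth (planted core, severities, attacked pairs). Deterministic given
#' `config$seed`. When `dir` is supplied, the study is also written to disk
#' in the interchange layout (per-layer TSV matrices, per-subject JSON
#' manifests, behavior table, `ground_truth.json`) readable by
#' [read_cohort()].
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @return an object of class `"mcp_study"`: list with `subjects` (list of
#'   multiplexes), `group` (factor, levels `hc`, `ad`), `behavior`,
#'   `ground_truth` and `config`.
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  subjects <- vector("list", config$n_hc + config$n_ad)
  ids <- c(sprintf("hc%02d", seq_len(config$n_hc)),
           sprintf("ad%02d", seq_len(config$n_ad)))
  group <- factor(rep(c("hc", "ad"), c(config$n_hc, config$n_ad)),
                  levels = c("hc", "ad"))
  for (s in seq_len(config$n_hc)) subjects[[s]] <- generate_hc_subject(config)
  severities <- stats::runif(config$n_ad, config$severity_range[1L],
                             config$severity_range[2L])
  gt_pairs <- vector("list", config$n_ad)
  for (s in seq_len(config$n_ad)) {
    res <- generate_ad_subject(config, severities[s])
    subjects[[config$n_hc + s]] <- res$net
    gt_pairs[[s]] <- res$ground_truth$attacked_pairs
  }
  names(subjects) <- ids
  behavior <- generate_behavior(severities, config)
  study <- structure(
    list(subjects = subjects, group = group, behavior = behavior,
         ground_truth = list(core = seq_len(config$n_core),
                             severities = severities,
                             attacked_pairs = gt_pairs),
         config = config),
    class = "mcp_study")
  if (!is.null(dir)) write_cohort(study, dir)
  study
}

#' @export
print.mcp_study <- function(x, ...) {
  cat("Synthetic multiplex study:", sum(x$group == levels(x$group)[1L]),
      "+", sum(x$group == levels(x$group)[2L]), "subjects,",
      n_nodes(x$subjects[[1L]]), "nodes x",
      n_layers(x$subjects[[1L]]), "layers\n")
  invisible(x)
}
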
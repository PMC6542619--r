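# Shared fixtures and independent brute-force oracles. The oracles use
# naive loops, explicit edge sums and data-frame sorting on purpose: they
# share no code with the package's sweep implementation.

rand_sym <- function(N) {
  W <- matrix(stats::runif(N * N), N, N)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

rand_multiplex <- function(N, M) {
  normalize_multiplex(multiplex(lapply(seq_len(M), function(m) rand_sym(N))))
}

# Naive full-sweep coreness: for every k independently re-threshold each
# layer by sorting an explicit edge table, recompute strengths and the
# richness split with triple loops, and apply the boundary rule.
oracle_coreness <- function(net, cv) {
  W <- net$W
  N <- length(net$nodes)
  M <- dim(W)[3L]
  K <- N - 1L
  delta <- matrix(0L, K, N)
  for (k in seq_len(K)) {
    L <- floor(N * k / 2 + 0.5)
    Wf <- array(0, dim = dim(W))
    for (m in seq_len(M)) {
      ed <- NULL
      for (i in 1:(N - 1)) for (j in (i + 1):N) if (W[i, j, m] > 0)
        ed <- rbind(ed, data.frame(i = i, j = j, w = W[i, j, m]))
      if (!is.null(ed)) {
        ed <- ed[order(-ed$w, ed$i, ed$j), , drop = FALSE]
        keep <- utils::head(ed, L)
        for (r in seq_len(nrow(keep))) {
          Wf[keep$i[r], keep$j[r], m] <- keep$w[r]
          Wf[keep$j[r], keep$i[r], m] <- keep$w[r]
        }
      }
    }
    s <- matrix(0, M, N)
    for (m in seq_len(M)) for (i in seq_len(N)) s[m, i] <- sum(Wf[i, , m])
    mu <- numeric(N)
    for (i in seq_len(N)) mu[i] <- sum(cv * s[, i])
    ord <- order(-mu, seq_len(N))
    pos <- match(seq_len(N), ord)
    mup <- numeric(N)
    for (i in seq_len(N)) for (m in seq_len(M)) for (j in seq_len(N))
      if (pos[j] < pos[i]) mup[i] <- mup[i] + cv[m] * Wf[i, j, m]
    mup_rank <- mup[ord]
    if (any(mup_rank > 0)) {
      rstar <- which.max(mup_rank)
      delta[k, ord[seq_len(rstar)]] <- 1L
    }
  }
  list(coreness = colSums(delta) / K, indicator = delta)
}

# Single-threshold richness oracle on an already filtered multiplex.
oracle_richness <- function(net, cv) {
  W <- net$W
  N <- length(net$nodes)
  M <- dim(W)[3L]
  s <- matrix(0, M, N)
  for (m in seq_len(M)) for (i in seq_len(N)) s[m, i] <- sum(W[i, , m])
  mu <- numeric(N)
  for (i in seq_len(N)) mu[i] <- sum(cv * s[, i])
  ord <- order(-mu, seq_len(N))
  pos <- match(seq_len(N), ord)
  mup <- numeric(N)
  for (i in seq_len(N)) for (m in seq_len(M)) for (j in seq_len(N))
    if (pos[j] < pos[i]) mup[i] <- mup[i] + cv[m] * W[i, j, m]
  list(mu = mu, mu_plus = mup, rank_order = ord)
}

# Small synthetic configuration used where full study scale is not needed.
small_config <- function(seed = NULL, n_nodes = 30L, n_hc = 8L, n_ad = 6L) {
  synthetic_config(n_nodes = n_nodes, n_core = max(4L, n_nodes %/% 5L),
                   n_hc = n_hc, n_ad = n_ad, seed = seed)
}
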
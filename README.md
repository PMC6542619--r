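# coreplex

Core-periphery analysis of multiplex brain networks.

Neurodegeneration is increasingly read as a *disconnection* process: damage
concentrates on the densely interconnected core of the brain network and
degrades global integration. `coreplex` is for researchers who have
multimodal connectivity — e.g. DWI tractography, resting-state fMRI and
band-specific MEG coherence, all parcellated on the same regions — and want
to ask core-periphery questions of the *multiplex* network that stacks
those modalities as layers over one shared node set, rather than of any
single modality alone.

## The method

For a multiplex with layers `m = 1..M` and layer weights `c` (nonnegative,
unit norm), each node's **multiplex richness** is

    mu_i = sum_m c[m] * s_i[m]

with `s_i[m]` the node strength in layer `m` after density filtering.
Splitting strengths into links towards richer (higher-`mu`) nodes gives
`mu_i+`, whose maximum along the richness ranking marks the rich-core
boundary. Sweeping density thresholds `k = 1..N-1` (each layer keeps its
`round(N*k/2)` strongest links) and counting how often node `i` falls in
the core yields its **coreness** `C_i in [0, 1]`.

For a two-group study the layer weights are chosen by maximizing the
**Fisher criterion**

    F(c) = ||mean_A(c) - mean_B(c)||^2 / (s_A^2 + s_B^2)

over the positive unit hypersphere (parametrized by `M-1` angles, searched
by particle swarm optimization). Group reorganization is summarized by the
**coreness disruption index** `kappa` — the OLS slope of the node-wise
coreness difference regressed on the reference group's mean coreness;
`kappa < 0` means preferential core weakening. Node-wise permutation tests
under a rough FDR threshold `alpha*(N+1)/(2N)` localize the change, and
per-subject `kappa` values are correlated (Spearman) with cognitive
scores. A seeded **attack simulation** reduces link weights of pairs drawn
with probability proportional to coreness (or its complement) to model
core- vs periphery-targeted disconnection.

Because no public cohort accompanies the method, the package includes a
seeded synthetic generator (`generate_cohort()`) producing 68-node,
9-layer two-group studies with a planted core, layer-localized group
effects and behavior scores tied to disruption severity.

## Worked example

```r
library(coreplex)

cfg <- synthetic_config(n_nodes = 30, n_core = 6, n_hc = 8, n_ad = 6,
                        seed = 1)
study <- generate_cohort(cfg)
fit <- mcp_fit(study,
               pso = pso_config(swarm_size = 12, max_iterations = 15,
                                seed = 2),
               stats = stats_config(n_permutations = 1000, seed = 3))
fit
```

```
Multiplex core-periphery fit (ad vs hc reference)
  Fisher criterion F* = 0.26185 
  layer weights c*: fmri=0.810, dwi=0.581, gamma=0.070 ...
  disruption index kappa = -0.7143 (p = 1.82e-09)
  significant nodes: 12 of 30 at alpha_FDR = 0.0258 
```

The fit says: the swarm concentrated the layer weights on the fMRI-like
and DWI-like layers — two of the three layers carrying the planted group
effect; patients' coreness drops preferentially at high-coreness nodes
(`kappa = -0.71`, significantly below 0); and 12 of 30 regions
individually survive the rough FDR threshold of 0.026. `summary(fit)` adds the per-node table and the
Spearman correlations between per-patient `kappa` and the behavior scores;
`plot(fit)` draws the `kappa` regression, `plot(fit, "trace")` the swarm
trace. The attack sweep is available separately:

```r
hc <- study$subjects[study$group == "hc"]
sweep <- disruption_sweep(hc, coef(fit), fractions = seq(0.1, 0.4, 0.1),
                          reduction = 0.75, mode = "core", n_rand = 3,
                          seed = 4)
aggregate(kappa ~ fraction, sweep, median)
#   fraction      kappa
# 1      0.1 -0.1770084
# 2      0.2 -0.5446376
# 3      0.3 -0.8672242
# 4      0.4 -0.9915584
```

MEG coherence layers can be built from multichannel epochs with
`coherence_spectrum()` (Welch, 2-s Hanning windows, 25% overlap, 0.5 Hz
resolution over 2–45 Hz), `band_average()` (delta through gamma) and
`epoch_average()`.

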
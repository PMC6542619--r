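---
title: "Core-periphery analysis of multiplex brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-periphery analysis of multiplex brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreplex)
```

## The model

`coreplex` analyzes *multiplex* brain networks: one shared set of `N` nodes
(cortical regions of interest) observed through `M` weighted, undirected
connectivity layers — e.g. seven MEG frequency-band coherence layers, one
fMRI correlation layer and one DWI streamline-count layer — with no
interlayer links. Because modalities live on incomparable scales, every
layer is first min–max normalized over its off-diagonal entries so all
weights lie in `[0, 1]`.

### Coreness over a density sweep

A single multiplex admits a deterministic *rich core*: rank the nodes by
their multiplex richness

$$\mu_i = \sum_{m=1}^{M} c^{[m]} s_i^{[m]},$$

where $s_i^{[m]}$ is node $i$'s strength (sum of retained link weights) in
layer $m$ and $c$ is a nonnegative vector of layer contribution
coefficients. Splitting each strength into links towards strictly
higher-ranked ("richer") nodes and the rest,
$s^{[m]} = s^{[m]-} + s^{[m]+}$, gives the richness towards richer nodes
$\mu_i^+ = \sum_m c^{[m]} s_i^{[m]+}$. Walking down the ranking, the core
boundary sits at the first rank position where $\mu^+$ is maximal; the core
is every node up to and including that boundary node.

Determinism means a single detection has no notion of confidence. The
package therefore sweeps density thresholds: for every target mean degree
$k = 1, \dots, N-1$ each layer independently keeps its
$\mathrm{round}(Nk/2)$ strongest links (weights are kept — the filtered
network stays weighted), the rich core is detected, and the *coreness* of
node $i$ is the fraction of thresholds at which it was in the core:

$$\mathcal{C}_i = \frac{1}{N-1} \sum_{k=1}^{N-1} \delta_i^{[k]} \in [0, 1].$$

### Data-driven layer weights

The coefficients $c$ are not known a priori. For a two-group study the
package selects them by maximizing the Fisher separation of the groups'
coreness vectors,

$$F(c) = \frac{\lVert \bar I_A(c) - \bar I_B(c) \rVert^2}{s_A^2 + s_B^2},
\qquad
s_{\mathrm{Pop}}^2 = \sum_{s \in \mathrm{Pop}} \lVert I_s(c) - \bar
I_{\mathrm{Pop}}(c) \rVert^2,$$

where $I_s(c)$ is subject $s$'s coreness vector. Since $F(c) = F(ac)$ for
any $a > 0$, $c$ is parametrized on the positive section of the unit
hypersphere by $M-1$ angles $\phi_k \in [0, \pi/2]$ (nested sine/cosine
products), and the angle box is searched by particle swarm optimization
(PSO).

### Disruption index and group statistics

Core-periphery reorganization between a target group (patients) and a
reference group (controls) is summarized by the *coreness disruption
index* $\kappa$: the OLS slope of the node-wise difference of mean
coreness regressed on the reference mean coreness. $\kappa < 0$ means
high-coreness nodes lose disproportionately — preferential core
weakening. The same regression applied to a single subject's coreness
yields a per-patient $\kappa$ for behavioral correlation (Spearman).
Node-wise group differences use two-sided permutation tests (Welch
statistic) under a rough FDR threshold $\alpha(N+1)/(2N)$ — 0.025 at
$\alpha = 0.05$, $N = 68$.

### Targeted disconnection

The attack simulation mimics a disconnection process: endpoints are drawn
with probability proportional to coreness (core mode) or its complement
(periphery mode); each of the $L$ selected distinct pairs has its weight
multiplied by $1-R$ in every layer, and layers are re-normalized
afterwards. Sweeping the attacked link fraction and recomputing $\kappa$
against the unattacked cohort mean shows how fast core-targeted damage
degrades the core-periphery structure relative to periphery-targeted
damage.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `c` / `phi` | optimized | layer contributions, unit norm, nonnegative |
| `k` sweep | `1..N-1` | target mean binary degree per density threshold |
| PSO swarm | `min(100, 10(M-1))` | constriction PSO, inertia 0.729, accelerations 1.49 |
| PSO stop | 200 iters / stall 20 / tol 1e-6 | iteration cap and stall rule |
| `reduction` R | 0.75 | fractional weight decrease per attacked pair |
| `n_rand` | 3 | attack replicates per subject and fraction |
| `alpha` | 0.05 | nominal level; rough FDR threshold `alpha(N+1)/(2N)` |
| `n_permutations` | 10000 | label permutations per node-wise test |
| coherence window | 2 s Hanning, 25% overlap | Welch segments |
| NFFT | `2 * fs` | 0.5 Hz resolution (2000 at 1000 Hz), 2–45 Hz |

The PSO stopping rule (stall window of 20 iterations with minimal
improvement 1e-6) is a design choice: the swarm literature offers no
single convention, and stall-based stopping matches common default
behavior of widely used implementations. Velocities are reflected at the
angle-box bounds so candidates always stay in the valid octant.

## Numerical choices and tie-breaking

Every operation is deterministic given its inputs and seed:

* **Retention quota.** `round(N k / 2)` links per layer, computed as
  `floor(N k / 2 + 0.5)` (half-up) so odd `N` cannot fall into
  banker's-rounding ambiguity. Zero-weight links are never "retained": a
  sparse layer simply has realized mean degree below `k`.
* **Weight ties** at the retention boundary break by lexicographic
  `(i, j)` node order; **richness ties** break by ascending node index,
  and tied nodes do not count as richer (they contribute to $s^-$).
* **Boundary ties**: the first (highest-rank) position attaining the
  $\mu^+$ maximum is the boundary, and the boundary node belongs to the
  core; if every $\mu^+$ is zero the core is empty. The minimal-core
  convention avoids spurious cores on empty graphs. Note one consequence:
  in a uniform star the core is the hub *plus* the first leaf, because the
  leaves all tie at the $\mu^+$ maximum and the earliest of them is the
  included boundary node.
* **Degenerate layers** (all off-diagonal weights equal) normalize to all
  zeros with a warning rather than an error, keeping batch runs alive.
* **Attack draws** rejecting `i = j` or an already attacked pair are
  redrawn without counting towards `L`, so exactly `L` distinct pairs are
  hit; when fewer pairs are reachable (endpoints with zero probability)
  the quota is capped with a warning.
* The coreness sweep has two implementations: a plain-R reference
  composition of the exported operations and a C++ kernel that exploits
  the fact that the retained link set at degree `k` is a prefix of each
  layer's weight-sorted edge list. Both are tested for exact agreement
  against an independently coded brute-force oracle.

## The synthetic cohort generator

No public cohort accompanies the method, so the package ships a seeded
generator that emulates the study design: 68-node, 9-layer multiplexes
(7 MEG-band-like, 1 fMRI-like, 1 DWI-like), 26 controls and 23 patients.

* **Planted core.** Every node carries a *prominence* declining linearly
  from 1 (top node) to 0.4 (weakest); a pair's expected weight is a
  Beta(2, 2) draw scaled by the product of its endpoints' prominences.
  The first 14 of 68 nodes are the planted (graded) core. A discrete
  block design was tried first and rejected: it saturates the planted
  core's coreness at 1 in every subject, so no intervention can ever
  *decrease* it — a graded gradient with subject-level prominence
  jitter (lognormal, sd 0.1) keeps rankings labile, as in measured
  connectomes, and lets disruption reorder them.
* **Layer families.** The DWI-like layer is sparsified over a structural
  skeleton that is a fixed function of the node pair — shared by all
  subjects, as anatomical backbones largely are — with retention
  probability increasing with pair prominence and heavy-tailed lognormal
  weight multipliers; fMRI-like layers are dense; the seven MEG-band-like
  layers mix a shared latent template (65%) with band-specific
  independent draws (35%), reproducing the strong inter-layer redundancy
  of band-limited coherence — which is exactly what makes data-driven
  layer weighting non-trivial.
* **Group effect.** A patient is a control-like draw attacked in core
  mode with `link_fraction = 0.4 * severity` at `R = 0.75`, restricted to
  the affected layers (default `dwi`, `fmri`, `alpha1` — the modalities
  the analysis highlights). Severities are uniform on `[0.25, 1]`: every
  patient carries a clinically visible effect, with enough spread to
  support severity–behavior correlations.
* **Behavior.** MMSE-like `30 - 12*severity + noise` clipped to
  `[18, 30]` (patients at or above the inclusion floor), recall-like
  scores on a 0–48 scale; controls near ceiling.

What passing tests on this generator do **not** show: anatomical realism
(no atlas geometry, no distance-dependent connectivity, no hemispheric
structure), realistic between-modality coupling, scanner/site noise, or
any claim about effect sizes in real cohorts. The generator validates the
*machinery* — that planted disruption is recovered as negative $\kappa$,
that the affected layers get the weight, that planted core nodes are
flagged, and that behavior correlations point the right way — not the
clinical findings themselves.

One behavior of the disconnection model is worth stating plainly: under
the density-sweep boundary rule, *weakening* links (however targeted)
mostly deepens the detected core boundary, so the dominant group-level
signature of an attacked cohort is a coreness *increase* of mid-ranked
(peripheral) nodes, with the top of the ranking pinned near its ceiling;
per-node coreness *decreases* appear only where the attack demotes a node
past the (extended) boundary, which at this cohort size yields few
individually significant decreases. The group disruption index is
negative either way — the regression slope does not care whether the
difference profile is driven by core loss or periphery gain — but
node-level decrease counts are small and their enrichment test is
under-powered at desk scale.

## Problem sizes used in the shipped checks

The automated checks run the full pipeline at the study's native scale
(68 nodes, 9 layers, 26 + 23 subjects) over 5 generator seeds, with a
swarm of 24 particles for up to 30 iterations and 2000 label permutations
per node-wise test; the attack-fraction sweep uses 12 control subjects at
40 nodes with 3 replicates per fraction, and unit tests use smaller
fixtures (4–40 nodes, 1–3 layers). These sizes were chosen so the entire
suite completes in minutes on a single core while leaving each statistical
recovery check enough power to be stable across seeds.

## Known limitations

* PSO cost grows quickly with the number of layers; beyond ~10 layers the
  angle space becomes expensive to explore (the Fisher criterion is also
  increasingly ill-conditioned as `N` approaches the cohort size).
* The Fisher criterion is optimized on the full cohort, as in the study
  design it follows; there is no cross-validation, so `F*` is an
  in-sample quantity and should not be read as classification accuracy.
* The disconnection model reduces a pair's weight in *all* (or the
  configured subset of) layers simultaneously — a structural
  "disconnection syndrome" reading. Per-layer attack accounting is a
  plausible alternative the package does not implement.
* Magnitude-squared coherence is the implemented estimator; magnitude
  coherence, PLV, wPLI or source-leakage-robust variants are out of
  scope, as are all acquisition and preprocessing steps.
```{r example, eval = FALSE}
# end-to-end example at reduced scale
cfg <- synthetic_config(n_nodes = 30, n_core = 6, n_hc = 8, n_ad = 6,
                        seed = 1)
study <- generate_cohort(cfg)
fit <- mcp_fit(study,
               pso = pso_config(swarm_size = 12, max_iterations = 15,
                                seed = 2),
               stats = stats_config(n_permutations = 1000, seed = 3))
summary(fit)
plot(fit)            # kappa regression
plot(fit, "trace")   # swarm trace
```
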
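---
title: "Multiplex frequency-resolved functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex frequency-resolved functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Resting-state functional connectivity is conventionally estimated after
band-pass filtering the ROI-averaged signals to a single "typical" band
(0.01–0.1 Hz), discarding higher-frequency components that are known to carry
topological information of their own. `multiplexfc` instead keeps every
frequency component: the range 0.01–0.25 Hz (the upper edge being the Nyquist
frequency of a TR = 2 s acquisition, the lower edge the conventional
drift cut-off) is decomposed into 12 contiguous bands of 0.02 Hz, one network
is built per band, and the networks become the layers of an interconnected
multiplex network over the shared set of ROIs.

The stages are:

1. **Band coherence.** For every channel pair the magnitude-squared coherence
   spectrum is estimated and averaged over the spectral bins of each band,
   giving a weight $w_{ij} \in [0, 1]$ per pair per band.
2. **Surrogate significance.** For each channel, IAAFT surrogates are drawn —
   randomised series preserving the amplitude distribution exactly and the
   power spectrum approximately, while destroying cross-channel and
   higher-order temporal structure. Surrogate pairs give a per-pair,
   per-band null with sample mean $\mu_{ij}$ and standard deviation
   $\sigma_{ij}$; the absolute z-score
   $z_{ij} = |w_{ij} - \mu_{ij}| / \sigma_{ij}$ is computed and edges with
   $z_{ij} < 3$ are discarded. Retained z-scores become the edge weights.
   Using $|z|$ deliberately does not distinguish correlated from
   anti-correlated signals.
3. **Multiplex assembly.** Layers are node-aligned and every node is linked
   to each of its replicas in all other layers with a common weight $D$
   (all-to-all replica coupling, realising the adjacency-tensor convention
   $M^{i\alpha}_{j\beta} = 0$ for $i \neq j,\ \alpha \neq \beta$ and
   $M^{i\alpha}_{i\beta} = D$). $D$ has no direct biological reading; it is a
   runtime parameter selected by downstream classification accuracy.
4. **Layer descriptors.** Degree, strength, degree assortativity, edge
   density, Barrat weighted clustering, Louvain modularity, hop-count
   characteristic path length, and the small-world index
   $S = (C / C_\mathrm{rand}) / (\ell / \ell_\mathrm{rand})$ against an
   Erdős–Rényi $G(N, m)$ ensemble with matched node and edge counts.
5. **Structural reducibility.** Each layer's weighted combinatorial Laplacian
   is rescaled to unit trace, $L = (S - A) / \sum_{ij} A_{ij}$; its
   eigenvalues form a probability distribution whose Shannon entropy (base 2)
   is the Von Neumann graph entropy $h$. Layer dissimilarity is the quantum
   Jensen–Shannon divergence, computed through the entropy identity
   $\mathrm{JSD}(L_a, L_b) = h\!\left(\tfrac{L_a + L_b}{2}\right) -
   \tfrac{1}{2}\left(h(L_a) + h(L_b)\right)$, and the metric distance is its
   square root. Layers are hierarchically clustered on this distance (Ward
   linkage) and at each merge step the merged groups are replaced by the sum
   of their adjacencies; the quality function
   $q = 1 - \langle h \rangle / h_\mathrm{agg}$ measures distinguishability
   from the fully aggregated graph. The reported optimum maximises $q$, with
   ties broken toward the least-reduced partition.
6. **Multiplex PageRank.** A damped random walk on the supra-adjacency
   (0.85 follow / 0.15 uniform teleport over the $N L$ node-layer states) is
   iterated to stationarity; the per-node centrality profile sums the
   stationary probabilities over a node's replicas. Single-layer PageRank of
   the full-band (0.01–0.25 Hz) and typical-band (0.01–0.1 Hz) baseline
   networks provides the conventional comparison, via Spearman rank
   correlation of profiles.
7. **Discrimination.** Centrality profiles are the feature vectors of a
   random-forest classifier (700 trees, at most 5 terminal nodes, 2 candidate
   variables per split) run leave-one-out. Features are ranked per fold by
   mean decrease in Gini importance and the ranks summed; a second LOO round
   uses only the top-k features. A $(D, k)$ grid scan selects the coupling
   weight and feature count by accuracy (the reference configuration uses
   $D = 24.7708$ and around 30 features at the 264-ROI scale). Hubs are the
   top 5% of nodes by group-averaged centrality (count rounded half-up, so
   264 ROIs give 13 hubs), and hub/feature set agreement is quantified by the
   Jaccard index.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band range / width | 0.01–0.25 / 0.02 | Hz | 12 equal bands; upper edge = Nyquist at TR = 2 s |
| Welch segment / overlap / taper | min(T, 64) / 50% / Hann | samples | standard estimator for short fMRI series; fixes bin spacing |
| `nSurrogates` | 100 | — | stable null mean/sd at acceptable cost |
| `zThreshold` | 3 | — | retention threshold on the absolute z-score |
| `D` | 24.7708 | z units | classification-selected coupling for centrality |
| damping | 0.85 / 0.15 | — | fixed follow/teleport split; expert override only |
| PageRank `tol` / `maxIter` | 1e-10 (L1) / 10000 | — | power iteration stopping rule |
| forest | 700 trees, 5 leaves, mtry 2 | — | many weak trees for many weak features |
| hub `fraction` | 0.05 | — | top-5% rule, round half-up, ties to lowest node id |

# The synthetic-data generator

The generator emulates the acquisition geometry the analysis targets — N ROIs
(default 40, configurable to 264), T = 180 time points at TR = 2 s (6 min of
data, Nyquist 0.25 Hz) — and plants known structure:

* **Band-specific coupling.** Each group effect adds a shared band-limited
  latent (white noise whose Fourier coefficients outside the band are zeroed,
  then standardised) to its member nodes, scaled by a coupling strength in
  [0, 1]; independent unit-sd Gaussian noise is added everywhere. Fourier
  masking gives exact band confinement with no filter ringing.
* **Hubs.** Planted hub nodes share a broadband latent with all other nodes
  (strength 0.8 at the hub, 35% of that elsewhere), so they become densely
  connected across bands. A faster fixture, `generatePlantedMultiplex()`,
  skips signal generation entirely: independent G(n, p) layers with hubs
  wired to extra uniformly chosen non-neighbours per layer.
* **Reproducibility.** All generators restore the caller's RNG state; subject
  s of a cohort uses seed `seed + s`, so cohorts are byte-identical across
  runs yet subjects are independent.

Effect sizes are free parameters of the generator — the source data's
empirical coherence distributions are not characterised, so nothing is
calibrated against them. For the end-to-end discrimination experiment the
package's reference condition gives each group a *three-band coupling
fingerprint* (group A: bands 2–4 over ROIs 1–8; group B: bands 8–10 over
ROIs 9–16; strength 0.9). One band alone shifts the multiplex profile only
weakly once the strong replica coupling ($D \approx 24.8$, which dominates
the walk's row strengths) smooths the layers, and per-node group separation
sits near $|t| \approx 1.8$; three adjacent bands per group raise it to
$|t| \approx 2.5$ on the coupled nodes, which a 20-subject cohort detects
reliably.

What the generator does **not** emulate: haemodynamics, 1/f spectra,
physiological noise, motion artefacts, spatial correlation of parcels, or
anti-correlated couplings. Passing tests therefore demonstrate that the
machinery recovers planted structure under clean conditions, not that it
would attain any particular accuracy on real acquisitions.

# Numerical choices and degenerate inputs

* **Spectral bins** belong to a band if $f_\mathrm{low} \le f <
  f_\mathrm{high}$; the top band also takes a bin exactly at its upper edge
  so no bin inside the analysed range is orphaned. A band containing no bins
  is an error (lengthen the series or widen the bands).
* **IAAFT** stops when the rank ordering stabilises or at `maxIter` (100);
  constant series are rejected. With only a handful of Welch segments and a
  strongly narrowband signal, surrogate coherence in the signal's band is
  itself high-variance, so the z-test is conservative for short series —
  edges planted at strength 0.9 with T = 180 may fall below $z = 3$ for a
  single subject while group-level profile differences remain detectable.
* **JSD** is always computed through the entropy identity; matrix logarithms
  of the (singular) Laplacians are used only as an independent cross-check on
  connected instances. Eigenvalues below 1e-12 are treated as exact zeros
  and $0 \log 0 = 0$.
* **Quality function.** The reduction literature the procedure follows
  defines distinguishability through relative entropy; the implemented form
  is $q = 1 - \langle h \rangle / h_\mathrm{agg}$. For L identical layers q
  is constant in the merge step and the tie-break reports "no reduction".
* **Replica symmetry caveat.** For L identical layers the multiplex walk
  lumps exactly onto a single-node chain with an added self-loop of weight
  $(L-1)D$ at every node, so the multiplex profile equals the single-layer
  PageRank only in the limit $D \to 0$; at finite D the self-loop weight is
  node-independent while strengths are not, and the profiles differ (the
  test suite asserts the exact lumped-chain equivalence instead).
* **Degree-based statistics.** Assortativity is flagged undefined (NA) on
  regular graphs; path lengths exclude disconnected pairs and report the
  connected fraction; nodes of degree < 2 are excluded from the Barrat
  clustering average; an edgeless layer is an error for modularity,
  path length and the Laplacian.
* **LOO bias.** Leave-one-out on a balanced two-class cohort makes the
  held-out subject's class the training minority, so under label permutation
  the accuracy null centres *below* 0.5. Significance statements therefore
  always compare against the empirical permutation null, never against 0.5;
  and the unbiased statistic is the first-round accuracy (the second round's
  feature selection sees all subjects through the summed ranking, which
  inflates permuted-label accuracy by construction).
* **Dangling states** (a node isolated in a layer when D = 0) receive a full
  uniform teleport row. Ranking ties use average ranks; top-k and hub ties
  resolve toward the lowest node id; the best (D, k) ties resolve toward
  smaller k, then smaller D.

# Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full pipeline completes in minutes on one core: cohorts of 20 subjects with
40 ROIs and 180 time points, 50 surrogates per channel for cohort runs and
100 for the single-subject calibration check (15 channels, 180 points,
1260 pair-band tests), 50 label permutations, 20 planted-multiplex fixtures,
and PageRank oracle fixtures up to 200 node-layer states. The 264-ROI scale
is configuration-only and changes no code path.

# Limitations

* Coherence is undirected and phase-blind; no partial coherence, wavelets or
  spectral Granger variants.
* Inter-layer coupling is uniform and diagonal (replica links only), not
  learned from data.
* The surrogate test controls per-pair significance, not family-wise error
  across the $\binom{N}{2} \times 12$ tests. Its calibration is
  length-dependent: at 180 points the independent-channel retention rate at
  $|z| \ge 3$ is about 0.6–0.9%, while at 512–1024 points the null's
  heavier-than-Gaussian tails push it to 1–2% (the z-scale is Gaussian-
  motivated but the coherence null is skewed).
* Gaussianity of the surrogate null is reported per pair (skew/kurtosis
  diagnostics on the `SurrogateNull` object) but not enforced.
* Classification results at desk scale quantify recovery of planted
  structure; they are not comparable to accuracies obtainable on real
  cohorts.
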
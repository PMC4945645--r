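# multiplexfc

Multiplex (multilayer) analysis of frequency-resolved functional
connectivity from multichannel ROI-averaged time series — for researchers
who want to keep *every* frequency component of resting-state activity as
its own network layer instead of filtering to a single band or aggregating
across bands.

## What it computes

Given one channels × time matrix per subject (e.g. 264 ROI-averaged fMRI
signals at TR = 2 s), the package:

1. estimates magnitude-squared coherence per channel pair (Welch segments,
   Hann taper, 50% overlap) and averages it within contiguous frequency
   bands — by default 0.01–0.25 Hz split into 12 bands of 0.02 Hz;
2. tests each band-specific weight *w<sub>ij</sub>* against an IAAFT
   surrogate null (surrogates preserve each channel's amplitude
   distribution exactly and power spectrum approximately), forming
   *z<sub>ij</sub>* = |*w<sub>ij</sub>* − μ<sub>ij</sub>| / σ<sub>ij</sub>
   and discarding edges with *z<sub>ij</sub>* < 3; retained z-scores are the
   layer's edge weights;
3. assembles the layers into an interconnected multiplex: every node is
   linked to its replicas in all other layers with weight *D*
   (supra-adjacency with *D*·I off-diagonal blocks);
4. characterises each layer (degree, strength, assortativity, density,
   Barrat weighted clustering, Louvain modularity, characteristic path
   length, small-world index *S* = (*C*/*C*<sub>rand</sub>) /
   (*ℓ*/*ℓ*<sub>rand</sub>) against G(N, m) nulls);
5. quantifies inter-layer redundancy: Von Neumann entropy
   *h* = −Σ λ<sub>i</sub> log₂ λ<sub>i</sub> of the unit-trace rescaled
   Laplacian, quantum Jensen–Shannon distances between layers, Ward
   clustering of layers, and a quality function
   *q* = 1 − ⟨*h*⟩/*h*<sub>agg</sub> whose maximum identifies the optimal
   reduction (on heterogeneous data: no reduction at all);
6. computes multiplex PageRank (0.85 follow / 0.15 teleport over node-layer
   states) and per-node centrality profiles π̃<sub>j</sub> = Σ<sub>β</sub>
   π<sub>jβ</sub>, plus full-band and typical-band single-layer baselines;
7. discriminates two groups of subjects from their centrality profiles with
   leave-one-out random forests (700 trees, ≤ 5 terminal nodes, mtry 2),
   including Gini-importance feature ranking, a top-k second round, a
   (D, k) grid scan, top-5% hub identification and Jaccard overlap of hub
   and feature sets.

A synthetic-cohort generator plants band-specific group coupling and hub
nodes so the whole pipeline is testable end to end without any external
data.

## Worked example

One synthetic subject, 12 ROIs, 480 time points at TR = 2 s, with ROIs 1–4
sharing a 0.9-strength latent confined to band 3 (0.05–0.07 Hz):

```r
library(multiplexfc)

cfg <- syntheticConfig(
  nSubjectsPerGroup = 1L, nRois = 12L, nTimepoints = 480L,
  groupEffects = list(list(group = "A", band = 3L, nodes = 1:4, strength = 0.9)),
  seed = 7L
)
ts <- generateSubjectTimeSeries(cfg, "A", seed = 7L)
ts
#> RoiTimeSeriesSet: 12 ROIs x 480 time points, TR = 2 s (Nyquist 0.25 Hz)

scheme <- makeBandScheme(0.01, 0.25, 0.02)
scheme
#> FrequencyBandScheme: 12 bands of width 0.02 Hz covering [0.01, 0.25) Hz

built <- buildLayers(ts, scheme, nSurrogates = 50, zThreshold = 3, seed = 7L)
built$layers[[3]]
#> LayerNetwork: 12 nodes, 6 edges, band [0.05, 0.07) Hz, z threshold 3

adjacency(built$layers[[3]])[1:4, 1:4]
#>          roi1     roi2     roi3     roi4
#> roi1 0.000000 7.341992 7.490353 5.346478
#> roi2 7.341992 0.000000 6.582658 6.652317
#> roi3 7.490353 6.582658 0.000000 5.754803
#> roi4 5.346478 6.652317 5.754803 0.000000
```

Exactly the 6 planted pairs survive the surrogate test, with z-scores
5.3–7.5 (well above the threshold 3); all other pairs are discarded. The
multiplex centrality profile then ranks the coupled nodes:

```r
prof <- multiplexPageRank(assembleMultiplex(built$layers, D = 24.7708))
prof
#> CentralityProfile: 12 nodes x 12 layers (D = 24.7708), 71 iterations, residual 8.51e-11

round(sort(nodeProfile(prof), decreasing = TRUE)[1:3], 4)
#> 0.0834 0.0834 0.0833
```

With this large replica coupling the profile is nearly uniform — D ≈ 24.8
dominates the intra-layer weights, which is exactly why group analyses use
the *differences* between subjects' profiles rather than a single subject's
spread. On a 20-subject cohort whose groups carry distinct three-band
coupling fingerprints, the first-round leave-one-out random forest on
multiplex profiles reaches accuracy 1.00 against a label-permutation null
of ≈ 0.35–0.41 (see the acceptance script below).

Layer reducibility on the non-empty layers of this subject:

```r
keep <- vapply(built$layers, function(l) any(adjacency(l) != 0), TRUE)
reduceLayers(built$layers[keep])
#> ReducibilityResult: 11 layers, optimal reduction step 1 (q = 0.8251)
```

The full pipeline (synthetic cohort → layers → descriptors → reducibility →
centrality → classification, with all artifacts on disk) runs from a single
config:

```r
runPipeline(list(synthetic = list(nSubjectsPerGroup = 5L),
                 output_dir = "out", seed = 7))
```

or from the shell via `inst/scripts/run_pipeline.R run-all --config cfg.yaml
--out out --seed 7`.

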
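# fnirsnet

Graph-theoretical analysis of whole-head fNIRS recordings made during
sensorimotor synchronization (tapping) tasks, for researchers who want a
tested, scriptable version of the standard degree-centrality pipeline:

1. **Geometry** — alternating emitter/detector probe grids (two 3×10 + one
   3×5, 116 channels, 30 mm spacing) and a packaged channel→brain-region
   lookup.
2. **Preprocessing** — zero-phase Butterworth band-pass (0.010–0.33 Hz)
   and motion-artifact channel rejection (any raw Oxy-Hb step
   > 0.1 mM·mm excludes the channel).
3. **Connectivity** — task-block Pearson correlations of Oxy-Hb, Fisher
   z-transform (z = atanh r), binarization by proportional thresholding at
   15% edge density.
4. **Graph metrics** — degree centrality k_i = Σ_j a_ij, top-10%-degree
   hubs, consensus (≥60% prevalence) edges, ROI degree t-tests.
5. **Clustering** — Ward hierarchical clustering of subjects by their
   degree profiles, dendrogram cut at the largest merge-height gap.
6. **Behavior** — synchronization error SE(n) = Response(n) − Stimulus(n)
   in ms (negative = predictive tap), per-cluster summaries and
   between-cluster t-tests.

Because no public dataset exists for this paradigm, the package includes a
first-class synthetic data generator (`generator_config()` /
`generate_dataset()`) that emulates the study design — 20 subjects in two
groups, planted group-specific network hubs carried by a shared
band-limited latent signal, physiological noise, motion-artifact steps,
and planted SE distributions (90.0 ± 154.9 ms and −8.9 ± 261.5 ms) — so
the entire pipeline is testable end to end.  See the vignette
(`vignettes/network-analysis.Rmd`) for the model, its assumptions, and
every numerical convention.

## Worked example

```r
library(fnirsnet)

ds  <- generate_dataset(generator_config(seed = 1))
res <- run_pipeline(ds$series, ds$behavior)
res
```

```
fnirs_pipeline: 20 subjects, density 0.15, block 'task'
clusters (k = 2): 1(n=10), 2(n=10)
cluster 1 hubs (top 10% degree): 5, 7, 18, 26, 27, 33, 45, 46, 83, 87, 91, 95
  regions:  right medial superior frontal gyrus; left middle frontal gyrus; left precentral gyrus; left triangular part of inferior frontal gyrus; right superior frontal gyrus; right cerebellum crus I; left cerebellum crus I; right cerebellum crus II
cluster 2 hubs (top 10% degree): 6, 19, 24, 28, 48, 59, 61, 75, 86, 92, 96, 104
  regions:  left superior frontal gyrus; left postcentral gyrus; right medial superior frontal gyrus; left supramarginal gyrus; left middle occipital gyrus; right middle temporal gyrus; left inferior temporal gyrus; right cerebellum crus II; right precentral gyrus; supplementary motor area
synchronization error by cluster:
 cluster n_subjects   mean_ms     sd_ms
       1         10  78.41889  49.74607
       2         10 -23.49299 146.98906
SE cluster difference: t = 2.077, p = 0.0524
```

The largest-gap Ward cut selects k = 2 and splits the cohort into exactly
the two planted groups.  Cluster 1's hub set contains all five planted
group-A hubs (channels 7, 26, 45 — left middle frontal gyrus; 27, 46 —
left triangular inferior frontal gyrus); cluster 2's contains all five
planted group-B hubs (59, 61 — left middle occipital; 19 — left
postcentral; 48 — left supramarginal; 75 — right middle temporal).  The
remaining hub slots are filled by peripheral or background channels and
vary with the seed: a 21-s task block gives every correlation estimate
only ~14 effective degrees of freedom, so single-subject graphs are noisy
by design.  The per-cluster SE means recover the planted reactive (+90 ms)
versus predictive (−8.9 ms) tapping styles within sampling error, and at
10 subjects per cluster the SE difference is not significant at α = 0.05 —
the behavioral contrast is weaker than the network contrast.

Compare a region's centrality between the clusters:

```r
roi_degree_test(res, "left middle frontal gyrus")
#> ROI degree: left middle frontal gyrus: t = 14.180, p = 0.0000 (significant at alpha = 0.05)
#>  group     mean       sd  n
#>      a 28.48571 2.387800 10
#>      b 14.27143 2.084877 10
```

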
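---
title: "Degree-based brain network analysis of fNIRS tapping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based brain network analysis of fNIRS tapping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsnet)
```

## The analysis in one paragraph

A whole-head fNIRS montage (two 3×10 probe grids plus one 3×5 grid, 116
channels at 30 mm optode spacing, 10 Hz sampling) records oxy- and
deoxy-hemoglobin concentration changes while subjects tap in synchrony with
auditory cues.  For each subject, the Oxy-Hb traces of the task block are
band-pass filtered, channels contaminated by motion artifacts are excluded,
and the remaining channels' pairwise Pearson correlations are Fisher
z-transformed.  The z-matrix is binarized by proportional thresholding at
15% edge density, the binary graph's degree centrality
$k_i = \sum_{j \in N} a_{ij}$ is computed per channel, and subjects are
clustered by the similarity of their 116-channel degree profiles using
Ward's hierarchical method, cut at the largest merge-height gap.  Each
cluster is then characterized by its top-10%-degree hub regions, its
consensus (≥60% prevalence) connections, and its tapping performance
(synchronization error, SE = response − stimulus, in ms).

## Pipeline stages and their parameters

### Probe geometry and anatomical lookup

In the alternating emitter/detector checkerboard every orthogonally
adjacent optode pair forms a channel, so an $r \times c$ grid yields
$r(c-1) + (r-1)c$ channels: 47 for 3×10, 22 for 3×5, and 116 for the
whole-head montage.  Channel-to-region assignment is a fixed packaged
lookup table (116 rows: region label and hemisphere per channel).  In the
original experimental workflow this assignment came from probabilistic
registration of digitized probe positions to MNI space; a fixed table is
the reproducible stand-in, and `channel_map(path)` accepts a user-supplied
table with the same three columns.  Channel indexing is 1-based everywhere,
and channels are masked rather than deleted so indices stay aligned with
the lookup throughout.

### Preprocessing

* **Pass band 0.010–0.33 Hz** (`preprocess_config()`): keeps task-related
  hemodynamics, removes drift below and respiratory/cardiac oscillations
  above the band.  The filter is a zero-phase (forward–backward)
  Butterworth, order 4, realized as a low-pass/high-pass cascade: at 10 Hz
  sampling the high-pass corner is 0.002 of Nyquist, where a direct-form
  8th-order band-pass is numerically fragile, while the cascade is well
  conditioned.  The high-pass section runs first with
  constant-continuation initial conditions, which makes the response to a
  constant input exactly zero.  Reflection padding (300 samples) absorbs
  the slow (~16 s) tail of the 0.01 Hz corner.
* **Motion-artifact screening, threshold 0.1 mM·mm**: a channel is
  excluded when any absolute single-sample first difference of its *raw*
  Oxy-Hb trace exceeds the threshold.  "Change per unit time" is
  interpreted as the per-sample difference at 10 Hz, and screening runs
  *before* filtering — a zero-phase filter smears a step over many
  samples, so the order matters; both choices are configurable.  Screening
  uses the oxy trace only; the deoxy trace inherits the flag.

### Connectivity and graph construction

Pearson correlations are computed over the task-block samples only, then
Fisher z-transformed ($z = \operatorname{atanh} r$; degenerate $|r| = 1$
entries are clipped to $\operatorname{atanh}(1-10^{-7})$ and flagged).
Proportional thresholding keeps the $\lfloor 0.15\,M + 0.5 \rfloor$
largest-z pairs (round half up) among the $M$ available pairs of valid
channels, so subjects with excluded channels are compared at the same
*density* rather than the same edge count.  Ranking uses signed z — strong
negative correlations are never selected — with an absolute-value mode
behind a flag; ties at the cutoff resolve by ascending channel-index pair,
making the graph deterministic.  Degree is the only network metric
computed; the package deliberately offers no clustering coefficient, path
length or small-world index.

### Hubs, consensus edges, ROI tests

Hubs are the $\lceil 0.10\,n_\mathrm{valid} \rceil$ highest-degree
channels (ceiling, index tie-break, both documented because the hub count
itself is a convention).  Consensus edges are channel pairs present in at
least 60% (inclusive) of the subjects in which both channels are valid;
the denominator is per pair.  ROI statistics use the mean degree over a
region's valid channels per subject, compared between clusters with an
unpaired two-sample t-test (Student by default, Welch behind a flag,
two-sided, α = 0.05, no multiplicity correction by default with a
Bonferroni flag left to the caller).

### Subject clustering

The feature vector is the per-channel degree profile — degree is the only
network measure the pipeline computes, so it is the faithful clustering
feature; a vectorized-adjacency alternative can be constructed from the
returned adjacency matrices.  Distances are Euclidean (required by Ward's
variance criterion) without standardization, since all features are
degrees and share a unit.  Channels invalid in any subject are dropped
from the feature space for all subjects.  `ward_cluster()` uses
`hclust(method = "ward.D2")`, whose merge heights are
$\sqrt{2\,\Delta SS}$; the number of clusters $k \in [2, 5]$ maximizes the
gap between successive merge heights ("cut where the dendrogram jumps
most"), with ties resolved to the smallest $k$.  The cap at 5 keeps the
rule from chasing singleton splits in a 20-subject cohort.

### Behavior

Responses are paired to stimuli greedily by proximity within ± half the
local inter-stimulus interval, each response used at most once, earlier
stimulus winning exact ties.  SE is reported in ms, negative when the
response precedes the cue (predictive tapping).  The first task stimulus
is a start reminder, not a cue to synchronize with, and its SE is dropped;
with seven task stimuli at most six SE values remain per subject.
Cluster summaries aggregate within subject first (mean SE per subject),
so subjects, not taps, are the unit of the between-cluster t-test —
pooling taps would pseudo-replicate.

## The synthetic data generator

No subject data were ever deposited for this paradigm, so the package
ships a generator whose defaults *are* the study conditions: 20 subjects
in two groups of 10, 116 channels, 10 Hz, blocks of 20/30/21/30 s
(pre-scan, control, task, post-control), seven task cues whose intervals
grow by ≈0.6 s (±0.03 s uniform jitter) — the published interval rule is
ambiguous, so cue count and increment are configurable — and per-group SE
distributions of 90.0 ± 154.9 ms and −8.9 ± 261.5 ms.

Planted network structure: each group has a latent band-limited
(0.01–0.30 Hz) signal; its five hub channels load on it with
$\sqrt{c}$ (coupling $c$, default 0.9 — the reference condition used by
the end-to-end recovery experiments) and 47 peripheral channels load with
$\sqrt{c\rho}$ ($\rho = 0.25$), so designed correlations are $c$
(hub–hub), $c\sqrt{\rho}$ (hub–peripheral) and $c\rho$
(peripheral–peripheral), all strictly increasing in $c$.  Group A hubs
sit in left middle frontal gyrus (channels 7, 26, 45) and the left
triangular inferior frontal gyrus (27, 46); group B hubs in left middle
occipital (59, 61), left postcentral (19), left supramarginal (48) and
right middle temporal (75) gyri.  These are representative subsets of the
regions rather than every channel of each region: the top-10% budget on
116 channels is 12 hubs, and a planted set well below that budget leaves
room to *measure* detection instead of saturating the slots.  Peripheral
channels are assigned round-robin from the non-hub pool, disjoint between
groups.  With 15% density the graph keeps 1001 edges, so the planted
network (hub clique, hub–peripheral and peripheral–peripheral pairs)
supplies a sizeable share of them and hub channels accumulate degree well
above the background.

Noise: cardiac (1.2 Hz), respiratory (0.25 Hz) and Mayer-wave (0.1 Hz)
sinusoids with per-channel random phase and ±10% per-channel frequency
spread (physiological rhythms are not phase-locked across the scalp;
identical frequencies everywhere would fabricate cross-channel
correlation), linear drift of up to 0.02 mM·mm per run, and white
measurement noise (sd 0.005 mM·mm), all on top of a 0.03 mM·mm network
signal.  Both the latent and the per-channel background are band-limited
to the analysis band, so the designed correlation structure passes
through the band-pass stage unchanged.  Motion artifacts are persistent
steps (default: 0.15 and −0.18 mM·mm in two subjects) injected on the raw
traces.  A single global seed expands into per-subject substreams, so
equal seeds give bit-identical datasets and growing the cohort never
reshuffles earlier subjects.

What the generator does *not* emulate: raw optical intensities and the
Beer–Lambert conversion, tapping biomechanics (behavior is a planted SE
distribution, not a phase-correction model), spatially correlated scalp
physiology, or hemodynamic response shapes locked to the block design.
Passing recovery tests therefore show that the pipeline's inference is
correct *given* its statistical assumptions, not that those assumptions
hold in any particular real recording.

## What the recovery experiments can and cannot show

The task block is 21 s of 0.01–0.33 Hz signal, which carries roughly
$2BT \approx 14$ effective degrees of freedom per correlation estimate.
Sample correlations at that length are extremely noisy (Fisher-z sd
≈ 0.3), so any single subject's thresholded graph — and hence their
individual hub set — is intrinsically unstable; this is a property of the
study design, not of the implementation.  The package's validation
therefore emphasizes aggregate recovery: the Ward cut over degree
profiles (which pools 116 channels) recovers the planted two-group split
essentially perfectly at the reference coupling, while per-subject hub
detection is measured as the rate at which planted hubs appear in each
subject's top-10% set (0.93–0.95 at the defaults in the bundled
acceptance battery; it degrades toward the 0.8 coupling boundary).
Cluster-level hub sets, computed from cluster-mean degree profiles,
are far more stable and are what the pipeline reports per cluster.

## Problem sizes used by the test suite

Unit tests run on small synthetic cohorts (4–6 subjects) and on toy
graphs solved by brute-force oracles (exhaustive degree checks up to 8
nodes; an explicit Ward agglomeration oracle up to 6 points).  The
end-to-end battery runs 100 replicates of the full 20-subject design for
the clustering-recovery rate, 10 replicates (200 subjects) for hub
detection, and 100 subjects per cluster for SE recovery — sizes chosen so
the rates being tested are estimated with a few percentage points of
Monte-Carlo error.

## Known limitations

* The anatomical lookup is a fixed table; real studies should substitute
  subject-specific registration via `channel_map(path)`.
* Channel exclusion is the only motion-artifact treatment; no correction
  (spline, wavelet, PCA, Kalman) is attempted.
* One correlation matrix per subject per run; no averaging over repeated
  runs, no partial correlation, coherence or lagged connectivity.
* The largest-gap cut is a heuristic; with weak group structure it can
  return any $k$ in its range, and the gap profile should be inspected.
* SNIRF input/output is not implemented; the plain-text interchange
  format (delimited matrices + JSON sidecar + events table) is the
  supported representation.
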
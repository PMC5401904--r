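---
title: "Quantifying circuit function: synchrony, colocalization and rhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circuit function: synchrony, colocalization and rhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitsync)
library(purrr)
```

## The scientific problem

When neurons lose the cell-surface identity code that normally restricts
which partners they synapse with — for example when all clustered
protocadherin isoforms are removed — the wiring of their circuits changes
in ways that are visible at three very different levels of observation:

* **Network activity.** In cultured clusters of hippocampal neurons imaged
  with a calcium indicator, healthy networks produce mostly solo events and
  small co-active groups ("cell assemblies") with a heavy-tailed,
  power-law-like distribution of per-neuron response frequencies. Networks
  without partner selectivity instead tend to fire all together: the modal
  event becomes the complete synchronisation of every neuron in the
  cluster.
* **Molecular contacts.** When a single tagged adhesion isoform is
  expressed in two populations of neurons, trans-homophilic binding shows
  up as colocalized two-channel puncta along neurites that run side by side
  (closer than 0.5 µm).
* **Motor output.** The spinal central pattern generator (CPG) normally
  drives left and right lumbar ventral roots in alternation (right-side
  burst onsets at phase 0.5 of the left cycle). Miswired CPGs lose the
  alternating pattern; blocking crossed inhibition produces left-right
  synchrony (phase 0).

`circuitsync` implements the complete quantitative pipeline for all three
readouts, together with a seeded synthetic-data generator that emulates
each input with known ground truth, so that every stage can be validated
without any original recordings.

## The synthetic-data generator

### Cluster recordings

A simulated cluster is a graph of `n` neurons (drawn uniformly from 9–25
by default, the size range of medium cultured clusters) on which activity
propagates as a **discrete-time branching cascade**: per 100-ms frame, a
neuron initiates an event spontaneously with probability
`1 − exp(−rate·dt)`, every event recruits each graph neighbour on the next
frame with a per-edge transmission probability, and a neuron is refractory
for 1 s after firing. Recordings last 2 min at 10 Hz (1200 frames), the
standard session. The cascade is the simplest model that produces both
solo events and whole-cluster synchronisation as wiring density and
transmission strength increase; it makes no claim about biophysics.

Two presets encode the contrast under study, and every value is
configurable:

| preset | wiring | transmission |
|---|---|---|
| `control_like` | small-world ring, degree 4, rewiring 0.1 | 0.2 |
| `mutant_like`  | random graph, edge probability 0.8 | 0.6 |

The control preset realises the hypothesis that healthy cultured networks
are scale-free/small-world; that topology is an inference from activity
statistics in the literature, not an established fact, which is why the
generator treats it as a configurable mode (`topology_spec()` also offers
`scale_free` and `complete`). With degree 4 and transmission 0.2 the
branching factor is ≈ 0.8 (subcritical: cascades die out quickly), while
the mutant preset's branching factor is ≈ 6–12 (supercritical: nearly
every initiation recruits the whole cluster within two or three frames).
The spontaneous rate default of 0.01 events·s⁻¹·neuron⁻¹ gives a cluster
of ~17 neurons about 20 initiations per 2-min session, matching the
sparse-event regime of such recordings.

Fluorescence is synthesised with generic fast-dye kinetics: instantaneous
rise, single-exponential decay (τ = 1 s), amplitude 0.3 ΔF/F per event,
transients summing linearly, plus Gaussian noise (SD 0.02 ΔF/F). One
master seed is expanded into per-cluster child seeds by the documented
rule `child = (1009·seed + 7919·index) mod (2³¹ − 1)`, so any cluster can
be regenerated in isolation.

What the generator does **not** emulate: slow baseline drift,
photobleaching, motion, overlapping ROIs, non-linear indicator saturation,
bursty spontaneous rates. Passing round-trip tests therefore demonstrate
correctness of the analysis code under the stated model, not detection
performance on arbitrary real recordings.

### Puncta scenes and ventral-root traces

`generate_puncta_scene()` draws gently curved neurite polylines crossing a
105.9 µm field (the standard confocal field), offsets each by the pair
separation, places puncta along both at a Poisson linear density, and
gives a chosen fraction of channel-A puncta a channel-B partner within a
0.1 µm jitter. Ground truth (which spots are true partners, which
polylines are pairs) is returned with the scene; `render_puncta_image()` /
`write_puncta_tiff()` rasterise it with a Gaussian PSF for the image-based
part of the pipeline.

`generate_vr_traces()` renders bursts as amplitude pedestals on a flat
baseline with additive Gaussian noise — i.e. it simulates the trace at the
**rectified-envelope level** rather than as an AC electroneurogram. This
choice keeps the noiseless limits exact (a clean square burst has a
defined onset sample) and loses nothing relevant to burst-timing analysis,
which operates on the envelope anyway. Right-burst onsets are placed at
phase 0.5 (alternating), 0.0 (synchronous) or uniformly at random
(arrhythmic) of each left cycle; `silent` produces no bursts, emulating
activity abolished pharmacologically.

## Calcium analysis

### ΔF/F and onset detection

The baseline `F0(t)` is a rolling 20th percentile of the raw trace over a
100-frame (10 s) window, truncated (not padded) at the recording edges,
and `ΔF/F = (F − F0)/F0`. For speed the percentile is evaluated every 10
frames and linearly interpolated — exact for constant baselines and
indistinguishable from the per-frame version for slowly varying ones.
Within half a window of the recording edges, and in windows crowded with
transients, the percentile baseline is biased slightly upward; this is an
intrinsic property of percentile baselines and is why validation of the
amplitude round trip uses isolated interior events.

Detection marks an onset where **both** of two robust criteria hold: the
ΔF/F level exceeds the trace median by `z = 3` times the Gaussian-scaled
MAD of the trace, **and** the one-frame increment exceeds `z` times the
MAD of the differenced trace. The level criterion alone is not usable:
with a percentile baseline the ΔF/F median sits ≈ +0.8σ above zero, and
even a correctly centred pure crossing rule would fire ≈ 1.6 times per
neuron per 1200 noise-only frames (P(z ≥ 3) per frame). Adding the rise
criterion exploits the fast-rise/slow-decay asymmetry of calcium
transients: the joint noise tail is ≈ 2×10⁻⁴ per frame (≈ 0.25 false
onsets per recording), while a true transient's one-frame rise of 0.3
ΔF/F (~15σ at default noise) is never missed. It also recovers events that
initiate on the decay tail of a previous transient, which no pure
level-crossing rule can. Candidates within 5 frames of an accepted onset
are suppressed. All thresholds are `detection_params()` fields and should
be reported with results; they are analysis choices, not measured
constants.

### Synchrony statistics

`synchronous_groups()` merges onsets into one group whenever each onset is
within the synchrony window (default 1 frame = 100 ms, the imaging
interval) of another onset of the group — transitive chain merging,
implemented as connected components over onset frames. A fixed frame
lattice was rejected because it splits events that straddle a bin edge.
The group size is the number of distinct neurons involved. Derived
summaries follow the field's standard presentation:

* `synchrony_histogram()` — counts per size with a distinguished `"all"`
  bin for complete synchronisation (only groups of exactly `n` neurons);
* `active_fraction()` / `bin_active_fractions()` — percentage of active
  neurons per cluster, binned as {0}, ten half-open interior bins
  `[0,10) … [90,100)`, {100} (the reporting convention that gives the
  exact 0% and 100% clusters their own bars; the half-open choice of the
  interior edges is ours — the convention itself does not fix one);
* `response_frequencies()` / `frequency_histogram()` — per-neuron onset
  counts at unit bin width;
* `classify_full_sync()` — TRUE iff some group spans the whole cluster.

`fit_power_law()` fits the log-log line by ordinary least squares over the
non-empty histogram bins, matching the straight-line-on-a-log-log-inset
presentation; maximum-likelihood exponent estimation is deliberately out
of scope. Two caveats are documented rather than patched: zero-count bins
must be excluded (log 0), and because sparse tail bins are zero-truncated
Poisson counts, the estimator is biased toward shallower slopes on small
samples — at 280 neurons with a generating exponent of 0.981 on {1..64}
the mean recovered slope is ≈ −0.87. We keep the plain OLS definition
because it is what the log-log presentation fits, and report the bias
instead of correcting it silently.

`compare_groups()` applies a two-sided Mann-Whitney U test per histogram
bin (exact enumeration when both groups have ≤ 8 clusters without ties,
tie-corrected normal approximation otherwise) with the three-star
significance convention (0.05 / 0.005 / 10⁻⁴). P values are reported
uncorrected per bin, as the histogram annotation convention does; a
Bonferroni column is emitted alongside as an extension. Bins that are
identical in every cluster of both groups (e.g. empty synchrony bins)
carry no information and are reported as `U = n₁n₂/2, p = 1`.

## Puncta colocalization and counts

`detect_spots()` convolves the image with a negated
Laplacian-of-Gaussian kernel at the expected PSF scale, extracts local
maxima above a threshold relative to the strongest response, and refines
each peak with a response-weighted 3×3 centroid (sub-pixel accuracy on
rendered scenes; two spots closer than about one PSF sigma merge, as they
must for any single-scale detector).

`pair_neurites()` accepts an A/B polyline pair when a contiguous stretch
of at least `min_parallel_um` (default 5 µm) stays within
`max_sep_um = 0.5` µm point-to-curve distance — the standard side-by-side
criterion. `count_colocalized()` then matches A to B puncta within a
radius by greedy nearest-first **one-to-one** assignment (deterministic
coordinate-order tie-break), so dense clumps cannot be double counted; the
0.5 µm default radius reuses the neurite-separation criterion because no
separate dot-overlap radius is established, and the matching definition is
centroid distance (whether "overlap" means pixel overlap or centroid
distance is not standardised; centroid distance is ours). The chance
expectation for spots on two parallel lines separated by `s` is
`2·sqrt(r² − s²)·density` matches per spot, which the tests verify by
Monte Carlo and use for chance correction.

`density_per_field()` counts in-field spots; `group_test()` wraps the
classical one-way ANOVA + Tukey HSD used for per-field comparisons;
`survival_ratio()` computes double-positive percentages rounded to one
decimal. `survival_table()` flags rows whose pooled ratio disagrees with a
previously reported percentage — published tables sometimes average over
sections rather than pooling counts, and the discrepancy should be
surfaced, not reproduced.

## Ventral-root rhythm classification

`vr_envelope()` is a moving average (default 0.1 s) of the absolute
deviation from the trace median. `detect_bursts()` thresholds it in two
passes so bursts cannot inflate the noise estimate: a provisional
median + 3·MAD cut (mid-range when the envelope is noise-free) selects
baseline samples, the final threshold is the baseline median + 3·robust SD
of the baseline, sub-threshold gaps shorter than 0.1 s are fused, runs
shorter than 0.2 s dropped, and each burst edge is refined to the
half-height crossing of its peak — exact to one sample on clean square
bursts because a centred moving average crosses half-height exactly at a
step edge.

`cycle_phases()` expresses each right-burst onset as a phase of its left
cycle `[onset_i, onset_{i+1})`; onsets (not burst centres) are the
reference because onset timing is the standard CPG coordination metric and
is robust to duty-cycle differences. Fewer than three left bursts cannot
define a rhythm and yield `no_rhythm`. `classify_rhythm()` computes the
circular mean μ and resultant length R: R < 0.6 → `arrhythmic`; else μ
within ±0.125 cycle of 0.5 → `alternating`, of 0 → `synchronous`; a
concentrated phase away from both anchors is also `arrhythmic`. The
R-threshold and phase tolerance are analysis definitions — published
classifications of such traces are typically by inspection — so both are
parameters recorded in every result. At the defaults, an arrhythmic
recording of ~29 cycles has P(R ≥ 0.6) ≈ 10⁻⁵ under uniform phases, and
end-to-end mode recovery on synthetic pairs exceeds 95% across seeds at
the default noise level.

## Numerical and testing choices

* Problem sizes in the test-suite simulations (50-seed property loops,
  clusters of 9–25 neurons × 1200 frames, 4-pair puncta scenes in
  40–50 µm fields) were chosen as the smallest sizes at which the
  statistical properties under test are comfortably resolved.
* Determinism: every stochastic function takes an explicit seed and is
  bit-reproducible; RNG state is isolated with `withr::with_seed` so
  library calls never perturb a user's session RNG.
* Degenerate inputs have defined behaviour throughout: empty rasters give
  empty group lists and zero active fractions; all-tied comparison bins
  give p = 1; saturated envelopes (no baseline) and too-few left bursts
  give `no_rhythm`; fits with fewer than three non-empty bins are flagged
  `fitted = FALSE` rather than extrapolated.
* `survival_ratio()` uses R's `round()` (IEEE round-half-even); at the
  printed one-decimal precision of the worked examples this is
  indistinguishable from round-half-up.

## Known limitations

* The cascade model has no biophysics (no conductances, plasticity or
  inhibition); it is a statistical emulator for validating analysis code.
* The log-log OLS slope is a presentation-matched estimator, not an
  efficient one; for inference about exponents use larger samples or an
  ML estimator (out of scope here).
* Spot detection is single-scale and 2-D; axially overlapping puncta and
  mixed spot sizes are outside its design envelope, as are
  intensity-correlation colocalization measures (Pearson/Manders), which
  are deliberately not implemented — the counting-based definition is the
  one under study.
* Neurite polylines are taken as input (traced or synthetic); automatic
  neurite tracing from micrographs is out of scope.
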
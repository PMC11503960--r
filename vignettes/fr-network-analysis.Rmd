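---
title: "Fast-ripple network analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-ripple network analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frnetsim)
```

## Scope and assumptions

`frnetsim` treats inter-ictal fast-ripple (FR) generation as a marked
point process observed on SEEG contacts: each contact contributes onset
trains per event class over a single artefact-free non-REM epoch of
10–60 min. Everything downstream — networks, resection metrics, the
classifier, the virtual resection and RNS simulators — consumes only
these onset times, contact geometry (MNI mm), region labels, SOZ and
resection masks, and outcome labels. Detection of events from raw iEEG,
imaging, and electrode localization are explicitly out of scope; the
package starts where an HFO detector ends.

Key modelling assumptions:

- FR > 350 Hz (FR on oscillations above 350 Hz plus all FR on spikes) is
  the analysis band; ripple-band classes (RonS, RonO) enter only through
  resection/stimulation ratios, never through graphs.
- Temporal coupling between contacts is symmetric and undirected; the MI
  between onset trains is a sufficient edge weight, with 1/MI as the
  distance (an MI-0 edge has infinite length and carries no paths).
- Rates are events/min; times are seconds from epoch start; all spatial
  quantities are MNI millimetres. Hemisphere is read from the stored
  label, which must agree with `sign(x)` beyond 2 mm of the midline
  (within it, the stored label wins — midline structures are genuinely
  ambiguous and the simulator needs a deterministic laterality rule).

## The mutual-information estimator

The estimator is Darbellay–Vajda adaptive partitioning over paired
inter-event-interval samples. For each event in train A (except the
last), the sample is *(interval to A's next event, forward waiting time
to B's next event)*. We chose the forward-waiting construction after
rejecting the superficially natural "signed interval to B's nearest
event": for two identical trains the nearest-event interval is
identically zero, a constant, and the MI of a constant with anything is
zero — the convention would score perfect synchrony as independence. The
forward-waiting pair instead makes the two coordinates exactly equal for
identical trains, strongly dependent for jittered shared events, and
independent for unrelated Poisson trains, which is the contract the
downstream metrics rely on (≈ 0 under independence, large under
synchrony, symmetric, nonnegative).

The partition works on rank-transformed samples. A cell is split at its
rank midpoints into four quadrants; equiprobability is tested at two
depths (4 quadrants, chi-square 3 df, and 16 sub-quadrants, 15 df) at
`alpha = 0.05`, and the cell is refined while either test rejects.
The two-depth test matters: shared events with a few tens of
milliseconds of jitter concentrate probability on a *thin* diagonal
that a single quadrant test cannot see at n ≈ 100 samples. Cells
smaller than `mi_min_cell = 8` samples terminate. The estimator is run
in both directions and averaged, then clamped at zero, making it exactly
symmetric and nonnegative by construction. Degenerate trains (fewer than
2 events) score 0. Estimates are in nats.

What a green MI test establishes: correct null behaviour (circular-shift
permutation nulls) and detection of mother-process coupling at rates of
a few events/min over tens of minutes. It does not establish calibration
of the absolute MI value against the true functional coupling; only the
ordering and zero/nonzero structure are consumed downstream.

## Graph measures

Shortest paths treat weights as lengths (igraph Dijkstra; the test suite
cross-checks every measure against a hand-written Floyd–Warshall
oracle). The graph radius is the minimum over nodes of the maximum
shortest-path length to any other node. The characteristic path length
of a node subset averages finite ordered-pair distances *within the
subset-induced subgraph* — paths may not leave the resected set, which
is what makes temporal FRnet-A a property of the resection rather than
of the embedding network. Infinite pairs are excluded from the mean and
flagged; an all-infinite subset returns an `Inf` sentinel. Local
efficiency follows the weighted Brain Connectivity Toolbox convention
(cube-root weight normalization, neighbourhood-induced subgraph); global
efficiency averages inverse shortest-path distances with disconnected
pairs contributing zero.

## The four factors and their conventions

- **FR RR** is event-weighted; the SOZ ratio is contact-weighted. Both
  are monotone in the resected set.
- **Spatial FRnet** takes `sqrt(max(r_whole − r_resected, 0))`. The
  clamp is deliberate: a resected subgraph can have a larger radius than
  the whole graph (shortcuts through unresected nodes are lost), and the
  published per-patient tables contain exact zeros, which only a clamped
  convention produces.
- **Temporal FRnet-A** returns 0 with a `degenerate` flag when fewer
  than two resected nodes are in the network or the whole-network path
  length is not finite, rather than guessing a value.
- **Temporal FRnet-B** averages LE over *unresected* nodes with LE > 0
  (the "urmLE" reading), returning 1.0 when none remain, which
  reproduces the full-resection row pattern (FR RR 1, spatial 0, A 1,
  B 1). The literal all-nodes reading is available via
  `temporal_frnet_b(..., scope = "all")` for sensitivity analysis.

The autonomy clustering runs k-means with k = 2 on z-scored
(log10 rate, LE) with 50 restarts under a fixed seed; the autonomous set
is the cluster with the highest mean log rate (ties to lowest mean LE).
k = 2 encodes the two-regime structure (autonomous high-rate versus
synchronous low-rate nodes); zero-rate nodes are excluded since they
cannot be surgical candidates.

## Classifier

The seizure-freedom classifier is an RBF SVM with C = 1 and
gamma = 1/n_factors = 0.25 on normalized features. Where an "automatic"
kernel scale and the explicit 1/n_factors formula conflict, the explicit
formula wins by default; the median-pairwise-distance heuristic is
exposed as `svm_gamma_rule = "auto_scale"`. Normalization is z-scoring
by default (min–max is available) and is *refit inside every
leave-one-out fold* — the suite contains a leakage sentinel verifying an
outlier in the held-out sample cannot shift training statistics. The
dual problem is solved by a deterministic SMO (second index chosen by
maximal |E_i − E_j|), so training is reproducible bit-for-bit; at n ≈ 18
this converges in milliseconds. Ties at decision value exactly 0 label
not-seizure-free (the conservative surgical default).

## Virtual resection

Candidates are network nodes with FR rate > 1/min ordered by ascending
LE (most autonomous first); when exhausted or absent, remaining nodes
follow by descending rate; all ties break on contact id. The sphere is
centred on the first candidate for the whole run — the radius-update
rule measures from the first node, so a moving centre would change the
semantics — with radius 10 mm initially and
`distance(center, candidate_k) + 10 mm` when candidate k lies outside
the current sphere (never shrinking; candidates already inside advance
the iteration without growth). The virtual set is every ipsilateral
contact inside the sphere; contralateral contacts are excluded outright.
Unsampled space contributes nothing: the sphere only collects sampled
contacts. Stopping: a seizure-free label; or the virtual set spanning 3
distinct lobes (counted over resected nodes' lobe labels from a fixed
Desikan–Killiany lookup, insula and cingulate each counting as a lobe —
the only computable reading when all we observe are sampled contacts);
or candidate exhaustion, which labels the run not seizure free.

## The synthetic generator

The generator states a world rather than tuning one: 8–16 collinear
shanks of 7–15 contacts at 3.5–10 mm pitch (about a quarter mirrored
through x = 0 so contralateral logic is exercised), 10–60 min epochs, a
planted "epileptogenic core" of adjacent contacts generating FR at
6/min with 80% private (autonomous) events, background FR at 0.4/min on
~30% of remaining contacts coupled through a thinned, 20-ms-jittered
mother Poisson process, ripple-class events at 3/min near the core and
0.5/min elsewhere, SOZ flags on and within 10 mm of the core, and a
resection mask per policy (`covers_core`, `misses_core`, `partial`).
The outcome rule — seizure free iff every core node is resected — gives
the classifier a recoverable signal whose strength is a *consequence*
of the stated rates, not a tuned quantity. Tests and the acceptance
script use a deliberately scaled-down cohort (8 × 7 contacts, 20-min
epochs) to stay well inside a single-CPU time budget; this is a size
reduction, not a parameter search.

What the generator does not emulate: waveform-level detection noise,
rate nonstationarity across the night, spatially continuous sources
(events live on contacts, not in tissue), eloquent-cortex constraints,
and any relationship between lesion anatomy and FR. A green end-to-end
test therefore establishes internal consistency of the pipeline under
the stated statistical structure — not clinical validity on real SEEG.

## Statistics

The Kruskal–Wallis statistic uses the standard tie correction and a
chi-square p-value at any n (matching the common numerical
implementations, so published statistics reproduce exactly). The
Wilcoxon signed-rank test drops zero differences, enumerates all 2^n
sign assignments over the observed (possibly tied) ranks for n ≤ 15,
and reports twice the smaller tail capped at 1; above n = 15 a normal
approximation with tie and continuity corrections is used. Trial sizing
uses the unpooled two-sided Z-test formula with ceiling, and enrolment
inflation is `ceil(n / (1 − dropout))` — ceiling, not rounding,
reproduces both published enrolment figures from the same n.

## Known limitations

- The MI estimator's sample construction is a documented stand-in for
  the cited estimator family; absolute MI values are not calibrated
  across estimators.
- Spherical resection geometry over-covers real cavities; overlap
  metrics against actual resections inherit that bias.
- The LE-versus-raw-MI normalization question is resolved as raw MI;
  a normalized adjacency would rescale LE and hence temporal FRnet-B.
- Exact per-patient reproduction of published virtual-resection tables
  is impossible without the original recordings; only the printed
  summary statistics are reproduced, from the bundled tables.
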
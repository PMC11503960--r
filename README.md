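# frnetsim

Fast-ripple network metrics, virtual resections and responsive
neurostimulator (RNS) placement for stereo-EEG.

## The problem

In medication-resistant focal epilepsy, surgery aims to remove the tissue
that generates seizures while resecting as little cortex as possible. The
standard of care targets the clinically delineated seizure-onset zone
(SOZ), yet SOZ resection does not reliably produce seizure freedom.
Pathological **fast ripples** (FR, 200–600 Hz; here the high-band subset:
FR on oscillations > 350 Hz plus all FR on spikes) recorded on stereo-EEG
(SEEG) contacts are a candidate biomarker of the epileptogenic network.
`frnetsim` is for epilepsy researchers who want to analyse FR event trains
as a weighted network, score actual or simulated resections against it,
and explore classifier-guided surgical planning — without access to any
patient recordings, via a synthetic-cohort generator that emulates the
relevant statistics.

## The model

From each patient's FR > 350 Hz onset trains the package builds a
**mutual-information (MI) network**: nodes are FR-generating contacts,
edge weights are MI (nats) between onset trains estimated by
adaptive partitioning of paired inter-event intervals, and distances are
1/MI. Four factors summarize a resected contact set *R*:

- **FR RR** — resection ratio: events on resected contacts / all events;
- **spatial FRnet** — `sqrt(max(radius(G_all) − radius(G_R), 0))` on the
  rate–distance graph (edge = mean pair FR rate × Euclidean mm);
- **temporal FRnet-A (gammaRR)** — `L(R) / L(V)`, the characteristic path
  length of the resected induced subnetwork over that of the whole network;
- **temporal FRnet-B (urmLE)** — mean nodal local efficiency (Brain
  Connectivity Toolbox weighted convention) over unresected nodes with
  LE > 0 (1.0 when none remain).

An RBF-kernel SVM (C = 1, gamma = 1/4 on normalized factors; in-package
deterministic SMO solver) is trained on actual outcomes and evaluated by
leave-one-out cross-validation. A **virtual resection** grows a sphere
(initial radius 10 mm) over candidate nodes ordered by FR autonomy
(ascending local efficiency, descending-rate fallback), labels every
iteration with the SVM, and stops on a seizure-free label, a three-lobe
extent, or candidate exhaustion. RNS support computes stimulated contacts
(strictly < 15 mm from 8 stimulation contacts), SOZ/FR stimulation
ratios, the stimulated-subnetwork global efficiency, and virtual lead
placement on the hottest FR sites. A statistics module provides the
tie-corrected Kruskal–Wallis test, the exact Wilcoxon signed-rank test,
and two-proportion trial sample-size/power with dropout inflation.

## Worked example

```r
library(frnetsim)

spec <- cohort_spec(n_patients = 1, shanks_per_patient = 8,
                    contacts_per_shank = 7, epoch_minutes = 20,
                    core_rate = 6, n_core_nodes = 4, seed = 21)
rec <- generate_cohort(spec)[[1]]
rec
#> <patient_record> S001
#>   contacts: 56  events: 2874  epoch: 20 min  outcome: seizure_free

net <- build_mi_network(rec)
net
#> <mi_network> 20 nodes, mean MI 0.00585 nats

resected <- rec$contacts$contact_id[rec$contacts$is_resected]
round(unlist(unclass(metric_vector(rec, net, resected))), 3)
#>            fr_rr    spatial_frnet temporal_frnet_a temporal_frnet_b
#>            0.810            6.026            1.609            1.000
#>           soz_rr          rons_rr          rono_rr         allfr_rr
#>            1.000            0.304            0.308            0.668

model <- function(m) if (m$fr_rr > 0.6) "seizure_free" else "not_seizure_free"
tr <- run_virtual_resection(rec, net, model)
tr$iterations[, c("iteration", "candidate", "radius_mm", "n_resected",
                  "fr_rr", "svm_label")]
#>   iteration   candidate radius_mm n_resected     fr_rr        svm_label
#> 1         1 S001-E01-01  10.00000          2 0.4023973 not_seizure_free
#> 2         2 S001-E01-02  10.00000          2 0.4023973 not_seizure_free
#> 3         3 S001-E01-03  25.23973          5 0.8099315     seizure_free

actual_resection_radius(rec)
#> [1] 15.23973
```

The 56-contact patient has a planted 4-node epileptogenic core generating
FR at ~6/min. The actual resection covers the core (FR RR 0.81, SOZ RR
1.0), and the virtual resection captures it in three iterations, ending
virtually seizure free with a 25.2 mm sphere versus the 15.2 mm actual
resection radius — virtual resections being larger than sufficient actual
ones is the expected regime. (A trained `fr_svm` from `train_svm()` can
replace the threshold-rule stub shown here; the stub makes the stopping
logic explicit.)

## Command line

```sh
inst/cli/frnetsim simulate-cohort --out d/ --n 4 --policy covers_core --seed 1
inst/cli/frnetsim compute-networks --patient d/S001 --out net.json
inst/cli/frnetsim compute-metrics --patient d/S001 --out metrics.json
inst/cli/frnetsim cohort-stats --cmd signrank --in pairs.csv --out out.json
```

See `vignettes/fr-network-analysis.Rmd` for the methods account: model
assumptions, parameter choices, estimator design, and limitations.
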
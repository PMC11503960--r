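Package: frnetsim
Title: Fast-Ripple Network Metrics, Virtual Resections and Neurostimulator
    Placement for Stereo-EEG
Version: 0.1.0
Authors@R:
    person("frnetsim", "developers", email = "frnetsim@example.org",
           role = c("aut", "cre"))
Description: Builds mutual-information networks from fast-ripple (FR) event
    trains recorded on stereo-EEG contacts, derives resection metrics (FR
    resection ratio, spatial FRnet, temporal FRnet-A/B), trains a radial basis
    function support vector machine to classify seizure freedom with
    leave-one-out cross-validation, simulates iterative spherical virtual
    resections labelled by the trained classifier, and evaluates actual and
    virtual responsive-neurostimulator (RNS) stimulation-contact placements.
    Includes a synthetic stereo-EEG cohort generator with planted
    epileptogenic cores for end-to-end testing, and the supporting
    statistics: tie-corrected Kruskal-Wallis, exact Wilcoxon signed-rank, and
    two-proportion trial sample-size calculations with dropout inflation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
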
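# Published summary metrics from a reference 18-patient SEEG resection
# cohort (9 seizure-free, 9 not), bundled so the statistical machinery can
# be validated desk-scale without any recordings. Values are per-patient
# virtual/actual resection radii (mm), resection ratios, FR network
# metrics, and virtual-vs-actual contact overlap summaries.

#' Reference cohort tables
#'
#' `ref_seizure_free_metrics()`: the nine seizure-free patients, all of
#' whom were also virtually seizure free. `ref_not_seizure_free_metrics()`:
#' the nine non-seizure-free patients; `v_radius_mm` is `NA` for the four
#' whose virtual resection never reached a seizure-free label.
#' `ref_overlap_seizure_free()` / `ref_overlap_not_seizure_free()`:
#' virtual-vs-actual contact contingency summaries for the patients with a
#' virtually-seizure-free resection.
#'
#' @return data.frame (one row per patient).
#' @export
ref_seizure_free_metrics <- function() {
  data.frame(
    patient = c("466", "477", "IO018", "4145", "4124", "4166", "IO008",
                "IO001", "453"),
    v_radius_mm = c(45.91, 18.57, 44.09, 29.42, 28.91, 85.00, 51.89,
                    45.38, 72.01),
    a_radius_mm = c(26.76, 10.77, 53.98, 22.42, 20.27, 40.07, 47.51,
                    23.59, 27.18),
    soz_rr = c(1.000, 1.000, 0.563, 0.885, 1.000, 1.000, 0.538, 1.000, 1.000),
    rons_rr = c(0.593, 0.880, 0.750, 0.874, 0.959, 1.000, 0.623, 0.882, 0.263),
    fr_rr = c(0.459, 0.845, 0.661, 0.976, 0.652, 1.000, 0.627, 0.800, 0.589),
    spatial_frnet = c(1.869, 3.561, 0.666, 0.000, 1.841, 0.000, 5.312,
                      0.978, 0.000),
    temporal_frnet_a = c(0.874, 3.905, 2.376, 2.062, 1.861, 1.000, 1.946,
                         1.622, 1.279),
    temporal_frnet_b = c(0.539, 0.406, 0.545, 0.264, 1.000, 1.000, 0.121,
                         1.000, 1.110),
    percent_r = c(1.000, 1.000, 0.406, 0.900, 0.909, 1.000, 0.679, 0.909,
                  1.000),
    novel_r = c(0.548, 0.000, 0.395, 0.486, 0.730, 0.639, 0.367, 0.836,
                0.452),
    stringsAsFactors = FALSE
  )
}

#' @rdname ref_seizure_free_metrics
#' @export
ref_not_seizure_free_metrics <- function() {
  data.frame(
    patient = c("IO005", "IO012", "469", "4110", "462", "IO023", "IO013",
                "IO015", "IO019"),
    virtually_seizure_free = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                               FALSE, FALSE),
    v_radius_mm = c(29.85, NA, 53.05, 35.08, 75.66, 74.12, NA, NA, NA),
    a_radius_mm = c(22.40, 18.42, 33.44, 27.11, 26.06, 9.02, 85.60, 50.24,
                    64.90),
    soz_rr = c(0.818, 1.000, 1.000, 0.318, 1.000, 1.000, 1.000, 0.625, 1.000),
    rons_rr = c(0.821, 0.879, 0.824, 0.191, 0.906, 0.935, 0.769, 0.992,
                0.998),
    fr_rr = c(0.776, 0.737, 0.947, 0.833, 0.429, 0.942, 0.814, 0.915, 0.932),
    spatial_frnet = c(0.000, 3.083, 0.000, 0.000, 4.360, 0.000, 2.517,
                      3.261, 2.602),
    temporal_frnet_a = c(2.222, 4.898, 1.249, 1.282, 0.894, 1.206, 1.076,
                         1.629, 1.001),
    temporal_frnet_b = c(0.207, 0.084, 0.353, 0.088, 0.262, 0.096, 1.000,
                         0.099, 1.000),
    percent_r = c(0.600, 0.818, 0.857, 0.162, 1.000, 0.000, 1.000, 0.000,
                  1.000),
    novel_r = c(0.800, 0.471, 0.478, 0.905, 0.600, 1.000, 0.832, 1.000,
                0.589),
    stringsAsFactors = FALSE
  )
}

#' @rdname ref_seizure_free_metrics
#' @export
ref_overlap_seizure_free <- function() {
  data.frame(
    patient = c("466", "477", "IO018", "4145", "4124", "4166", "IO008",
                "IO001", "453"),
    sensitivity = c(1.000, 1.000, 0.406, 0.900, 0.909, 1.000, 0.500, 0.476,
                    1.000),
    specificity = c(0.354, 1.000, 0.527, 0.624, 0.641, 0.238, 0.866, 0.573,
                    0.354),
    ppv = c(0.452, 0.140, 0.351, 0.237, 0.132, 0.698, 0.165, 0.109, 0.500),
    npv = c(1.000, 1.000, 0.558, 0.967, 0.985, 1.000, 0.835, 0.882, 1.000),
    accuracy = c(0.500, 1.000, 0.477, 0.673, 0.667, 0.508, 0.773, 0.561,
                 0.523),
    f1 = c(0.475, 1.000, 0.391, 0.493, 0.345, 0.591, 0.528, 0.217, 0.523),
    stringsAsFactors = FALSE
  )
}

#' @rdname ref_seizure_free_metrics
#' @export
ref_overlap_not_seizure_free <- function() {
  data.frame(
    patient = c("IO005", "469", "4110", "462"),
    sensitivity = c(0.600, 0.857, 0.162, 1.000),
    specificity = c(0.928, 0.324, 0.655, 0.681),
    ppv = c(0.065, 0.522, 0.077, 0.273),
    npv = c(0.956, 0.846, 0.699, 1.000),
    accuracy = c(0.896, 0.479, 0.531, 0.746),
    f1 = c(0.529, 0.490, 0.148, 0.615),
    stringsAsFactors = FALSE
  )
}
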
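test_that("candidate sequence: LE order, rate fallback, tie-breaks", {
  mi <- random_mi_matrix(3, zero_frac = 0, seed = 1)
  rownames(mi) <- colnames(mi) <- c("a", "b", "c")
  net <- fake_net(mi)
  net$nodal_le <- stats::setNames(c(0.1, 0.4, 0.2), c("a", "b", "c"))
  rates <- stats::setNames(c(2, 3, 0.5), c("a", "b", "c"))
  expect_identical(candidate_sequence(net, rates), c("a", "b", "c"))
  # none above threshold: pure descending-rate order
  expect_identical(candidate_sequence(net, rates, threshold = 5),
                   c("b", "a", "c"))
  # LE tie -> lexicographic contact id
  net$nodal_le <- stats::setNames(c(0.3, 0.3, 0.3), c("a", "b", "c"))
  expect_identical(candidate_sequence(net, stats::setNames(c(2, 2, 2),
                                                           c("a", "b", "c"))),
                   c("a", "b", "c"))
})

test_that("virtual resection captures a compact core and stops seizure-free", {
  rec <- generate_cohort(small_cohort_spec(seed = 21))[[1]]
  net <- build_mi_network(rec)
  stub <- function(mv) {
    if (mv$fr_rr > 0.6) "seizure_free" else "not_seizure_free"
  }
  tr <- run_virtual_resection(rec, net, stub)
  expect_s3_class(tr, "resection_trace")
  expect_identical(tr$termination, "virtually_seizure_free")
  expect_true(all(attr(rec, "core_nodes") %in% tr$virtual_set))
  expect_equal(tr$iterations$radius_mm[1], 10)       # initial 1-cm sphere
})

test_that("trace invariants: monotone radii, nested sets, ipsilateral only", {
  for (seed in c(21, 22)) {
    rec <- generate_cohort(small_cohort_spec(seed = seed))[[1]]
    net <- build_mi_network(rec)
    never <- function(mv) "not_seizure_free"
    tr <- run_virtual_resection(rec, net, never)
    expect_true(all(diff(tr$iterations$radius_mm) >= 0))
    for (k in seq_along(tr$virtual_sets)[-1]) {
      expect_true(all(tr$virtual_sets[[k - 1]] %in% tr$virtual_sets[[k]]))
    }
    # FR RR monotone along the trace
    expect_true(all(diff(tr$iterations$fr_rr) >= -1e-12))
    # contralateral contacts never enter any virtual set
    center_h <- rec$contacts$hemisphere[rec$contacts$contact_id == tr$center]
    for (vs in tr$virtual_sets) {
      hemi <- rec$contacts$hemisphere[match(vs, rec$contacts$contact_id)]
      expect_true(all(hemi == center_h))
    }
  }
})

test_that("three-lobe extent stops the simulation as not seizure free", {
  f <- make_fixture("two_lobe_core")
  net <- build_mi_network(f)
  never <- function(mv) "not_seizure_free"
  tr <- run_virtual_resection(f, net, never)
  expect_identical(tr$termination, "three_lobe_stop")
  last <- tr$iterations[nrow(tr$iterations), ]
  expect_gte(last$n_lobes, 3)
  expect_identical(last$svm_label, "not_seizure_free")
})

test_that("candidate exhaustion labels the patient not seizure free", {
  tw <- make_fixture("twin_trains")
  net <- build_mi_network(tw)
  never <- function(mv) "not_seizure_free"
  tr <- run_virtual_resection(tw, net, never)
  expect_identical(tr$termination, "candidates_exhausted")
  expect_false(tr$virtually_seizure_free)
})

test_that("overlap metrics follow the contingency formulas", {
  ids <- paste0("c", 1:10)
  same <- overlap_metrics(ids[1:4], ids[1:4], ids)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)
  expect_equal(same$accuracy, 1)
  expect_equal(same$f1, 1)
  expect_equal(same$percent_r, 1)
  expect_equal(same$novel_r, 0)
  disj <- overlap_metrics(ids[1:3], ids[4:6], ids)
  expect_equal(disj$percent_r, 0)
  expect_equal(disj$novel_r, 1)
  m <- overlap_metrics(ids[1:4], ids[c(1:3, 5)], ids)   # TP3 FP1 FN1 TN5
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  empty <- overlap_metrics(ids[1:2], character(0), ids)
  expect_true(is.na(empty$percent_r))
  expect_true(attr(empty, "empty_actual"))
})

test_that("actual resection radius matches the Euclidean graph oracle", {
  contacts <- contact_table(c("a", "b"), "E1", c(5, 25), 0, 0, "insula", "R")
  ev <- event_table("a", "fRonS", 1)
  rec <- patient_record("p", contacts, ev, 10)
  expect_equal(actual_resection_radius(rec, c("a", "b")), 20)
  expect_equal(actual_resection_radius(rec, "a"), 0)
  expect_error(actual_resection_radius(rec, character(0)), "empty")
  f <- make_fixture("line3")
  expect_equal(actual_resection_radius(f), 10)
  rec2 <- generate_cohort(small_cohort_spec(seed = 33))[[1]]
  res <- rec2$contacts$contact_id[rec2$contacts$is_resected]
  pos <- as.matrix(rec2$contacts[match(res, rec2$contacts$contact_id),
                                 c("x", "y", "z")])
  expect_equal(actual_resection_radius(rec2, res),
               oracle_radius(as.matrix(dist(pos))))
})
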
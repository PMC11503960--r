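make_rr_patient <- function() {
  contacts <- contact_table(c("a", "b", "c"), "E1", c(10, 15, 20), 0, 0,
                            "middletemporal", "R",
                            is_soz = c(TRUE, TRUE, TRUE))
  ev <- event_table(c(rep("a", 3), "b"), "fRonS", c(1, 2, 3, 4))
  patient_record("p", contacts, ev, 10)
}

test_that("event-weighted and contact-weighted resection ratios", {
  rec <- make_rr_patient()
  expect_equal(as.numeric(resection_ratio(rec, "a")), 0.75)
  expect_equal(as.numeric(resection_ratio(rec, c("a", "b", "c"))), 1.0)
  expect_equal(as.numeric(resection_ratio(rec, character(0))), 0.0)
  expect_equal(soz_resection_ratio(rec, c("a", "b")), 2 / 3)
  expect_error(resection_ratio(rec, "zz"), "unknown contacts")
  r0 <- resection_ratio(rec, "a", "RonO")            # class with no events
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "no_events"))
  # adding a zero-event contact never changes an event-weighted RR
  expect_equal(as.numeric(resection_ratio(rec, c("a", "c"))), 0.75)
  # monotone in the resected set
  expect_lte(as.numeric(resection_ratio(rec, "a")),
             as.numeric(resection_ratio(rec, c("a", "b"))))
})

test_that("spatial FRnet: zero on full resection, closed form, oracle", {
  f <- make_fixture("line3")
  expect_equal(spatial_frnet(f, c("a", "b", "c")), 0.0)
  # constructed radii 9 (whole) vs 5 (resected pair) -> sqrt(4) = 2
  contacts <- contact_table(c("a", "b", "c"), "E1", c(2, 7, 16), 0, 0,
                            "insula", "R")
  ev <- event_table(c("a", "b", "c"), "fRonS", c(1, 2, 3))
  rec <- patient_record("p", contacts, ev, 1)        # all rates 1/min
  expect_equal(spatial_frnet(rec, c("a", "b")), 2.0)
  # random fixture: equals sqrt(max(delta radius, 0)) via the FW oracle
  rec2 <- generate_cohort(small_cohort_spec(seed = 23))[[1]]
  rates <- compute_rates(rec2)
  fr_nodes <- rates$contact_id[rates$FR_gt350 > 0]
  res <- intersect(fr_nodes, rec2$contacts$contact_id[rec2$contacts$is_resected])
  w <- rate_distance_graph(rec2$contacts, rates, fr_nodes)
  expected <- sqrt(max(oracle_radius(w) -
                         oracle_radius(w[res, res, drop = FALSE]), 0))
  expect_equal(spatial_frnet(rec2, res, rates), expected)
})

test_that("temporal FRnet-A: whole-network ratio 1, oracle, degenerate", {
  mi <- random_mi_matrix(8, zero_frac = 0.2, seed = 31)
  net <- fake_net(mi)
  expect_equal(temporal_frnet_a(net, rownames(mi)), 1.0)
  sub <- rownames(mi)[sample(8, 4)]
  expect_equal(temporal_frnet_a(net, sub),
               oracle_cpl(mi, match(sub, rownames(mi))) / oracle_cpl(mi))
  deg <- temporal_frnet_a(net, rownames(mi)[1])
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  # resecting exactly the pair with the single largest distance -> ratio > 1
  worst <- which(net$distance == max(net$distance[is.finite(net$distance)]),
                 arr.ind = TRUE)[1, ]
  pair <- rownames(mi)[worst]
  d_pair <- net$distance[pair[1], pair[2]]
  if (is.finite(d_pair) && d_pair > oracle_cpl(mi)) {
    expect_gt(temporal_frnet_a(net, pair), 1)
  }
})

test_that("temporal FRnet-B: unresected-mean convention", {
  mi <- random_mi_matrix(6, zero_frac = 0.1, seed = 37)
  net <- fake_net(mi)
  expect_equal(temporal_frnet_b(net, rownames(mi)), 1.0)  # full resection
  net2 <- net
  net2$nodal_le <- stats::setNames(c(0.4, 0.4, 0.4, 0, 0, 0), rownames(mi))
  expect_equal(temporal_frnet_b(net2, character(0)), 0.4) # LE 0 excluded
  expect_equal(temporal_frnet_b(net2, rownames(mi)[1:3]), 1.0)
  # literal all-nodes reading via scope switch
  expect_equal(temporal_frnet_b(net2, rownames(mi)[1:3], scope = "all"), 0.4)
})

test_that("metric vector: full and empty resection patterns", {
  rec <- generate_cohort(small_cohort_spec(seed = 29))[[1]]
  net <- build_mi_network(rec)
  all_ids <- rec$contacts$contact_id
  mv_full <- metric_vector(rec, net, all_ids)
  expect_equal(mv_full$fr_rr, 1.0)
  expect_equal(mv_full$spatial_frnet, 0.0)
  expect_equal(mv_full$temporal_frnet_a, 1.0)
  expect_equal(mv_full$temporal_frnet_b, 1.0)
  mv_none <- metric_vector(rec, net, character(0))
  expect_equal(mv_none$fr_rr, 0)
  expect_equal(mv_none$soz_rr, 0)
  expect_equal(mv_none$rons_rr, 0)
  expect_true(all(is.finite(unlist(as_feature_row(mv_none)))))
})

test_that("whole-set invariants hold across generated cohorts (property)", {
  for (seed in c(41, 43)) {
    rec <- generate_cohort(small_cohort_spec(seed = seed))[[1]]
    net <- build_mi_network(rec)
    expect_equal(as.numeric(temporal_frnet_a(net, net$node_ids)), 1.0)
    expect_equal(spatial_frnet(rec, rec$contacts$contact_id), 0.0)
  }
})

test_that("autonomy clustering recovers planted structure", {
  # well-separated planted clusters: exact recovery
  set.seed(6)
  rates <- stats::setNames(c(10^runif(6, 0.8, 1.2), 10^runif(8, -1.2, -0.8)),
                           paste0("n", 1:14))
  le <- stats::setNames(c(runif(6, 0, 0.05), runif(8, 0.6, 0.9)),
                        names(rates))
  cl <- autonomy_cluster(rates, le, seed = 3)
  expect_setequal(cl$autonomous_set, paste0("n", 1:6))
  expect_false(cl$degenerate)
  # identical nodes -> single effective cluster, flagged
  same <- stats::setNames(rep(2, 4), paste0("m", 1:4))
  le0 <- stats::setNames(rep(0.3, 4), names(same))
  expect_true(autonomy_cluster(same, le0)$degenerate)
})

test_that("unresected autonomous nodes differ by resection policy", {
  count_unresected_autonomous <- function(policy, seed) {
    rec <- generate_cohort(small_cohort_spec(policy, seed = seed))[[1]]
    net <- build_mi_network(rec)
    rates <- compute_rates(rec)
    r <- stats::setNames(rates$FR_gt350, rates$contact_id)[net$node_ids]
    cl <- autonomy_cluster(r, net$nodal_le, seed = 1)
    resected <- rec$contacts$contact_id[rec$contacts$is_resected]
    length(setdiff(cl$autonomous_set, resected))
  }
  miss <- sum(vapply(1:3, function(s)
    count_unresected_autonomous("misses_core", 50 + s), numeric(1)))
  cover <- sum(vapply(1:3, function(s)
    count_unresected_autonomous("covers_core", 50 + s), numeric(1)))
  expect_gt(miss, cover)
  # misses_core always leaves autonomous nodes unresected
  expect_gt(count_unresected_autonomous("misses_core", 61), 0)
})
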
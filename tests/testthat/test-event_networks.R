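test_that("rates are count / epoch_minutes", {
  contacts <- contact_table(c("a", "b"), "E1", c(10, 15), 0, 0, "insula", "R")
  ev <- event_table(rep("a", 30), "fRonS", seq_len(30))
  rec <- patient_record("p", contacts, ev, 30)
  r <- compute_rates(rec)
  expect_equal(r$fRonS[r$contact_id == "a"], 1.0)
  expect_equal(r$FR_gt350[r$contact_id == "b"], 0.0)        # empty train
  ev2 <- event_table(rep("a", 45), "RonO", seq_len(45))
  rec2 <- patient_record("p", contacts, ev2, 10)
  expect_equal(compute_rates(rec2)$RonO[1], 4.5)
  expect_error(compute_rates(ev2, epoch_minutes = 0), "positive")
})

test_that("MI is symmetric, nonnegative, and zero on degenerate input", {
  set.seed(3)
  for (i in 1:5) {
    a <- sort(runif(50 + i * 10, 0, 1800))
    b <- sort(runif(60, 0, 1800))
    m1 <- mi_between_trains(a, b)
    expect_identical(m1, mi_between_trains(b, a))
    expect_gte(m1, 0)
  }
  expect_identical(mi_between_trains(numeric(0), 1:10), 0)
  expect_identical(mi_between_trains(c(1, 2), 5), 0)
})

test_that("MI separates identical trains from independence (shift null)", {
  tw <- make_fixture("twin_trains")
  a <- event_train(tw, "a")
  epoch_s <- tw$epoch_minutes * 60
  null <- mi_shift_null(a, a, epoch_s, n_shift = 200, seed = 4)
  expect_gt(mi_between_trains(a, a), stats::quantile(null, 0.95))

  set.seed(9)
  p <- sort(runif(120, 0, 3600))
  q <- sort(runif(120, 0, 3600))
  null_pq <- mi_shift_null(p, q, 3600, n_shift = 200, seed = 5)
  expect_lte(mi_between_trains(p, q), stats::quantile(null_pq, 0.95))

  # time-reversed-and-shifted copy looks independent
  rev_a <- sort((epoch_s - a + 137) %% epoch_s)
  expect_lte(mi_between_trains(a, rev_a), stats::quantile(null, 0.95))
})

test_that("build_mi_network shapes, symmetry and failure mode", {
  tw <- make_fixture("twin_trains")
  net <- build_mi_network(tw)
  expect_setequal(net$node_ids, c("a", "b"))
  expect_gt(net$mi["a", "b"], 0)
  expect_identical(net$mi, t(net$mi))
  expect_equal(net$distance["a", "b"], 1 / net$mi["a", "b"])

  rec <- generate_cohort(small_cohort_spec(seed = 3))[[1]]
  net2 <- build_mi_network(rec)
  expect_identical(net2$mi, t(net2$mi))
  expect_true(all(net2$mi >= 0))
  expect_equal(unname(diag(net2$mi)), rep(0, length(net2$node_ids)))

  lone <- patient_record("p",
    contact_table(c("a", "b"), "E1", c(10, 15), 0, 0, "insula", "R"),
    event_table("a", "fRonS", c(1, 2, 3)), 10)
  expect_error(build_mi_network(lone), "no FR MI network")
})

test_that("graph radius: closed forms and oracle equivalence", {
  f <- make_fixture("line3")
  len <- as.matrix(dist(as.matrix(f$contacts[, c("x", "y", "z")])))
  expect_equal(graph_radius(len), 10)               # middle-node eccentricity
  expect_equal(graph_radius(matrix(0, 1, 1)), 0)
  expect_equal(graph_radius(matrix(c(0, 7, 7, 0), 2)), 7)
  expect_error(graph_radius(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(2:8, 1)
    len <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    expect_equal(graph_radius(len), oracle_radius(len))
    d <- fw_shortest(len)
    expect_lte(graph_radius(len), max(apply(d, 1, max)))
  }
})

test_that("characteristic path length: closed forms and oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  rownames(tri) <- colnames(tri) <- c("a", "b", "c")
  expect_equal(characteristic_path_length(fake_net(tri)), 1.0)
  two <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(characteristic_path_length(fake_net(two)), 2.0)
  expect_error(characteristic_path_length(fake_net(two), "a"), ">= 2")
  for (seed in 1:6) {
    mi <- random_mi_matrix(7, zero_frac = 0.3, seed = seed)
    expect_equal(as.numeric(characteristic_path_length(fake_net(mi))),
                 oracle_cpl(mi))
    sub <- sample(7, 4)
    expect_equal(
      as.numeric(characteristic_path_length(fake_net(mi), rownames(mi)[sub])),
      oracle_cpl(mi, sub))
  }
  # fully disconnected subset -> Inf sentinel with flag
  z <- matrix(0, 3, 3); rownames(z) <- colnames(z) <- c("a", "b", "c")
  cpl <- characteristic_path_length(fake_net(z))
  expect_identical(as.numeric(cpl), Inf)
  expect_true(attr(cpl, "all_infinite"))
})

test_that("local efficiency: definitional cases and oracle", {
  k3 <- matrix(0.6, 3, 3); diag(k3) <- 0
  rownames(k3) <- colnames(k3) <- c("a", "b", "c")
  le <- local_efficiency(k3)
  expect_equal(unname(le), rep(0.6, 3))             # symmetry + closed form
  path2 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3) # middle node has 2 nbrs
  rownames(path2) <- colnames(path2) <- c("a", "b", "c")
  lp <- local_efficiency(path2)
  expect_equal(unname(lp[c("a", "c")]), c(0, 0))    # < 2 neighbours
  for (seed in 1:6) {
    mi <- random_mi_matrix(6, zero_frac = 0.35, seed = 100 + seed)
    expect_equal(local_efficiency(mi), oracle_le(mi))
  }
})

test_that("global efficiency: closed forms and oracle", {
  one <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(global_efficiency(one), 1.0)
  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(global_efficiency(zero), 0.0)
  expect_equal(global_efficiency(matrix(0, 1, 1)), 0)
  for (seed in 1:6) {
    mi <- random_mi_matrix(6, zero_frac = 0.3, seed = 200 + seed)
    expect_equal(global_efficiency(mi), oracle_ge(mi))
  }
})

test_that("homogeneity: scaling MI by c scales CPL by 1/c and GE by c", {
  mi <- random_mi_matrix(6, zero_frac = 0.2, seed = 42)
  for (c_ in c(0.5, 3)) {
    expect_equal(as.numeric(characteristic_path_length(fake_net(c_ * mi))),
                 as.numeric(characteristic_path_length(fake_net(mi))) / c_)
    expect_equal(global_efficiency(c_ * mi), c_ * global_efficiency(mi))
  }
})

test_that("rate-distance graph weights are mean pair rate times distance", {
  f <- make_fixture("line3")
  rates <- compute_rates(f)
  w <- rate_distance_graph(f$contacts, rates)
  r <- stats::setNames(rates$FR_gt350, rates$contact_id)
  expect_equal(w["a", "b"], unname((r["a"] + r["b"]) / 2 * 10))
  expect_equal(w["a", "c"], unname((r["a"] + r["c"]) / 2 * 20))
  expect_identical(w, t(w))
})
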
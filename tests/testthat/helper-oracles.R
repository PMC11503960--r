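# Independent oracles: plain-loop Floyd-Warshall all-pairs shortest paths
# and direct-formula graph measures, used to cross-check the package's
# igraph-backed implementations.

fw_shortest <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_radius <- function(len) {
  if (nrow(len) <= 1) return(0)
  d <- fw_shortest(len)
  min(apply(d, 1, max))
}

oracle_cpl <- function(mi, subset_idx = seq_len(nrow(mi))) {
  len <- ifelse(mi > 0, 1 / mi, Inf)
  diag(len) <- 0
  len <- len[subset_idx, subset_idx, drop = FALSE]
  d <- fw_shortest(len)
  vals <- d[row(d) != col(d)]
  mean(vals[is.finite(vals)])
}

oracle_ge <- function(mi, subset_idx = seq_len(nrow(mi))) {
  mi <- mi[subset_idx, subset_idx, drop = FALSE]
  if (nrow(mi) < 2) return(0)
  len <- ifelse(mi > 0, 1 / mi, Inf)
  diag(len) <- 0
  d <- fw_shortest(len)
  vals <- d[row(d) != col(d)]
  mean(ifelse(is.finite(vals) & vals > 0, 1 / vals, 0))
}

oracle_le <- function(w) {
  n <- nrow(w)
  le <- numeric(n)
  for (u in seq_len(n)) {
    V <- which(w[u, ] > 0 & seq_len(n) != u)
    k <- length(V)
    if (k < 2) next
    len <- ifelse(w[V, V, drop = FALSE] > 0,
                  (1 / w[V, V, drop = FALSE])^(1 / 3), Inf)
    diag(len) <- 0
    d <- fw_shortest(len)
    s <- 0
    for (j in seq_len(k)) {
      for (h in seq_len(k)) {
        if (j != h && is.finite(d[j, h]) && d[j, h] > 0) {
          s <- s + (w[u, V[j]] * w[u, V[h]])^(1 / 3) / d[j, h]
        }
      }
    }
    le[u] <- s / (k * (k - 1))
  }
  names(le) <- rownames(w)
  le
}

# random symmetric nonnegative MI matrix with a given zero-edge fraction
random_mi_matrix <- function(n, zero_frac = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  v <- runif(sum(ut), 0.05, 2)
  v[runif(length(v)) < zero_frac] <- 0
  m[ut] <- v
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("n", seq_len(n))
  m
}

fake_net <- function(mi, positions = NULL) {
  dist <- ifelse(mi > 0, 1 / mi, Inf)
  diag(dist) <- 0
  net <- structure(list(node_ids = rownames(mi), mi = mi, distance = dist,
                        nodal_le = NULL, positions = positions),
                   class = "mi_network")
  net$nodal_le <- local_efficiency(net)
  net
}

# circular-shift permutation null for the MI between two trains
mi_shift_null <- function(a, b, epoch_s, n_shift = 200, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n_shift), function(i) {
    s <- runif(1, 0, epoch_s)
    mi_between_trains(a, sort((b + s) %% epoch_s))
  }, numeric(1))
}

small_cohort_spec <- function(policy = "covers_core", n = 1, seed = 1) {
  cohort_spec(n_patients = n, shanks_per_patient = 8, contacts_per_shank = 7,
              epoch_minutes = 20, resection_policy = policy, seed = seed)
}
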
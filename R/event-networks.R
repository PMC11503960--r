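# Per-contact event rates, mutual information between event trains, and the
# weighted graph measures (radius, characteristic path length, local and
# global efficiency) used by the resection metrics.
#
# Conventions: MI is in nats; an MI edge of 0 has infinite length (no path
# through it); shortest paths treat edge weights as lengths; distances are
# millimetres throughout the spatial graphs.

#' Per-contact event rates
#'
#' Rate = event count / epoch duration, events/min, per (contact, class)
#' pair. Classes with no events have rate 0. The synthetic column
#' `FR_gt350` is the analysis union (fRonO > 350 Hz plus all fRonS).
#'
#' @param record a `patient_record`, or an event table if `epoch_minutes`
#'   is supplied.
#' @param epoch_minutes epoch duration (min) when `record` is an event table.
#' @return data.frame: one row per contact, one column per event class plus
#'   `FR_gt350`, values in events/min.
#' @export
compute_rates <- function(record, epoch_minutes = NULL) {
  if (inherits(record, "patient_record")) {
    events <- record$events
    epoch_minutes <- record$epoch_minutes
    ids <- record$contacts$contact_id
  } else {
    events <- record
    ids <- unique(events$contact_id)
  }
  if (is.null(epoch_minutes) || epoch_minutes <= 0) {
    stop("epoch_minutes must be positive")
  }
  classes <- c(EVENT_CLASSES, "FR_gt350")
  out <- data.frame(contact_id = ids, stringsAsFactors = FALSE)
  for (cls in EVENT_CLASSES) {
    cnt <- table(factor(events$contact_id[events$event_class == cls],
                        levels = ids))
    out[[cls]] <- as.numeric(cnt) / epoch_minutes
  }
  out$FR_gt350 <- out$fRonO_gt350 + out$fRonS
  out
}

#' Mutual information between two event trains
#'
#' Darbellay-Vajda adaptive-partition estimator applied to paired
#' inter-event-interval samples. For each event in train `a` (except the
#' last), the sample is (interval to `a`'s next event, forward waiting time
#' to the next event of `b`). The partition over the rank-transformed plane
#' is refined while a chi-square equiprobability test rejects at
#' `alpha`; the estimator is run in both directions and averaged, and the
#' result clamped at 0. Trains with fewer than 2 events give MI = 0.
#'
#' @param a,b numeric onset vectors (s), sorted.
#' @param alpha chi-square level for partition refinement.
#' @param min_cell smallest cell the partition may split.
#' @return MI in nats, >= 0; exactly symmetric in its arguments.
#' @export
mi_between_trains <- function(a, b, alpha = 0.05, min_cell = 8) {
  if (length(a) < 2 || length(b) < 2) return(0)
  m <- (mi_directed(a, b, alpha, min_cell) +
          mi_directed(b, a, alpha, min_cell)) / 2
  max(m, 0)
}

mi_directed <- function(a, b, alpha, min_cell) {
  x <- diff(a)                                   # interval to next a-event
  ref <- a[-length(a)]
  idx <- findInterval(ref, b) + 1L               # first b-event > ref
  y <- ifelse(idx <= length(b), b[idx] - ref, NA_real_)
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) return(0)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  mi_adaptive_ranks(rx, ry, n, alpha, min_cell)
}

# Recursive adaptive partitioning on the rank plane. A cell spanning rank
# windows [x1,x2] x [y1,y2] is split at the window midpoints into four
# quadrants. Equiprobability is tested at two depths (the 4 quadrants,
# chi-square 3 df, and the 16 sub-quadrants, 15 df): if either rejects at
# `alpha` the quadrants are refined further, otherwise the cell contributes
# p * log(p / (px * py)) where p, px, py are the joint and marginal
# probabilities implied by the rank windows. The two-depth test is what
# gives the estimator power against thin (near-diagonal) dependence.
mi_adaptive_ranks <- function(rx, ry, n, alpha, min_cell) {
  crit4 <- stats::qchisq(1 - alpha, df = 3)
  crit16 <- stats::qchisq(1 - alpha, df = 15)
  quarter_counts <- function(v, lo, hi, idx) {
    # counts of v[idx] in the 4 near-equal rank quarters of [lo, hi]
    qs <- lo - 1 + floor((hi - lo + 1) * (1:3) / 4)
    f <- findInterval(v[idx], c(qs + 0.5))
    tabulate(f + 1L, nbins = 4L)
  }
  rec <- function(idx, x1, x2, y1, y2) {
    m <- length(idx)
    if (m == 0) return(0)
    term <- function() {
      p <- m / n
      px <- (x2 - x1 + 1) / n
      py <- (y2 - y1 + 1) / n
      p * log(p / (px * py))
    }
    if (m < min_cell || x2 - x1 < 1 || y2 - y1 < 1) return(term())
    mx <- floor((x1 + x2) / 2)
    my <- floor((y1 + y2) / 2)
    left <- rx[idx] <= mx
    low <- ry[idx] <= my
    cnt <- c(sum(left & low), sum(left & !low),
             sum(!left & low), sum(!left & !low))
    chi2 <- sum((cnt - m / 4)^2) / (m / 4)
    reject <- chi2 > crit4
    if (!reject && x2 - x1 >= 3 && y2 - y1 >= 3 && m >= 4 * min_cell) {
      fx <- findInterval(rx[idx],
                         x1 - 1 + floor((x2 - x1 + 1) * (1:3) / 4) + 0.5)
      fy <- findInterval(ry[idx],
                         y1 - 1 + floor((y2 - y1 + 1) * (1:3) / 4) + 0.5)
      cnt16 <- tabulate(fx * 4L + fy + 1L, nbins = 16L)
      chi16 <- sum((cnt16 - m / 16)^2) / (m / 16)
      reject <- chi16 > crit16
    }
    if (!reject) return(term())
    rec(idx[left & low], x1, mx, y1, my) +
      rec(idx[left & !low], x1, mx, my + 1, y2) +
      rec(idx[!left & low], mx + 1, x2, y1, my) +
      rec(idx[!left & !low], mx + 1, x2, my + 1, y2)
  }
  rec(seq_len(length(rx)), 1L, n, 1L, n)
}

#' Build the FR > 350 Hz mutual-information network
#'
#' Nodes are contacts with at least one FR>350 Hz event; edges are pairwise
#' MI between their onset trains; distances are the elementwise inverse of
#' MI (infinite where MI = 0). Nodal local efficiency is attached.
#'
#' @param record a `patient_record`.
#' @param alpha,min_cell MI estimator parameters.
#' @return object of class `mi_network`: `node_ids`, `mi` (symmetric
#'   matrix, nats), `distance`, `nodal_le` (named), `positions`.
#' @export
build_mi_network <- function(record, alpha = 0.05, min_cell = 8) {
  trains <- lapply(record$contacts$contact_id, function(id) {
    event_train(record, id, "FR_gt350")
  })
  names(trains) <- record$contacts$contact_id
  keep <- vapply(trains, length, integer(1)) >= 1
  ids <- names(trains)[keep]
  if (length(ids) < 2) {
    stop("no FR MI network: fewer than 2 FR>350 Hz generating contacts ",
         "(poor spatial sampling)")
  }
  k <- length(ids)
  mi <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- mi_between_trains(trains[[ids[i]]], trains[[ids[j]]],
                             alpha = alpha, min_cell = min_cell)
      mi[i, j] <- v
      mi[j, i] <- v
    }
  }
  dist <- ifelse(mi > 0, 1 / mi, Inf)
  diag(dist) <- 0
  pos <- as.matrix(record$contacts[match(ids, record$contacts$contact_id),
                                   c("x", "y", "z")])
  rownames(pos) <- ids
  net <- structure(list(node_ids = ids, mi = mi, distance = dist,
                        nodal_le = NULL, positions = pos),
                   class = "mi_network")
  net$nodal_le <- local_efficiency(net)
  net
}

#' @export
print.mi_network <- function(x, ...) {
  cat("<mi_network>", length(x$node_ids), "nodes, mean MI",
      signif(mean(x$mi[upper.tri(x$mi)]), 3), "nats\n")
  invisible(x)
}

# All-pairs shortest path lengths treating `len` entries as edge lengths.
# Inf entries are absent edges. Returns a matrix with 0 diagonal.
shortest_paths_len <- function(len) {
  n <- nrow(len)
  if (n <= 1) return(matrix(0, n, n))
  ut <- which(upper.tri(len), arr.ind = TRUE)
  w <- len[ut]
  fin <- is.finite(w)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(fin)) {
    g <- igraph::add_edges(g, t(ut[fin, , drop = FALSE]))
    d <- igraph::distances(g, weights = w[fin], algorithm = "dijkstra")
  } else {
    d <- igraph::distances(g)
  }
  dimnames(d) <- dimnames(len)
  d
}

#' Radius of a complete weighted graph
#'
#' Eccentricity of a node is its largest shortest-path length to any other
#' node (edge weights are lengths); the radius is the smallest eccentricity.
#' Graphs with 0 or 1 node have radius 0.
#'
#' @param edge_lengths symmetric nonnegative matrix of edge lengths (use
#'   `Inf` for absent edges).
#' @return scalar radius (same units as the lengths).
#' @export
graph_radius <- function(edge_lengths) {
  n <- nrow(edge_lengths)
  if (is.null(n) || n <= 1) return(0)
  if (any(edge_lengths[is.finite(edge_lengths)] < 0)) {
    stop("edge lengths must be nonnegative")
  }
  d <- shortest_paths_len(edge_lengths)
  ecc <- apply(d, 1, max)
  min(ecc)
}

#' Characteristic path length of a node subset
#'
#' Mean of the finite pairwise shortest-path distances (lengths = 1/MI)
#' over ordered pairs within `node_subset`, with paths restricted to the
#' subset-induced subgraph. If no pair has a finite path, returns `Inf`
#' with attribute `all_infinite = TRUE`; if some pairs are infinite the
#' result carries `has_infinite = TRUE`.
#'
#' @param net an `mi_network` (or any list with a `distance` matrix).
#' @param node_subset node ids, length >= 2 (default: all nodes).
#' @return scalar path length (1/nats units).
#' @export
characteristic_path_length <- function(net, node_subset = NULL) {
  if (is.null(node_subset)) node_subset <- rownames(net$distance)
  if (length(node_subset) < 2) stop("node subset must have >= 2 nodes")
  len <- net$distance[node_subset, node_subset, drop = FALSE]
  d <- shortest_paths_len(len)
  vals <- d[row(d) != col(d)]
  fin <- is.finite(vals)
  if (!any(fin)) {
    return(structure(Inf, all_infinite = TRUE))
  }
  out <- mean(vals[fin])
  if (!all(fin)) attr(out, "has_infinite") <- TRUE
  out
}

#' Weighted nodal local efficiency
#'
#' Brain Connectivity Toolbox convention: for node u with neighbourhood V
#' (positive-MI neighbours), local efficiency is the mean over neighbour
#' pairs of `w(u,j)^(1/3) * w(u,h)^(1/3) * e(j,h)`, where `e` is the
#' inverse shortest-path length within the subgraph induced by V computed on
#' cube-root edge lengths `(1/w)^(1/3)`. Nodes with fewer than two
#' positive-MI neighbours have LE 0.
#'
#' @param net an `mi_network`, or a symmetric nonnegative weight matrix.
#' @return named numeric vector of per-node LE, >= 0.
#' @export
local_efficiency <- function(net) {
  w <- if (inherits(net, "mi_network")) net$mi else net
  n <- nrow(w)
  ids <- rownames(w)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  le <- stats::setNames(numeric(n), ids)
  if (n == 0) return(le)
  len3 <- ifelse(w > 0, (1 / w)^(1 / 3), Inf)
  diag(len3) <- 0
  for (u in seq_len(n)) {
    V <- which(w[u, ] > 0 & seq_len(n) != u)
    k <- length(V)
    if (k < 2) next
    e <- shortest_paths_len(len3[V, V, drop = FALSE])
    einv <- ifelse(is.finite(e) & e > 0, 1 / e, 0)
    a <- w[u, V]^(1 / 3)
    num <- sum(outer(a, a) * einv)        # diagonal of einv is 0
    le[u] <- num / (k * (k - 1))
  }
  le
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance
#' (distance = 1/MI); a disconnected pair contributes 0. Fewer than 2 nodes
#' gives 0.
#'
#' @param net an `mi_network`, or a symmetric nonnegative MI matrix.
#' @param node_subset optional node ids restricting to an induced subgraph.
#' @return scalar efficiency >= 0 (nats units).
#' @export
global_efficiency <- function(net, node_subset = NULL) {
  w <- if (inherits(net, "mi_network")) net$mi else net
  if (!is.null(node_subset)) w <- w[node_subset, node_subset, drop = FALSE]
  n <- nrow(w)
  if (is.null(n) || n < 2) return(0)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- shortest_paths_len(len)
  vals <- d[row(d) != col(d)]
  mean(ifelse(is.finite(vals) & vals > 0, 1 / vals,
              ifelse(vals == 0, 0, 0)))
}

#' Rate-distance spatial graph
#'
#' Complete graph over FR>350 Hz generating contacts whose edge weight is
#' the mean of the two contacts' FR>350 Hz rates (events/min) multiplied by
#' their Euclidean distance (mm). Used as edge *lengths* by the spatial
#' FRnet radius.
#'
#' @param contacts a contact table.
#' @param rates a [compute_rates()] table.
#' @param node_ids contacts to include (default: all with FR_gt350 rate > 0).
#' @return symmetric matrix of edge weights (rate x mm units).
#' @export
rate_distance_graph <- function(contacts, rates, node_ids = NULL) {
  r <- stats::setNames(rates$FR_gt350, rates$contact_id)
  if (is.null(node_ids)) node_ids <- rates$contact_id[rates$FR_gt350 > 0]
  k <- length(node_ids)
  pos <- as.matrix(contacts[match(node_ids, contacts$contact_id),
                            c("x", "y", "z")])
  w <- matrix(0, k, k, dimnames = list(node_ids, node_ids))
  if (k < 2) return(w)
  dmat <- as.matrix(stats::dist(pos))
  rmean <- outer(r[node_ids], r[node_ids], function(a, b) (a + b) / 2)
  w <- rmean * dmat
  dimnames(w) <- list(node_ids, node_ids)
  w
}
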
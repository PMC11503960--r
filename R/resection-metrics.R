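# The four classifier factors -- FR resection ratio, spatial FRnet,
# temporal FRnet-A (gammaRR), temporal FRnet-B (urmLE) -- plus auxiliary
# resection ratios and the k-means autonomy clustering. All functions are
# used identically for actual and virtual resected sets.

#' Event-weighted resection ratio
#'
#' Total number of events of `event_class` on resected contacts divided by
#' the total number of events of that class on all contacts.
#' `event_class = "FR_gt350"` uses the analysis union (fRonO > 350 Hz plus
#' all fRonS). If the class has no events at all, returns 0 with attribute
#' `no_events = TRUE`.
#'
#' @param record a `patient_record`.
#' @param resected_set character vector of resected contact ids (must all
#'   exist in the record).
#' @param event_class event class or `"FR_gt350"`.
#' @return scalar in \[0, 1\].
#' @export
resection_ratio <- function(record, resected_set, event_class = "FR_gt350") {
  bad <- setdiff(resected_set, record$contacts$contact_id)
  if (length(bad)) stop("resected set contains unknown contacts: ",
                        paste(bad, collapse = ", "))
  cls <- if (identical(event_class, "FR_gt350")) c("fRonO_gt350", "fRonS")
  else event_class
  ev <- record$events[record$events$event_class %in% cls, , drop = FALSE]
  if (!nrow(ev)) return(structure(0, no_events = TRUE))
  sum(ev$contact_id %in% resected_set) / nrow(ev)
}

#' Seizure-onset-zone resection ratio
#'
#' Contact-count rule: number of resected SOZ contacts divided by the total
#' number of SOZ contacts. No SOZ contacts gives 0 with attribute
#' `no_soz = TRUE`.
#'
#' @inheritParams resection_ratio
#' @return scalar in \[0, 1\].
#' @export
soz_resection_ratio <- function(record, resected_set) {
  soz <- record$contacts$contact_id[record$contacts$is_soz]
  if (!length(soz)) return(structure(0, no_soz = TRUE))
  sum(soz %in% resected_set) / length(soz)
}

#' Spatial FRnet
#'
#' Square root of the difference between the radius of the whole-brain
#' rate-distance graph (all FR>350 Hz generating contacts) and the radius of
#' the same graph restricted to the resected FR>350 Hz contacts. Edge
#' weights are mean pair rate (events/min) times Euclidean distance (mm),
#' used as lengths. The difference is clamped at 0 before the square root,
#' so a full-network resection gives exactly 0.
#'
#' @param record a `patient_record`.
#' @param resected_set resected contact ids.
#' @param rates optional precomputed [compute_rates()] table.
#' @return scalar >= 0.
#' @export
spatial_frnet <- function(record, resected_set, rates = NULL) {
  if (is.null(rates)) rates <- compute_rates(record)
  fr_nodes <- rates$contact_id[rates$FR_gt350 > 0]
  if (!length(fr_nodes)) return(structure(0, no_fr_nodes = TRUE))
  w_all <- rate_distance_graph(record$contacts, rates, fr_nodes)
  r_whole <- graph_radius(w_all)
  res_nodes <- intersect(fr_nodes, resected_set)
  r_res <- if (length(res_nodes) >= 2) {
    graph_radius(w_all[res_nodes, res_nodes, drop = FALSE])
  } else 0
  sqrt(max(r_whole - r_res, 0))
}

#' Temporal FRnet-A (gammaRR)
#'
#' Ratio of the characteristic path length of the resected-node induced
#' subnetwork (numerator) to that of the whole MI network (denominator),
#' distances = 1/MI. Degenerate cases (fewer than 2 resected network nodes,
#' or an infinite whole-network path length) return 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param net an `mi_network`.
#' @param resected_set resected contact ids.
#' @return scalar >= 0.
#' @export
temporal_frnet_a <- function(net, resected_set) {
  res <- intersect(net$node_ids, resected_set)
  if (length(res) < 2) return(structure(0, degenerate = TRUE))
  cpl_whole <- characteristic_path_length(net)
  if (!is.finite(cpl_whole) || cpl_whole <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  cpl_res <- characteristic_path_length(net, res)
  if (!is.finite(cpl_res)) return(structure(0, degenerate = TRUE))
  as.numeric(cpl_res / cpl_whole)
}

#' Temporal FRnet-B (urmLE)
#'
#' Mean nodal local efficiency over *unresected* network nodes with LE > 0.
#' When no such node exists (e.g. a full-network resection) the value is
#' 1.0 by convention. `scope = "all"` gives the literal all-nodes reading.
#'
#' @param net an `mi_network`.
#' @param resected_set resected contact ids.
#' @param scope `"unresected"` (default) or `"all"`.
#' @return scalar >= 0.
#' @export
temporal_frnet_b <- function(net, resected_set, scope = "unresected") {
  le <- net$nodal_le
  pool <- if (identical(scope, "unresected")) {
    le[setdiff(names(le), resected_set)]
  } else le
  pool <- pool[pool > 0]
  if (!length(pool)) return(1.0)
  mean(pool)
}

#' Assemble the metric vector for a resected set
#'
#' Computes the four classifier factors (FR RR, spatial FRnet, temporal
#' FRnet-A, temporal FRnet-B) plus the auxiliary resection ratios (SOZ,
#' RonS, RonO, all-FR), identically for actual and virtual resections.
#'
#' @param record a `patient_record`.
#' @param net an `mi_network` built from the record.
#' @param resected_set resected contact ids.
#' @param rates optional precomputed rate table.
#' @param frnet_b_scope passed to [temporal_frnet_b()].
#' @return named list of class `metric_vector`.
#' @export
metric_vector <- function(record, net, resected_set, rates = NULL,
                          frnet_b_scope = "unresected") {
  if (is.null(rates)) rates <- compute_rates(record)
  structure(list(
    fr_rr = as.numeric(resection_ratio(record, resected_set, "FR_gt350")),
    spatial_frnet = as.numeric(spatial_frnet(record, resected_set, rates)),
    temporal_frnet_a = as.numeric(temporal_frnet_a(net, resected_set)),
    temporal_frnet_b = as.numeric(temporal_frnet_b(net, resected_set,
                                                   frnet_b_scope)),
    soz_rr = as.numeric(soz_resection_ratio(record, resected_set)),
    rons_rr = as.numeric(resection_ratio(record, resected_set, "RonS")),
    rono_rr = as.numeric(resection_ratio(record, resected_set, "RonO")),
    allfr_rr = as.numeric(resection_ratio(record, resected_set, "FR_all"))
  ), class = "metric_vector")
}

#' @rdname metric_vector
#' @param x a `metric_vector`.
#' @export
as_feature_row <- function(x) {
  stopifnot(inherits(x, "metric_vector"))
  c(fr_rr = x$fr_rr, spatial_frnet = x$spatial_frnet,
    temporal_frnet_a = x$temporal_frnet_a,
    temporal_frnet_b = x$temporal_frnet_b)
}

#' K-means autonomy clustering
#'
#' Clusters FR-generating nodes on (log10 FR rate, nodal LE) with z-scored
#' axes; the autonomous set is the cluster with the highest mean log-rate
#' (ties broken by lowest mean LE). Nodes with zero rate are excluded.
#' With fewer than `k` eligible nodes all nodes form one cluster and the
#' result is flagged `degenerate = TRUE`.
#'
#' @param rates named FR>350 Hz rates (events/min) per node.
#' @param nodal_le named local efficiencies (same names).
#' @param k number of clusters (default 2, the two-regime structure).
#' @param seed RNG seed for the restarts.
#' @return list of class `autonomy_clustering`: `nodes` (data.frame with
#'   log10 rate, LE, cluster), `autonomous_set`, `degenerate`.
#' @export
autonomy_cluster <- function(rates, nodal_le, k = 2, seed = 1) {
  ids <- intersect(names(rates)[rates > 0], names(nodal_le))
  df <- data.frame(contact_id = ids,
                   log10_rate = log10(rates[ids]),
                   le = as.numeric(nodal_le[ids]),
                   stringsAsFactors = FALSE)
  degenerate <- FALSE
  if (nrow(df) < k || nrow(unique(df[, c("log10_rate", "le")])) < k) {
    df$cluster <- 1L
    degenerate <- TRUE
    auto <- df$contact_id
  } else {
    z <- scale(df[, c("log10_rate", "le")])
    z[is.nan(z)] <- 0                       # constant axis
    km <- with_local_seed(seed, stats::kmeans(z, centers = k, nstart = 50))
    df$cluster <- km$cluster
    mrate <- tapply(df$log10_rate, df$cluster, mean)
    mle <- tapply(df$le, df$cluster, mean)
    best <- names(mrate)[mrate == max(mrate)]
    if (length(best) > 1) best <- best[which.min(mle[best])]
    auto <- df$contact_id[df$cluster == as.integer(best)]
  }
  structure(list(nodes = df, autonomous_set = auto, degenerate = degenerate),
            class = "autonomy_clustering")
}
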
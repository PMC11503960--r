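# Iterative sphere-growing virtual resection: candidates are FR>350 Hz
# nodes ordered by autonomy (ascending local efficiency) with a
# descending-rate fallback; the sphere stays centred on the first candidate
# and grows monotonically; each iteration's metric vector is labelled by
# the trained classifier; the simulation stops on a virtually-seizure-free
# label, a three-lobe extent, or candidate exhaustion.

#' Candidate node sequence for the virtual resection
#'
#' Network nodes with FR>350 Hz rate above `threshold`, ordered by
#' ascending local efficiency; once exhausted (or when none qualify) the
#' remaining network nodes follow, ordered by descending FR rate. Ties
#' break lexicographically on contact id.
#'
#' @param net an `mi_network`.
#' @param rates a [compute_rates()] table (or named FR_gt350 vector).
#' @param threshold candidate rate threshold, events/min (default 1).
#' @return ordered character vector of contact ids.
#' @export
candidate_sequence <- function(net, rates, threshold = 1) {
  if (!length(net$node_ids)) stop("empty network")
  r <- if (is.data.frame(rates)) {
    stats::setNames(rates$FR_gt350, rates$contact_id)
  } else rates
  ids <- net$node_ids
  r <- r[ids]
  le <- net$nodal_le[ids]
  hot <- ids[r > threshold]
  hot <- hot[order(le[hot], hot)]
  rest <- setdiff(ids, hot)
  rest <- rest[order(-r[rest], rest)]
  c(hot, rest)
}

#' Run the iterative virtual resection
#'
#' Iteration 1 places a sphere of `config$initial_margin_mm` (10 mm) on the
#' first candidate; iteration k grows the radius to
#' `distance(center, candidate_k) + margin` whenever candidate k lies
#' outside the current sphere (radii never shrink). The virtual resected
#' set is every contact inside the sphere excluding contacts contralateral
#' to the centre. Per iteration the full metric vector is computed and
#' labelled by `model`; the run stops on a `seizure_free` label
#' (`virtually_seizure_free`), when the virtual set spans
#' `config$lobe_stop_count` (3) lobes (`three_lobe_stop`, labelled not
#' seizure free), or when candidates run out (`candidates_exhausted`).
#'
#' @param record a `patient_record`.
#' @param net its `mi_network`.
#' @param model a trained `fr_svm` (or a function `metric_vector -> label`
#'   for rule stubs).
#' @param config a [run_config()].
#' @param rates optional precomputed rate table.
#' @return object of class `resection_trace`: per-iteration data.frame
#'   (`iterations`), list of virtual sets, termination reason, final
#'   radius, centre id.
#' @export
run_virtual_resection <- function(record, net, model, config = run_config(),
                                  rates = NULL) {
  if (is.null(rates)) rates <- compute_rates(record)
  cand <- candidate_sequence(net, rates, config$fr_rate_threshold)
  if (!length(cand)) stop("no candidate nodes")
  contacts <- record$contacts
  pos <- as.matrix(contacts[, c("x", "y", "z")])
  rownames(pos) <- contacts$contact_id
  center_id <- cand[1]
  center <- pos[center_id, ]
  center_hemi <- contacts$hemisphere[contacts$contact_id == center_id]
  ipsi <- contacts$hemisphere == center_hemi
  d_center <- sqrt(colSums((t(pos) - center)^2))
  actual <- contacts$contact_id[contacts$is_resected]

  margin <- config$initial_margin_mm
  radius <- 0
  rows <- list()
  vsets <- list()
  termination <- "candidates_exhausted"
  for (k in seq_along(cand)) {
    d_k <- d_center[cand[k]]
    radius <- if (k == 1) margin else
      if (d_k <= radius) radius else max(radius, d_k + margin)
    vset <- contacts$contact_id[d_center <= radius & ipsi]
    mv <- metric_vector(record, net, vset, rates, config$frnet_b_scope)
    label <- predict_label(model, mv)
    lobes <- unique(contacts$lobe[contacts$contact_id %in% vset])
    ov <- overlap_metrics(vset, actual, contacts$contact_id)
    stopped_lobes <- length(lobes) >= config$lobe_stop_count
    if (stopped_lobes) label <- "not_seizure_free"
    rows[[k]] <- data.frame(
      iteration = k, candidate = cand[k], radius_mm = radius,
      n_resected = length(vset), n_lobes = length(lobes),
      fr_rr = mv$fr_rr, spatial_frnet = mv$spatial_frnet,
      temporal_frnet_a = mv$temporal_frnet_a,
      temporal_frnet_b = mv$temporal_frnet_b,
      soz_rr = mv$soz_rr, rons_rr = mv$rons_rr,
      percent_r = ov$percent_r, novel_r = ov$novel_r,
      svm_label = label, stringsAsFactors = FALSE
    )
    vsets[[k]] <- vset
    if (stopped_lobes) { termination <- "three_lobe_stop"; break }
    if (label == "seizure_free") { termination <- "virtually_seizure_free"; break }
  }
  iters <- do.call(rbind, rows)
  structure(list(
    iterations = iters, virtual_sets = vsets, termination = termination,
    center = center_id, final_radius = radius,
    virtual_set = vsets[[length(vsets)]],
    virtually_seizure_free = termination == "virtually_seizure_free"
  ), class = "resection_trace")
}

#' @export
print.resection_trace <- function(x, ...) {
  cat("<resection_trace>", nrow(x$iterations), "iterations,",
      x$termination, "| final radius", round(x$final_radius, 1), "mm\n")
  invisible(x)
}

#' Contingency overlap between virtual and actual resected sets
#'
#' TP = contacts in both sets, FP = virtual only, FN = actual only, TN =
#' neither. Ratios follow the standard contingency formulas; `percent_r` is
#' the fraction of actually resected contacts captured by the virtual set,
#' `novel_r` the fraction of the virtual set outside the actual resection.
#' An empty actual set leaves `percent_r` as `NA` with attribute
#' `empty_actual = TRUE` on the result.
#'
#' @param virtual_set,actual_set character vectors of contact ids.
#' @param all_contacts all contact ids of the patient.
#' @return list: tp, tn, fp, fn, sensitivity, specificity, ppv, npv,
#'   accuracy, f1, percent_r, novel_r.
#' @export
overlap_metrics <- function(virtual_set, actual_set, all_contacts) {
  stopifnot(all(virtual_set %in% all_contacts),
            all(actual_set %in% all_contacts))
  v <- all_contacts %in% virtual_set
  a <- all_contacts %in% actual_set
  tp <- sum(v & a); fp <- sum(v & !a); fn <- sum(!v & a); tn <- sum(!v & !a)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  out <- list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    ppv = ppv,
    npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / length(all_contacts),
    f1 = f1,
    percent_r = ratio(tp, sum(a)),
    novel_r = ratio(fp, sum(v))
  )
  if (sum(a) == 0) attr(out, "empty_actual") <- TRUE
  out
}

#' Radius of the actual resection
#'
#' Graph radius of the complete Euclidean graph over the resected contacts
#' (mm); a single resected contact gives 0.
#'
#' @param record a `patient_record` (or a contact table).
#' @param resected_set resected contact ids (default: the record's
#'   `is_resected` flags).
#' @return radius in mm.
#' @export
actual_resection_radius <- function(record, resected_set = NULL) {
  contacts <- if (inherits(record, "patient_record")) record$contacts else record
  if (is.null(resected_set)) {
    resected_set <- contacts$contact_id[contacts$is_resected]
  }
  if (!length(resected_set)) stop("resected set is empty")
  pos <- as.matrix(contacts[match(resected_set, contacts$contact_id),
                            c("x", "y", "z")])
  if (nrow(pos) == 1) return(0)
  graph_radius(as.matrix(stats::dist(pos)))
}
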
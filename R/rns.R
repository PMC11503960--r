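# Responsive neurostimulator (RNS) placement metrics: which SEEG contacts
# a given 8-contact stimulation montage reaches (strict 15 mm rule), the
# SOZ / FR stimulation ratios, the stimulated-subnetwork global efficiency
# ("RNS temporal FRnet"), and virtual repositioning of the stimulation
# contacts onto the highest-rate FR sites.

#' SEEG contacts stimulated by an RNS montage
#'
#' A contact is stimulated when it lies strictly within `radius_mm` of any
#' of the 8 stimulation-contact positions (monopolar 1-3 mA field folded
#' into the single radius). An empty result carries attribute
#' `none_in_range = TRUE`.
#'
#' @param contacts a contact table.
#' @param stim_positions 8 x 3 numeric matrix, MNI mm.
#' @param radius_mm strict radius (default 15).
#' @return character vector of stimulated contact ids.
#' @export
stimulated_set <- function(contacts, stim_positions, radius_mm = 15) {
  stim_positions <- as.matrix(stim_positions)
  if (nrow(stim_positions) != 8 || ncol(stim_positions) != 3) {
    stop("stim_positions must be an 8 x 3 matrix")
  }
  pos <- as.matrix(contacts[, c("x", "y", "z")])
  dmin <- apply(stim_positions, 1, function(s) {
    sqrt(colSums((t(pos) - s)^2))
  })
  hit <- apply(dmin, 1, min) < radius_mm
  out <- contacts$contact_id[hit]
  if (!length(out)) attr(out, "none_in_range") <- TRUE
  out
}

#' SOZ and FR stimulation ratios
#'
#' `soz_sr` is the contact-count ratio of stimulated SOZ contacts to all
#' SOZ contacts (mirroring the SOZ resection ratio); `fr_sr` is the
#' event-count ratio of FR>350 Hz events on stimulated contacts to all
#' FR>350 Hz events (mirroring the FR resection ratio). Zero denominators
#' give 0 with a flag attribute.
#'
#' @param record a `patient_record`.
#' @param stim_set stimulated contact ids.
#' @return list with `soz_sr`, `fr_sr`.
#' @export
stimulation_ratios <- function(record, stim_set) {
  soz <- record$contacts$contact_id[record$contacts$is_soz]
  soz_sr <- if (length(soz)) sum(soz %in% stim_set) / length(soz)
  else structure(0, no_soz = TRUE)
  ev <- record$events[record$events$event_class %in%
                        c("fRonO_gt350", "fRonS"), , drop = FALSE]
  fr_sr <- if (nrow(ev)) sum(ev$contact_id %in% stim_set) / nrow(ev)
  else structure(0, no_events = TRUE)
  list(soz_sr = soz_sr, fr_sr = fr_sr)
}

#' RNS temporal FRnet
#'
#' Global efficiency of the MI subnetwork induced by the stimulated nodes
#' plus their first-degree MI neighbours (any node sharing a positive-MI
#' edge with a stimulated node, optionally above `mi_floor`). Fewer than
#' two subgraph nodes gives 0.
#'
#' @param net an `mi_network`.
#' @param stim_set stimulated contact ids.
#' @param mi_floor edge-existence floor for neighbourhood membership.
#' @return scalar >= 0.
#' @export
rns_temporal_frnet <- function(net, stim_set, mi_floor = 0) {
  s <- intersect(net$node_ids, stim_set)
  if (!length(s)) return(0)
  adj <- net$mi[s, , drop = FALSE] > mi_floor
  nbrs <- net$node_ids[colSums(adj) > 0]
  sub <- union(s, nbrs)
  if (length(sub) < 2) return(0)
  global_efficiency(net, sub)
}

#' Evaluate an RNS placement
#'
#' Computes the stimulated set, SOZ/FR stimulation ratios and RNS temporal
#' FRnet for an arbitrary 8-contact montage.
#'
#' @param record a `patient_record`.
#' @param net its `mi_network`.
#' @param stim_positions 8 x 3 matrix (defaults to the record's actual RNS
#'   contacts).
#' @param radius_mm strict stimulation radius, mm.
#' @return list of class `rns_placement`.
#' @export
rns_placement_metrics <- function(record, net, stim_positions = NULL,
                                  radius_mm = 15) {
  if (is.null(stim_positions)) stim_positions <- record$rns_contacts
  if (is.null(stim_positions)) stop("record has no RNS contacts")
  stim <- stimulated_set(record$contacts, stim_positions, radius_mm)
  sr <- stimulation_ratios(record, stim)
  structure(list(
    stim_positions = as.matrix(stim_positions),
    stimulated_set = as.character(stim),
    soz_sr = as.numeric(sr$soz_sr), fr_sr = as.numeric(sr$fr_sr),
    rns_temporal_frnet = rns_temporal_frnet(net, stim)
  ), class = "rns_placement")
}

#' Virtual RNS stimulation lead placement
#'
#' Repositions the 8 stimulation contacts (two leads of 4) onto the SEEG
#' sites with the highest FR>350 Hz rates. Unilateral: the two shanks whose
#' best contacts have the highest rates each contribute a contiguous run of
#' 4 contacts containing the shank's top-rate contact and maximizing the
#' run's summed rate. Bilateral: one such run per hemisphere, anchored on
#' each hemisphere's top-rate contact.
#'
#' @param record a `patient_record`.
#' @param net its `mi_network`.
#' @param rates optional precomputed rate table.
#' @param is_bilateral place one lead per hemisphere?
#' @param radius_mm strict stimulation radius, mm.
#' @return an `rns_placement` with the additional fields
#'   `stim_contact_ids` and `is_bilateral`.
#' @export
virtual_rns_placement <- function(record, net, rates = NULL,
                                  is_bilateral = FALSE, radius_mm = 15) {
  if (is.null(rates)) rates <- compute_rates(record)
  contacts <- record$contacts
  r <- stats::setNames(rates$FR_gt350, rates$contact_id)

  best_run <- function(shank) {
    rows <- which(contacts$shank_id == shank)     # physical order on shank
    rr <- r[contacts$contact_id[rows]]
    k <- length(rows)
    if (k <= 4) return(contacts$contact_id[rows])
    top <- which.max(rr)
    starts <- seq_len(k - 3)
    starts <- starts[starts <= top & starts + 3 >= top]  # runs containing top
    sums <- vapply(starts, function(s) sum(rr[s:(s + 3)]), numeric(1))
    s <- starts[which.max(sums)]
    contacts$contact_id[rows[s:(s + 3)]]
  }

  if (is_bilateral) {
    ids <- unlist(lapply(c("L", "R"), function(h) {
      hc <- contacts[contacts$hemisphere == h, , drop = FALSE]
      if (!nrow(hc) || all(r[hc$contact_id] == 0)) {
        stop("hemisphere ", h, " has no FR-generating contacts")
      }
      sh_best <- tapply(r[hc$contact_id], hc$shank_id, max)
      shank <- names(sh_best)[order(-sh_best, names(sh_best))][1]
      run <- best_run(shank)
      run[run %in% hc$contact_id]
    }))
  } else {
    sh_best <- tapply(r[contacts$contact_id], contacts$shank_id, max)
    shanks <- names(sh_best)[order(-sh_best, names(sh_best))][1:2]
    ids <- unlist(lapply(shanks, best_run))
  }
  ids <- head(ids, 8)
  stim_positions <- as.matrix(contacts[match(ids, contacts$contact_id),
                                       c("x", "y", "z")])
  # pad degenerate fixtures (< 8 physical contacts) by repeating the last
  while (nrow(stim_positions) < 8) {
    stim_positions <- rbind(stim_positions,
                            stim_positions[nrow(stim_positions), ])
  }
  out <- rns_placement_metrics(record, net, stim_positions, radius_mm)
  out$stim_contact_ids <- ids
  out$is_bilateral <- is_bilateral
  out
}
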
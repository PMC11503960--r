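# Synthetic stereo-EEG cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: 8-16
# collinear depth-electrode shanks of 7-15 contacts, 10-60 min epochs,
# fast-ripple event trains with a planted "epileptogenic core" of autonomous
# high-rate nodes, temporal coupling among background nodes via a thinned and
# jittered mother Poisson process, SOZ flags on the core, a resection mask
# per policy, and an outcome label tied to complete core removal.

#' Specification for a synthetic cohort
#'
#' Ranges are sampled per patient (uniformly) when given as a length-2
#' vector. Defaults state the emulated world: background fast-ripple (FR)
#' rate well below 1/min, core rate well above it, strong within-core
#' autonomy, and moderate background coupling.
#'
#' @param n_patients number of patients.
#' @param shanks_per_patient integer or range in \[8, 16\].
#' @param contacts_per_shank integer or range in \[7, 15\].
#' @param epoch_minutes scalar or range in \[10, 60\] (min).
#' @param background_rate background FR>350 Hz rate, events/min.
#' @param core_rate core-node FR>350 Hz rate, events/min (>> 1).
#' @param n_core_nodes planted core size.
#' @param coupling_prob probability a mother-process event is kept by a
#'   coupled background node.
#' @param jitter_sd_ms Gaussian jitter of shared events, ms.
#' @param core_autonomy probability a core event is private to its node.
#' @param bg_fr_fraction fraction of non-core contacts that generate
#'   background FR>350 Hz events at all.
#' @param ripple_rate_core,ripple_rate_bg RonS/RonO rates (events/min) on
#'   core/SOZ versus other contacts.
#' @param resection_policy `"covers_core"`, `"misses_core"` or `"partial"`.
#' @param seed integer RNG seed; cohorts are byte-identical given the seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1L,
                        shanks_per_patient = c(8L, 16L),
                        contacts_per_shank = c(7L, 15L),
                        epoch_minutes = c(10, 60),
                        background_rate = 0.4,
                        core_rate = 6,
                        n_core_nodes = 4L,
                        coupling_prob = 0.5,
                        jitter_sd_ms = 20,
                        core_autonomy = 0.8,
                        bg_fr_fraction = 0.3,
                        ripple_rate_core = 3,
                        ripple_rate_bg = 0.5,
                        resection_policy = c("covers_core", "misses_core",
                                             "partial"),
                        seed = 1L) {
  rng_ok <- function(v, lo, hi) all(v >= lo) && all(v <= hi)
  stopifnot(n_patients >= 1,
            rng_ok(shanks_per_patient, 8, 16),
            rng_ok(contacts_per_shank, 7, 15),
            rng_ok(epoch_minutes, 10, 60),
            coupling_prob >= 0, coupling_prob <= 1,
            core_autonomy >= 0, core_autonomy <= 1,
            bg_fr_fraction >= 0, bg_fr_fraction <= 1,
            background_rate >= 0, core_rate > 0, jitter_sd_ms >= 0)
  structure(list(
    n_patients = as.integer(n_patients),
    shanks_per_patient = shanks_per_patient,
    contacts_per_shank = contacts_per_shank,
    epoch_minutes = epoch_minutes,
    background_rate = background_rate, core_rate = core_rate,
    n_core_nodes = as.integer(n_core_nodes),
    coupling_prob = coupling_prob, jitter_sd_ms = jitter_sd_ms,
    core_autonomy = core_autonomy, bg_fr_fraction = bg_fr_fraction,
    ripple_rate_core = ripple_rate_core, ripple_rate_bg = ripple_rate_bg,
    resection_policy = match.arg(resection_policy),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Evaluate expr with a locally-seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sample_range <- function(v, integer = TRUE) {
  if (length(v) == 1) return(v)
  if (integer) sample(seq(v[1], v[2]), 1) else stats::runif(1, v[1], v[2])
}

# Homogeneous Poisson onsets on [0, minutes * 60], strictly increasing.
rpoisson_train <- function(rate_per_min, minutes) {
  n <- stats::rpois(1, rate_per_min * minutes)
  if (n == 0) return(numeric(0))
  unique(sort(stats::runif(n, 0, minutes * 60)))
}

clip_train <- function(t, minutes) {
  unique(sort(t[t >= 0 & t <= minutes * 60]))
}

#' Generate a synthetic cohort
#'
#' Deterministic given `spec$seed`. Each patient record carries its ground
#' truth as attributes: `core_nodes` (planted autonomous high-rate contact
#' ids) and `policy`.
#'
#' @param spec a [cohort_spec()].
#' @return list of `patient_record` objects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(i) {
      generate_patient(spec, sprintf("S%03d", i))
    })
  })
}

generate_patient <- function(spec, patient_id) {
  n_shanks <- sample_range(spec$shanks_per_patient)
  epoch <- round(sample_range(spec$epoch_minutes, integer = FALSE), 1)

  # Geometry: collinear contact runs, 3.5-10 mm pitch, mostly right
  # hemisphere with ~1/4 of shanks mirrored through x = 0 so the
  # contralateral-exclusion logic is exercised.
  n_contra <- max(1L, n_shanks %/% 4L)
  shank_regions <- sample(dk_regions(), n_shanks, replace = TRUE)
  contacts <- NULL
  for (s in seq_len(n_shanks)) {
    k <- sample_range(spec$contacts_per_shank)
    if (k * 3.5 > 140) stop("infeasible shank geometry: ", k,
                            " contacts cannot fit a 140 mm run")
    pitch <- stats::runif(1, 3.5, min(10, 140 / k))
    origin <- c(stats::runif(1, 8, 30), stats::runif(1, -60, 60),
                stats::runif(1, -30, 50))
    dir <- c(stats::runif(1, 0.3, 1), stats::runif(1, -0.5, 0.5),
             stats::runif(1, -0.5, 0.5))
    dir <- dir / sqrt(sum(dir^2))
    pos <- t(origin + outer(dir, (seq_len(k) - 1) * pitch))
    mirrored <- s > n_shanks - n_contra
    if (mirrored) pos[, 1] <- -pos[, 1]
    hemi <- ifelse(pos[, 1] >= 2, "R", ifelse(pos[, 1] <= -2, "L",
                                              if (mirrored) "L" else "R"))
    df <- data.frame(
      contact_id = sprintf("%s-E%02d-%02d", patient_id, s, seq_len(k)),
      shank_id = sprintf("E%02d", s),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      region = shank_regions[s], hemisphere = hemi,
      is_soz = FALSE, is_resected = FALSE, stringsAsFactors = FALSE
    )
    contacts <- rbind(contacts, df)
  }
  contacts$lobe <- region_to_lobe(contacts$region)
  ipsi <- contacts$hemisphere == "R"

  # Planted core: adjacent contacts on one ipsilateral shank (spilling onto
  # the spatially nearest shank if the shank is too short).
  core_shank <- contacts$shank_id[ipsi][1]
  core_ids <- if (spec$n_core_nodes > 0) {
    head(contacts$contact_id[contacts$shank_id == core_shank],
         spec$n_core_nodes)
  } else character(0)
  if (length(core_ids) < spec$n_core_nodes) {
    pool <- contacts$contact_id[ipsi & !contacts$contact_id %in% core_ids]
    core_ids <- c(core_ids, head(pool, spec$n_core_nodes - length(core_ids)))
  }
  jit_s <- spec$jitter_sd_ms / 1000

  # FR > 350 Hz trains ------------------------------------------------------
  fr_trains <- list()
  for (id in core_ids) {
    priv <- rpoisson_train(spec$core_rate * spec$core_autonomy, epoch)
    fr_trains[[id]] <- priv
  }
  if (spec$core_autonomy < 1 && length(core_ids)) {
    mother <- rpoisson_train(spec$core_rate * (1 - spec$core_autonomy), epoch)
    for (id in core_ids) {
      shared <- mother + stats::rnorm(length(mother), 0, jit_s)
      fr_trains[[id]] <- clip_train(c(fr_trains[[id]], shared), epoch)
    }
  }
  bg_pool <- setdiff(contacts$contact_id, core_ids)
  n_bg <- round(spec$bg_fr_fraction * length(bg_pool))
  bg_ids <- if (n_bg > 0) sample(bg_pool, n_bg) else character(0)
  if (length(bg_ids)) {
    if (spec$coupling_prob > 0) {
      mother <- rpoisson_train(spec$background_rate / spec$coupling_prob, epoch)
      for (id in bg_ids) {
        keep <- mother[stats::runif(length(mother)) < spec$coupling_prob]
        keep <- keep + stats::rnorm(length(keep), 0, jit_s)
        fr_trains[[id]] <- clip_train(keep, epoch)
      }
    } else {
      for (id in bg_ids) {
        fr_trains[[id]] <- rpoisson_train(spec$background_rate, epoch)
      }
    }
  }

  # Assemble long event table; each FR>350 event is labelled fRonO_gt350 or
  # fRonS; the broadband FR class is their superset plus slower FR events.
  rows <- list()
  for (id in names(fr_trains)) {
    tr <- fr_trains[[id]]
    if (!length(tr)) next
    cls <- ifelse(stats::runif(length(tr)) < 0.5, "fRonO_gt350", "fRonS")
    rows[[length(rows) + 1L]] <- data.frame(contact_id = id, event_class = cls,
                                            onset_s = tr)
    extra <- rpoisson_train(0.5, epoch)
    rows[[length(rows) + 1L]] <- data.frame(contact_id = id,
                                            event_class = "FR_all",
                                            onset_s = clip_train(c(tr, extra),
                                                                 epoch))
  }
  soz_ids <- soz_flags(contacts, core_ids)
  for (id in contacts$contact_id) {
    r <- if (id %in% c(core_ids, soz_ids)) spec$ripple_rate_core else
      spec$ripple_rate_bg
    for (cls in c("RonS", "RonO")) {
      tr <- rpoisson_train(r, epoch)
      if (length(tr)) {
        rows[[length(rows) + 1L]] <- data.frame(contact_id = id,
                                                event_class = cls, onset_s = tr)
      }
    }
  }
  events <- do.call(rbind, rows)
  events <- event_table(events$contact_id, events$event_class, events$onset_s)

  contacts$is_soz <- contacts$contact_id %in% soz_ids
  contacts$is_resected <- resection_mask(contacts, core_ids,
                                         spec$resection_policy)
  outcome <- if (all(core_ids %in% contacts$contact_id[contacts$is_resected]))
    "seizure_free" else "not_seizure_free"

  rec <- patient_record(patient_id, contacts, events, epoch,
                        outcome = outcome)
  attr(rec, "core_nodes") <- core_ids
  attr(rec, "policy") <- spec$resection_policy
  rec
}

soz_flags <- function(contacts, core_ids) {
  if (!length(core_ids)) return(character(0))
  pos <- as.matrix(contacts[, c("x", "y", "z")])
  core <- pos[contacts$contact_id %in% core_ids, , drop = FALSE]
  cen <- colMeans(core)
  d <- sqrt(colSums((t(pos) - cen)^2))
  union(core_ids, contacts$contact_id[d <= 10])
}

resection_mask <- function(contacts, core_ids, policy) {
  pos <- as.matrix(contacts[, c("x", "y", "z")])
  core_idx <- contacts$contact_id %in% core_ids
  if (!any(core_idx)) {
    # no planted core: resect the first shank's neighbourhood
    cen <- colMeans(pos[contacts$shank_id == contacts$shank_id[1], ,
                        drop = FALSE])
    d <- sqrt(colSums((t(pos) - cen)^2))
    return(d <= 15)
  }
  cen <- colMeans(pos[core_idx, , drop = FALSE])
  d_cen <- sqrt(colSums((t(pos) - cen)^2))
  r_core <- max(d_cen[core_idx]) + 5
  same_hemi <- contacts$hemisphere == contacts$hemisphere[core_idx][1]
  switch(policy,
    covers_core = d_cen <= r_core & same_hemi | core_idx,
    misses_core = {
      # resect the same-hemisphere region farthest from the core
      far <- which(same_hemi & !core_idx)
      if (!length(far)) far <- which(!core_idx)
      anchor <- far[which.max(d_cen[far])]
      d_far <- sqrt(colSums((t(pos) - pos[anchor, ])^2))
      d_far <= r_core & !core_idx
    },
    partial = {
      keep <- core_ids[seq_len(ceiling(length(core_ids) / 2))]
      kept_idx <- contacts$contact_id %in% keep
      d_k <- sqrt(colSums((t(pos) -
                             colMeans(pos[kept_idx, , drop = FALSE]))^2))
      (d_k <= 7 & same_hemi & !core_idx) | kept_idx
    }
  )
}

#' Hand-built micro-fixtures with analytically known metrics
#'
#' * `"line3"`: three collinear contacts at (0,0,0), (10,0,0), (20,0,0) —
#'   Euclidean graph radius 10 mm.
#' * `"twin_trains"`: two contacts 10 mm apart carrying identical 60-event
#'   FR>350 Hz trains over a 30-min epoch.
#' * `"two_lobe_core"`: high-rate FR nodes spread over frontal, temporal and
#'   parietal shanks, for exercising the three-lobe stopping rule.
#'
#' @param name fixture name.
#' @return a `patient_record`.
#' @export
make_fixture <- function(name) {
  switch(name,
    line3 = {
      contacts <- contact_table(
        contact_id = c("a", "b", "c"), shank_id = "E01",
        x = c(0, 10, 20), y = 0, z = 0,
        region = "superiortemporal", hemisphere = "R",
        is_soz = FALSE, is_resected = c(TRUE, TRUE, TRUE)
      )
      events <- event_table(c("a", "b", "c"), "fRonS", c(1, 2, 3))
      patient_record("line3", contacts, events, 30)
    },
    twin_trains = {
      onsets <- with_local_seed(42, sort(stats::runif(60, 0, 1800)))
      contacts <- contact_table(
        contact_id = c("a", "b"), shank_id = "E01",
        x = c(10, 20), y = 0, z = 0,
        region = "middletemporal", hemisphere = "R"
      )
      events <- event_table(rep(c("a", "b"), each = 60), "fRonS",
                            c(onsets, onsets))
      patient_record("twin_trains", contacts, events, 30)
    },
    two_lobe_core = {
      # three shanks in three lobes, all carrying high-rate FR nodes
      mk <- function(shank, region, origin, n = 4) {
        data.frame(contact_id = sprintf("%s-%d", shank, seq_len(n)),
                   shank_id = shank,
                   x = origin[1] + (seq_len(n) - 1) * 5,
                   y = origin[2], z = origin[3],
                   region = region, stringsAsFactors = FALSE)
      }
      geo <- rbind(mk("F", "superiorfrontal", c(20, 40, 20)),
                   mk("T", "middletemporal", c(20, -10, -10)),
                   mk("P", "superiorparietal", c(20, -55, 45)))
      contacts <- contact_table(geo$contact_id, geo$shank_id, geo$x, geo$y,
                                geo$z, geo$region, "R",
                                is_soz = geo$shank_id != "P")
      events <- with_local_seed(7, {
        do.call(rbind, lapply(seq_len(nrow(geo)), function(i) {
          data.frame(contact_id = geo$contact_id[i], event_class = "fRonS",
                     onset_s = rpoisson_train(3, 20))
        }))
      })
      events <- event_table(events$contact_id, events$event_class,
                            events$onset_s)
      patient_record("two_lobe_core", contacts, events, 20)
    },
    stop("unknown fixture name: ", name)
  )
}
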
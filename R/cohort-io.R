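# Domain data model: contacts, event trains, patient records, run config.
#
# Contacts are kept as a data.frame (one row per SEEG contact), events as a
# long data.frame (one row per detected event), which is the natural R
# representation for tabular SEEG annotation exports.

EVENT_CLASSES <- c("fRonO_gt350", "fRonS", "FR_all", "RonS", "RonO")
HEMISPHERES <- c("L", "R")
OUTCOMES <- c("seizure_free", "not_seizure_free", "unknown")
RNS_OUTCOMES <- c("super", "intermediate", "poor")

#' Construct a contact table
#'
#' One row per implanted SEEG contact. Positions are MNI millimetres,
#' right-handed, with x > 0 the right hemisphere. The stored `hemisphere`
#' field must agree with `sign(x)` except within 2 mm of the midline, where
#' the stored field wins.
#'
#' @param contact_id,shank_id character vectors.
#' @param x,y,z numeric MNI coordinates (mm).
#' @param region Desikan-Killiany labels (see [region_to_lobe()]).
#' @param hemisphere `"L"` or `"R"`.
#' @param is_soz,is_resected logical flags.
#' @return data.frame with a derived `lobe` column.
#' @export
contact_table <- function(contact_id, shank_id, x, y, z, region,
                          hemisphere, is_soz = FALSE, is_resected = FALSE) {
  df <- data.frame(
    contact_id = as.character(contact_id),
    shank_id = as.character(shank_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    region = as.character(region),
    hemisphere = as.character(hemisphere),
    is_soz = as.logical(is_soz),
    is_resected = as.logical(is_resected),
    stringsAsFactors = FALSE
  )
  df$lobe <- region_to_lobe(df$region)
  validate_contacts(df)
  df
}

validate_contacts <- function(df) {
  if (anyDuplicated(df$contact_id)) {
    stop("duplicate contact_id: ",
         paste(unique(df$contact_id[duplicated(df$contact_id)]), collapse = ", "))
  }
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("contact positions must be finite")
  }
  if (!all(df$hemisphere %in% HEMISPHERES)) stop("hemisphere must be 'L' or 'R'")
  # laterality consistency: stored field wins only near the midline
  off_mid <- abs(df$x) >= 2
  implied <- ifelse(df$x > 0, "R", "L")
  bad <- off_mid & implied != df$hemisphere
  if (any(bad)) {
    stop("hemisphere field disagrees with sign(x) off the midline for: ",
         paste(df$contact_id[bad], collapse = ", "))
  }
  invisible(df)
}

#' Construct an event table
#'
#' Long-format table of detected events: one row per event with its contact,
#' class and onset time in seconds from epoch start.
#'
#' @param contact_id character vector.
#' @param event_class one of
#'   `fRonO_gt350, fRonS, FR_all, RonS, RonO`.
#' @param onset_s numeric onsets, seconds (0-based).
#' @return data.frame sorted by contact, class, onset.
#' @export
event_table <- function(contact_id, event_class, onset_s) {
  df <- data.frame(
    contact_id = as.character(contact_id),
    event_class = as.character(event_class),
    onset_s = as.numeric(onset_s),
    stringsAsFactors = FALSE
  )
  if (!all(df$event_class %in% EVENT_CLASSES)) {
    stop("unknown event_class: ",
         paste(setdiff(unique(df$event_class), EVENT_CLASSES), collapse = ", "))
  }
  df[order(df$contact_id, df$event_class, df$onset_s), , drop = FALSE]
}

#' Assemble and validate a patient record
#'
#' @param patient_id character scalar.
#' @param contacts a [contact_table()].
#' @param events an [event_table()]; every contact_id must exist in `contacts`.
#' @param epoch_minutes positive epoch duration (min).
#' @param outcome `"seizure_free"`, `"not_seizure_free"` or `"unknown"`.
#' @param rns_contacts optional 8 x 3 numeric matrix of RNS stimulation
#'   contact positions (MNI mm).
#' @param rns_outcome optional `"super"`, `"intermediate"` or `"poor"`.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(patient_id, contacts, events, epoch_minutes,
                           outcome = "unknown", rns_contacts = NULL,
                           rns_outcome = NULL) {
  rec <- structure(
    list(patient_id = as.character(patient_id), contacts = contacts,
         events = events, epoch_minutes = as.numeric(epoch_minutes),
         outcome = outcome, rns_contacts = rns_contacts,
         rns_outcome = rns_outcome),
    class = "patient_record"
  )
  validate_patient_record(rec)
}

#' @rdname patient_record
#' @param record a `patient_record`.
#' @export
validate_patient_record <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  validate_contacts(record$contacts)
  if (length(record$epoch_minutes) != 1 || !is.finite(record$epoch_minutes) ||
      record$epoch_minutes <= 0) {
    stop("epoch_minutes must be a positive scalar")
  }
  if (!record$outcome %in% OUTCOMES) stop("invalid outcome label")
  ev <- record$events
  unknown <- setdiff(unique(ev$contact_id), record$contacts$contact_id)
  if (length(unknown)) {
    stop("events reference unknown contact id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(ev)) {
    lim <- record$epoch_minutes * 60
    if (any(ev$onset_s < 0 | ev$onset_s > lim)) {
      stop("event onsets must lie within [0, epoch_minutes * 60]")
    }
    # onsets strictly increasing within each (contact, class) train
    sp <- split(ev$onset_s, paste(ev$contact_id, ev$event_class))
    if (any(vapply(sp, function(o) any(diff(sort(o)) <= 0), logical(1)))) {
      stop("duplicate onsets within an event train")
    }
  }
  if (!is.null(record$rns_contacts)) {
    m <- record$rns_contacts
    if (!is.matrix(m) || nrow(m) != 8 || ncol(m) != 3 || !all(is.finite(m))) {
      stop("rns_contacts must be a finite 8 x 3 matrix")
    }
  }
  if (!is.null(record$rns_outcome) && !record$rns_outcome %in% RNS_OUTCOMES) {
    stop("invalid rns_outcome label")
  }
  invisible(record)
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "\n",
      " contacts:", nrow(x$contacts),
      " events:", nrow(x$events),
      " epoch:", x$epoch_minutes, "min",
      " outcome:", x$outcome, "\n")
  invisible(x)
}

#' Extract one event train
#'
#' Returns the sorted onset times (s) for one contact and event class.
#' `event_class = "FR_gt350"` is the analysis union: fast ripples on
#' oscillations above 350 Hz plus all fast ripples on spikes.
#'
#' @param record a `patient_record`.
#' @param contact_id contact id.
#' @param event_class an event class or `"FR_gt350"`.
#' @return numeric vector of onsets (possibly empty).
#' @export
event_train <- function(record, contact_id, event_class = "FR_gt350") {
  cls <- if (identical(event_class, "FR_gt350")) {
    c("fRonO_gt350", "fRonS")
  } else event_class
  ev <- record$events
  sort(ev$onset_s[ev$contact_id == contact_id & ev$event_class %in% cls])
}

#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults:
#' candidate rate threshold 1 event/min, initial resection margin 10 mm, RNS
#' stimulation radius 15 mm, SVM cost 1, kernel width rule `1/n_factors`,
#' three-lobe stopping count.
#'
#' @param fr_rate_threshold events/min threshold for virtual-resection
#'   candidates.
#' @param initial_margin_mm initial (and incremental) sphere margin, mm.
#' @param rns_stim_radius_mm strict stimulation radius, mm.
#' @param svm_C soft-margin cost.
#' @param svm_gamma_rule `"n_factors"` (gamma = 1/4) or `"auto_scale"`
#'   (median-pairwise-distance kernel width).
#' @param svm_normalization `"zscore"` or `"minmax"`.
#' @param mi_alpha chi-square level for adaptive-partition refinement.
#' @param mi_min_cell smallest cell size the partition may split.
#' @param frnet_b_scope `"unresected"` (urmLE, default) or `"all"`.
#' @param lobe_stop_count stop when the virtual set spans this many lobes.
#' @param rng_seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(fr_rate_threshold = 1.0, initial_margin_mm = 10.0,
                       rns_stim_radius_mm = 15.0, svm_C = 1.0,
                       svm_gamma_rule = c("n_factors", "auto_scale"),
                       svm_normalization = c("zscore", "minmax"),
                       mi_alpha = 0.05, mi_min_cell = 8,
                       frnet_b_scope = c("unresected", "all"),
                       lobe_stop_count = 3L, rng_seed = 1L) {
  stopifnot(fr_rate_threshold >= 0, initial_margin_mm > 0,
            rns_stim_radius_mm > 0, svm_C > 0, mi_alpha > 0, mi_alpha < 1,
            lobe_stop_count >= 1)
  structure(list(
    fr_rate_threshold = fr_rate_threshold,
    initial_margin_mm = initial_margin_mm,
    rns_stim_radius_mm = rns_stim_radius_mm,
    svm_C = svm_C,
    svm_gamma_rule = match.arg(svm_gamma_rule),
    svm_normalization = match.arg(svm_normalization),
    mi_alpha = mi_alpha,
    mi_min_cell = mi_min_cell,
    frnet_b_scope = match.arg(frnet_b_scope),
    lobe_stop_count = as.integer(lobe_stop_count),
    rng_seed = as.integer(rng_seed)
  ), class = "run_config")
}

#' Read / write patient records
#'
#' `write_patient()` emits `contacts.csv`, `events.csv` and `meta.json` into
#' `out_dir`; `read_patient()` inverts it. All files are UTF-8 CSV/JSON with
#' mandatory header rows.
#'
#' @param contact_table_path,event_table_path CSV paths.
#' @param meta path to the metadata JSON, or an equivalent named list with
#'   `patient_id`, `epoch_minutes`, `outcome` and an optional `rns` block.
#' @return `read_patient()`: a validated `patient_record`;
#'   `write_patient()`: named character vector of the three paths written.
#' @export
read_patient <- function(contact_table_path, event_table_path, meta) {
  if (is.character(meta)) meta <- jsonlite::fromJSON(meta)
  cdf <- utils::read.csv(contact_table_path, stringsAsFactors = FALSE,
                         colClasses = c(contact_id = "character",
                                        shank_id = "character"))
  need <- c("contact_id", "shank_id", "x", "y", "z", "region",
            "hemisphere", "is_soz", "is_resected")
  if (!all(need %in% names(cdf))) {
    stop("contact table missing column(s): ",
         paste(setdiff(need, names(cdf)), collapse = ", "))
  }
  contacts <- contact_table(cdf$contact_id, cdf$shank_id, cdf$x, cdf$y, cdf$z,
                            cdf$region, cdf$hemisphere, cdf$is_soz,
                            cdf$is_resected)
  edf <- utils::read.csv(event_table_path, stringsAsFactors = FALSE,
                         colClasses = c(contact_id = "character"))
  if (!all(c("contact_id", "event_class", "onset_s") %in% names(edf))) {
    stop("event table must have columns contact_id,event_class,onset_s")
  }
  events <- event_table(edf$contact_id, edf$event_class, edf$onset_s)
  rns_contacts <- NULL
  rns_outcome <- NULL
  if (!is.null(meta$rns)) {
    pm <- meta$rns$positions
    rns_contacts <- if (is.list(pm)) {
      do.call(rbind, lapply(pm, as.numeric))
    } else {
      matrix(as.numeric(pm), ncol = 3)
    }
    rns_outcome <- meta$rns$outcome
  }
  patient_record(meta$patient_id, contacts, events, meta$epoch_minutes,
                 outcome = meta$outcome %||% "unknown",
                 rns_contacts = rns_contacts, rns_outcome = rns_outcome)
}

#' @rdname read_patient
#' @param record a validated `patient_record`.
#' @param out_dir output directory (created if needed).
#' @export
write_patient <- function(record, out_dir) {
  validate_patient_record(record)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(out_dir, "contacts.csv")
  epath <- file.path(out_dir, "events.csv")
  mpath <- file.path(out_dir, "meta.json")
  utils::write.csv(record$contacts[, c("contact_id", "shank_id", "x", "y", "z",
                                       "region", "hemisphere", "is_soz",
                                       "is_resected")],
                   cpath, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(record$events, epath, row.names = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(patient_id = record$patient_id,
               epoch_minutes = record$epoch_minutes,
               outcome = record$outcome)
  if (!is.null(record$rns_contacts)) {
    meta$rns <- list(
      positions = lapply(seq_len(8),
                         function(i) as.numeric(record$rns_contacts[i, ])),
      outcome = record$rns_outcome
    )
  }
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA)
  c(contacts = cpath, events = epath, meta = mpath)
}

#' @rdname read_patient
#' @param dir directory previously written by `write_patient()`.
#' @export
read_patient_dir <- function(dir) {
  read_patient(file.path(dir, "contacts.csv"),
               file.path(dir, "events.csv"),
               file.path(dir, "meta.json"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
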
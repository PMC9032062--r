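#' Sliding-window boundaries over an acquisition
#'
#' Windows start at 0 and advance by `window_ms * (1 - overlap_fraction)`;
#' the trailing remainder that cannot fill a window is dropped, so a
#' `duration`-ms acquisition yields
#' `floor((duration - window_ms) / step) + 1` windows (23 windows for 30 s /
#' 2500 ms / 50 percent overlap; 119 for 500 ms windows).
#'
#' @param acq an `egm_acquisition` (or a duration in ms).
#' @param window_ms window length, ms.
#' @param overlap_fraction overlap in `[0, 1)`; 0.5 by default.
#' @return data.frame with `start_ms`, `end_ms`, `i0`, `i1` (1-based sample
#'   columns; `i0:i1` has `window_ms * fs / 1000` samples when `acq` is an
#'   acquisition).
#' @export
slide_windows <- function(acq, window_ms, overlap_fraction = 0.5) {
  if (inherits(acq, "egm_acquisition")) {
    duration <- acq_duration_ms(acq); fs <- acq$fs
  } else {
    duration <- acq; fs <- NA_real_
  }
  if (!(overlap_fraction >= 0 && overlap_fraction < 1))
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  if (window_ms > duration)
    stop("window longer than the acquisition", call. = FALSE)
  step <- window_ms * (1 - overlap_fraction)
  n_win <- floor((duration - window_ms) / step) + 1L
  start_ms <- (seq_len(n_win) - 1L) * step
  out <- data.frame(start_ms = start_ms, end_ms = start_ms + window_ms)
  if (!is.na(fs)) {
    nsamp <- floor(window_ms * fs / 1000)
    out$i0 <- floor(start_ms * fs / 1000) + 1L
    out$i1 <- out$i0 + nsamp - 1L
  }
  out
}

#' Label a window from rotational events
#'
#' A window is positive when some event overlaps it by at least
#' `min_rotation_overlap` rotation durations (one full rotation by default;
#' an event's rotation duration is its span divided by its rotation count).
#' The `"any"` rule instead marks any nonzero overlap positive.
#'
#' @param window numeric `c(start_ms, end_ms)`.
#' @param events event data.frame of the same acquisition (`t_start`, `t_end`,
#'   `n_rotations`).
#' @param min_rotation_overlap required overlap, in rotations.
#' @param rule `"rotation"` (default) or `"any"`.
#' @return integer label, 0 or 1.
#' @export
label_window <- function(window, events, min_rotation_overlap = 1,
                         rule = c("rotation", "any")) {
  rule <- match.arg(rule)
  if (is.null(events) || !nrow(events)) return(0L)
  ov <- pmin(window[2], events$t_end) - pmax(window[1], events$t_start)
  if (rule == "any") return(as.integer(any(ov > 0)))
  rot_dur <- (events$t_end - events$t_start) / events$n_rotations
  as.integer(any(ov >= min_rotation_overlap * rot_dur))
}

#' Construct a labeled window
#'
#' @param x channels x samples matrix (normalized to \[0, 1\] when produced by
#'   [build_dataset()]).
#' @param y binary rotor label.
#' @param ordering the `channel_ordering` of the rows.
#' @param patient_id,acq_index,t_offset_ms lineage.
#' @param aug augmentation tag (`"base"`, `"rot3"`, `"tflip"`, ...).
#' @return object of class `labeled_window`.
#' @export
labeled_window <- function(x, y, ordering, patient_id = NA_character_,
                           acq_index = NA_integer_, t_offset_ms = NA_real_,
                           aug = "base") {
  structure(list(x = x, y = as.integer(y), ordering = ordering,
                 patient_id = patient_id, acq_index = acq_index,
                 t_offset_ms = t_offset_ms, aug = aug),
            class = "labeled_window")
}

#' Time-axis flip of a labeled window
#'
#' Reverses the time axis. The rotor label is preserved: a time-reversed
#' staircase is a staircase of the opposite chirality, still a rotor.
#' Involution: flipping twice is the identity.
#'
#' @param w a `labeled_window`.
#' @return flipped `labeled_window`.
#' @export
flip_time <- function(w) {
  w$x <- w$x[, rev(seq_len(ncol(w$x))), drop = FALSE]
  w$aug <- paste0(w$aug, "+tflip")
  w
}

#' Channel-axis flip of a labeled window
#'
#' Reverses the channel (row) order; label preserved, involution.
#'
#' @param w a `labeled_window`.
#' @return flipped `labeled_window`.
#' @export
flip_channels <- function(w) {
  w$x <- w$x[rev(seq_len(nrow(w$x))), , drop = FALSE]
  w$aug <- paste0(w$aug, "+cflip")
  w
}

#' Spline-rotation (and optional flip) augmentation
#'
#' Produces the `n_splines` spline-rotation variants of a window (the
#' enumeration starting at spline 1 is the identity; starting at spline
#' `n_splines` is the last permutation), each optionally composed with the
#' time and channel flips. All variants keep the label: relabeling splines
#' or mirroring axes does not create or destroy a rotor.
#'
#' @param w a `labeled_window`.
#' @param flips also apply the four flip combinations (yields `4 * n_splines`
#'   variants).
#' @return list of `labeled_window`s, length `n_splines` (times 4 with
#'   `flips`), first element the unmodified window.
#' @export
augment_window <- function(w, flips = FALSE) {
  ns <- w$ordering$n_splines
  base <- lapply(seq_len(ns), function(s) {
    perm <- spline_rotation_perm(w$ordering, s)
    out <- w
    out$x <- w$x[perm, , drop = FALSE]
    out$aug <- if (s == 1L) w$aug else paste0(w$aug, "+rot", s)
    out
  })
  if (!flips) return(base)
  out <- list()
  for (b in base) {
    out <- c(out, list(b, flip_time(b), flip_channels(b),
                       flip_channels(flip_time(b))))
  }
  out
}

#' Per-patient 1:1 class rebalancing
#'
#' Keeps all positive windows of each patient together with a seeded random
#' sample of that patient's negatives of `ratio` times the positive count
#' (1:1 by default). Patients with no positive window are dropped entirely.
#' Operates on a window manifest (data.frame with `patient_id` and `y`).
#'
#' @param manifest data.frame with at least `patient_id`, `y`.
#' @param ratio negatives kept per positive.
#' @param seed integer seed for the negative subsampling.
#' @return row-subset of `manifest`.
#' @export
rebalance_windows <- function(manifest, ratio = 1, seed = 1L) {
  set.seed(seed)
  keep <- integer(0)
  for (p in unique(manifest$patient_id)) {
    rows <- which(manifest$patient_id == p)
    pos <- rows[manifest$y[rows] == 1L]
    neg <- rows[manifest$y[rows] == 0L]
    if (!length(pos)) next
    n_neg <- min(length(neg), round(ratio * length(pos)))
    keep <- c(keep, pos, if (n_neg) sample(neg, n_neg) else integer(0))
  }
  manifest[sort(keep), , drop = FALSE]
}

#' Chronological patient-wise train/validation/test split
#'
#' Patients (in chronological order of their identifiers) are split
#' `train_fraction` : the rest between training and test, so no patient
#' contributes windows to both. The validation set is a stratified (by
#' label), seeded carve-out of the training windows.
#'
#' @param manifest window manifest (`patient_id`, `y`, ...).
#' @param train_fraction fraction of patients assigned to training (0.9).
#' @param val_fraction fraction of training windows carved out for
#'   validation.
#' @param seed seed for the stratified validation draw.
#' @return list of manifests: `train`, `val`, `test`.
#' @export
split_patients <- function(manifest, train_fraction = 0.9, val_fraction = 0.12,
                           seed = 1L) {
  patients <- sort(unique(manifest$patient_id))
  if (length(patients) < 2L)
    stop("patient split needs at least 2 patients", call. = FALSE)
  n_train <- floor(train_fraction * length(patients))
  n_train <- max(1L, min(n_train, length(patients) - 1L))
  train_pat <- patients[seq_len(n_train)]
  test <- manifest[!(manifest$patient_id %in% train_pat), , drop = FALSE]
  train_all <- manifest[manifest$patient_id %in% train_pat, , drop = FALSE]
  set.seed(seed)
  val_rows <- integer(0)
  for (cls in unique(train_all$y)) {
    rows <- which(train_all$y == cls)
    n_val <- round(val_fraction * length(rows))
    if (n_val) val_rows <- c(val_rows, sample(rows, n_val))
  }
  list(train = train_all[-val_rows, , drop = FALSE],
       val = train_all[sort(val_rows), , drop = FALSE],
       test = test)
}

preprocess_for_type <- function(acq, layout, signal_type, target_fs,
                                filter = TRUE, lat_refractory = 120) {
  a <- acq
  if (signal_type == "lat-train") {
    lats <- detect_lats(a, refractory_ms = lat_refractory)
    a <- lat_train(a, lats$lats)
    return(eg_resample(a, target_fs))
  }
  if (signal_type == "bipolar") a <- derive_bipolar(a, layout)
  if (filter) {
    a <- eg_bandpass(a)
    a <- eg_notch50(a)
  }
  eg_resample(a, target_fs)
}

#' Build train/validation/test window datasets from a cohort
#'
#' End-to-end dataset construction: per acquisition, condition the signal for
#' the requested representation (band-pass + notch + optional bipolar
#' derivation, or binary activation trains, then down-sampling), slice
#' sliding windows, label them against the cohort's rotational events,
#' percentile-normalize each window, rebalance classes 1:1 per patient, and
#' split patients chronologically. Ring-permutation / flip augmentation is
#' applied to the training partition only.
#'
#' @param cohort an `egm_cohort` from [simulate_cohort()] or a
#'   `lazy_egm_cohort` from [lazy_cohort()].
#' @param signal_type `"bipolar"`, `"unipolar"`, or `"lat-train"`.
#' @param window_ms window length (500 or 2500 in the reference protocol).
#' @param target_fs sampling rate after down-sampling (500/250/100 Hz).
#' @param overlap_fraction sliding-window overlap (0.5).
#' @param filter apply band-pass + notch before windowing.
#' @param augment `"none"`, `"rings"` (5 spline rotations), or
#'   `"rings+flips"` (20 variants), training partition only.
#' @param label_rule,min_rotation_overlap see [label_window()].
#' @param max_train optional cap on training windows (balanced, seeded
#'   subsample) to bound training cost.
#' @param train_fraction,val_fraction,seed see [split_patients()] /
#'   [rebalance_windows()].
#' @return list with `train`, `val`, `test`: each a `window_set` (list of
#'   `labeled_window`s with a `manifest` attribute), plus `layout`,
#'   `signal_type`.
#' @export
build_dataset <- function(cohort, signal_type = c("bipolar", "unipolar", "lat-train"),
                          window_ms = 2500, target_fs = 500,
                          overlap_fraction = 0.5, filter = TRUE,
                          augment = c("none", "rings", "rings+flips"),
                          label_rule = "rotation", min_rotation_overlap = 1,
                          max_train = Inf, train_fraction = 0.9,
                          val_fraction = 0.12, seed = 1L) {
  signal_type <- match.arg(signal_type)
  augment <- match.arg(augment)
  layout <- cohort$layout
  lazy <- inherits(cohort, "lazy_egm_cohort")
  n_acq <- if (lazy) nrow(cohort$meta) else length(cohort$acquisitions)
  acq_info <- function(k) {
    if (lazy)
      list(patient_id = cohort$meta$patient_id[k],
           acq_index = cohort$meta$acq_index[k],
           duration_ms = cohort$config$duration_ms)
    else {
      a <- cohort$acquisitions[[k]]
      list(patient_id = a$patient_id, acq_index = a$acq_index,
           duration_ms = acq_duration_ms(a))
    }
  }
  fetch_acq <- function(k) if (lazy) cohort$get(k) else cohort$acquisitions[[k]]
  ## pass 1: label manifest without materializing signals
  rows <- vector("list", n_acq)
  for (k in seq_len(n_acq)) {
    info <- acq_info(k)
    wb <- slide_windows(info$duration_ms, window_ms, overlap_fraction)
    ev <- cohort$events[cohort$events$acq_id == k, , drop = FALSE]
    y <- vapply(seq_len(nrow(wb)), function(i)
      label_window(c(wb$start_ms[i], wb$end_ms[i]), ev,
                   min_rotation_overlap, label_rule), integer(1))
    rows[[k]] <- data.frame(acq_id = k, patient_id = info$patient_id,
                            acq_index = info$acq_index,
                            start_ms = wb$start_ms, end_ms = wb$end_ms, y = y)
  }
  manifest <- do.call(rbind, rows)
  manifest <- rebalance_windows(manifest, ratio = 1, seed = seed)
  parts <- split_patients(manifest, train_fraction, val_fraction, seed = seed + 1L)
  if (is.finite(max_train) && nrow(parts$train) > max_train) {
    set.seed(seed + 2L)
    tr <- parts$train
    take <- c(sample(which(tr$y == 1L), min(sum(tr$y == 1L), ceiling(max_train / 2))),
              sample(which(tr$y == 0L), min(sum(tr$y == 0L), floor(max_train / 2))))
    parts$train <- tr[sort(take), , drop = FALSE]
  }

  ## pass 2: materialize, preprocessing each needed acquisition once
  cache_id <- NA_integer_; cache_acq <- NULL
  get_proc <- function(id) {
    if (!identical(id, cache_id)) {
      cache_acq <<- preprocess_for_type(fetch_acq(id), layout, signal_type,
                                        target_fs, filter)
      cache_id <<- id
    }
    cache_acq
  }
  ## one acquisition-ordered sweep over all three partitions, so an
  ## acquisition shared by train and validation is preprocessed once
  combined <- do.call(rbind, lapply(names(parts), function(p) {
    mf <- parts[[p]]
    mf$part <- rep(p, nrow(mf))
    mf
  }))
  combined <- combined[order(combined$acq_id, combined$start_ms), , drop = FALSE]
  made <- vector("list", nrow(combined))
  for (i in seq_len(nrow(combined))) {
    a <- get_proc(combined$acq_id[i])
    i0 <- floor(combined$start_ms[i] * a$fs / 1000) + 1L
    i1 <- i0 + floor(window_ms * a$fs / 1000) - 1L
    x <- percentile_normalize(a$signal[, i0:i1, drop = FALSE])
    attr(x, "percentiles") <- NULL
    made[[i]] <- labeled_window(x, combined$y[i], a$ordering,
                                combined$patient_id[i],
                                combined$acq_index[i], combined$start_ms[i])
  }
  take_part <- function(p, do_augment) {
    out <- made[combined$part == p]
    if (do_augment != "none") {
      out <- unlist(lapply(out, augment_window,
                           flips = (do_augment == "rings+flips")),
                    recursive = FALSE)
    }
    structure(out, manifest = combined[combined$part == p, , drop = FALSE],
              class = "window_set")
  }
  res <- list(train = take_part("train", augment),
              val = take_part("val", "none"),
              test = take_part("test", "none"))
  res$layout <- layout
  res$signal_type <- signal_type
  res$window_ms <- window_ms
  res$target_fs <- target_fs
  res
}

#' @export
print.window_set <- function(x, ...) {
  y <- vapply(x, `[[`, integer(1), "y")
  cat(sprintf("<window_set> %d windows (%d pos / %d neg)\n",
              length(x), sum(y == 1L), sum(y == 0L)))
  invisible(x)
}

#' Stack a window set into a network input tensor
#'
#' @param ws a `window_set` (list of `labeled_window`s).
#' @return list with `x`: array (time, channels, 1, n), `y`: integer labels.
#' @export
as_net_input <- function(ws) {
  n <- length(ws)
  stopifnot(n > 0L)
  ch <- nrow(ws[[1L]]$x); tm <- ncol(ws[[1L]]$x)
  x <- array(0, dim = c(tm, ch, 1L, n))
  for (i in seq_len(n)) x[, , 1L, i] <- t(ws[[i]]$x)
  list(x = x, y = vapply(ws, `[[`, integer(1), "y"))
}
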
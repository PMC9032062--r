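#' Zero-phase band-pass filtering
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), so the filter is zero-phase and activation timing
#' is preserved for the downstream activation-time detector. Default bands
#' follow the clinical acquisition settings by channel kind: 30-240 Hz for
#' bipolar, 0.1-100 Hz for unipolar electrograms.
#'
#' @param acq an `egm_acquisition`.
#' @param low,high band edges, Hz; defaults chosen from `acq$kind`.
#' @param order Butterworth prototype order.
#' @return filtered acquisition, same shape and sampling rate.
#' @export
eg_bandpass <- function(acq, low = NULL, high = NULL, order = 4L) {
  stopifnot(inherits(acq, "egm_acquisition"))
  if (is.null(low))  low  <- if (acq$kind == "bipolar") 30 else 0.1
  if (is.null(high)) high <- if (acq$kind == "bipolar") 240 else 100
  nyq <- acq$fs / 2
  if (!(low >= 0 && low < high && high < nyq))
    stop("band must satisfy 0 <= low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- acq
  out$signal <- t(apply(acq$signal, 1L, function(r) signal::filtfilt(bf, r)))
  out$meta$band <- c(low, high)
  out
}

#' Zero-phase 50 Hz notch
#'
#' Mains interference removal: a narrow Butterworth band-stop (48-52 Hz)
#' applied forward-backward. Requires `fs > 100` Hz so the notch sits below
#' Nyquist; designed for the native 1 kHz acquisition rate.
#'
#' @param acq an `egm_acquisition`.
#' @param width half-width of the stop band around 50 Hz, Hz.
#' @return filtered acquisition.
#' @export
eg_notch50 <- function(acq, width = 2) {
  stopifnot(inherits(acq, "egm_acquisition"))
  if (acq$fs <= 100)
    stop("50 Hz notch requires fs > 100 Hz", call. = FALSE)
  nyq <- acq$fs / 2
  bf <- signal::butter(2L, c(50 - width, 50 + width) / nyq, type = "stop")
  out <- acq
  out$signal <- t(apply(acq$signal, 1L, function(r) signal::filtfilt(bf, r)))
  out$meta$notch <- 50
  out
}

#' Derive bipolar channels from a unipolar acquisition
#'
#' Row `i` of the result is the difference of the two unipolar electrodes of
#' `bipolar_pairs(layout)[i, ]` (inner minus outer). Any component common to
#' a pair -- far-field ventricular activity, mains pickup -- cancels exactly.
#' The default 20-electrode layout yields 15 bipoles.
#'
#' @param acq a unipolar `egm_acquisition` in canonical by-spline order.
#' @param layout the `catheter_layout` the rows follow.
#' @return a bipolar `egm_acquisition`.
#' @export
derive_bipolar <- function(acq, layout = build_layout()) {
  stopifnot(inherits(acq, "egm_acquisition"))
  if (acq$kind != "unipolar")
    stop("bipolar derivation requires a unipolar acquisition", call. = FALSE)
  pairs <- bipolar_pairs(layout)
  sig <- acq$signal[pairs[, "a"] + 1L, , drop = FALSE] -
    acq$signal[pairs[, "b"] + 1L, , drop = FALSE]
  eps <- layout$electrodes_per_spline
  im <- cbind(spline = pairs[, "a"] %/% eps, position = pairs[, "a"] %% eps)
  ord <- new_channel_ordering("bipolar-by-spline", im, layout)
  new_acquisition(sig, acq$fs, "bipolar", ord, acq$patient_id, acq$acq_index,
                  c(acq$meta, list(derived = "bipolar")))
}

#' Down-sample an acquisition
#'
#' Applies a zero-phase Butterworth anti-alias low-pass (cutoff 90 percent of
#' the target Nyquist), then keeps `floor(n * target_fs / fs)` samples at the
#' decimated grid. Binary activation trains (`kind = "lat-train"`) are
#' re-binned by index arithmetic (a max-pool over each output bin) instead of
#' filtered, preserving their 0/1 nature. Upsampling is refused.
#'
#' @param acq an `egm_acquisition`.
#' @param target_fs target sampling rate, Hz (<= `acq$fs`).
#' @return acquisition at `target_fs`.
#' @export
eg_resample <- function(acq, target_fs) {
  stopifnot(inherits(acq, "egm_acquisition"))
  if (target_fs > acq$fs)
    stop("`target_fs` must not exceed the current rate (no upsampling)", call. = FALSE)
  if (target_fs == acq$fs) return(acq)
  n <- ncol(acq$signal)
  out_n <- floor(n * target_fs / acq$fs)
  out <- acq
  if (acq$kind == "lat-train") {
    sig <- matrix(0, nrow(acq$signal), out_n)
    hits <- which(acq$signal != 0, arr.ind = TRUE)
    if (nrow(hits)) {
      j <- floor((hits[, 2L] - 1L) * target_fs / acq$fs) + 1L
      keep <- j <= out_n
      sig[cbind(hits[keep, 1L], j[keep])] <- 1
    }
  } else {
    band <- acq$meta$band
    if (!is.null(band) && band[2] <= target_fs / 2) {
      filt <- acq$signal        # already band-limited below the target Nyquist
    } else {
      bf <- signal::butter(8L, 0.9 * target_fs / acq$fs, type = "low")
      filt <- t(apply(acq$signal, 1L, function(r) signal::filtfilt(bf, r)))
    }
    idx <- floor((seq_len(out_n) - 1L) * acq$fs / target_fs) + 1L
    sig <- filt[, idx, drop = FALSE]
  }
  out$signal <- sig
  out$fs <- target_fs
  out$meta$resampled_from <- acq$fs
  out
}

#' Percentile normalization of a window
#'
#' Maps a signal window affinely so the 2nd percentile of all its entries
#' (channels pooled) lands at 0 and the 98th at 1, then clips to \[0, 1\].
#' This both standardizes the dynamic range and suppresses isolated extreme
#' peaks. A degenerate window (98th percentile equal to the 2nd) maps to the
#' constant 0.5.
#'
#' @param window numeric matrix (channels x samples).
#' @param probs the two percentile levels.
#' @return matrix of the same shape with entries in \[0, 1\]; the percentiles
#'   used are attached as attribute `"percentiles"`.
#' @export
percentile_normalize <- function(window, probs = c(0.02, 0.98)) {
  if (!length(window)) stop("empty window", call. = FALSE)
  q <- stats::quantile(window, probs = probs, names = FALSE)
  out <- if (q[2] <= q[1]) {
    array(0.5, dim = dim(window))
  } else {
    pmin(pmax((window - q[1]) / (q[2] - q[1]), 0), 1)
  }
  if (is.null(dim(out))) dim(out) <- dim(window)
  attr(out, "percentiles") <- q
  out
}

#' Binary activation-train representation
#'
#' Converts a unipolar acquisition plus per-channel activation times into a
#' 0/1 matrix of the same shape: 1 at each activation sample, 0 elsewhere --
#' the activation-train input representation for the classifiers.
#'
#' @param acq a unipolar `egm_acquisition` (shape/rate template).
#' @param lats list of per-channel activation-time vectors, ms (e.g. from
#'   [detect_lats()], field `lats`).
#' @return an `egm_acquisition` of kind `"lat-train"`.
#' @export
lat_train <- function(acq, lats) {
  stopifnot(inherits(acq, "egm_acquisition"))
  if (acq$kind != "unipolar")
    stop("activation trains are defined for unipolar acquisitions", call. = FALSE)
  if (length(lats) != nrow(acq$signal))
    stop("one activation-time vector per channel required", call. = FALSE)
  dur <- acq_duration_ms(acq)
  n <- ncol(acq$signal)
  sig <- matrix(0, nrow(acq$signal), n)
  for (e in seq_along(lats)) {
    tt <- lats[[e]]
    if (any(tt < 0 | tt >= dur))
      stop("activation time outside the acquisition", call. = FALSE)
    if (length(tt)) sig[e, pmin(round(tt * acq$fs / 1000) + 1L, n)] <- 1
  }
  new_acquisition(sig, acq$fs, "lat-train", acq$ordering, acq$patient_id,
                  acq$acq_index, c(acq$meta, list(derived = "lat-train")))
}
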
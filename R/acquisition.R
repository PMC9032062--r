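#' Multi-channel electrogram acquisition
#'
#' Container for one catheter acquisition: a channels-by-samples signal
#' matrix with its sampling rate, channel kind and provenance. Unipolar
#' acquisitions on the default layout have 20 rows; bipolar, 15.
#'
#' @param signal numeric matrix, channels x samples, millivolts (or 0/1 for
#'   `kind = "lat-train"`).
#' @param fs sampling rate, Hz.
#' @param kind one of `"unipolar"`, `"bipolar"`, `"lat-train"`.
#' @param ordering a `channel_ordering` describing the rows.
#' @param patient_id,acq_index provenance: patient label and chronological
#'   acquisition index within patient.
#' @param meta optional named list of processing provenance (band, percentiles,
#'   ...).
#' @return an object of class `egm_acquisition`.
#' @export
new_acquisition <- function(signal, fs, kind = c("unipolar", "bipolar", "lat-train"),
                            ordering, patient_id = NA_character_,
                            acq_index = NA_integer_, meta = list()) {
  kind <- match.arg(kind)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (!all(is.finite(signal)))
    stop("`signal` contains non-finite samples", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  if (!inherits(ordering, "channel_ordering"))
    stop("`ordering` must be a channel_ordering", call. = FALSE)
  if (nrow(signal) != nrow(ordering$index_map))
    stop("row count of `signal` does not match `ordering`", call. = FALSE)
  structure(
    list(signal = signal, fs = fs, kind = kind, ordering = ordering,
         patient_id = patient_id, acq_index = acq_index, meta = meta),
    class = "egm_acquisition"
  )
}

#' @export
print.egm_acquisition <- function(x, ...) {
  cat(sprintf("<egm_acquisition> %s, %d ch x %d samples @ %g Hz (%.1f s)%s\n",
              x$kind, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs,
              if (is.na(x$patient_id)) "" else paste0(", ", x$patient_id)))
  invisible(x)
}

#' Duration of an acquisition in milliseconds
#' @param acq an `egm_acquisition`.
#' @return duration, ms.
#' @export
acq_duration_ms <- function(acq) 1000 * ncol(acq$signal) / acq$fs
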
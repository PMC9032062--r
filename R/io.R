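#' Write / read a simulated cohort on disk
#'
#' Signals are stored one columnar text file per acquisition (samples in
#' rows, channels in columns) next to an `acquisitions.csv` manifest and an
#' `events.csv` ground-truth table, so detected and simulated annotations
#' can be diffed directly.
#'
#' @param cohort an `egm_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort`: the directory, invisibly. `read_cohort`: an
#'   `egm_cohort` (without schedules).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(acq_id = seq_along(cohort$acquisitions),
                    patient_id = vapply(cohort$acquisitions, `[[`, character(1), "patient_id"),
                    acq_index = vapply(cohort$acquisitions, `[[`, integer(1), "acq_index"),
                    fs = vapply(cohort$acquisitions, `[[`, numeric(1), "fs"),
                    kind = vapply(cohort$acquisitions, `[[`, character(1), "kind"),
                    file = sprintf("acq_%04d.csv", seq_along(cohort$acquisitions)))
  data.table::fwrite(man, file.path(dir, "acquisitions.csv"))
  write_events(cohort$events, file.path(dir, "events.csv"))
  data.table::fwrite(as.data.frame(layout_to_config(cohort$layout)),
                     file.path(dir, "layout.csv"))
  for (i in seq_along(cohort$acquisitions))
    data.table::fwrite(as.data.frame(t(cohort$acquisitions[[i]]$signal)),
                       file.path(dir, man$file[i]))
  invisible(dir)
}

#' @rdname write_cohort
#' @param layout optional `catheter_layout`; default rebuilt from the stored
#'   config.
#' @export
read_cohort <- function(dir, layout = NULL) {
  man <- data.table::fread(file.path(dir, "acquisitions.csv"), data.table = FALSE)
  if (is.null(layout)) {
    lc <- data.table::fread(file.path(dir, "layout.csv"), data.table = FALSE)
    layout <- build_layout(lc$n_splines[1], lc$electrodes_per_spline[1],
                           electrode_radii = lc$electrode_radii)
  }
  acqs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sig <- t(as.matrix(data.table::fread(file.path(dir, man$file[i]),
                                         data.table = FALSE)))
    dimnames(sig) <- NULL
    acqs[[i]] <- new_acquisition(sig, man$fs[i], man$kind[i],
                                 unipolar_order(layout),
                                 man$patient_id[i], man$acq_index[i])
  }
  structure(list(acquisitions = acqs,
                 events = read_events(file.path(dir, "events.csv")),
                 config = NULL, layout = layout, schedules = NULL),
            class = "egm_cohort")
}

#' Write / read rotational-event tables
#'
#' Columnar text with one row per event: acquisition id, interval, chirality,
#' rotation count, ring index.
#'
#' @param events event data.frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
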
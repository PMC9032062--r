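#' Simulation configuration
#'
#' Parameters of the synthetic electrogram generator. Defaults emulate the
#' clinical acquisition protocol: 30 s stable acquisitions at 1 kHz on a
#' 20-pole star catheter, with rotor episode cycle lengths drawn from a
#' truncated normal centered at 166.8 ms (sd 36.1 ms, floor 100 ms), the
#' cohort statistics of persistent-AF rotor episodes.
#'
#' @param duration_ms acquisition length, ms.
#' @param fs sampling rate, Hz.
#' @param cycle_length_mean,cycle_length_sd,cycle_length_floor truncated-normal
#'   parameters for per-episode (and per-acquisition background) cycle length, ms.
#' @param rotor_fraction probability that an acquisition contains at least one
#'   rotor episode.
#' @param rotations_per_episode integer range (length 2) of full rotations per
#'   rotor episode.
#' @param episodes_per_acquisition integer range of rotor episodes inserted in
#'   a rotor-positive acquisition.
#' @param noise_sd additive white-noise standard deviation, mV.
#' @param farfield_amplitude amplitude of the periodic common-mode far-field
#'   deflection (ventricular surrogate), mV; 0 disables.
#' @param farfield_period_range period range of the far-field deflections, ms.
#' @param mains_amplitude amplitude of 50 Hz interference, mV; 0 disables.
#' @param deflection_amplitude nominal activation deflection amplitude, mV.
#' @param amplitude_jitter relative amplitude jitter per activation (0.2 =
#'   +/-20 percent).
#' @param template_sigma_ms Gaussian width of the biphasic deflection template,
#'   ms (biphasic peaks sit at +/- one sigma; support about +/- 4 sigma).
#' @param refractory_ms floor on the spacing of consecutive activations on one
#'   electrode, ms.
#' @param conduction_velocity_mm_ms planar/focal wavefront speed, mm/ms.
#' @param fractionated_fraction probability a non-rotor acquisition carries
#'   fractionated channels (bursts of low-amplitude deflections, the classic
#'   false-positive surrogate of rotational activity).
#' @param seed integer seed; all cohort randomness flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration_ms = 30000, fs = 1000,
                       cycle_length_mean = 166.8, cycle_length_sd = 36.1,
                       cycle_length_floor = 100,
                       rotor_fraction = 0.5,
                       rotations_per_episode = c(3L, 10L),
                       episodes_per_acquisition = c(1L, 3L),
                       noise_sd = 0.05,
                       farfield_amplitude = 0.2,
                       farfield_period_range = c(700, 900),
                       mains_amplitude = 0.05,
                       deflection_amplitude = 1.0,
                       amplitude_jitter = 0.2,
                       template_sigma_ms = 2,
                       refractory_ms = 90,
                       conduction_velocity_mm_ms = 0.5,
                       fractionated_fraction = 0.3,
                       seed = 1L) {
  stopifnot(duration_ms > 0, fs > 0, cycle_length_mean > 0,
            rotor_fraction >= 0, rotor_fraction <= 1,
            length(rotations_per_episode) == 2L, rotations_per_episode[1] >= 1L)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## truncated-normal draw (lower bound only); vectorized rejection
rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

empty_schedule <- function(layout, duration_ms) {
  ne <- n_electrodes(layout)
  structure(
    list(lats = rep(list(numeric(0)), ne),
         deflections = NULL,    # built from the pruned activations at finalize
         fractionation = data.frame(electrode = integer(0), t0 = numeric(0),
                                    t1 = numeric(0)),
         pattern_segments = data.frame(start = numeric(0), end = numeric(0),
                                       pattern = character(0)),
         duration_ms = duration_ms, layout = layout, finalized = FALSE),
    class = "activation_schedule"
  )
}

#' @export
print.activation_schedule <- function(x, ...) {
  cat(sprintf("<activation_schedule> %d electrodes, %.1f s, %d activations\n",
              length(x$lats), x$duration_ms / 1000, sum(lengths(x$lats))))
  invisible(x)
}

add_activations <- function(schedule, electrode, times, amp = 1) {
  e <- electrode + 1L
  schedule$lats[[e]] <- sort(c(schedule$lats[[e]], times))
  schedule
}

segment <- function(schedule, start, end, pattern) {
  schedule$pattern_segments <- rbind(
    schedule$pattern_segments,
    data.frame(start = start, end = end, pattern = pattern))
  schedule
}

## per-electrode geometric delays (ms) of a planar wavefront
planar_delays <- function(layout, direction_deg, velocity) {
  pos <- electrode_positions(layout)
  u <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
  proj <- pos %*% u
  as.numeric(proj - min(proj)) / velocity
}

#' Planar (passing wavefront) activation schedule
#'
#' Negative-class generator: a plane wave sweeping the catheter at the
#' configured conduction velocity, repeating every `cl` ms. Activation times
#' increase linearly along the projection of electrode positions on the
#' propagation direction, so the per-ring spread is far below the cycle
#' length (22 ms across an 11 mm radius at 0.5 mm/ms).
#'
#' @param config a [sim_config()].
#' @param layout a `catheter_layout`.
#' @param direction_deg propagation direction, degrees.
#' @param t0,t1 segment interval, ms (within the acquisition).
#' @param cl cycle length, ms.
#' @param schedule schedule to extend (default: new empty one).
#' @return an `activation_schedule`.
#' @export
schedule_planar <- function(config, layout, direction_deg, t0, t1, cl,
                            schedule = empty_schedule(layout, config$duration_ms)) {
  check_interval(config, t0, t1)
  delays <- planar_delays(layout, direction_deg, config$conduction_velocity_mm_ms)
  ks <- t0 + cl * (seq_len(ceiling((t1 - t0) / cl) + 1L) - 1L)
  for (e in seq_along(delays)) {
    tt <- ks + delays[e]
    schedule <- add_activations(schedule, e - 1L, tt[tt < t1 - 1e-6], amp = 1)
  }
  segment(schedule, t0, t1, "planar")
}

#' Focal (radial source) activation schedule
#'
#' Negative-class generator: activation spreads radially from a source point,
#' so electrodes activate by distance from the source; on each ring the
#' activation spread stays well below the cycle length.
#'
#' @inheritParams schedule_planar
#' @param origin length-2 source position (mm); default random within the
#'   catheter footprint.
#' @export
schedule_focal <- function(config, layout, origin, t0, t1, cl,
                           schedule = empty_schedule(layout, config$duration_ms)) {
  check_interval(config, t0, t1)
  pos <- electrode_positions(layout)
  d <- sqrt((pos[, 1] - origin[1])^2 + (pos[, 2] - origin[2])^2)
  delays <- d / config$conduction_velocity_mm_ms
  ks <- t0 + cl * (seq_len(ceiling((t1 - t0) / cl) + 1L) - 1L)
  for (e in seq_along(delays)) {
    tt <- ks + delays[e]
    schedule <- add_activations(schedule, e - 1L, tt[tt < t1 - 1e-6], amp = 1)
  }
  segment(schedule, t0, t1, "focal")
}

check_interval <- function(config, t0, t1) {
  if (t0 >= t1 || t0 < 0 || t1 > config$duration_ms)
    stop("segment interval outside the acquisition", call. = FALSE)
  invisible(TRUE)
}

#' Rotor (rotational activity) schedule plus its ground-truth event
#'
#' Within each rotation `k`, the electrode sitting at ring angle `theta`
#' activates at `t0 + k*cl + (theta/360)*cl` for counterclockwise chirality
#' (angle progression negated for clockwise), so activation times on a ring
#' form a staircase spanning `(n_ring - 1)/n_ring` of the cycle (80 percent
#' for 5-electrode rings, comfortably above the 50-percent rule threshold).
#' All rings share the same core: electrodes on one spline activate together.
#'
#' @inheritParams schedule_planar
#' @param t0 episode start, ms.
#' @param n_rotations number of full rotations (>= 1).
#' @param chirality `"ccw"` (activation time increases with spline angle) or
#'   `"cw"`.
#' @param cl episode cycle length, ms.
#' @return list with `schedule` (extended) and `event` (one-row data.frame:
#'   `t_start`, `t_end`, `chirality`, `n_rotations`, `ring_index = NA` since
#'   all rings participate).
#' @export
schedule_rotor <- function(config, layout, t0, n_rotations,
                           chirality = c("ccw", "cw"), cl,
                           schedule = empty_schedule(layout, config$duration_ms)) {
  chirality <- match.arg(chirality)
  n_rotations <- as.integer(n_rotations)
  if (n_rotations < 1L) stop("`n_rotations` must be >= 1", call. = FALSE)
  t_end <- t0 + n_rotations * cl
  if (t0 < 0 || t_end > config$duration_ms)
    stop("rotor episode does not fit in the acquisition", call. = FALSE)
  ord <- unipolar_order(layout)$index_map
  th <- layout$spline_angles[ord[, 1L] + 1L]
  frac <- if (chirality == "ccw") th / 360 else (-th / 360) %% 1
  for (e in seq_along(frac)) {
    tt <- t0 + (seq_len(n_rotations) - 1L) * cl + frac[e] * cl
    schedule <- add_activations(schedule, e - 1L, tt, amp = 1)
  }
  schedule <- segment(schedule, t0, t_end, "rotor")
  list(schedule = schedule,
       event = data.frame(t_start = t0, t_end = t_end, chirality = chirality,
                          n_rotations = n_rotations, ring_index = NA_integer_))
}

#' Overlay fractionation on selected channels
#'
#' Marks the selected electrodes as fractionated inside `[t0, t1)`: at
#' rendering time each of their activations in the interval is expanded into
#' a burst of 3-5 low-amplitude deflections within 40 ms -- the complex
#' multi-deflection electrograms that act as a false-positive surrogate of
#' rotational activity.
#'
#' @inheritParams schedule_planar
#' @param electrodes 0-based flat electrode indices to fractionate.
#' @export
schedule_fractionate <- function(config, layout, schedule, electrodes, t0, t1) {
  schedule$fractionation <- rbind(
    schedule$fractionation,
    data.frame(electrode = as.integer(electrodes), t0 = t0, t1 = t1))
  segment(schedule, t0, t1, "fractionated")
}

## drop activations violating the refractory floor (keep earlier)
enforce_refractory <- function(times, refractory_ms) {
  if (length(times) < 2L) return(times)
  times <- sort(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

## Enforce the refractory floor on every electrode's activation train, then
## derive the deflections the renderer will draw: one unit-amplitude
## deflection per surviving activation, except on fractionated electrodes
## where marked activations expand into 3-5 jittered low-amplitude
## deflections spread over 40 ms. Idempotent.
finalize_schedule <- function(schedule, config) {
  if (isTRUE(schedule$finalized)) return(schedule)
  deflections <- vector("list", length(schedule$lats))
  fr <- schedule$fractionation
  for (e in seq_along(schedule$lats)) {
    tt <- enforce_refractory(schedule$lats[[e]], config$refractory_ms)
    schedule$lats[[e]] <- tt
    d <- data.frame(t = tt, amp = rep(1, length(tt)))
    fre <- fr[fr$electrode == e - 1L, , drop = FALSE]
    if (nrow(fre) && length(tt)) {
      in_frac <- rep(FALSE, length(tt))
      for (i in seq_len(nrow(fre)))
        in_frac <- in_frac | (tt >= fre$t0[i] & tt < fre$t1[i])
      keep <- d[!in_frac, , drop = FALSE]
      burst <- do.call(rbind, lapply(tt[in_frac], function(tc) {
        k <- sample(3:5, 1L)
        data.frame(t = tc + sort(stats::runif(k, 0, 40)) - 20,
                   amp = stats::runif(k, 0.2, 0.45))
      }))
      if (!is.null(burst))
        burst <- burst[burst$t >= 0 & burst$t < schedule$duration_ms, , drop = FALSE]
      d <- rbind(keep, burst)
    }
    deflections[[e]] <- d[order(d$t), , drop = FALSE]
  }
  schedule$deflections <- deflections
  schedule$finalized <- TRUE
  schedule
}

#' Render an activation schedule into a unipolar acquisition
#'
#' Each deflection becomes a biphasic waveform `w(t) = -A (t/sigma)
#' exp(1/2 - t^2 / (2 sigma^2))`, the negated first derivative of a Gaussian:
#' positive peak at `-sigma`, negative peak at `+sigma`, and -- by
#' construction -- steepest negative slope exactly at the scheduled
#' activation time. Additive white noise, an optional periodic common-mode
#' far-field deflection, and optional 50 Hz interference complete the model.
#' Output is reproducible given `seed`.
#'
#' @param schedule an `activation_schedule`.
#' @param config a [sim_config()].
#' @param patient_id,acq_index provenance stamps.
#' @param seed integer; default `config$seed`.
#' @return a unipolar `egm_acquisition`.
#' @export
render_unipolar <- function(schedule, config, patient_id = NA_character_,
                            acq_index = NA_integer_, seed = config$seed) {
  set.seed(seed)
  schedule <- finalize_schedule(schedule, config)
  layout <- schedule$layout
  fs <- config$fs
  n <- floor(config$duration_ms * fs / 1000)
  ne <- length(schedule$lats)
  sig <- matrix(0, nrow = ne, ncol = n)
  sigma <- config$template_sigma_ms
  half_ms <- 4 * sigma
  half <- ceiling(half_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs

  for (e in seq_len(ne)) {
    d <- schedule$deflections[[e]]
    if (nrow(d) == 0L) next
    amp <- config$deflection_amplitude * d$amp *
      (1 + config$amplitude_jitter * stats::runif(nrow(d), -1, 1))
    row <- numeric(n)
    for (j in seq_len(nrow(d))) {
      ic <- round(d$t[j] * fs / 1000) + 1L
      i0 <- max(1L, ic - half); i1 <- min(n, ic + half)
      if (i0 > n || i1 < 1L) next
      tt <- t_ms[i0:i1] - d$t[j]
      row[i0:i1] <- row[i0:i1] -
        amp[j] * (tt / sigma) * exp(0.5 - tt^2 / (2 * sigma^2))
    }
    sig[e, ] <- row
  }

  if (config$farfield_amplitude > 0) {
    period <- stats::runif(1, config$farfield_period_range[1], config$farfield_period_range[2])
    phase <- stats::runif(1, 0, period)
    centers <- seq(phase, config$duration_ms, by = period)
    ff <- numeric(n)
    sig_ff <- 15
    for (tc in centers) {
      i0 <- max(1L, round((tc - 4 * sig_ff) * fs / 1000) + 1L)
      i1 <- min(n, round((tc + 4 * sig_ff) * fs / 1000) + 1L)
      if (i0 > i1) next
      tt <- t_ms[i0:i1] - tc
      ff[i0:i1] <- ff[i0:i1] + config$farfield_amplitude * exp(-tt^2 / (2 * sig_ff^2))
    }
    sig <- sweep(sig, 2L, ff, `+`)
  }
  if (config$mains_amplitude > 0) {
    mains <- config$mains_amplitude * sin(2 * pi * 50 * t_ms / 1000 +
                                            stats::runif(1, 0, 2 * pi))
    sig <- sweep(sig, 2L, mains, `+`)
  }
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(ne * n, 0, config$noise_sd), ne, n)

  new_acquisition(sig, fs, "unipolar", unipolar_order(layout),
                  patient_id = patient_id, acq_index = acq_index,
                  meta = list(simulated = TRUE, seed = seed))
}

#' Simulate one acquisition with ground-truth events
#'
#' Builds a background schedule (planar or focal wavefront at a
#' per-acquisition cycle length, optionally with fractionated channels),
#' inserts rotor episodes with probability `rotor_fraction`, enforces the
#' refractory floor, and renders the waveforms.
#'
#' @param config a [sim_config()].
#' @param layout a `catheter_layout`.
#' @param patient_id,acq_index provenance stamps.
#' @param seed integer seed for this acquisition.
#' @return list with `acq` (unipolar `egm_acquisition`), `events` (data.frame,
#'   possibly 0-row), and `schedule`.
#' @export
simulate_acquisition <- function(config, layout = build_layout(),
                                 patient_id = "P001", acq_index = 1L,
                                 seed = config$seed) {
  sr <- simulate_schedule(config, layout, seed)
  render_seed <- (seed + 1L) %% .Machine$integer.max
  set.seed(render_seed)
  sch <- finalize_schedule(sr$schedule, config)
  acq <- render_unipolar(sch, config, patient_id, acq_index, seed = render_seed + 1L)
  list(acq = acq, events = sr$events, schedule = sch)
}

## schedule phase only: cheap, deterministic in `seed`, no waveforms
simulate_schedule <- function(config, layout, seed) {
  set.seed(seed)
  dur <- config$duration_ms
  cl_bg <- rtrunc_norm(1, config$cycle_length_mean, config$cycle_length_sd,
                       config$cycle_length_floor)

  has_rotor <- stats::runif(1) < config$rotor_fraction
  events <- data.frame(t_start = numeric(0), t_end = numeric(0),
                       chirality = character(0), n_rotations = integer(0),
                       ring_index = integer(0))
  episodes <- list()
  if (has_rotor) {
    n_ep <- sample(seq(config$episodes_per_acquisition[1],
                       config$episodes_per_acquisition[2]), 1L)
    guard <- 2 * config$cycle_length_mean
    for (i in seq_len(n_ep)) {
      for (try in 1:20) {
        n_rot <- sample(seq(config$rotations_per_episode[1],
                            config$rotations_per_episode[2]), 1L)
        cl_ep <- rtrunc_norm(1, config$cycle_length_mean, config$cycle_length_sd,
                             config$cycle_length_floor)
        len <- n_rot * cl_ep
        if (dur - len - guard <= guard) next   # episode cannot fit
        t0 <- stats::runif(1, guard, dur - len - guard)
        ok <- !length(episodes) || all(vapply(episodes, function(ep)
          t0 + len + guard < ep$t0 || t0 > ep$t0 + ep$len + guard, logical(1)))
        if (ok) {
          episodes[[length(episodes) + 1L]] <-
            list(t0 = t0, len = len, n_rot = n_rot, cl = cl_ep,
                 chirality = sample(c("ccw", "cw"), 1L))
          break
        }
      }
    }
    episodes <- episodes[order(vapply(episodes, `[[`, numeric(1), "t0"))]
  }

  ## background in the gaps between episodes
  sch <- empty_schedule(layout, dur)
  bg_kind <- sample(c("planar", "focal"), 1L)
  direction <- stats::runif(1, 0, 360)
  origin <- stats::runif(2, -6, 6)
  gaps <- list()
  cursor <- 0
  for (ep in episodes) {
    if (ep$t0 > cursor) gaps[[length(gaps) + 1L]] <- c(cursor, ep$t0)
    cursor <- ep$t0 + ep$len
  }
  if (cursor < dur) gaps[[length(gaps) + 1L]] <- c(cursor, dur)
  for (g in gaps) {
    if (g[2] - g[1] < cl_bg / 2) next
    sch <- if (bg_kind == "planar")
      schedule_planar(config, layout, direction, g[1], g[2], cl_bg, sch)
    else
      schedule_focal(config, layout, origin, g[1], g[2], cl_bg, sch)
  }
  if (!has_rotor && stats::runif(1) < config$fractionated_fraction) {
    nfr <- sample(3:8, 1L)
    sch <- schedule_fractionate(config, layout, sch,
                                sample(n_electrodes(layout), nfr) - 1L, 0, dur)
  }
  for (ep in episodes) {
    r <- schedule_rotor(config, layout, ep$t0, ep$n_rot, ep$chirality, ep$cl, sch)
    sch <- r$schedule
    events <- rbind(events, r$event)
  }
  list(schedule = sch, events = events)
}

#' Simulate a multi-patient cohort
#'
#' Generates `n_patients * acquisitions_per_patient` acquisitions with
#' ground-truth rotational-event annotations. Patients are labeled in
#' chronological order (`P001`, `P002`, ...) so the patient-wise
#' chronological train/test split can be exercised. All randomness derives
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_patients,acquisitions_per_patient cohort dimensions.
#' @param layout a `catheter_layout`.
#' @param keep_schedules keep each acquisition's activation schedule (memory
#'   permitting); needed for activation-time round-trip checks.
#' @return list of class `egm_cohort` with `acquisitions` (list), `events`
#'   (data.frame with `acq_id`, `patient_id`, `acq_index` + event columns),
#'   `config`, `layout`, and optionally `schedules`.
#' @export
simulate_cohort <- function(config, n_patients = 48L, acquisitions_per_patient = 10L,
                            layout = build_layout(), keep_schedules = FALSE) {
  stopifnot(n_patients >= 1L, acquisitions_per_patient >= 1L)
  acqs <- vector("list", n_patients * acquisitions_per_patient)
  schedules <- if (keep_schedules) vector("list", length(acqs)) else NULL
  ev_list <- vector("list", length(acqs))
  k <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (a in seq_len(acquisitions_per_patient)) {
      k <- k + 1L
      sub_seed <- (config$seed + 7919L * k) %% 2147483647L
      res <- simulate_acquisition(config, layout, pid, a, seed = sub_seed)
      acqs[[k]] <- res$acq
      if (keep_schedules) schedules[[k]] <- res$schedule
      if (nrow(res$events)) {
        ev_list[[k]] <- cbind(acq_id = k, patient_id = pid, acq_index = a,
                              res$events)
      }
    }
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(acq_id = integer(0), patient_id = character(0),
                         acq_index = integer(0), t_start = numeric(0),
                         t_end = numeric(0), chirality = character(0),
                         n_rotations = integer(0), ring_index = integer(0))
  structure(list(acquisitions = acqs, events = events, config = config,
                 layout = layout, schedules = schedules),
            class = "egm_cohort")
}

#' @export
print.egm_cohort <- function(x, ...) {
  cat(sprintf("<egm_cohort> %d acquisitions, %d patients, %d rotor events\n",
              length(x$acquisitions),
              length(unique(vapply(x$acquisitions, `[[`, character(1), "patient_id"))),
              nrow(x$events)))
  invisible(x)
}

#' Lazily evaluated synthetic cohort
#'
#' Same study design as [simulate_cohort()], but acquisitions are
#' regenerated on demand from their per-acquisition seeds instead of being
#' held in memory: only the ground-truth events and the per-acquisition
#' provenance are materialized up front (via the cheap scheduling phase).
#' Useful for cohorts whose rendered signals would not fit comfortably in
#' memory. [build_dataset()] accepts either representation.
#'
#' @inheritParams simulate_cohort
#' @return list of class `lazy_egm_cohort` with `meta` (one row per
#'   acquisition: `acq_id`, `patient_id`, `acq_index`, `seed`), `events`,
#'   `config`, `layout`, and `get(k)` returning acquisition `k` as an
#'   `egm_acquisition`.
#' @export
lazy_cohort <- function(config, n_patients = 48L, acquisitions_per_patient = 10L,
                        layout = build_layout()) {
  stopifnot(n_patients >= 1L, acquisitions_per_patient >= 1L)
  n <- n_patients * acquisitions_per_patient
  meta <- data.frame(
    acq_id = seq_len(n),
    patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                     each = acquisitions_per_patient),
    acq_index = rep(seq_len(acquisitions_per_patient), times = n_patients),
    seed = (config$seed + 7919L * seq_len(n)) %% 2147483647L)
  ev_list <- vector("list", n)
  for (k in seq_len(n)) {
    sr <- simulate_schedule(config, layout, meta$seed[k])
    if (nrow(sr$events))
      ev_list[[k]] <- cbind(acq_id = k, patient_id = meta$patient_id[k],
                            acq_index = meta$acq_index[k], sr$events)
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(acq_id = integer(0), patient_id = character(0),
                         acq_index = integer(0), t_start = numeric(0),
                         t_end = numeric(0), chirality = character(0),
                         n_rotations = integer(0), ring_index = integer(0))
  obj <- list(meta = meta, events = events, config = config, layout = layout)
  obj$get <- function(k) {
    simulate_acquisition(config, layout, meta$patient_id[k], meta$acq_index[k],
                         seed = meta$seed[k])$acq
  }
  class(obj) <- "lazy_egm_cohort"
  obj
}

#' @export
print.lazy_egm_cohort <- function(x, ...) {
  cat(sprintf("<lazy_egm_cohort> %d acquisitions, %d patients, %d rotor events\n",
              nrow(x$meta), length(unique(x$meta$patient_id)), nrow(x$events)))
  invisible(x)
}
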
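## shared miniature fixtures for the test suite

## a lat_series built directly from per-channel activation times
make_lat_series <- function(lats, fs = 1000, duration_ms = NULL,
                            refractory_ms = 90, layout = build_layout()) {
  structure(list(lats = lats, refractory_ms = refractory_ms, fs = fs,
                 duration_ms = duration_ms %||% (max(unlist(lats), 0) + 500),
                 ordering = unipolar_order(layout)),
            class = "lat_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## a quiet short simulation config for fast tests (overrides win)
quick_sim_config <- function(...) {
  args <- utils::modifyList(
    list(duration_ms = 8000, noise_sd = 0, farfield_amplitude = 0,
         mains_amplitude = 0, fractionated_fraction = 0),
    list(...))
  do.call(sim_config, args)
}

## pure staircase lat series: one ring rotating at cycle `cl`, all rings
## synchronized spline-wise, plus optional planar padding before/after
staircase_lats <- function(t0, n_rot, cl, chirality = "ccw",
                           layout = build_layout()) {
  ord <- unipolar_order(layout)$index_map
  th <- layout$spline_angles[ord[, 1] + 1]
  frac <- if (chirality == "ccw") th / 360 else (-th / 360) %% 1
  lapply(seq_along(frac), function(e)
    t0 + (seq_len(n_rot) - 1) * cl + frac[e] * cl)
}
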
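test_that("LAT detection finds steep negative slopes under the refractory rule", {
  cfg <- quick_sim_config(amplitude_jitter = 0)
  lay1 <- build_layout(1L, 1L)

  flat <- new_acquisition(matrix(0, 1, 3000), 1000, "unipolar",
                          unipolar_order(lay1))
  expect_equal(lengths(detect_lats(flat)$lats), 0L, ignore_attr = TRUE)

  ## two deflections 160 ms apart, the second steeper
  sch <- rotoregm:::empty_schedule(lay1, cfg$duration_ms)
  sch <- rotoregm:::add_activations(sch, 0L, 1000)
  sch <- rotoregm:::finalize_schedule(sch, cfg)
  sch$deflections[[1]] <- data.frame(t = c(1000, 1160), amp = c(1, 1.3))
  acq <- render_unipolar(sch, cfg, seed = 2L)

  both <- detect_lats(acq, refractory_ms = 90)$lats[[1]]
  expect_length(both, 2L)
  expect_equal(both, c(1000, 1160), tolerance = 2)

  ## a 200 ms refractory admits only the steeper of the two
  one <- detect_lats(acq, refractory_ms = 200)$lats[[1]]
  expect_length(one, 1L)
  expect_equal(one, 1160, tolerance = 2)
})

test_that("noiseless rendering round-trips scheduled LATs within 2 ms", {
  cfg <- quick_sim_config()
  lay <- build_layout()
  sch <- schedule_planar(cfg, lay, 45, 0, 3800, 170)
  sch <- schedule_rotor(cfg, lay, 4000, 3L, "ccw", 160, sch)$schedule
  sch <- rotoregm:::finalize_schedule(sch, cfg)
  acq <- render_unipolar(sch, cfg, seed = 7L)
  det <- detect_lats(acq)
  for (e in 1:20) {
    tt <- sch$lats[[e]]
    tt <- tt[tt > 20 & tt < cfg$duration_ms - 20]
    for (t in tt) expect_lt(min(abs(det$lats[[e]] - t)), 2)
  }
})

test_that("dominant cycle is the pooled median inter-activation interval", {
  lay <- build_layout()
  periodic <- make_lat_series(lapply(1:20, function(e) seq(0, 2000, by = 167)))
  expect_equal(dominant_cycle(periodic)$cl, 167)

  ## robust to a missed beat: intervals {160 x 9, 400 x 1}
  tt <- cumsum(c(0, rep(160, 9), 400))
  lone <- make_lat_series(c(list(tt), rep(list(numeric(0)), 19)))
  expect_equal(dominant_cycle(lone)$cl, 160)

  three <- make_lat_series(c(list(c(0, 170, 340)), rep(list(numeric(0)), 19)))
  expect_equal(dominant_cycle(three)$cl, 170)

  none <- make_lat_series(rep(list(numeric(0)), 20))
  expect_null(dominant_cycle(none))
})

test_that("the staircase scan accepts rotors and rejects planar geometry", {
  lay <- build_layout()
  cl <- structure(list(cl = 160, method = "fixed"), class = "cycle_estimate")

  rotor <- make_lat_series(staircase_lats(1000, 4, 160, "ccw"))
  cand <- ring_staircase_scan(rotor, ring_order(lay, 0L), cl)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$chirality == "ccw"))
  expect_true(all(cand$t_end - cand$t_start > 80))

  ## reversed staircase: opposite chirality, nothing else changes
  rotor_cw <- make_lat_series(staircase_lats(1000, 4, 160, "cw"))
  cand_cw <- ring_staircase_scan(rotor_cw, ring_order(lay, 0L), cl)
  expect_equal(nrow(cand_cw), nrow(cand))
  expect_true(all(cand_cw$chirality == "cw"))

  ## planar wavefront: span far below half a cycle, not a rotor
  planar <- make_lat_series(lapply(1:20, function(e)
    seq(0, 2000, by = 160) + c(0, 10, 20, 10, 0)[(e - 1) %/% 4 + 1]))
  expect_equal(nrow(ring_staircase_scan(planar, ring_order(lay, 0L), cl)), 0L)

  expect_error(ring_staircase_scan(rotor, unipolar_order(build_layout(2L, 1L)), cl),
               ">= 3")
})

test_that("grouping requires at least three consecutive rotations", {
  cl <- structure(list(cl = 160, method = "fixed"), class = "cycle_estimate")
  mk <- function(starts, chir = "ccw")
    data.frame(t_start = starts, t_end = starts + 128, chirality = chir,
               anchor = 1L, anchor_t = starts)

  ev3 <- group_consecutive(mk(c(0, 160, 320)), cl)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$n_rotations, 3L)
  expect_equal(ev3$chirality, "ccw")

  expect_equal(nrow(group_consecutive(mk(c(0, 160)), cl)), 0L)

  ## chirality flip after two candidates: no run reaches three rotations
  four <- rbind(mk(c(0, 160)), mk(c(320, 480), "cw"))
  expect_equal(nrow(group_consecutive(four, cl)), 0L)

  ## a gap larger than one cycle breaks the run
  gap <- mk(c(0, 160, 640, 800))
  expect_equal(nrow(group_consecutive(gap, cl)), 0L)
})

test_that("full detection recovers simulated rotors with chirality and shift equivariance", {
  cfg <- quick_sim_config()
  lay <- build_layout()
  build_acq <- function(t0, chir) {
    sch <- schedule_planar(cfg, lay, 10, 0, t0 - 200, 170)
    sch <- schedule_rotor(cfg, lay, t0, 4L, chir, 150, sch)$schedule
    sch <- schedule_planar(cfg, lay, 10, t0 + 4 * 150 + 50, cfg$duration_ms, 170, sch)
    render_unipolar(rotoregm:::finalize_schedule(sch, cfg), cfg, seed = 4L)
  }

  ev <- detect_rotational_activity(build_acq(3000, "ccw"), lay)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$chirality, "ccw")
  expect_equal(ev$n_rotations, 4L)
  ## detected interval overlaps the true [3000, 3600] episode
  expect_lt(ev$t_start, 3600); expect_gt(ev$t_end, 3000)

  ## chirality equivariance
  ev_cw <- detect_rotational_activity(build_acq(3000, "cw"), lay)
  expect_equal(ev_cw$chirality, "cw")

  ## time-shift equivariance: moving the episode moves the event
  ev_shift <- detect_rotational_activity(build_acq(4000, "ccw"), lay)
  expect_equal(ev_shift$t_start - ev$t_start, 1000, tolerance = 30)

  ## determinism
  ev2 <- detect_rotational_activity(build_acq(3000, "ccw"), lay)
  expect_identical(ev, ev2)
})
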
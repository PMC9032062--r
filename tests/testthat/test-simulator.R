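test_that("rotor schedules are staircases spanning 80% of the cycle", {
  cfg <- quick_sim_config()
  lay <- build_layout()
  r <- schedule_rotor(cfg, lay, t0 = 1000, n_rotations = 3L,
                      chirality = "ccw", cl = 160)
  ## ring LATs of the first rotation, ordered by spline angle
  ring <- ring_order(lay, 0L)$index_map
  lats <- vapply(seq_len(5), function(i) {
    e <- ring[i, "spline"] * 4L + ring[i, "position"] + 1L
    r$schedule$lats[[e]][1L]
  }, numeric(1))
  expect_equal(lats - 1000, c(0, 32, 64, 96, 128))
  expect_equal(max(lats) - min(lats), 0.8 * 160)

  ev <- r$event
  expect_equal(ev$n_rotations, 3L)
  expect_equal(ev$t_end - ev$t_start, 3 * 160)

  ## chirality flip reverses the per-ring staircase
  r2 <- schedule_rotor(cfg, lay, 1000, 3L, "cw", 160)
  lats2 <- vapply(seq_len(5), function(i) {
    e <- ring[i, "spline"] * 4L + ring[i, "position"] + 1L
    r2$schedule$lats[[e]][1L]
  }, numeric(1))
  expect_equal((lats2 - 1000)[-1], rev((lats - 1000)[-1]))

  expect_error(schedule_rotor(cfg, lay, 7800, 3L, "ccw", 160), "fit")
})

test_that("planar schedules follow the geometric projection", {
  cfg <- quick_sim_config()
  lay <- build_layout()
  sch <- schedule_planar(cfg, lay, direction_deg = 0, t0 = 0, t1 = 340, cl = 170)
  first <- vapply(sch$lats, `[[`, numeric(1), 1L)
  ## expected delays from electrode coordinates and conduction velocity
  pos <- electrode_positions(lay)
  delays <- (pos[, 1] - min(pos[, 1])) / cfg$conduction_velocity_mm_ms
  expect_equal(first, delays, tolerance = 1e-9, ignore_attr = TRUE)
  ## widest projection spread of the 5-spline star: 11 mm * (1 - cos 144 deg)
  expect_equal(max(first) - min(first),
               11 * (1 - cos(144 * pi / 180)) / 0.5, tolerance = 1e-9)
  ## two cycles at CL 170: exactly 2 activations per electrode in [t0, t0+340)
  expect_true(all(lengths(sch$lats) == 2L))
})

test_that("rendered deflections put the steepest negative slope at the LAT", {
  cfg <- quick_sim_config(noise_sd = 0, amplitude_jitter = 0)
  lay <- build_layout(1L, 1L)
  sch <- rotoregm:::empty_schedule(lay, cfg$duration_ms)
  sch <- rotoregm:::add_activations(sch, 0L, 1000)
  acq <- render_unipolar(sch, cfg, seed = 3L)
  d <- diff(acq$signal[1L, ])
  expect_equal(which.min(d), 1000L, tolerance = 1)

  ## superposition: two activations 160 ms apart give two derivative minima
  sch2 <- rotoregm:::add_activations(sch, 0L, 1160)
  acq2 <- render_unipolar(sch2, cfg, seed = 3L)
  d2 <- diff(acq2$signal[1L, ])
  mins <- order(d2)[1:2]
  expect_equal(abs(diff(sort(mins))), 160L, tolerance = 1)

  ## determinism: identical seed, bit-identical signal
  acq3 <- render_unipolar(sch2, cfg, seed = 3L)
  expect_identical(acq2$signal, acq3$signal)
})

test_that("cohorts respect the rotor fraction and the refractory floor", {
  lay <- build_layout()
  coh0 <- simulate_cohort(quick_sim_config(rotor_fraction = 0, seed = 5L),
                          n_patients = 3L, acquisitions_per_patient = 2L, lay)
  expect_equal(nrow(coh0$events), 0L)

  coh1 <- simulate_cohort(quick_sim_config(rotor_fraction = 1, seed = 5L),
                          n_patients = 5L, acquisitions_per_patient = 2L, lay)
  expect_gte(nrow(coh1$events), 10L)

  ## empirical per-acquisition event rate within the binomial 95% interval
  cfg <- quick_sim_config(rotor_fraction = 0.5, seed = 6L)
  coh <- simulate_cohort(cfg, 10L, 6L, lay)
  n_pos <- length(unique(coh$events$acq_id))
  ci <- qbinom(c(0.025, 0.975), 60L, 0.5)
  expect_gte(n_pos, ci[1]); expect_lte(n_pos, ci[2])

  ## schedule invariant: consecutive activations >= refractory floor apart
  coh2 <- simulate_cohort(cfg, 2L, 2L, lay, keep_schedules = TRUE)
  for (sch in coh2$schedules)
    for (tt in sch$lats)
      if (length(tt) > 1L) expect_gte(min(diff(tt)), cfg$refractory_ms)
})

test_that("identical seeds give identical cohorts", {
  cfg <- quick_sim_config(noise_sd = 0.05, seed = 9L)
  a <- simulate_cohort(cfg, 2L, 2L)
  b <- simulate_cohort(cfg, 2L, 2L)
  expect_identical(a$events, b$events)
  for (k in seq_along(a$acquisitions))
    expect_identical(a$acquisitions[[k]]$signal, b$acquisitions[[k]]$signal)
})
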
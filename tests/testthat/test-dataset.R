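test_that("window counts match brute-force start enumeration", {
  expect_equal(nrow(slide_windows(30000, 2500, 0.5)), 23L)
  expect_equal(nrow(slide_windows(30000, 500, 0.5)), 119L)
  expect_equal(nrow(slide_windows(30000, 30000, 0.5)), 1L)
  expect_error(slide_windows(1000, 2500, 0.5), "longer")
  expect_error(slide_windows(30000, 500, 1), "overlap")

  set.seed(11)
  for (i in 1:25) {
    dur <- sample(2000:40000, 1)
    win <- sample(200:min(dur, 5000), 1)
    ov <- runif(1, 0, 0.9)
    step <- win * (1 - ov)
    brute <- sum((seq(0, dur, by = step) + win) <= dur + 1e-9)
    expect_equal(nrow(slide_windows(dur, win, ov)), brute,
                 info = sprintf("dur=%d win=%d ov=%.3f", dur, win, ov))
  }
})

test_that("window labels follow the one-full-rotation overlap rule", {
  ev <- data.frame(t_start = 10000, t_end = 10600, chirality = "ccw",
                   n_rotations = 3L)           # rotation duration 200 ms
  expect_equal(label_window(c(10000, 10500), ev), 1L)   # inside the event
  expect_equal(label_window(c(0, 2500), ev), 0L)        # zero overlap
  expect_equal(label_window(c(9600, 10100), ev), 0L)    # half a rotation
  expect_equal(label_window(c(9600, 10100), ev, rule = "any"), 1L)
  expect_equal(label_window(c(0, 2500), NULL), 0L)
})

make_window <- function(y = 1L) {
  lay <- build_layout()
  labeled_window(matrix(seq_len(20 * 40), 20, 40), y, unipolar_order(lay))
}

test_that("flips are label-preserving involutions", {
  w <- make_window()
  expect_equal(flip_time(flip_time(w))$x, w$x)
  expect_equal(flip_channels(flip_channels(w))$x, w$x)
  expect_equal(flip_time(w)$y, w$y)
  expect_equal(flip_channels(w)$y, w$y)
  expect_equal(flip_time(w)$x[, 1], w$x[, 40])
  expect_equal(flip_channels(w)$x[1, ], w$x[20, ])
})

test_that("spline-rotation augmentation yields 5 label-preserving variants", {
  w <- make_window()
  aug <- augment_window(w)
  expect_length(aug, 5L)
  expect_equal(aug[[1]]$x, w$x)              # start at spline 1 = identity
  expect_true(all(vapply(aug, `[[`, integer(1), "y") == w$y))
  ## each variant is a row permutation; applying 5 single-step rotations
  ## returns the original rows
  for (a in aug) expect_equal(sort(a$x[, 1]), sort(w$x[, 1]))
  expect_length(unique(lapply(aug, function(a) a$x[1, 1])), 5L)

  with_flips <- augment_window(w, flips = TRUE)
  expect_length(with_flips, 20L)
  expect_true(all(vapply(with_flips, `[[`, integer(1), "y") == w$y))
})

test_that("rebalancing keeps a 1:1 ratio per patient and drops rotor-free patients", {
  man <- data.frame(
    patient_id = rep(c("P001", "P002", "P003"), c(60, 30, 20)),
    y = c(rep(c(1L, 0L), c(10, 50)), rep(c(1L, 0L), c(15, 15)), rep(0L, 20)))
  out <- rebalance_windows(man, seed = 3L)
  expect_equal(sum(out$patient_id == "P001" & out$y == 1), 10L)
  expect_equal(sum(out$patient_id == "P001" & out$y == 0), 10L)
  expect_equal(sum(out$patient_id == "P003"), 0L)        # no positives
  expect_equal(sum(out$y == 1), sum(out$y == 0))
  expect_identical(rebalance_windows(man, seed = 3L), out)
})

test_that("patient split is chronological, disjoint, and 90:10", {
  man48 <- data.frame(patient_id = rep(sprintf("P%03d", 1:48), each = 4),
                      y = rep(c(0L, 1L), 96))
  sp <- split_patients(man48, seed = 1L)
  expect_setequal(unique(c(sp$train$patient_id, sp$val$patient_id)),
                  sprintf("P%03d", 1:43))
  expect_setequal(unique(sp$test$patient_id), sprintf("P%03d", 44:48))
  expect_length(intersect(unique(c(sp$train$patient_id, sp$val$patient_id)),
                          unique(sp$test$patient_id)), 0L)

  man10 <- data.frame(patient_id = rep(sprintf("P%03d", 1:10), each = 4),
                      y = rep(c(0L, 1L), 20))
  sp10 <- split_patients(man10, seed = 1L)
  expect_setequal(unique(sp10$test$patient_id), "P010")

  expect_identical(split_patients(man48, seed = 5L),
                   split_patients(man48, seed = 5L))
  expect_error(split_patients(data.frame(patient_id = "P001", y = 1L)),
               "2 patients")
})

test_that("dataset builder produces normalized, patient-disjoint window sets", {
  cfg <- quick_sim_config(rotor_fraction = 1, duration_ms = 10000, seed = 21L)
  coh <- simulate_cohort(cfg, n_patients = 4L, acquisitions_per_patient = 2L)
  ds <- build_dataset(coh, signal_type = "bipolar", window_ms = 2500,
                      target_fs = 250, filter = FALSE, seed = 21L)
  expect_s3_class(ds$train, "window_set")
  w <- ds$train[[1L]]
  expect_equal(dim(w$x), c(15L, 625L))       # 2500 ms at 250 Hz, 15 bipoles
  expect_gte(min(w$x), 0); expect_lte(max(w$x), 1)
  tr_pat <- unique(vapply(ds$train, `[[`, character(1), "patient_id"))
  te_pat <- unique(vapply(ds$test, `[[`, character(1), "patient_id"))
  expect_length(intersect(tr_pat, te_pat), 0L)
  ## rebalanced: never more negatives than positives (every rotor-positive
  ## acquisition here is positive-rich, so negatives are the scarce class)
  yy <- vapply(c(ds$train, ds$val), `[[`, integer(1), "y")
  expect_lte(sum(yy == 0), sum(yy == 1))
  expect_gt(sum(yy == 0), 0)

  ni <- as_net_input(ds$val)
  expect_equal(dim(ni$x), c(625L, 15L, 1L, length(ds$val)))
})
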
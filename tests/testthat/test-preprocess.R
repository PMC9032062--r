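make_tone_acq <- function(freq, fs = 1000, dur_s = 2, kind = "bipolar") {
  lay <- build_layout(1L, 2L)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  sig <- matrix(sin(2 * pi * freq * t), nrow = 1)
  ord <- if (kind == "bipolar")
    rotoregm:::new_channel_ordering("bipolar-by-spline",
                                    cbind(spline = 0L, position = 0L), lay)
  else unipolar_order(build_layout(1L, 1L))
  new_acquisition(sig, fs, kind, ord)
}

mid_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[(n %/% 4):(3 * n %/% 4)]^2))
}

test_that("band-pass keeps the passband and rejects out-of-band tones", {
  in_band <- make_tone_acq(100)
  out_band <- make_tone_acq(300)
  bp_in <- eg_bandpass(in_band)      # bipolar default 30-240 Hz
  bp_out <- eg_bandpass(out_band)
  expect_gt(mid_rms(bp_in$signal[1, ]), mid_rms(in_band$signal[1, ]) / sqrt(2))  # within 3 dB
  expect_lt(mid_rms(bp_out$signal[1, ]), 0.1 * mid_rms(out_band$signal[1, ]))
  zero <- make_tone_acq(100)
  zero$signal[] <- 0
  expect_equal(eg_bandpass(zero)$signal, zero$signal)
  expect_error(eg_bandpass(make_tone_acq(100), low = 100, high = 600), "fs/2")
})

test_that("the 50 Hz notch removes mains and spares neighbors", {
  mains <- make_tone_acq(50, kind = "unipolar")
  slow <- make_tone_acq(10, kind = "unipolar")
  expect_lt(mid_rms(eg_notch50(mains)$signal[1, ]),
            0.1 * mid_rms(mains$signal[1, ]))
  expect_equal(mid_rms(eg_notch50(slow)$signal[1, ]),
               mid_rms(slow$signal[1, ]), tolerance = 0.05)
  zero <- mains; zero$signal[] <- 0
  expect_equal(eg_notch50(zero)$signal, zero$signal)
  lowfs <- mains; lowfs$fs <- 100
  expect_error(eg_notch50(lowfs), "fs > 100")
})

test_that("bipolar derivation cancels common mode and is linear", {
  lay <- build_layout()
  cfg <- quick_sim_config()
  common <- matrix(rep(sin(seq_len(2000) / 50), each = 20), nrow = 20)
  acq <- new_acquisition(common, 1000, "unipolar", unipolar_order(lay))
  bi <- derive_bipolar(acq, lay)
  expect_equal(nrow(bi$signal), 15L)
  expect_equal(max(abs(bi$signal)), 0)

  ## impulse on the innermost electrode of spline 1 -> exactly one bipole
  imp <- acq; imp$signal[] <- 0; imp$signal[1L, 500L] <- 1
  bi2 <- derive_bipolar(imp, lay)
  expect_equal(sum(rowSums(abs(bi2$signal)) > 0), 1L)

  ## linearity
  a <- acq; a$signal <- matrix(rnorm(20 * 100), 20)
  b <- acq; b$signal <- matrix(rnorm(20 * 100), 20)
  ab <- acq; ab$signal <- a$signal + b$signal
  expect_equal(derive_bipolar(ab, lay)$signal,
               derive_bipolar(a, lay)$signal + derive_bipolar(b, lay)$signal)
  expect_error(derive_bipolar(bi, lay), "unipolar")
})

test_that("down-sampling scales the sample count by floor(n*target/fs)", {
  lay <- build_layout(1L, 1L)
  acq <- new_acquisition(matrix(rnorm(30000), 1), 1000, "unipolar",
                         unipolar_order(lay))
  expect_equal(ncol(eg_resample(acq, 500)$signal), 15000L)
  expect_equal(ncol(eg_resample(acq, 100)$signal), 3000L)
  expect_identical(eg_resample(acq, 1000), acq)
  expect_error(eg_resample(acq, 2000), "upsampling")
  ## channel count is preserved
  expect_equal(nrow(eg_resample(acq, 250)$signal), 1L)
})

test_that("percentile normalization maps the 2nd/98th percentiles to [0, 1]", {
  ## symmetric window: p2 = -p98, so 0 mV lands exactly at 0.5
  w <- matrix(seq(-1, 1, length.out = 101), nrow = 1)
  nw <- percentile_normalize(w)
  expect_equal(nw[1, 51], 0.5)
  expect_gte(min(nw), 0); expect_lte(max(nw), 1)

  expect_equal(unique(as.numeric(percentile_normalize(matrix(3, 4, 5)))), 0.5)

  ## idempotence on a window whose p2 = 0 and p98 = 1
  v <- matrix(seq(0, 1, length.out = 101), nrow = 1)
  v2 <- percentile_normalize(v)
  q <- quantile(v2, c(0.02, 0.98), names = FALSE)
  expect_equal(q, c(0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(percentile_normalize(v2)), as.numeric(v2),
               tolerance = 1e-12)

  ## heavy outliers are clipped, not stretched
  w2 <- matrix(c(rnorm(1000), 50, -50), nrow = 1)
  nw2 <- percentile_normalize(w2)
  expect_equal(range(nw2), c(0, 1))
})

test_that("activation trains are binary, aligned, and re-binned on resampling", {
  lay <- build_layout()
  acq <- new_acquisition(matrix(0, 20, 5000), 1000, "unipolar",
                         unipolar_order(lay))
  none <- lat_train(acq, rep(list(numeric(0)), 20))
  expect_equal(sum(none$signal), 0)

  lats <- lapply(1:20, function(e) 100 * e)
  tr <- lat_train(acq, lats)
  expect_equal(rowSums(tr$signal), rep(1, 20))
  expect_equal(sort(unique(as.numeric(tr$signal))), c(0, 1))

  ## 1 kHz -> 100 Hz maps LAT sample i to floor(i/10), still binary
  tr100 <- eg_resample(tr, 100)
  expect_equal(ncol(tr100$signal), 500L)
  expect_equal(sort(unique(as.numeric(tr100$signal))), c(0, 1))
  hits <- which(tr$signal != 0, arr.ind = TRUE)
  hits100 <- which(tr100$signal != 0, arr.ind = TRUE)
  expect_equal(hits100[, 2], floor((hits[, 2] - 1) / 10) + 1,
               ignore_attr = TRUE)

  expect_error(lat_train(acq, lapply(1:20, function(e) 6000)), "outside")
})
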
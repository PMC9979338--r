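test_that("resampling preserves duration and spectral content", {
  m2 <- site_montage(2)
  rec <- simulate_recording(m2, state_profile("PreMF", duration = 60), seed = 7)
  rr <- resample_recording(rec, 300)
  expect_equal(rr$montage$sampling_rate, 300)
  expect_equal(ncol(rr$samples), 18000)
  # identity at equal rate, error on upsampling
  expect_identical(resample_recording(rr, 300), rr)
  expect_error(resample_recording(rr, 500), "upsampling")
  # a 10 Hz sinusoid keeps its Welch peak at 10 Hz after 500 -> 300 Hz
  x <- sin(2 * pi * 10 * (0:29999) / 500)
  rs <- rs_recording(matrix(rep(x, each = 1), nrow = length(m2$channel_labels),
                            ncol = 30000, byrow = TRUE), m2, "PreMF")
  rd <- resample_recording(rs, 300)
  p <- welch_psd(rd$samples[1, ], 300, seg_seconds = 1)
  expect_equal(p$freq[which.max(p$psd)], 10)
})

test_that("Kaiser band-pass removes DC, attenuates 45 Hz, passes 10 Hz", {
  m <- site_montage(1)
  n <- 9000
  mk <- function(x) rs_recording(matrix(rep(x, 21), nrow = 21, byrow = TRUE),
                                 m, "PreMF")
  # DC offset -> mean ~ 0
  rdc <- bandpass_filter(mk(rep(5, n)))
  expect_lt(abs(mean(rdc$samples[1, 3000:6000])), 0.01)
  # 45 Hz attenuated by >= 40 dB
  x45 <- sin(2 * pi * 45 * (0:(n - 1)) / 300)
  r45 <- bandpass_filter(mk(x45))
  att <- 10 * log10(mean(r45$samples[1, 3000:6000]^2) / mean(x45[3000:6000]^2))
  expect_lt(att, -40)
  # 10 Hz within +-0.5 dB
  x10 <- sin(2 * pi * 10 * (0:(n - 1)) / 300)
  r10 <- bandpass_filter(mk(x10))
  g <- 10 * log10(mean(r10$samples[1, 3000:6000]^2) / mean(x10[3000:6000]^2))
  expect_lt(abs(g), 0.5)
  expect_error(bandpass_filter(mk(x10), lo = 1, hi = 150), "Nyquist")
})

test_that("bad-channel rules flag flat and line-noise channels", {
  rec <- clean_recording()
  expect_length(detect_bad_channels(rec), 0)
  r1 <- inject_artifacts(rec, list(list(type = "flat_channel", channels = "T3",
                                        start = 10, duration = 6)))
  expect_identical(detect_bad_channels(r1), "T3")
  r2 <- inject_artifacts(rec, list(list(type = "line_noise", channels = "F7",
                                        freq = 50, amplitude = 30)))
  expect_identical(detect_bad_channels(r2), "F7")
  expect_error(detect_bad_channels(
    simulate_recording(site_montage(1), state_profile("PreMF", duration = 3),
                       seed = 1)), "shorter")
})

test_that("subspace reconstruction removes bursts and passes clean data", {
  rec <- clean_recording()
  # artifact-free pass-through: relative RMS change < 1%
  rp <- asr_clean(rec)
  expect_lt(sqrt(mean((rp$samples - rec$samples)^2)) /
              sqrt(mean(rec$samples^2)), 0.01)
  # x50 burst on two channels: burst-window RMS reduced >= 10-fold
  rb <- inject_artifacts(rec, list(list(type = "burst",
                                        channels = c("P3", "C3"),
                                        start = 20, duration = 1, factor = 50)))
  ra <- asr_clean(rb)
  w <- (20 * 300 + 1):(21 * 300)
  expect_gt(sqrt(mean(rb$samples[, w]^2)) / sqrt(mean(ra$samples[, w]^2)), 10)
  # all-zero recording unchanged
  rz <- rec; rz$samples[] <- 0
  expect_identical(asr_clean(rz)$samples, rz$samples)
  # too short for calibration
  short <- simulate_recording(site_montage(1),
                              state_profile("PreMF", duration = 10), seed = 2)
  expect_error(asr_clean(short), "calibration")
})

test_that("segment rejection drops the burst window iff enough channels", {
  rec <- clean_recording()
  expect_length(attr(reject_bad_segments(rec), "rejected_windows"), 0)
  six <- c("P3", "C3", "F3", "Fz", "F4", "C4")
  rb <- inject_artifacts(rec, list(list(type = "burst", channels = six,
                                        start = 20, duration = 1, factor = 50)))
  rr <- reject_bad_segments(rb)
  expect_identical(attr(rr, "rejected_windows"), 21L)  # window 21 = [20, 21) s
  expect_equal(ncol(rr$samples), 59 * 300)
  expect_false(21 %in% (attr(rr, "kept_intervals")$start + 1))
  # only 2 of 21 channels: below the quarter threshold, nothing removed
  r2 <- inject_artifacts(rec, list(list(type = "burst",
                                        channels = c("P3", "C3"),
                                        start = 20, duration = 1, factor = 50)))
  expect_length(attr(reject_bad_segments(r2), "rejected_windows"), 0)
})

test_that("re-referencing subtracts the A1/A2 mean", {
  rec <- clean_recording()
  # zero ear channels: unchanged
  r0 <- rec; r0$samples[c("A1", "A2"), ] <- 0
  expect_equal(rereference(r0)$samples, r0$samples)
  # common-mode shift removed
  rshift <- rec; rshift$samples <- rec$samples + 7.5
  expect_equal(rereference(rshift)$samples, rereference(rec)$samples,
               tolerance = 1e-12)
  # algebraic identity: referenced A1/A2 average is zero
  rr <- rereference(rec)
  expect_lt(max(abs(colMeans(rr$samples[c("A1", "A2"), ]))), 1e-10)
  # fallback to common average with a warning
  mon <- montage_spec(setdiff(site_montage(1)$channel_labels, c("A1", "A2")),
                      sampling_rate = 300)
  sub <- rs_recording(rec$samples[mon$channel_labels, ], mon, "PreMF")
  expect_warning(rc <- rereference(sub), "common average")
  expect_lt(max(abs(colMeans(rc$samples))), 1e-10)
})

test_that("epoching uses the floor rule on non-overlapping 1-s windows", {
  m <- site_montage(1)
  rec <- simulate_recording(m, state_profile("PreMF", duration = 60), seed = 4)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(60, 21, 300))
  expect_identical(ep$retained_index, 1:60)
  # epoch k is the half-open interval [k-1, k) seconds
  expect_identical(ep$data[2, "O1", ], rec$samples["O1", 301:600])
  r25 <- rec; r25$samples <- rec$samples[, 1:750]
  expect_equal(dim(epoch_recording(r25)$data)[1], 2)
  r09 <- rec; r09$samples <- rec$samples[, 1:270]
  expect_error(epoch_recording(r09), "shorter than one epoch")
})

test_that("spherical-spline interpolation reproduces constants and smooth fields", {
  m <- site_montage(1)
  const_ep <- epochs_from_field(function(e, labs, n) matrix(5, length(labs), n))
  expect_identical(interpolate_channels(const_ep, character(0)), const_ep)
  ci <- interpolate_channels(const_ep, "Cz")
  expect_equal(ci$data[1, "Cz", ], rep(5, 300), tolerance = 1e-6)
  # smooth dipolar field: leave-one-out error below a channel-noise level
  dvec <- c(0.2, 0.5, 0.84); dvec <- dvec / sqrt(sum(dvec^2))
  pos <- electrode_positions(m$channel_labels)
  fld <- exp(1.5 * as.vector(pos %*% dvec))
  dip_ep <- epochs_from_field(function(e, labs, n)
    matrix(rep(fld, n), length(labs), n))
  for (ch in c("Cz", "T5", "F3")) {
    di <- interpolate_channels(dip_ep, ch)
    err <- abs(di$data[1, ch, 1] - fld[match(ch, m$channel_labels)])
    expect_lt(err, 0.05 * diff(range(fld)))
  }
  expect_error(interpolate_channels(const_ep, "XX"), "not in montage")
})

test_that("the full cleaning chain yields 1-s epochs and a rejection log", {
  # the zero-phase FIR smears ~1.8 s into the flat zone from each edge, so
  # the chain (which filters before detection) needs a 10-s flat interval
  rec <- inject_artifacts(clean_recording(),
                          list(list(type = "flat_channel", channels = "T3",
                                    start = 5, duration = 10)))
  pp <- preprocess_recording(rec)
  expect_identical(pp$bad_channels, "T3")
  expect_s3_class(pp$epochs, "epoch_set")
  expect_equal(dim(pp$epochs$data)[3], 300)
  expect_equal(pp$epochs$rate, 300)
  expect_true(all(c("resample", "bandpass", "bad_channels", "rereference",
                    "epoch", "interpolate") %in% pp$log$stage))
  # interpolated T3 is no longer flat
  expect_gt(stats::sd(pp$epochs$data[7, "T3", ]), 0.01)
})
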
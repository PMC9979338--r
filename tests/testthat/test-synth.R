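test_that("simulator is deterministic and linear in band gains", {
  m <- site_montage(1)
  pr <- state_profile("PreMF", duration = 10)
  r1 <- simulate_recording(m, pr, seed = 42)
  r2 <- simulate_recording(m, pr, seed = 42)
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_recording(m, pr, seed = 43)
  expect_false(identical(r1$samples, r3$samples))

  # zero gains and zero pink noise give the all-zero signal
  pr0 <- state_profile("PreMF", duration = 10,
                       band_gains = c(theta = 0, alpha = 0, beta = 0))
  r0 <- simulate_recording(m, pr0, seed = 42, pink_amplitude = 0)
  expect_true(all(r0$samples == 0))

  # doubling the alpha gain with the same seed quadruples alpha power
  pr_a2 <- state_profile("PreMF", duration = 30, band_gains = c(alpha = 2))
  pr_a1 <- state_profile("PreMF", duration = 30)
  ra2 <- simulate_recording(m, pr_a2, seed = 9, pink_amplitude = 0)
  ra1 <- simulate_recording(m, pr_a1, seed = 9, pink_amplitude = 0)
  p2 <- band_power(welch_psd(ra2$samples["O1", ], 300, seg_seconds = 1), "Alpha")
  p1 <- band_power(welch_psd(ra1$samples["O1", ], 300, seg_seconds = 1), "Alpha")
  expect_equal(p2 / p1, 4, tolerance = 0.05)
})

test_that("unknown band names are rejected", {
  expect_error(state_profile("PreMF", band_gains = c(gamma = 1)), "unknown band")
  expect_error(simulate_recording(site_montage(1), state_profile("PreMF"),
                                  participant_gains = c(delta_band = 1)),
               "unknown band")
})

test_that("cohorts have the four-state structure and site presets", {
  coh <- simulate_cohort(3, delta = 0, seed = 5,
                         durations = c(TaskRest1 = 12, PreMF = 6,
                                       PostMF = 6, TaskRest2 = 6))
  expect_length(coh, 3)
  expect_identical(names(coh[[1]]$recordings),
                   c("TaskRest1", "PreMF", "PostMF", "TaskRest2"))
  # default alternating site presets: site 2 recordings are at 500 Hz
  expect_equal(coh[[1]]$recordings$PreMF$montage$sampling_rate, 300)
  expect_equal(coh[[2]]$recordings$PreMF$montage$sampling_rate, 500)
  expect_equal(ncol(coh[[2]]$recordings$PostMF$samples), 6 * 500)
  expect_equal(recording_duration(coh[[1]]$recordings$TaskRest1), 12)
  # determinism across construction
  coh2 <- simulate_cohort(3, delta = 0, seed = 5,
                          durations = c(TaskRest1 = 12, PreMF = 6,
                                        PostMF = 6, TaskRest2 = 6))
  expect_identical(coh[[2]]$recordings$PostMF$samples,
                   coh2[[2]]$recordings$PostMF$samples)
})

test_that("delta shifts alpha up and beta down at Post-MF (pooled epochs)", {
  coh <- simulate_cohort(4, delta = 0.3, seed = 21, site_assignment = rep(1, 4),
                         durations = c(TaskRest1 = 30, PreMF = 30,
                                       PostMF = 30, TaskRest2 = 30))
  rel <- list(PreMF = c(), PostMF = c(), beta_pre = c(), beta_post = c())
  for (p in coh) {
    for (s in c("PreMF", "PostMF")) {
      ft <- extract_features(epoch_recording(p$recordings[[s]]))
      av <- average_over_channels(ft, feature_channels())
      rel[[s]] <- c(rel[[s]], av[, "RelAlpha"])
      key <- if (s == "PreMF") "beta_pre" else "beta_post"
      rel[[key]] <- c(rel[[key]], av[, "RelBeta"])
    }
  }
  ra <- rank_sum(rel$PostMF, rel$PreMF)
  expect_lt(ra$p, 0.05)
  expect_identical(ra$direction, "greater")
  rb <- rank_sum(rel$beta_pre, rel$beta_post)
  expect_lt(rb$p, 0.05)
  expect_identical(rb$direction, "greater")
})

test_that("effect monotonicity: Post-Pre alpha power difference grows with delta", {
  diffs <- sapply(c(0, 0.25, 0.5), function(d) {
    coh <- simulate_cohort(2, delta = d, seed = 31, site_assignment = c(1, 1),
                           durations = c(TaskRest1 = 10, PreMF = 10,
                                         PostMF = 10, TaskRest2 = 10))
    mean(sapply(coh, function(p) {
      pa <- function(s) band_power(
        welch_psd(p$recordings[[s]]$samples["O1", ], 300, seg_seconds = 1), "Alpha")
      pa("PostMF") - pa("PreMF")
    }))
  })
  expect_true(all(diff(diffs) > 0))
})

test_that("artifact injection is a superposition with interval checks", {
  rec <- clean_recording()
  expect_identical(inject_artifacts(rec, list()), rec)
  expect_error(inject_artifacts(rec, list(list(type = "flat_channel",
                                               channels = "T3", start = 58,
                                               duration = 6))),
               "outside recording")
  expect_error(inject_artifacts(rec, list(list(type = "burst",
                                               channels = "XX", start = 0,
                                               duration = 1))),
               "unknown channel")
  r <- inject_artifacts(rec, list(list(type = "line_noise", channels = "F7",
                                       freq = 50, amplitude = 10,
                                       start = 0, duration = 60)))
  delta <- r$samples["F7", ] - rec$samples["F7", ]
  expect_equal(sqrt(mean(delta^2)), 10 / sqrt(2), tolerance = 0.01)
  expect_identical(r$samples["F3", ], rec$samples["F3", ])
})
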
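# Shared fixtures and memoised expensive runs.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A clean 60-s site-1 recording used by several preprocessing tests.
clean_recording <- function() memo("clean_rec", {
  simulate_recording(site_montage(1), state_profile("PreMF", duration = 60),
                     seed = 3)
})

# Minimal-profile config for pipeline-shaped tests that only need the
# mechanics, not the study-scale Monte-Carlo load.
mini_config <- function(seed = 1) {
  mf_config("fast", sel_folds = 3, sel_mc = 1, max_pairs = 3,
            eval_folds = 3, eval_mc = 3, seed = seed)
}

# Epoch set built directly from a matrix-valued field (bypasses the
# cleaning chain; for spectral/interpolation unit tests).
epochs_from_field <- function(values_fn, montage = site_montage(1),
                              n_epochs = 2, slen = 300, rate = 300,
                              state = "PreMF") {
  labs <- montage$channel_labels
  arr <- array(0, c(n_epochs, length(labs), slen),
               dimnames = list(NULL, labs, NULL))
  for (e in seq_len(n_epochs)) arr[e, , ] <- values_fn(e, labs, slen)
  structure(list(data = arr, channels = labs, rate = rate, epoch_length = slen / rate,
                 retained_index = seq_len(n_epochs), state = state,
                 participant = "P01", site = 1), class = "epoch_set")
}

# Study-conditions effect cohort run (delta = 0.3, n = 10, fast profile),
# shared by the effect-recovery and validation acceptance tests.
effect_run <- function() memo("effect_run", {
  cohort <- simulate_cohort(10, delta = 0.3, seed = 7)
  mf_run(cohort, mf_config("fast", seed = 7))
})

# Pre/Post z-scored feature matrices of one delta = 0.5 participant for
# classifier tests with a real planted effect.
planted_features <- function() memo("planted_feats", {
  coh <- simulate_cohort(1, delta = 0.5, seed = 13, site_assignment = 1,
                         durations = c(TaskRest1 = 60, PreMF = 60,
                                       PostMF = 60, TaskRest2 = 60))
  prepare_features(coh[[1]], mini_config())$normalized
})
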
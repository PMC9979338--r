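# Synthetic resting-state EEG generator.
#
# Each channel is a sum of band-limited Gaussian oscillations (white noise
# masked to the band in the Fourier domain, so within-band spectra are flat
# rather than line spectra) plus 1/f pink background noise.  Per-state band
# gains encode the experiment's structure: a mild monotone drift across the
# session plus, at Post-MF, an alpha increase and beta decrease of
# log-amplitude delta.  Everything is seeded and reproducible.

.GEN_BANDS <- list(theta = c(4, 7), alpha = c(8, 12), beta = c(16, 30))

# Baseline per-band RMS amplitudes (µV), realistic for awake eyes-open rest.
.BASE_AMP <- c(theta = 3, alpha = 4, beta = 2)
.PINK_AMP_DEFAULT <- 5

# Fixed per-label topography multipliers: alpha dominant occipitally, beta
# frontally.  These make channel selection learnable and testable.
.topo_weight <- function(label, band) {
  if (band == "alpha" && label %in% c("O1", "O2", "Oz")) return(1.5)
  if (band == "beta"  && label %in% c("F3", "F4", "F7", "F8")) return(1.3)
  1
}

#' State profile for the simulator
#'
#' Duration and per-band linear amplitude multipliers of one resting state.
#' Default durations follow the task battery: TaskRest1 lasts 2 minutes,
#' the other three states 1 minute each.
#'
#' @param state resting-state label.
#' @param duration duration in seconds (default by state).
#' @param band_gains named numeric vector of linear amplitude multipliers
#'   for `theta`, `alpha`, `beta` (all > 0; they multiply the baseline
#'   amplitudes).
#' @return an object of class `state_profile`.
#' @export
state_profile <- function(state = c("TaskRest1", "PreMF", "PostMF", "TaskRest2"),
                          duration = NULL,
                          band_gains = c(theta = 1, alpha = 1, beta = 1)) {
  state <- match.arg(state)
  if (is.null(duration))
    duration <- if (state == "TaskRest1") 120 else 60
  if (duration <= 0) stop("duration must be positive")
  unknown <- setdiff(names(band_gains), names(.GEN_BANDS))
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  if (any(band_gains < 0)) stop("band gains must be non-negative")
  gains <- c(theta = 1, alpha = 1, beta = 1)
  gains[names(band_gains)] <- band_gains
  structure(list(state = state, duration = duration, band_gains = gains),
            class = "state_profile")
}

# Band-limited unit-RMS Gaussian noise via Fourier masking with 1-Hz
# raised-cosine edges; deterministic given the current RNG state.
.band_noise <- function(n, fs, lo, hi, edge = 1) {
  w <- stats::rnorm(n)
  f <- pmin(seq(0, fs, length.out = n + 1)[1:n],
            fs - seq(0, fs, length.out = n + 1)[1:n])
  mask <- rep(0, n)
  mask[f >= lo & f <= hi] <- 1
  ramp_lo <- f >= lo - edge & f < lo
  mask[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f[ramp_lo]) / edge))
  ramp_hi <- f > hi & f <= hi + edge
  mask[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi) / edge))
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# Unit-RMS pink noise (power spectral density proportional to 1/f).
.pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  f <- pmin(seq(0, fs, length.out = n + 1)[1:n],
            fs - seq(0, fs, length.out = n + 1)[1:n])
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Simulate one resting-state recording
#'
#' Generates `duration * sampling_rate` samples per montage channel as a
#' sum of band-limited oscillations and pink noise.  Output is linear in
#' the band gains: with an identical seed, doubling a gain exactly doubles
#' that band's waveform (quadrupling its power).
#'
#' @param montage a [montage_spec()].
#' @param profile a [state_profile()].
#' @param participant_gains named per-band linear multipliers modelling
#'   between-participant variability (default all 1).
#' @param seed integer seed.
#' @param pink_amplitude RMS amplitude (µV) of the 1/f background
#'   (0 disables it).
#' @param participant,site provenance labels for the returned recording.
#' @return an [rs_recording()].
#' @export
simulate_recording <- function(montage, profile,
                               participant_gains = c(theta = 1, alpha = 1, beta = 1),
                               seed = 1, pink_amplitude = .PINK_AMP_DEFAULT,
                               participant = "P01", site = 1) {
  stopifnot(inherits(montage, "montage_spec"), inherits(profile, "state_profile"))
  unknown <- setdiff(names(participant_gains), names(.GEN_BANDS))
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  fs <- montage$sampling_rate
  n <- round(profile$duration * fs)
  labs <- montage$channel_labels
  pg <- c(theta = 1, alpha = 1, beta = 1)
  pg[names(participant_gains)] <- participant_gains
  with_seed(seed, {
    X <- matrix(0, nrow = length(labs), ncol = n)
    for (ci in seq_along(labs)) {
      acc <- numeric(n)
      for (b in names(.GEN_BANDS)) {
        # noise is always drawn so the draw sequence (and hence the
        # waveform for fixed seed) does not depend on the gain values
        osc <- .band_noise(n, fs, .GEN_BANDS[[b]][1], .GEN_BANDS[[b]][2])
        amp <- .BASE_AMP[[b]] * pg[[b]] * profile$band_gains[[b]] *
          .topo_weight(labs[ci], b)
        acc <- acc + amp * osc
      }
      pink <- .pink_noise(n, fs)
      acc <- acc + pink_amplitude * pink
      X[ci, ] <- acc
    }
    rs_recording(X, montage, state = profile$state,
                 participant = participant, site = site)
  })
}

#' Simulate a cohort with the four-rest-state structure
#'
#' Produces `n` participants, each with recordings for TaskRest1, Pre-MF,
#' Post-MF and TaskRest2 in task order.  Per-band baseline gains vary
#' between participants (log-normal, sd `between_sd`).  All bands drift
#' upward by `drift` log-units per no-meditation transition; at Post-MF the
#' alpha gain is additionally multiplied by `exp(delta)` and the beta gain
#' by `exp(-delta)`.  At TaskRest2 half of the meditation effect is
#' retained on top of the drift, giving the partial rebound seen in the
#' band-power trajectories the simulator emulates.
#'
#' @param n_participants number of participants (>= 1).
#' @param delta log-amplitude effect size of the meditation contrast
#'   (>= 0; 0 gives the null cohort).
#' @param between_sd between-participant sd of log band gains.
#' @param drift per-transition log-gain drift applied to all bands.
#' @param retention fraction of the meditation effect still present at
#'   TaskRest2.
#' @param site_assignment integer vector (1/2) per participant; default
#'   alternates the two site presets.
#' @param durations named durations in seconds for the four states.
#' @param seed integer seed; fixed seed implies identical cohorts.
#' @param pink_amplitude background-noise RMS amplitude (µV).
#' @return a list of class `rs_cohort`; each element has `id`, `site`,
#'   `gains` and `recordings` (a named list of four [rs_recording()]s).
#' @export
simulate_cohort <- function(n_participants, delta = 0, between_sd = 0.1,
                            drift = 0.05, retention = 0.5,
                            site_assignment = NULL,
                            durations = c(TaskRest1 = 120, PreMF = 60,
                                          PostMF = 60, TaskRest2 = 60),
                            seed = 1, pink_amplitude = .PINK_AMP_DEFAULT) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (delta < 0) stop("delta must be >= 0")
  if (is.null(site_assignment))
    site_assignment <- rep_len(c(1, 2), n_participants)
  if (length(site_assignment) != n_participants)
    stop("site_assignment must have one entry per participant")
  states <- c("TaskRest1", "PreMF", "PostMF", "TaskRest2")
  # per-state log-gain offsets for (theta, alpha, beta)
  offs <- list(
    TaskRest1 = c(0, 0, 0),
    PreMF     = c(drift, drift, drift),
    PostMF    = c(2 * drift, 2 * drift + delta, 2 * drift - delta),
    TaskRest2 = c(3 * drift, 3 * drift + retention * delta,
                  3 * drift - retention * delta))
  base_gains <- with_seed(subseed(seed, 17), {
    matrix(exp(stats::rnorm(3 * n_participants, 0, between_sd)),
           nrow = n_participants, dimnames = list(NULL, c("theta", "alpha", "beta")))
  })
  cohort <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    id <- sprintf("P%02d", i)
    site <- site_assignment[i]
    montage <- site_montage(site)
    recs <- list()
    for (s in states) {
      gains <- base_gains[i, ] * exp(offs[[s]])
      prof <- state_profile(s, duration = durations[[s]],
                            band_gains = c(theta = 1, alpha = 1, beta = 1))
      recs[[s]] <- simulate_recording(
        montage, prof, participant_gains = gains,
        seed = subseed(seed, i, match(s, states)),
        pink_amplitude = pink_amplitude, participant = id, site = site)
    }
    cohort[[i]] <- list(id = id, site = site, gains = base_gains[i, ],
                        recordings = recs)
  }
  structure(cohort, class = "rs_cohort",
            config = list(n_participants = n_participants, delta = delta,
                          between_sd = between_sd, drift = drift,
                          retention = retention, seed = seed,
                          durations = durations,
                          pink_amplitude = pink_amplitude))
}

#' @export
print.rs_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<rs_cohort> ", length(x), " participants, delta = ", cfg$delta,
      ", seed = ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Inject artifacts into a recording
#'
#' Superimposes test artifacts on a copy of the recording: a flat
#' (zeroed) channel interval, a high-amplitude burst across chosen
#' channels, or an additive 50/60 Hz line-noise sinusoid.
#'
#' @param rec an [rs_recording()].
#' @param artifacts list of artifact descriptors.  Each is a list with
#'   `type` in `"flat_channel"`, `"burst"`, `"line_noise"` plus:
#'   `channels` (labels), `start`/`duration` (seconds) and, for bursts,
#'   `factor` (amplitude multiplier) or, for line noise, `freq`
#'   (50 or 60) and `amplitude` (µV).
#' @return a modified copy of `rec`.
#' @export
inject_artifacts <- function(rec, artifacts = list()) {
  stopifnot(inherits(rec, "rs_recording"))
  if (!length(artifacts)) return(rec)
  fs <- rec$montage$sampling_rate
  n <- ncol(rec$samples)
  X <- rec$samples
  for (a in artifacts) {
    type <- match.arg(a$type, c("flat_channel", "burst", "line_noise"))
    chans <- a$channels
    bad <- setdiff(chans, rownames(X))
    if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
    start <- if (is.null(a$start)) 0 else a$start
    dur <- if (is.null(a$duration)) n / fs - start else a$duration
    i0 <- floor(start * fs) + 1
    i1 <- floor((start + dur) * fs)
    if (i0 < 1 || i1 > n || i0 > i1)
      stop("artifact interval [", start, ", ", start + dur,
           "] s outside recording")
    idx <- i0:i1
    if (type == "flat_channel") {
      X[chans, idx] <- 0
    } else if (type == "burst") {
      fac <- if (is.null(a$factor)) 50 else a$factor
      X[chans, idx] <- X[chans, idx] * fac
    } else {
      freq <- if (is.null(a$freq)) 60 else a$freq
      if (!freq %in% c(50, 60)) stop("line_noise freq must be 50 or 60")
      amp <- if (is.null(a$amplitude)) 20 else a$amplitude
      tt <- (idx - 1) / fs
      X[chans, idx] <- sweep(X[chans, idx, drop = FALSE], 2,
                             amp * sin(2 * pi * freq * tt), "+")
    }
  }
  rec$samples <- X
  rec
}
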
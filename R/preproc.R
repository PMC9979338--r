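# Cleaning chain from raw recording to 1-s epochs:
# resample -> Kaiser FIR band-pass -> bad-channel detection -> subspace
# reconstruction -> segment rejection -> A1/A2 re-reference -> epoching ->
# spherical-spline interpolation of the removed channels.

#' Resample a recording
#'
#' Anti-aliased rate conversion in the Fourier domain: the spectrum is
#' truncated at the new Nyquist frequency and inverted at the new length,
#' which is exact for band-limited finite recordings.  Only downsampling
#' (or the identity) is supported.
#'
#' @param rec an [rs_recording()].
#' @param target_rate target sampling rate in Hz (<= current rate).
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_rate = 300) {
  stopifnot(inherits(rec, "rs_recording"))
  fs <- rec$montage$sampling_rate
  if (target_rate > fs) stop("upsampling not supported (target ", target_rate,
                             " > ", fs, " Hz)")
  if (target_rate == fs) return(rec)
  n <- ncol(rec$samples)
  m <- round(n * target_rate / fs)
  X <- rec$samples
  Y <- matrix(0, nrow(X), m)
  half <- ceiling(m / 2) - 1          # positive-frequency bins to keep
  for (ci in seq_len(nrow(X))) {
    Fx <- stats::fft(X[ci, ])
    Fy <- complex(m)
    Fy[1] <- Fx[1]
    if (half > 0) {
      Fy[2:(half + 1)] <- Fx[2:(half + 1)]
      Fy[m:(m - half + 1)] <- Fx[n:(n - half + 1)]
    }
    if (m %% 2 == 0) Fy[m / 2 + 1] <- Re(Fx[m / 2 + 1])
    Y[ci, ] <- Re(stats::fft(Fy, inverse = TRUE)) / n
  }
  mon <- rec$montage
  mon$sampling_rate <- target_rate
  rs_recording(Y, mon, state = rec$state, participant = rec$participant,
               site = rec$site)
}

# Kaiser FIR band-pass design for a 60 dB stopband and 1 Hz transition
# width; returns the (odd-length, symmetric) tap vector.
.design_kaiser_bandpass <- function(fs, lo, hi, atten = 60, trans = 1) {
  beta <- 0.1102 * (atten - 8.7)
  dw <- 2 * pi * trans / fs
  ord <- ceiling((atten - 7.95) / (2.285 * dw))
  if (ord %% 2 == 1) ord <- ord + 1      # even order -> integer group delay
  signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass",
               window = signal::kaiser(ord + 1, beta))
}

#' Zero-phase Kaiser band-pass filter
#'
#' Linear-phase FIR band-pass (Kaiser window, 60 dB stopband attenuation,
#' 1 Hz transition width) applied with group-delay compensation, so the
#' output is zero-phase.
#'
#' @param rec an [rs_recording()].
#' @param lo,hi cut-off frequencies in Hz (default 1 and 30).
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 30) {
  stopifnot(inherits(rec, "rs_recording"))
  fs <- rec$montage$sampling_rate
  if (!(lo < hi)) stop("lo must be < hi")
  if (hi >= fs / 2) stop("hi (", hi, " Hz) must be below Nyquist (", fs / 2, " Hz)")
  b <- .design_kaiser_bandpass(fs, lo, hi)
  gd <- (length(b) - 1) / 2
  n <- ncol(rec$samples)
  X <- rec$samples
  for (ci in seq_len(nrow(X))) {
    y <- signal::fftfilt(b, c(X[ci, ], numeric(gd)))
    X[ci, ] <- y[(gd + 1):(gd + n)]
  }
  rec$samples <- X
  rec
}

#' Detect bad channels
#'
#' Flags a channel if (a) it has any contiguous interval of at least
#' `flat_window` seconds whose peak-to-peak amplitude is below
#' `flat_floor` µV, or (b) its line-noise ratio (power within ±2.5 Hz of
#' 50 or 60 Hz divided by total power) is more than `line_sd` standard
#' deviations above the across-channel mean.
#'
#' @param rec an [rs_recording()] of at least `flat_window` seconds.
#' @param flat_floor peak-to-peak floor in µV for the "no signal" rule.
#' @param flat_window length of the flat interval in seconds.
#' @param line_sd z-score threshold of the line-noise rule.
#' @param line_freqs mains frequencies checked (Hz).
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_floor = 1e-6, flat_window = 5,
                                line_sd = 4, line_freqs = c(50, 60)) {
  stopifnot(inherits(rec, "rs_recording"))
  fs <- rec$montage$sampling_rate
  n <- ncol(rec$samples)
  if (n / fs < flat_window)
    stop("recording shorter than the ", flat_window, " s flat-channel window")
  labs <- rownames(rec$samples)
  bad <- character(0)

  # (a) flat intervals, scanned on a 0.25-s block grid
  blk <- max(1L, round(0.25 * fs))
  nblk <- floor(n / blk)
  wlen <- ceiling(flat_window * fs / blk)
  for (ci in seq_along(labs)) {
    x <- rec$samples[ci, seq_len(nblk * blk)]
    dim(x) <- c(blk, nblk)
    bmin <- apply(x, 2, min); bmax <- apply(x, 2, max)
    for (s in seq_len(nblk - wlen + 1)) {
      idx <- s:(s + wlen - 1)
      if (max(bmax[idx]) - min(bmin[idx]) < flat_floor) {
        bad <- c(bad, labs[ci]); break
      }
    }
  }

  # (b) line-noise ratio z-scored across channels
  if (length(labs) >= 3) {
    ratios <- sapply(line_freqs, function(f0) {
      apply(rec$samples, 1, function(x) {
        p <- welch_psd(x, fs, seg_seconds = 1)
        in_band <- p$freq >= f0 - 2.5 & p$freq <= f0 + 2.5
        if (!any(in_band)) return(NA_real_)
        tot <- sum(p$psd)
        if (tot <= 0) return(0) else sum(p$psd[in_band]) / tot
      })
    })
    for (j in seq_len(ncol(ratios))) {
      r <- ratios[, j]
      if (anyNA(r)) next
      s <- stats::sd(r)
      if (s > 0) bad <- c(bad, labs[(r - mean(r)) / s > line_sd])
    }
  }
  unique(bad)
}

#' Subspace-reconstruction cleaning
#'
#' A simplified artifact subspace reconstruction: calibration statistics
#' are taken from the cleanest `calib_frac` of fixed-length windows (by
#' total RMS); each window is decomposed onto the calibration principal
#' components, components whose standard deviation exceeds `cutoff` times
#' the calibration component standard deviation are zeroed, and the window
#' is reconstructed.  Artifact-free data passes through unchanged.
#'
#' @param rec an [rs_recording()] of at least `min_calib` seconds.
#' @param window window length in seconds.
#' @param cutoff rejection multiple of the calibration component sd.
#' @param calib_frac fraction of windows (lowest RMS) used for calibration.
#' @param min_calib minimum recording length in seconds.
#' @return the cleaned recording; attribute `"asr_rejections"` counts
#'   zeroed components per window.
#' @export
asr_clean <- function(rec, window = 0.5, cutoff = 30, calib_frac = 0.5,
                      min_calib = 30) {
  stopifnot(inherits(rec, "rs_recording"))
  fs <- rec$montage$sampling_rate
  n <- ncol(rec$samples)
  if (n / fs < min_calib)
    stop("need at least ", min_calib, " s of data for ASR calibration")
  wlen <- round(window * fs)
  nw <- floor(n / wlen)
  X <- rec$samples
  wrms <- sapply(seq_len(nw), function(w)
    sqrt(mean(X[, ((w - 1) * wlen + 1):(w * wlen)]^2)))
  ncal <- max(2L, ceiling(calib_frac * nw))
  calib_w <- order(wrms)[seq_len(ncal)]
  calib_idx <- unlist(lapply(calib_w, function(w) ((w - 1) * wlen + 1):(w * wlen)))
  C <- X[, calib_idx, drop = FALSE]
  ctr <- rowMeans(C)
  C <- C - ctr
  sd_floor <- 1e-12 * max(stats::sd(as.vector(C)), 1e-300)
  rejections <- integer(nw)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    Xw <- X[, idx, drop = FALSE] - ctr
    # principal components of this window; compare each component's sd
    # against the calibration data projected onto the same direction.
    # Iterate: zeroing the dominant artifact components can leave a mixed
    # direction just under threshold, caught on re-decomposition.
    for (pass in 1:5) {
      eg <- eigen(Xw %*% t(Xw) / ncol(Xw), symmetric = TRUE)
      V <- eg$vectors
      comp_sd <- sqrt(pmax(eg$values, 0))
      calib_sd <- apply(t(V) %*% C, 1, stats::sd)
      kill <- comp_sd > cutoff * pmax(calib_sd, sd_floor)
      if (!any(kill)) break
      rejections[w] <- rejections[w] + sum(kill)
      S <- t(V) %*% Xw
      S[kill, ] <- 0
      Xw <- V %*% S
      X[, idx] <- Xw + ctr
    }
  }
  rec$samples <- X
  attr(rec, "asr_rejections") <- rejections
  rec
}

#' Reject high-power segments
#'
#' Splits the recording into fixed-length windows and removes any window
#' whose log-power is more than `z_thresh` robust standard deviations
#' (median/MAD across windows, per channel) above typical power in at
#' least a quarter (ceiling) of the channels.  Remaining windows are
#' concatenated.
#'
#' @param rec an [rs_recording()].
#' @param window window length in seconds.
#' @param z_thresh robust z-score threshold.
#' @param channel_frac fraction of channels that must exceed the threshold.
#' @return the pruned recording; attribute `"kept_intervals"` is a
#'   data.frame of retained `[start, end)` intervals (seconds) and
#'   `"rejected_windows"` the dropped window indices.
#' @export
reject_bad_segments <- function(rec, window = 1, z_thresh = 20,
                                channel_frac = 0.25) {
  stopifnot(inherits(rec, "rs_recording"))
  fs <- rec$montage$sampling_rate
  wlen <- round(window * fs)
  nw <- floor(ncol(rec$samples) / wlen)
  if (nw < 1) stop("recording shorter than one rejection window")
  nch <- nrow(rec$samples)
  lp <- matrix(0, nch, nw)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    lp[, w] <- log(rowMeans(rec$samples[, idx, drop = FALSE]^2) + 1e-300)
  }
  med <- apply(lp, 1, stats::median)
  s <- pmax(apply(lp, 1, stats::mad), 1e-12)
  z <- (lp - med) / s
  need <- ceiling(channel_frac * nch)
  drop_w <- which(colSums(z > z_thresh) >= need)
  if (length(drop_w) == nw)
    stop("all segments rejected; recording unusable")
  keep_w <- setdiff(seq_len(nw), drop_w)
  keep_idx <- unlist(lapply(keep_w, function(w) ((w - 1) * wlen + 1):(w * wlen)))
  tail_idx <- if (nw * wlen < ncol(rec$samples))
    (nw * wlen + 1):ncol(rec$samples) else integer(0)
  rec$samples <- rec$samples[, c(keep_idx, tail_idx), drop = FALSE]
  attr(rec, "kept_intervals") <- data.frame(
    start = (keep_w - 1) * window, end = keep_w * window)
  attr(rec, "rejected_windows") <- drop_w
  rec
}

#' Re-reference to linked ears
#'
#' Subtracts the mean of channels A1 and A2 from every channel.  If either
#' ear channel is absent (or listed in `exclude`), falls back to the
#' common average reference with a warning.
#'
#' @param rec an [rs_recording()].
#' @param exclude channels (e.g. detected-bad ones) not usable as reference.
#' @return the re-referenced recording.
#' @export
rereference <- function(rec, exclude = character(0)) {
  stopifnot(inherits(rec, "rs_recording"))
  labs <- rownames(rec$samples)
  ears <- setdiff(intersect(c("A1", "A2"), labs), exclude)
  if (length(ears) == 2) {
    ref <- colMeans(rec$samples[ears, , drop = FALSE])
  } else {
    warning("A1/A2 unavailable; falling back to common average reference")
    ref <- colMeans(rec$samples[setdiff(labs, exclude), , drop = FALSE])
  }
  rec$samples <- sweep(rec$samples, 2, ref)
  rec
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping consecutive epochs (default 1 s); a trailing partial
#' epoch is discarded.
#'
#' @param rec an [rs_recording()].
#' @param epoch_length epoch length in seconds.
#' @return an object of class `epoch_set` with fields `data` (an epochs x
#'   channels x samples array), `channels`, `rate`, `epoch_length`,
#'   `retained_index`, `state`, `participant`, `site`.
#' @export
epoch_recording <- function(rec, epoch_length = 1) {
  stopifnot(inherits(rec, "rs_recording"))
  fs <- rec$montage$sampling_rate
  slen <- round(epoch_length * fs)
  nep <- floor(ncol(rec$samples) / slen)
  if (nep < 1) stop("recording shorter than one epoch (", epoch_length, " s)")
  arr <- array(0, dim = c(nep, nrow(rec$samples), slen),
               dimnames = list(NULL, rownames(rec$samples), NULL))
  for (e in seq_len(nep))
    arr[e, , ] <- rec$samples[, ((e - 1) * slen + 1):(e * slen)]
  structure(list(data = arr, channels = rownames(rec$samples), rate = fs,
                 epoch_length = epoch_length, retained_index = seq_len(nep),
                 state = rec$state, participant = rec$participant,
                 site = rec$site),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " epochs x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples (", x$state, ", ",
      x$participant, ")\n", sep = "")
  invisible(x)
}

# Legendre polynomials P_1..P_L evaluated at x (vector), via recursion.
.legendre_upto <- function(x, L) {
  P <- matrix(0, length(x), L)
  P[, 1] <- x
  if (L >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (L >= 3) for (l in 3:L)
    P[, l] <- ((2 * l - 1) * x * P[, l - 1] - (l - 1) * P[, l - 2]) / l
  P
}

# Spherical-spline kernel g(cos angle) of Perrin et al., order m, L terms.
.spline_g <- function(cosang, m = 4, L = 7) {
  P <- .legendre_upto(pmin(pmax(cosang, -1), 1), L)
  l <- seq_len(L)
  w <- (2 * l + 1) / (l^m * (l + 1)^m)
  as.vector(P %*% w) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the signals of the given channels, in every epoch, with
#' spherical-spline estimates (spline order m = 4, 7 Legendre terms,
#' ridge regularization 1e-5) computed from the remaining channels at
#' their standard unit-sphere 10-20 positions.
#'
#' @param epochs an `epoch_set`.
#' @param bad channel labels to interpolate (subset of the montage).
#' @param m spline order.
#' @param terms number of Legendre terms.
#' @param lambda ridge regularization added to the spline system.
#' @return the `epoch_set` with interpolated channels.
#' @export
interpolate_channels <- function(epochs, bad, m = 4, terms = 7, lambda = 1e-5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!length(bad)) return(epochs)
  labs <- epochs$channels
  if (!all(bad %in% labs)) stop("bad channels not in montage")
  good <- setdiff(labs, bad)
  if (length(good) < 4) stop("need at least 4 good channels to interpolate")
  pos <- electrode_positions(labs)
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bad, , drop = FALSE]
  Ggg <- matrix(.spline_g(tcrossprod(pg), m, terms), length(good))
  Gbg <- matrix(.spline_g(pb %*% t(pg), m, terms), length(bad))
  A <- rbind(cbind(Ggg + diag(lambda, length(good)), 1),
             c(rep(1, length(good)), 0))
  nep <- dim(epochs$data)[1]; slen <- dim(epochs$data)[3]
  gi <- match(good, labs); bi <- match(bad, labs)
  for (e in seq_len(nep)) {
    Y <- rbind(epochs$data[e, gi, , drop = TRUE], 0)
    if (length(good) == 1) dim(Y) <- c(2, slen)
    sol <- solve(A, Y)
    C <- sol[seq_along(good), , drop = FALSE]
    c0 <- sol[length(good) + 1, ]
    epochs$data[e, bi, ] <- Gbg %*% C + rep(c0, each = length(bad))
  }
  epochs
}

#' Run the full cleaning chain
#'
#' Applies, in fixed order: resampling to `target_rate`, zero-phase Kaiser
#' band-pass, bad-channel detection, subspace reconstruction and segment
#' rejection on the good channels, A1/A2 re-referencing, 1-s epoching and
#' spherical-spline interpolation of the detected-bad channels.  Every
#' rejection is logged with its rule and threshold.
#'
#' @param rec an [rs_recording()].
#' @param target_rate common analysis rate in Hz.
#' @param lo,hi band-pass cut-offs in Hz.
#' @param epoch_length epoch length in seconds.
#' @param flat_floor,flat_window,line_sd bad-channel rule parameters
#'   (see [detect_bad_channels()]).
#' @param asr_cutoff component-rejection multiple (see [asr_clean()]).
#' @param seg_z,seg_frac segment-rejection parameters
#'   (see [reject_bad_segments()]).
#' @param pc_kurtosis_max optional kurtosis threshold for an additional
#'   principal-component rejection pass; `NULL` (default) disables it.
#' @return a list with `epochs` (an `epoch_set`), `bad_channels` and `log`
#'   (a data.frame of actions).
#' @export
preprocess_recording <- function(rec, target_rate = 300, lo = 1, hi = 30,
                                 epoch_length = 1, flat_floor = 1e-6,
                                 flat_window = 5, line_sd = 4,
                                 asr_cutoff = 30, seg_z = 20, seg_frac = 0.25,
                                 pc_kurtosis_max = NULL) {
  log <- data.frame(stage = character(0), detail = character(0),
                    threshold = character(0))
  note <- function(stage, detail, threshold = "") {
    log <<- rbind(log, data.frame(stage = stage, detail = detail,
                                  threshold = as.character(threshold)))
  }
  rec <- resample_recording(rec, target_rate)
  note("resample", paste0("rate=", target_rate, " Hz"))
  rec <- bandpass_filter(rec, lo, hi)
  note("bandpass", paste0("[", lo, ", ", hi, "] Hz"))
  bad <- detect_bad_channels(rec, flat_floor = flat_floor,
                             flat_window = flat_window, line_sd = line_sd)
  if (length(bad))
    note("bad_channels", paste(bad, collapse = ","),
         paste0("flat<", flat_floor, "uV/", flat_window, "s or line z>", line_sd))
  good <- setdiff(rownames(rec$samples), bad)
  sub <- rec
  sub$samples <- rec$samples[good, , drop = FALSE]
  sub$montage <- structure(list(channel_labels = good,
                                reference_labels = rec$montage$reference_labels,
                                sampling_rate = rec$montage$sampling_rate),
                           class = "montage_spec")
  sub <- asr_clean(sub, cutoff = asr_cutoff)
  nrej <- sum(attr(sub, "asr_rejections"))
  if (nrej > 0) note("asr", paste0(nrej, " components zeroed"),
                     paste0("sd>", asr_cutoff, "x calibration"))
  sub <- reject_bad_segments(sub, z_thresh = seg_z, channel_frac = seg_frac)
  dropped <- attr(sub, "rejected_windows")
  if (length(dropped))
    note("segment_rejection", paste0("windows ", paste(dropped, collapse = ",")),
         paste0("log-power z>", seg_z, " in >=", seg_frac, " of channels"))
  if (!is.null(pc_kurtosis_max)) {
    sub <- .reject_kurtotic_components(sub, pc_kurtosis_max, note)
  }
  sub <- rereference(sub, exclude = character(0))
  note("rereference", if (all(c("A1", "A2") %in% rownames(sub$samples)))
    "A1/A2 mean" else "common average")
  eps <- epoch_recording(sub, epoch_length)
  note("epoch", paste0(dim(eps$data)[1], " epochs of ", epoch_length, " s"))
  if (length(bad)) {
    # reinsert removed channels as zeros on the montage grid, then
    # reconstruct them from the cleaned good channels
    full <- array(0, dim = c(dim(eps$data)[1], length(rownames(rec$samples)),
                             dim(eps$data)[3]),
                  dimnames = list(NULL, rownames(rec$samples), NULL))
    full[, good, ] <- eps$data
    eps$data <- full
    eps$channels <- rownames(rec$samples)
    eps <- interpolate_channels(eps, bad)
    note("interpolate", paste(bad, collapse = ","), "spherical spline m=4")
  }
  list(epochs = eps, bad_channels = bad, log = log)
}

# Optional extra pass: zero principal components with excess kurtosis
# above the threshold (a rough stand-in for classifier-based IC pruning;
# off by default).
.reject_kurtotic_components <- function(rec, kmax, note) {
  X <- rec$samples - rowMeans(rec$samples)
  eg <- eigen(X %*% t(X) / ncol(X), symmetric = TRUE)
  S <- t(eg$vectors) %*% X
  ku <- apply(S, 1, function(s) mean((s - mean(s))^4) / stats::var(s)^2 - 3)
  kill <- which(ku > kmax)
  if (length(kill)) {
    S[kill, ] <- 0
    rec$samples <- eg$vectors %*% S + rowMeans(rec$samples)
    note("pc_kurtosis", paste0(length(kill), " components zeroed"),
         paste0("kurtosis>", kmax))
  }
  rec
}
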
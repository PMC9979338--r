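# Welch spectral estimation and the seven per-channel band-power features.

.BANDS <- list(Theta = c(4, 7), Alpha = c(8, 12), Beta = c(16, 30),
               Total = c(4, 30))

.FEATURE_NAMES <- c("TotalPower", "TotalTheta", "TotalAlpha", "TotalBeta",
                    "RelTheta", "RelAlpha", "RelBeta")

#' Spectral band definitions
#'
#' Theta 4-7 Hz, Alpha 8-12 Hz, Beta 16-30 Hz and the Total 4-30 Hz range.
#' The 7-8 and 12-16 Hz gaps belong to Total only.
#'
#' @return named list of `c(lo, hi)` pairs in Hz.
#' @export
band_definitions <- function() .BANDS

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hamming-windowed segments and 50%
#' overlap, one-sided density scaling: the integral of the PSD over
#' frequency approximates the signal variance (Parseval, up to window
#' bias).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param seg_seconds segment length in seconds (default 0.5, giving three
#'   segments on a 1-s epoch).
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz, 0..Nyquist) and `psd` (µV²/Hz).
#' @export
welch_psd <- function(x, fs, seg_seconds = 0.5, overlap = 0.5) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  nseg <- min(n, round(seg_seconds * fs))
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = hop)
  w <- signal::hamming(nseg)
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    P <- Mod(stats::fft(seg))^2 * scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nseg even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nseg, psd = psd * dbl)
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the PSD over the bins whose centre frequency
#' lies in `[lo, hi]`, both ends inclusive.
#'
#' @param psd a list with `freq` and `psd`, as from [welch_psd()].
#' @param band numeric `c(lo, hi)` in Hz, or a band name from
#'   [band_definitions()].
#' @return band power in µV².
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) {
    if (!band %in% names(.BANDS)) stop("unknown band: ", band)
    band <- .BANDS[[band]]
  }
  if (band[1] > max(psd$freq) || band[2] < min(psd$freq))
    stop("band outside the frequency grid")
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  if (length(sel) == 0) stop("no PSD bins inside band")
  if (length(sel) == 1) {
    df <- if (length(psd$freq) > 1) psd$freq[2] - psd$freq[1] else 1
    return(psd$psd[sel] * df)
  }
  sum(diff(psd$freq[sel]) * (head(psd$psd[sel], -1) + psd$psd[sel][-1]) / 2)
}

#' Extract the seven spectral features per channel and epoch
#'
#' For every epoch and feature channel: total 4-30 Hz power, absolute
#' theta/alpha/beta band powers, and relative theta/alpha/beta powers
#' (band divided by the 4-30 Hz total).  Columns are channel-major:
#' 19 channels x 7 features = 133 columns.
#'
#' @param epochs an `epoch_set` containing the 19 feature channels.
#' @param channels channels to use (default [feature_channels()]).
#' @return an object of class `feature_table`: list with `values`
#'   (epochs x 133 matrix), `channels`, `features`, `state` (per-epoch
#'   labels), `participant`, `site`.
#' @export
extract_features <- function(epochs, channels = feature_channels()) {
  stopifnot(inherits(epochs, "epoch_set"))
  missing <- setdiff(channels, epochs$channels)
  if (length(missing))
    stop("epochs lack feature channels: ", paste(missing, collapse = ", "))
  nep <- dim(epochs$data)[1]
  vals <- matrix(0, nep, length(channels) * length(.FEATURE_NAMES))
  colnames(vals) <- as.vector(outer(.FEATURE_NAMES, channels,
                                    function(f, ch) paste(ch, f, sep = ".")))
  warned <- FALSE
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    for (e in seq_len(nep)) {
      p <- welch_psd(epochs$data[e, ch, ], epochs$rate)
      tot <- band_power(p, "Total")
      th <- band_power(p, "Theta")
      al <- band_power(p, "Alpha")
      be <- band_power(p, "Beta")
      if (tot > 0) {
        rel <- c(th, al, be) / tot
      } else {
        rel <- c(0, 0, 0)
        if (!warned) {
          warning("zero total power in at least one epoch; relative powers set to 0")
          warned <- TRUE
        }
      }
      vals[e, (ci - 1) * 7 + 1:7] <- c(tot, th, al, be, rel)
    }
  }
  structure(list(values = vals, channels = channels,
                 features = .FEATURE_NAMES,
                 state = rep(epochs$state, nep),
                 participant = epochs$participant, site = epochs$site),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " epochs x ", ncol(x$values),
      " columns (", length(x$channels), " channels x ", length(x$features),
      " features), participant ", x$participant, "\n", sep = "")
  cat("  states: ", paste(names(table(x$state)), table(x$state),
                          sep = ":", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Combine feature tables from several states of one participant
#'
#' Row-binds feature tables sharing channels/features (e.g. the four
#' resting states of a participant), keeping per-epoch state labels.
#'
#' @param ... `feature_table` objects or a single list of them.
#' @return a combined `feature_table`.
#' @export
combine_features <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && !inherits(tabs[[1]], "feature_table"))
    tabs <- tabs[[1]]
  stopifnot(all(vapply(tabs, inherits, TRUE, "feature_table")))
  base <- tabs[[1]]
  for (t in tabs[-1]) {
    if (!identical(t$channels, base$channels))
      stop("feature tables have different channels")
  }
  structure(list(values = do.call(rbind, lapply(tabs, `[[`, "values")),
                 channels = base$channels, features = base$features,
                 state = unlist(lapply(tabs, `[[`, "state")),
                 participant = base$participant, site = base$site),
            class = "feature_table")
}

#' Z-score normalize a feature table
#'
#' Per participant, every column is centred and scaled to unit standard
#' deviation across all pooled epochs (all states together).  Columns with
#' zero variance are set to 0 with a warning.
#'
#' @param table a `feature_table` with at least 2 epochs.
#' @return the normalized `feature_table`.
#' @export
zscore_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2) stop("need at least 2 epochs to normalize")
  mu <- colMeans(table$values)
  sdv <- apply(table$values, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) set to 0")
    sdv[zero] <- 1
  }
  vals <- sweep(sweep(table$values, 2, mu), 2, sdv, "/")
  vals[, zero] <- 0
  table$values <- vals
  table
}

#' Serialize a feature table to CSV
#'
#' One row per epoch; first columns are participant, site and state,
#' followed by the labelled feature columns.
#'
#' @param table a `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(table, path) {
  df <- data.frame(participant = table$participant, site = table$site,
                   state = table$state, table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
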
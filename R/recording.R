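# The resting-state recording container and its plain-text serialization.

#' Resting-state recording container
#'
#' A continuous multichannel EEG segment with its montage, resting-state
#' label and provenance.  `samples` is a channels x time matrix in
#' microvolts with row names equal to the montage channel labels.
#'
#' @param samples channels x time numeric matrix (µV).
#' @param montage a [montage_spec()].
#' @param state one of `"TaskRest1"`, `"PreMF"`, `"PostMF"`, `"TaskRest2"`.
#' @param participant participant identifier.
#' @param site site identifier (1 or 2).
#' @return an object of class `rs_recording`.
#' @export
rs_recording <- function(samples, montage, state = "PreMF",
                         participant = "P01", site = 1) {
  if (!inherits(montage, "montage_spec")) stop("montage must be a montage_spec")
  samples <- as.matrix(samples)
  if (nrow(samples) != length(montage$channel_labels))
    stop("samples row count must equal montage channel count")
  if (anyNA(samples)) stop("recording contains missing values")
  rownames(samples) <- montage$channel_labels
  state <- match.arg(state, c("TaskRest1", "PreMF", "PostMF", "TaskRest2"))
  structure(list(samples = samples, montage = montage, state = state,
                 participant = participant, site = site),
            class = "rs_recording")
}

#' @export
print.rs_recording <- function(x, ...) {
  cat("<rs_recording> ", x$state, ", participant ", x$participant,
      " (site ", x$site, ")\n", sep = "")
  cat("  ", nrow(x$samples), " channels x ", ncol(x$samples), " samples @ ",
      x$montage$sampling_rate, " Hz (",
      round(ncol(x$samples) / x$montage$sampling_rate, 2), " s)\n", sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `rs_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$montage$sampling_rate

#' Read and write recordings as plain text
#'
#' A simple self-describing tab-separated container: a `#key value` header
#' (state, participant, site, sampling rate, reference labels) followed by
#' one column per channel, one row per sample.  Loss is limited to the
#' 15-significant-digit text representation.
#'
#' @param rec an `rs_recording`.
#' @param path file path.
#' @return `read_recording` returns an `rs_recording`;
#'   `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("#state", rec$state),
    paste("#participant", rec$participant),
    paste("#site", rec$site),
    paste("#sampling_rate", format(rec$montage$sampling_rate, digits = 15)),
    paste("#reference", paste(rec$montage$reference_labels, collapse = ",")),
    paste(rownames(rec$samples), collapse = "\t")), con)
  utils::write.table(format(t(rec$samples), digits = 15, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), " ", fixed = TRUE))
  meta <- setNames(kv[, 2], kv[, 1])
  labels <- strsplit(lines[length(hdr) + 1], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(path, sep = "\t", skip = length(hdr) + 1)
  m <- montage_spec(labels,
                    reference_labels = strsplit(meta[["reference"]], ",")[[1]],
                    sampling_rate = as.numeric(meta[["sampling_rate"]]))
  rs_recording(t(as.matrix(dat)), m, state = meta[["state"]],
               participant = meta[["participant"]],
               site = as.integer(meta[["site"]]))
}

# Seeded evaluation helper: runs expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Deterministic small sub-seed derivation, kept well below 2^31.
subseed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed %% 1000003L)
  for (x in k) s <- (s * 69069 + as.double(x)) %% 2147483647
  as.integer(s)
}
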
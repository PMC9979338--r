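# Montage definitions: 10-20 channel sets for the two recording sites,
# the 19 feature channels, brain-region groupings, and unit-sphere
# electrode positions (standard 10-20/10-10 coordinates) used by the
# spherical-spline interpolation.

# The 19 channels on which spectral features are computed.  The site-1 dry
# headset records these plus the A1/A2 ear references.  Pz doubles as the
# site-1 hardware reference but is retained in the feature list.
.FEATURE_CHANNELS <- c(
  "P3", "C3", "F3", "Fz", "F4", "C4", "P4", "Cz", "Fp1", "Fp2",
  "T3", "T5", "O1", "O2", "F7", "F8", "T6", "T4", "Pz"
)

# Brain regions used for the regional rank-sum comparisons.
.REGION_MAP <- list(
  frontal    = c("F3", "F4", "F7", "F8"),
  midline    = c("Cz", "Pz", "Fz"),
  prefrontal = c("Fp1", "Fp2"),
  parietal   = c("P3", "P4"),
  occipital  = c("O1", "O2"),
  temporal   = c("T3", "T4", "T5", "T6"),
  central    = c("C3", "C4")
)

# Unit-sphere electrode positions (x toward right ear, y toward nasion,
# z up), standard 10-20/10-10 montage.  Older temporal names map onto the
# modern ones (T3=T7, T4=T8, T5=P7, T6=P8).
.ELECTRODE_XYZ <- matrix(c(
  -0.329991,  0.940726, -0.078359,   # Fp1
   0.330899,  0.940402, -0.078426,   # Fp2
   0.001272,  0.999811, -0.019408,   # Fpz
  -0.847627,  0.512395, -0.137767,   # F7
  -0.595220,  0.629189,  0.499834,   # F3
   0.003526,  0.660786,  0.750566,   # Fz
   0.606623,  0.635512,  0.477633,   # F4
   0.846108,  0.514567, -0.139004,   # F8
  -0.314606,  0.651404,  0.690432,   # F1
   0.335604,  0.654987,  0.677025,   # F2
  -0.375357,  0.286639,  0.881445,   # FC1
   0.386023,  0.293400,  0.874587,   # FC2
  -0.976571, -0.185874, -0.108447,   # T3 (T7)
  -0.706876, -0.125802,  0.696060,   # C3
  -0.371708, -0.102635,  0.922659,   # C1
   0.003983, -0.091066,  0.995837,   # Cz
   0.390044, -0.099645,  0.915389,   # C2
   0.720988, -0.117092,  0.682983,   # C4
   0.978884, -0.172815, -0.109187,   # T4 (T8)
  -0.326425, -0.434692,  0.839339,   # CP1
   0.351645, -0.431251,  0.830884,   # CP2
   0.003504, -0.429705,  0.902963,   # CPz
  -0.701950, -0.711819, -0.024101,   # T5 (P7)
  -0.480960, -0.714878,  0.507570,   # P3
  -0.251075, -0.706414,  0.661771,   # P1
   0.002804, -0.700597,  0.713552,   # Pz
   0.275926, -0.695760,  0.663161,   # P2
   0.498504, -0.703519,  0.506513,   # P4
   0.706832, -0.706954, -0.024575,   # T6 (P8)
  -0.252329, -0.964666,  0.075827,   # O1
   0.000929, -0.991960,  0.126546,   # Oz
   0.256398, -0.963610,  0.075607,   # O2
  -0.765138, -0.222136, -0.604334,   # A1
   0.763880, -0.222674, -0.605725    # A2
), ncol = 3, byrow = TRUE,
  dimnames = list(c("Fp1", "Fp2", "Fpz", "F7", "F3", "Fz", "F4", "F8",
                    "F1", "F2", "FC1", "FC2", "T3", "C3", "C1", "Cz",
                    "C2", "C4", "T4", "CP1", "CP2", "CPz", "T5", "P3",
                    "P1", "Pz", "P2", "P4", "T6", "O1", "Oz", "O2",
                    "A1", "A2"), c("x", "y", "z")))

#' Montage specification
#'
#' Describes the channel set, reference labels and sampling rate of a
#' recording setup.  Two presets mirror the study sites: site 1 is a
#' 21-channel dry headset sampled at 300 Hz, site 2 a 32-channel cap
#' sampled at 500 Hz.  Both contain the 19 feature channels and the A1/A2
#' ear channels.
#'
#' @param channel_labels character vector of unique 10-20 labels.
#' @param reference_labels labels used for re-referencing (default A1, A2).
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `montage_spec`.
#' @examples
#' m <- site_montage(1)
#' m$sampling_rate  # 300
#' @export
montage_spec <- function(channel_labels, reference_labels = c("A1", "A2"),
                         sampling_rate) {
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels))
    stop("montage channel labels must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  missing_feat <- setdiff(.FEATURE_CHANNELS, channel_labels)
  if (length(missing_feat))
    stop("montage lacks feature channels: ", paste(missing_feat, collapse = ", "))
  structure(list(channel_labels = channel_labels,
                 reference_labels = as.character(reference_labels),
                 sampling_rate = sampling_rate),
            class = "montage_spec")
}

#' @rdname montage_spec
#' @param site 1 or 2, selecting the study-site preset.
#' @export
site_montage <- function(site = 1) {
  if (site == 1) {
    montage_spec(
      channel_labels = c("P3", "C3", "F3", "Fz", "F4", "C4", "P4", "Cz",
                         "A1", "Fp1", "Fp2", "T3", "T5", "O1", "O2",
                         "F7", "F8", "A2", "T6", "T4", "Pz"),
      sampling_rate = 300)
  } else if (site == 2) {
    montage_spec(
      channel_labels = c(.FEATURE_CHANNELS, "A1", "A2", "Fpz", "Oz",
                         "F1", "F2", "FC1", "FC2", "C1", "C2",
                         "CP1", "CP2", "CPz"),
      sampling_rate = 500)
  } else stop("site must be 1 or 2")
}

#' Feature channels, brain regions and electrode positions
#'
#' `feature_channels()` returns the 19 channels on which spectral features
#' are computed; `region_map()` the seven brain-region channel groupings;
#' `electrode_positions()` unit-sphere coordinates for a set of labels.
#'
#' @return see description.
#' @export
feature_channels <- function() .FEATURE_CHANNELS

#' @rdname feature_channels
#' @export
region_map <- function() .REGION_MAP

#' @rdname feature_channels
#' @param labels channel labels to look up.
#' @export
electrode_positions <- function(labels) {
  unknown <- setdiff(labels, rownames(.ELECTRODE_XYZ))
  if (length(unknown))
    stop("no electrode coordinates for: ", paste(unknown, collapse = ", "))
  .ELECTRODE_XYZ[labels, , drop = FALSE]
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", length(x$channel_labels), " channels @ ",
      x$sampling_rate, " Hz\n", sep = "")
  cat("  channels: ", paste(x$channel_labels, collapse = " "), "\n", sep = "")
  cat("  reference: ", paste(x$reference_labels, collapse = " "), "\n", sep = "")
  invisible(x)
}
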
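#' @import methods
NULL

.CHANNEL_ROLES <- c("EEG", "EKG", "OTHER")
.EVENT_KINDS <- c("volume_trigger", "stimulus", "response", "other")

.emptyEvents <- function() {
  data.frame(sample = integer(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' Multichannel electrophysiological recording
#'
#' Container for a continuous EEG(+EKG) recording: a channels-by-samples
#' matrix in microvolts, a sampling rate, per-channel roles, and event
#' markers. Sample indices are 1-based throughout the package; the time of
#' sample \code{i} is \code{(i - 1) / fs} seconds.
#'
#' @slot data numeric matrix, channels in rows, samples in columns, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector of channel labels.
#' @slot channelRoles character vector, each one of \code{"EEG"},
#'   \code{"EKG"}, \code{"OTHER"}.
#' @slot events data.frame with integer column \code{sample} (1-based) and
#'   character column \code{kind} (one of \code{"volume_trigger"},
#'   \code{"stimulus"}, \code{"response"}, \code{"other"}).
#' @exportClass Recording
setClass("Recording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelNames = "character",
    channelRoles = "character",
    events = "data.frame"
  )
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  nch <- nrow(object@data)
  if (length(object@channelNames) != nch)
    msg <- c(msg, "channelNames length must equal nrow(data)")
  if (length(object@channelRoles) != nch)
    msg <- c(msg, "channelRoles length must equal nrow(data)")
  if (!all(object@channelRoles %in% .CHANNEL_ROLES))
    msg <- c(msg, "channelRoles must be EEG, EKG or OTHER")
  ev <- object@events
  if (!all(c("sample", "kind") %in% names(ev))) {
    msg <- c(msg, "events must have columns 'sample' and 'kind'")
  } else if (nrow(ev) > 0) {
    if (any(ev$sample < 1L) || any(ev$sample > ncol(object@data)))
      msg <- c(msg, "event samples must lie in [1, n_samples]")
    if (!all(ev$kind %in% .EVENT_KINDS))
      msg <- c(msg, "event kinds must be volume_trigger/stimulus/response/other")
  }
  if (length(msg)) msg else TRUE
})

#' QRS complex annotations
#'
#' R-peak sample indices (1-based, at the recording's processing rate)
#' defining cardiac cycles. With K peaks there are \code{K - 1} complete
#' cycles; cycle m spans samples \code{[peaks[m], peaks[m + 1])}.
#'
#' @slot peaks strictly increasing integer vector of R-peak sample indices.
#' @slot fs sampling rate in Hz of the timeline the peaks refer to.
#' @exportClass QRSAnnotations
setClass("QRSAnnotations",
  representation(peaks = "integer", fs = "numeric")
)

setValidity("QRSAnnotations", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  p <- object@peaks
  if (length(p) > 1 && any(diff(p) <= 0))
    msg <- c(msg, "peaks must be strictly increasing")
  if (length(p) > 0 && any(p < 1L))
    msg <- c(msg, "peaks must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ballistocardiogram artifact estimate
#'
#' The modeled BCG artifact for each EEG channel, aligned sample-for-sample
#' with the recording it was estimated from. Samples without cardiac
#' coordinates (before the first or after the last detected R peak), or with
#' no usable neighbor cycles, carry a zero estimate and coverage FALSE.
#'
#' @slot data numeric matrix [n EEG channels x n samples], microvolts.
#' @slot coverage logical vector of length n samples.
#' @slot channelNames labels of the EEG channels the rows correspond to.
#' @exportClass ArtifactEstimate
setClass("ArtifactEstimate",
  representation(data = "matrix", coverage = "logical",
                 channelNames = "character")
)

setValidity("ArtifactEstimate", function(object) {
  msg <- character(0)
  if (length(object@coverage) != ncol(object@data))
    msg <- c(msg, "coverage length must equal ncol(data)")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames length must equal nrow(data)")
  if (ncol(object@data) > 0 && any(object@data[, !object@coverage] != 0))
    msg <- c(msg, "estimate must be exactly 0 where coverage is FALSE")
  if (length(msg)) msg else TRUE
})

#' Stimulus-locked epochs
#'
#' Trials extracted around stimulus onsets, linearly detrended, with
#' amplitude-based rejection flags. Rejected trials are kept in storage and
#' flagged \code{kept = FALSE}.
#'
#' @slot data numeric array [n trials x n channels x n times], microvolts.
#' @slot tmin,tmax epoch window in seconds relative to stimulus onset.
#' @slot fs sampling rate in Hz.
#' @slot kept logical per-trial flag (FALSE = rejected).
#' @slot channelNames channel labels.
#' @slot channelRoles channel roles (rejection considers EEG channels only).
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", tmin = "numeric", tmax = "numeric",
                 fs = "numeric", kept = "logical",
                 channelNames = "character", channelRoles = "character")
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array [trials x channels x times]")
  else {
    nt <- round((object@tmax - object@tmin) * object@fs) + 1L
    if (d[3] != nt)
      msg <- c(msg, sprintf("n_times must be %d for the given window/fs", nt))
    if (length(object@kept) != d[1])
      msg <- c(msg, "kept length must equal number of trials")
    if (length(object@channelNames) != d[2])
      msg <- c(msg, "channelNames length must equal number of channels")
  }
  if (length(msg)) msg else TRUE
})

#' Time-frequency representation
#'
#' Power of complex Morlet wavelet coefficients of the trial-averaged evoked
#' response.
#'
#' @slot power numeric array [n channels x n freqs x n times], >= 0.
#' @slot freqs frequencies in Hz.
#' @slot times times in seconds relative to stimulus onset.
#' @slot nCycles wavelet cycles (sigma_t = nCycles / (2 pi f)).
#' @slot baseline baseline window in seconds, c(start, end).
#' @slot channelNames channel labels.
#' @exportClass TFR
setClass("TFR",
  representation(power = "array", freqs = "numeric", times = "numeric",
                 nCycles = "numeric", baseline = "numeric",
                 channelNames = "character")
)

setValidity("TFR", function(object) {
  msg <- character(0)
  d <- dim(object@power)
  if (length(d) != 3L)
    msg <- c(msg, "power must be [channels x freqs x times]")
  else {
    if (d[2] != length(object@freqs)) msg <- c(msg, "freqs length mismatch")
    if (d[3] != length(object@times)) msg <- c(msg, "times length mismatch")
    if (d[1] != length(object@channelNames))
      msg <- c(msg, "channelNames length mismatch")
  }
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})
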
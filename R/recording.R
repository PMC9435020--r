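#' Construct a Recording
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolts).
#' @param fs sampling rate in Hz.
#' @param channelNames character vector of labels; defaults to Ch1..ChN.
#' @param channelRoles per-channel role in EEG/EKG/OTHER; by default channels
#'   whose name matches \code{ekgPattern} are EKG and the rest EEG.
#' @param events data.frame with columns \code{sample} (1-based integer) and
#'   \code{kind}.
#' @param ekgPattern case-insensitive regular expression used to tag EKG
#'   channels when \code{channelRoles} is NULL.
#' @return A \linkS4class{Recording}.
#' @export
Recording <- function(data, fs, channelNames = NULL, channelRoles = NULL,
                      events = NULL, ekgPattern = "^(EKG|ECG)") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelNames))
    channelNames <- paste0("Ch", seq_len(nrow(data)))
  if (is.null(channelRoles)) {
    channelRoles <- ifelse(grepl(ekgPattern, channelNames, ignore.case = TRUE),
                           "EKG", "EEG")
  }
  if (is.null(events)) events <- .emptyEvents()
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) == 0) events <- .emptyEvents()
  events$sample <- as.integer(events$sample)
  events$kind <- as.character(events$kind)
  new("Recording", data = data, fs = as.numeric(fs),
      channelNames = as.character(channelNames),
      channelRoles = as.character(channelRoles),
      events = events[, c("sample", "kind")])
}

#' @rdname Recording
#' @param object,x a Recording.
#' @export
setGeneric("recData", function(x) standardGeneric("recData"))

#' @rdname Recording
#' @export
setMethod("recData", "Recording", function(x) x@data)

#' @rdname Recording
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @rdname Recording
#' @export
setMethod("samplingRate", "QRSAnnotations", function(x) x@fs)

#' @rdname Recording
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname Recording
#' @export
setMethod("channelNames", "Recording", function(x) x@channelNames)

#' @rdname Recording
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname Recording
#' @export
setMethod("channelRoles", "Recording", function(x) x@channelRoles)

#' @rdname Recording
#' @export
setGeneric("recEvents", function(x) standardGeneric("recEvents"))

#' @rdname Recording
#' @export
setMethod("recEvents", "Recording", function(x) x@events)

#' @rdname Recording
#' @export
nChannels <- function(x) nrow(x@data)

#' @rdname Recording
#' @export
nSamples <- function(x) ncol(x@data)

#' Indices of channels by role
#' @param x a Recording.
#' @param role one of "EEG", "EKG", "OTHER".
#' @return integer vector of channel indices.
#' @export
channelsByRole <- function(x, role) which(x@channelRoles == role)

#' The single EKG channel of a recording
#'
#' @param x a Recording.
#' @return numeric vector of the EKG channel, or an error when no EKG channel
#'   is tagged; when several are tagged the first is used with a warning.
#' @export
ekgChannel <- function(x) {
  idx <- channelsByRole(x, "EKG")
  if (length(idx) == 0)
    stop("recording has no channel tagged EKG")
  if (length(idx) > 1) {
    warning("multiple EKG channels tagged; using the first (",
            x@channelNames[idx[1]], ")")
    idx <- idx[1]
  }
  x@data[idx, ]
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  tab <- table(factor(object@channelRoles, levels = .CHANNEL_ROLES))
  cat(sprintf("  roles: %d EEG, %d EKG, %d OTHER\n",
              tab[["EEG"]], tab[["EKG"]], tab[["OTHER"]]))
  if (nrow(object@events))
    cat("  events:",
        paste(sprintf("%s(%d)", names(table(object@events$kind)),
                      as.integer(table(object@events$kind))), collapse = ", "),
        "\n")
  else cat("  events: none\n")
})

#' Construct QRS annotations
#' @param peaks strictly increasing vector of R-peak sample indices (1-based).
#' @param fs sampling rate in Hz.
#' @return A \linkS4class{QRSAnnotations}.
#' @export
QRSAnnotations <- function(peaks, fs) {
  new("QRSAnnotations", peaks = as.integer(round(peaks)), fs = as.numeric(fs))
}

#' @rdname QRSAnnotations
#' @param x a QRSAnnotations.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname QRSAnnotations
#' @export
setMethod("peaks", "QRSAnnotations", function(x) x@peaks)

#' RR intervals in samples
#' @param x a QRSAnnotations.
#' @return integer vector of successive R-peak differences (samples).
#' @export
rrIntervals <- function(x) diff(x@peaks)

#' Number of complete cardiac cycles
#' @param x a QRSAnnotations.
#' @export
nCycles <- function(x) max(0L, length(x@peaks) - 1L)

setMethod("show", "QRSAnnotations", function(object) {
  k <- length(object@peaks)
  cat(sprintf("QRSAnnotations: %d R peaks (%d complete cycles) @ %g Hz\n",
              k, max(0L, k - 1L), object@fs))
  if (k > 1) {
    rr <- diff(object@peaks) / object@fs
    cat(sprintf("  RR: mean %.3f s, sd %.3f s, HR %.1f bpm\n",
                mean(rr), stats::sd(rr), 60 / mean(rr)))
  }
})

setMethod("show", "ArtifactEstimate", function(object) {
  cat(sprintf("ArtifactEstimate: %d channels x %d samples, coverage %.1f%%\n",
              nrow(object@data), ncol(object@data),
              100 * mean(object@coverage)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d trials (%d kept) x %d channels x %d times [%g, %g] s @ %g Hz\n",
    d[1], sum(object@kept), d[2], d[3], object@tmin, object@tmax, object@fs))
})

setMethod("show", "TFR", function(object) {
  d <- dim(object@power)
  cat(sprintf("TFR: %d channels x %d freqs (%g-%g Hz) x %d times, %g cycles\n",
              d[1], d[2], min(object@freqs), max(object@freqs), d[3],
              object@nCycles))
})

#' Coverage mask of an artifact estimate
#' @param x an ArtifactEstimate.
#' @export
coverageMask <- function(x) x@coverage

#' Fraction of samples with a usable artifact estimate
#' @param x an ArtifactEstimate.
#' @export
coverageFraction <- function(x) mean(x@coverage)
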
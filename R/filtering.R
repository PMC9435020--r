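#' Band-pass filter specification
#'
#' @param lowHz,highHz passband edges in Hz; must satisfy
#'   0 < lowHz < highHz < fs/2 for the recording being filtered.
#' @param zeroPhase apply the filter forward-backward (zero group delay).
#' @param order Butterworth order of the single-pass filter (the effective
#'   order doubles when zeroPhase is TRUE).
#' @return list of class "FilterSpec".
#' @export
filterSpec <- function(lowHz = 1, highHz = 50, zeroPhase = TRUE, order = 4) {
  stopifnot(lowHz > 0, highHz > lowHz, order >= 1)
  structure(list(lowHz = lowHz, highHz = highHz, zeroPhase = zeroPhase,
                 order = order), class = "FilterSpec")
}

.filtfiltMat <- function(data, filt) {
  t(apply(data, 1L, function(x) signal::filtfilt(filt, x)))
}

#' Zero-phase band-pass filter a recording
#'
#' All channels are filtered with a Butterworth band-pass applied
#' forward-backward, so the group delay is zero by construction and events
#' keep their sample indices.
#'
#' @param rec a \linkS4class{Recording}.
#' @param spec a \code{\link{filterSpec}}.
#' @return the filtered Recording (events, names, roles, fs unchanged).
#' @export
bandpass <- function(rec, spec = filterSpec()) {
  stopifnot(is(rec, "Recording"), inherits(spec, "FilterSpec"))
  nyq <- rec@fs / 2
  if (spec$highHz >= nyq)
    stop(sprintf("passband edge %g Hz violates Nyquist (%g Hz)",
                 spec$highHz, nyq))
  bf <- signal::butter(spec$order, c(spec$lowHz, spec$highHz) / nyq,
                       type = "pass")
  out <- rec
  if (spec$zeroPhase) {
    out@data <- .filtfiltMat(rec@data, bf)
  } else {
    out@data <- t(apply(rec@data, 1L, function(x) signal::filter(bf, x)))
  }
  dimnames(out@data) <- dimnames(rec@data)
  out
}

#' Resample a recording to a lower rate
#'
#' An anti-alias zero-phase Butterworth low-pass at 0.45 * targetFs is
#' applied (skipped when the data are already band-limited well below the new
#' Nyquist, i.e. when \code{antiAlias = FALSE}), then channels are read off at
#' the new time grid by linear interpolation. Event indices are rescaled by
#' targetFs/fs and rounded half away from zero.
#'
#' @param rec a \linkS4class{Recording}.
#' @param targetFs new sampling rate in Hz, <= samplingRate(rec).
#' @param antiAlias apply the internal anti-alias low-pass (default TRUE).
#' @return the resampled Recording.
#' @export
resampleRecording <- function(rec, targetFs, antiAlias = TRUE) {
  stopifnot(is(rec, "Recording"))
  if (!is.numeric(targetFs) || length(targetFs) != 1L || targetFs <= 0)
    stop("targetFs must be a single positive number")
  if (targetFs > rec@fs)
    stop("targetFs must not exceed the current sampling rate")
  if (targetFs == rec@fs) return(rec)
  n <- ncol(rec@data)
  data <- rec@data
  if (antiAlias) {
    bf <- signal::butter(4, (0.45 * targetFs) / (rec@fs / 2), type = "low")
    data <- .filtfiltMat(data, bf)
  }
  ratio <- targetFs / rec@fs
  nNew <- as.integer(round(n * ratio))
  tOld <- (seq_len(n) - 1) / rec@fs
  tNew <- (seq_len(nNew) - 1) / targetFs
  out <- matrix(0, nrow(data), nNew)
  for (ch in seq_len(nrow(data)))
    out[ch, ] <- stats::approx(tOld, data[ch, ], xout = tNew, rule = 2)$y
  rownames(out) <- rownames(rec@data)
  ev <- rec@events
  if (nrow(ev)) {
    # 1-based index i at time (i-1)/fs maps to round((i-1)*ratio) + 1,
    # rounding half away from zero
    ev$sample <- as.integer(.roundHalfAway((ev$sample - 1) * ratio) + 1L)
    ev$sample <- pmin(pmax(ev$sample, 1L), nNew)
  }
  res <- rec
  res@data <- out
  res@fs <- targetFs
  res@events <- ev
  res
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
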
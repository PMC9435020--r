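#' Detect QRS complexes (R peaks) in an EKG trace
#'
#' A Pan-Tompkins style detector: zero-phase 5-15 Hz band-pass, five-point
#' derivative, squaring, 150-ms moving-window integration, adaptive
#' signal/noise thresholds with a 200-ms refractory period, T-wave
#' discrimination by slope within 360 ms, and search-back at 1.66x the
#' running mean RR. Each detection is refined to the local extremum of the
#' absolute band-passed EKG within +/- 50 ms, so detection is insensitive to
#' the polarity and any constant offset of the input.
#'
#' @param ekg numeric vector, single EKG channel (microvolts), or a
#'   \linkS4class{Recording} from which the EKG channel is taken.
#' @param fs sampling rate in Hz (>= 100); ignored when \code{ekg} is a
#'   Recording.
#' @param refractory_s minimum RR interval in seconds (default 0.2).
#' @return a \linkS4class{QRSAnnotations}.
#' @export
detectQRS <- function(ekg, fs = NULL, refractory_s = 0.2) {
  if (is(ekg, "Recording")) {
    fs <- samplingRate(ekg)
    ekg <- ekgChannel(ekg)
  }
  stopifnot(is.numeric(ekg))
  if (is.null(fs) || fs < 100)
    stop("fs must be given and >= 100 Hz")
  if (length(ekg) < 2 * fs)
    stop("need at least 2 s of EKG data")
  if (all(!is.finite(ekg)) || stats::sd(ekg[is.finite(ekg)]) == 0) {
    warning("flat or non-finite EKG; no QRS detected")
    return(QRSAnnotations(integer(0), fs))
  }
  ekg[!is.finite(ekg)] <- 0
  ekg <- ekg - mean(ekg)

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, ekg)
  # five-point derivative (Pan-Tompkins), then squaring
  pad <- c(bp[1], bp[1], bp, bp[length(bp)], bp[length(bp)])
  n <- length(bp)
  der <- (2 * pad[5:(n + 4)] + pad[4:(n + 3)] -
            pad[2:(n + 1)] - 2 * pad[1:n]) / 8
  sq <- der^2
  win <- max(1L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / win, win), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate fiducial marks: local maxima of the integrated signal
  isPeak <- c(FALSE, mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                mwi[2:(n - 1)] >= mwi[3:n], FALSE)
  cand <- which(isPeak)
  if (!length(cand)) {
    warning("no candidate peaks in EKG")
    return(QRSAnnotations(integer(0), fs))
  }

  refr <- round(refractory_s * fs)
  twave <- round(0.360 * fs)
  # initialize thresholds from the first 2 s
  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  qrsSlope <- numeric(0)
  rrBuf <- numeric(0)
  lastQrs <- -Inf

  maxSlope <- function(i) {
    lo <- max(1L, i - round(0.075 * fs)); hi <- min(n, i + round(0.075 * fs))
    max(abs(der[lo:hi]))
  }
  accept <- function(i) {
    qrs <<- c(qrs, i)
    qrsSlope <<- c(qrsSlope, maxSlope(i))
    if (length(qrs) > 1) {
      rrBuf <<- c(rrBuf, i - lastQrs)
      if (length(rrBuf) > 8) rrBuf <<- rrBuf[(length(rrBuf) - 7):length(rrBuf)]
    }
    lastQrs <<- i
    spki <<- 0.125 * mwi[i] + 0.875 * spki
    thr1 <<- npki + 0.25 * (spki - npki)
  }
  for (i in cand) {
    if (mwi[i] > thr1) {
      if (i - lastQrs < refr) {
        # inside refractory: a larger peak supersedes the previous detection
        if (length(qrs) && mwi[i] > mwi[qrs[length(qrs)]]) {
          qrs[length(qrs)] <- i
          qrsSlope[length(qrsSlope)] <- maxSlope(i)
          if (length(rrBuf)) rrBuf[length(rrBuf)] <-
              rrBuf[length(rrBuf)] + (i - lastQrs)
          lastQrs <- i
          spki <- 0.125 * mwi[i] + 0.875 * spki
          thr1 <- npki + 0.25 * (spki - npki)
        }
        next
      }
      isT <- FALSE
      if (is.finite(lastQrs) && i - lastQrs < twave && length(qrsSlope)) {
        # T waves have markedly lower maximal slope than the preceding QRS
        if (maxSlope(i) < 0.5 * qrsSlope[length(qrsSlope)]) isT <- TRUE
      }
      if (isT) {
        npki <- 0.125 * mwi[i] + 0.875 * npki
        thr1 <- npki + 0.25 * (spki - npki)
      } else accept(i)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      thr1 <- npki + 0.25 * (spki - npki)
      # search-back for a missed beat
      if (length(rrBuf) >= 2 && is.finite(lastQrs) &&
          (i - lastQrs) > 1.66 * mean(rrBuf)) {
        sb <- cand[cand > lastQrs + refr & cand < i]
        if (length(sb)) {
          best <- sb[which.max(mwi[sb])]
          if (mwi[best] > 0.5 * thr1) {
            spki <- 0.25 * mwi[best] + 0.75 * spki
            qrs <- c(qrs, best)
            qrsSlope <- c(qrsSlope, maxSlope(best))
            rrBuf <- c(rrBuf, best - lastQrs)
            lastQrs <- best
            thr1 <- npki + 0.25 * (spki - npki)
          }
        }
      }
    }
  }
  if (!length(qrs)) {
    warning("no QRS complexes above threshold")
    return(QRSAnnotations(integer(0), fs))
  }
  # refine to the local extremum of the (demeaned) EKG within +/- 50 ms;
  # the R deflection dominates there whatever its polarity
  half <- round(0.050 * fs)
  refined <- vapply(qrs, function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(abs(ekg[lo:hi])) - 1)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement (keep the larger peak)
  keep <- rep(TRUE, length(refined))
  j <- 1L
  for (k in seq_along(refined)[-1]) {
    if (refined[k] - refined[j] < refr) {
      if (abs(ekg[refined[k]]) > abs(ekg[refined[j]])) { keep[j] <- FALSE; j <- k }
      else keep[k] <- FALSE
    } else j <- k
  }
  QRSAnnotations(refined[keep], fs)
}
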
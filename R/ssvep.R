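#' Extract, detrend and clean stimulus-locked epochs
#'
#' EEG is cut from \code{tmin} to \code{tmax} seconds around each stimulus
#' onset. Per trial and channel, the best-fit line (intercept plus slope over
#' the whole epoch) is subtracted; trials whose post-detrend absolute maximum
#' across EEG channels exceeds \code{rejectUv} are flagged
#' \code{kept = FALSE} (they stay in storage).
#'
#' @param rec a \linkS4class{Recording}.
#' @param onsets stimulus onset samples; default the recording's
#'   \code{stimulus} events.
#' @param tmin,tmax epoch window in seconds (defaults -0.2, +1.0).
#' @param rejectUv rejection threshold in microvolts (default 700).
#' @return an \linkS4class{EpochSet}.
#' @export
epochAndClean <- function(rec, onsets = NULL, tmin = -0.2, tmax = 1.0,
                          rejectUv = 700) {
  stopifnot(is(rec, "Recording"), tmax > tmin)
  fs <- samplingRate(rec)
  if (is.null(onsets))
    onsets <- rec@events$sample[rec@events$kind == "stimulus"]
  if (!length(onsets)) stop("no stimulus events to epoch around")
  i0 <- round(tmin * fs)
  nT <- round((tmax - tmin) * fs) + 1L
  lo <- onsets + i0
  ok <- lo >= 1 & lo + nT - 1L <= nSamples(rec)
  if (!all(ok)) {
    warning(sum(!ok), " stimulus window(s) fall outside the recording; dropped")
    onsets <- onsets[ok]; lo <- lo[ok]
    if (!length(onsets)) stop("no stimulus window fits inside the recording")
  }
  nTr <- length(onsets)
  nCh <- nChannels(rec)
  data <- array(0, c(nTr, nCh, nT))
  x <- seq_len(nT) - (nT + 1) / 2           # centered time index
  sxx <- sum(x^2)
  for (tr in seq_len(nTr)) {
    seg <- rec@data[, lo[tr]:(lo[tr] + nT - 1L), drop = FALSE]
    mu <- rowMeans(seg)
    slope <- (seg %*% x) / sxx
    data[tr, , ] <- seg - outer(slope[, 1], x) - mu
  }
  eeg <- channelRoles(rec) == "EEG"
  mx <- apply(abs(data[, eeg, , drop = FALSE]), 1, max)
  new("EpochSet", data = data, tmin = tmin, tmax = tmax, fs = fs,
      kept = mx <= rejectUv, channelNames = channelNames(rec),
      channelRoles = channelRoles(rec))
}

# complex Morlet wavelet, L2-normalized, sigma_t = nCycles / (2 pi f)
.morletKernel <- function(f, fs, nCycles) {
  sigma <- nCycles / (2 * pi * f)
  half <- ceiling(5 * sigma * fs)
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t)
  k / sqrt(sum(Mod(k)^2))
}

.convSame <- function(x, k) {
  n <- length(x); m <- length(k)
  N <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  K <- stats::fft(c(k, rep(0+0i, N - m)))
  full <- stats::fft(X * K, inverse = TRUE) / N
  full[((m - 1L) %/% 2L) + seq_len(n)]
}

#' Morlet time-frequency representation of the evoked response
#'
#' Kept trials are averaged first (the evoked response), then each channel is
#' convolved with complex Morlet wavelets (\code{nCycles} cycles,
#' L2-normalized); power is the squared coefficient magnitude. Set
#' \code{perTrial = TRUE} to average single-trial power instead.
#'
#' @param ep an \linkS4class{EpochSet} with >= 1 kept trial.
#' @param freqs frequencies in Hz (all below Nyquist).
#' @param nCycles wavelet cycles (default 5).
#' @param baseline baseline window in seconds (default c(tmin, 0)).
#' @param perTrial average power over trials instead of transforming the
#'   trial average (default FALSE).
#' @return a \linkS4class{TFR}.
#' @export
morletTFR <- function(ep, freqs, nCycles = 5, baseline = NULL,
                      perTrial = FALSE) {
  stopifnot(is(ep, "EpochSet"))
  if (any(freqs >= ep@fs / 2))
    stop("frequencies must be below the Nyquist rate ", ep@fs / 2, " Hz")
  if (!any(ep@kept)) stop("no kept trials")
  if (is.null(baseline)) baseline <- c(ep@tmin, 0)
  nCh <- dim(ep@data)[2]; nT <- dim(ep@data)[3]
  times <- ep@tmin + (seq_len(nT) - 1) / ep@fs
  pow <- array(0, c(nCh, length(freqs), nT))
  kernels <- lapply(freqs, .morletKernel, fs = ep@fs, nCycles = nCycles)
  if (perTrial) {
    for (tr in which(ep@kept))
      for (ch in seq_len(nCh))
        for (fi in seq_along(freqs))
          pow[ch, fi, ] <- pow[ch, fi, ] +
            Mod(.convSame(ep@data[tr, ch, ], kernels[[fi]]))^2
    pow <- pow / sum(ep@kept)
  } else {
    evoked <- apply(ep@data[ep@kept, , , drop = FALSE], c(2, 3), mean)
    for (ch in seq_len(nCh))
      for (fi in seq_along(freqs))
        pow[ch, fi, ] <- Mod(.convSame(evoked[ch, ], kernels[[fi]]))^2
  }
  new("TFR", power = pow, freqs = as.numeric(freqs), times = times,
      nCycles = nCycles, baseline = as.numeric(baseline),
      channelNames = ep@channelNames)
}

#' Mean oscillatory power at one frequency over a window and channel set
#'
#' The standard SSVEP readout: mean TFR power at \code{freqHz} (15 Hz for a
#' 7.5-Hz flashing checkerboard) over the post-stimulus window and the given
#' channels (classically O1, O2, Oz averaged).
#'
#' @param tfr a \linkS4class{TFR}.
#' @param channels channel names or indices (must exist).
#' @param freqHz frequency of interest (must be among \code{tfr@freqs}).
#' @param window time window in seconds, default c(0.2, 1.0).
#' @return scalar mean power.
#' @export
evokedPower <- function(tfr, channels = c("O1", "O2", "Oz"), freqHz = 15,
                        window = c(0.2, 1.0)) {
  stopifnot(is(tfr, "TFR"))
  fi <- which(abs(tfr@freqs - freqHz) < 1e-9)
  if (!length(fi)) stop(freqHz, " Hz is not among the TFR frequencies")
  if (is.character(channels)) {
    ci <- match(channels, tfr@channelNames)
    if (anyNA(ci)) stop("channel(s) not found: ",
                        paste(channels[is.na(ci)], collapse = ", "))
  } else ci <- channels
  ti <- which(tfr@times >= window[1] & tfr@times <= window[2])
  mean(tfr@power[ci, fi[1], ti])
}

#' Noise-normalize a TFR by its pre-stimulus baseline
#'
#' Per channel and frequency, power is divided by the standard deviation of
#' power over the baseline interval, so units become multiples of baseline
#' variability at that frequency.
#'
#' @param tfr a \linkS4class{TFR}.
#' @return the normalized \linkS4class{TFR}.
#' @export
noiseNormalize <- function(tfr) {
  stopifnot(is(tfr, "TFR"))
  bi <- which(tfr@times >= tfr@baseline[1] & tfr@times <= tfr@baseline[2])
  if (length(bi) < 2) stop("baseline window contains fewer than 2 samples")
  out <- tfr
  for (ch in seq_len(dim(tfr@power)[1]))
    for (fi in seq_len(dim(tfr@power)[2])) {
      s <- stats::sd(tfr@power[ch, fi, bi])
      if (s == 0)
        stop("degenerate baseline: zero SD at channel ", ch, ", ",
             tfr@freqs[fi], " Hz")
      out@power[ch, fi, ] <- tfr@power[ch, fi, ] / s
    }
  out
}

#' ROC curve and AUC of a detection statistic against a truth mask
#'
#' Threshold sweep over the unique statistic values (units with statistic >=
#' threshold are called positive); TPR and FPR per threshold plus the
#' endpoints, AUC by the trapezoid rule.
#'
#' @param stat numeric statistic per unit (channel or source).
#' @param truth logical mask per unit; needs >= 1 positive and >= 1 negative.
#' @return list of class "ROCResult": thresholds, tpr, fpr, auc.
#' @export
rocAuc <- function(stat, truth) {
  truth <- as.logical(truth)
  stopifnot(length(stat) == length(truth))
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0 || nN == 0)
    stop("truth mask must contain at least one positive and one negative")
  thr <- sort(unique(stat), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(stat >= th & truth) / nP, numeric(1))
  fpr <- vapply(thr, function(th) sum(stat >= th & !truth) / nN, numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  if (tpr[length(tpr)] < 1 || fpr[length(fpr)] < 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1); thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr, auc = auc),
            class = "ROCResult")
}

#' Bootstrap comparison of two per-subject samples
#'
#' Each group's mean is bootstrap-resampled \code{nBoot} times and a
#' two-sample t-test is applied between the two bootstrap distributions.
#' When the groups have equal length they are treated as the same subjects
#' measured under two methods, and each bootstrap iteration resamples one
#' set of subject indices applied to both groups (so identical inputs give
#' t = 0 exactly); unequal-length groups are resampled independently. The
#' bootstrap draws violate the t-test's independence assumption; the
#' procedure is nevertheless applied exactly in this form, faithful to the
#' evaluation tradition it mirrors. Deterministic given \code{seed}.
#'
#' @param a,b numeric vectors of per-subject scalars (length >= 2).
#' @param nBoot number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @return list with \code{t}, \code{p}, and the two bootstrap mean vectors.
#' @export
bootstrapCompare <- function(a, b, nBoot = 100, seed = 1L) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (nBoot < 2) stop("nBoot must be >= 2")
  set.seed(seed)
  if (length(a) == length(b)) {
    idx <- replicate(nBoot, sample(length(a), replace = TRUE),
                     simplify = FALSE)
    bootA <- vapply(idx, function(i) mean(a[i]), numeric(1))
    bootB <- vapply(idx, function(i) mean(b[i]), numeric(1))
  } else {
    bootA <- replicate(nBoot, mean(sample(a, replace = TRUE)))
    bootB <- replicate(nBoot, mean(sample(b, replace = TRUE)))
  }
  tt <- stats::t.test(bootA, bootB, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, bootA = bootA, bootB = bootB)
}
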
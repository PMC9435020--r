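#' Optimal-basis-set configuration
#'
#' @param n_components PCA order: number of principal components added to the
#'   mean-epoch template (default 3; 0 gives a mean-only basis).
#' @param epoch_pre_s epoch start before the R peak, seconds (default 0.1).
#' @param epoch_len_factor epoch length as a multiple of the median RR
#'   interval (default 1.1).
#' @return validated list of class "OBSConfig".
#' @export
obsConfig <- function(n_components = 3, epoch_pre_s = 0.1,
                      epoch_len_factor = 1.1) {
  stopifnot(n_components >= 0, epoch_pre_s >= 0, epoch_len_factor > 0)
  structure(list(n_components = as.integer(n_components),
                 epoch_pre_s = epoch_pre_s,
                 epoch_len_factor = epoch_len_factor), class = "OBSConfig")
}

#' Average-artifact-subtraction configuration
#'
#' @param window_trs sliding template window in TR epochs (odd, >= 3;
#'   default 7).
#' @param align_accuracies successive subsample alignment accuracies, in
#'   samples (default 0.2, 0.02, 0.002, 0.0002).
#' @return validated list of class "AASConfig".
#' @export
aasConfig <- function(window_trs = 7,
                      align_accuracies = c(0.2, 0.02, 0.002, 0.0002)) {
  if (window_trs %% 2 == 0 || window_trs < 3)
    stop("window_trs must be odd and >= 3")
  stopifnot(all(align_accuracies > 0), !is.unsorted(rev(align_accuracies)))
  structure(list(window_trs = as.integer(window_trs),
                 align_accuracies = align_accuracies), class = "AASConfig")
}

# QRS-locked epoch geometry shared by OBS and the static template method
.qrsEpochs <- function(p, fs, nS, cfg) {
  pre <- round(cfg$epoch_pre_s * fs)
  len <- round(cfg$epoch_len_factor * stats::median(diff(p)))
  starts <- p - pre
  keep <- starts >= 1 & starts + len - 1 <= nS
  list(starts = starts[keep], len = len, pre = pre)
}

# cross-fade weight profile: linear ramps over the typical overlap
.fadeWeights <- function(len, overlap) {
  w <- rep(1, len)
  if (overlap > 0) {
    ramp <- seq_len(min(overlap, len))
    w[ramp] <- ramp / (length(ramp) + 1)
    w[len + 1 - ramp] <- ramp / (length(ramp) + 1)
  }
  w
}

# fix PCA sign: largest-magnitude loading positive
.fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Suppress the BCG artifact with the optimal basis set (OBS) method
#'
#' Fixed-length epochs are extracted around each R peak; after removing the
#' across-epoch mean, a PCA across epochs yields the leading components. The
#' basis (mean epoch plus the first \code{n_components} PCs) is fitted to
#' each epoch by least squares and the fit subtracted. Overlapping corrected
#' windows are blended by a linear cross-fade; samples in no epoch pass
#' through unchanged.
#'
#' @param rec a \linkS4class{Recording}.
#' @param qrs \linkS4class{QRSAnnotations}.
#' @param cfg an \code{\link{obsConfig}}.
#' @return the corrected Recording. The fitted per-epoch artifact is
#'   available as \code{attr(, "artifact")} (a channels x samples matrix for
#'   the EEG channels).
#' @export
obsSuppress <- function(rec, qrs, cfg = obsConfig()) {
  stopifnot(is(rec, "Recording"), is(qrs, "QRSAnnotations"))
  fs <- samplingRate(rec)
  p <- peaks(qrs)
  geo <- .qrsEpochs(p, fs, nSamples(rec), cfg)
  nEp <- length(geo$starts)
  minEp <- 2L * cfg$n_components + 2L
  if (nEp < minEp)
    stop("OBS needs at least ", minEp, " complete cardiac epochs, got ", nEp)
  .fitSubtract(rec, geo, nPC = cfg$n_components, fitBasis = TRUE)
}

#' Static QRS-locked average-template subtraction
#'
#' The global mean epoch across all heartbeats is subtracted at every beat,
#' with the same epoch geometry and cross-fade blending as OBS but no
#' per-epoch fitting. This is the classic non-adaptive template method and
#' serves as a comparison floor for the dynamic methods.
#'
#' @inheritParams obsSuppress
#' @return the corrected Recording (artifact in \code{attr(, "artifact")}).
#' @export
templateSuppress <- function(rec, qrs, cfg = obsConfig(n_components = 0)) {
  stopifnot(is(rec, "Recording"), is(qrs, "QRSAnnotations"))
  geo <- .qrsEpochs(peaks(qrs), samplingRate(rec), nSamples(rec), cfg)
  if (length(geo$starts) < 2) stop("need >= 2 complete cardiac epochs")
  .fitSubtract(rec, geo, nPC = 0L, fitBasis = FALSE)
}

.fitSubtract <- function(rec, geo, nPC, fitBasis) {
  eegIdx <- channelsByRole(rec, "EEG")
  nS <- nSamples(rec)
  len <- geo$len
  nEp <- length(geo$starts)
  idx <- outer(geo$starts, seq_len(len) - 1L, "+")     # nEp x len
  overlap <- if (nEp >= 2) max(0L, len - min(diff(geo$starts))) else 0L
  w <- .fadeWeights(len, overlap)
  artifact <- matrix(0, length(eegIdx), nS)
  wsum <- numeric(nS)
  for (k in seq_len(nEp)) wsum[idx[k, ]] <- wsum[idx[k, ]] + w

  for (ci in seq_along(eegIdx)) {
    x <- rec@data[eegIdx[ci], ]
    E <- matrix(x[idx], nEp, len)
    meanEp <- colMeans(E)
    if (fitBasis) {
      B <- meanEp
      if (nPC > 0) {
        Ec <- sweep(E, 2, meanEp)
        sv <- svd(Ec, nu = 0, nv = min(nPC, len, nEp))
        B <- cbind(meanEp, .fixSigns(sv$v[, seq_len(nPC), drop = FALSE]))
      } else B <- matrix(meanEp, ncol = 1)
      beta <- qr.solve(B, t(E))                        # (1+nPC) x nEp
      fit <- t(B %*% beta)                             # nEp x len
    } else {
      fit <- matrix(meanEp, nEp, len, byrow = TRUE)
    }
    acc <- numeric(nS)
    for (k in seq_len(nEp)) acc[idx[k, ]] <- acc[idx[k, ]] + w * fit[k, ]
    artifact[ci, wsum > 0] <- acc[wsum > 0] / wsum[wsum > 0]
  }
  out <- rec
  out@data[eegIdx, ] <- rec@data[eegIdx, ] - artifact
  attr(out, "artifact") <- artifact
  out
}

#' QRS-locked average epoch amplitude
#'
#' RMS over channels and time of the heartbeat-locked epoch average: the
#' standard measure of residual BCG artifact strength.
#'
#' @param rec a \linkS4class{Recording} (EEG channels are used) or a numeric
#'   channels x samples matrix.
#' @param qrs \linkS4class{QRSAnnotations}.
#' @param cfg epoch geometry, an \code{\link{obsConfig}}.
#' @return scalar RMS amplitude in microvolts.
#' @export
qrsLockedAmplitude <- function(rec, qrs, cfg = obsConfig()) {
  if (is(rec, "Recording")) {
    fs <- samplingRate(rec)
    X <- rec@data[channelsByRole(rec, "EEG"), , drop = FALSE]
  } else {
    fs <- samplingRate(qrs)
    X <- rec
  }
  geo <- .qrsEpochs(peaks(qrs), fs, ncol(X), cfg)
  idx <- outer(geo$starts, seq_len(geo$len) - 1L, "+")
  avg <- t(apply(X, 1, function(x) colMeans(matrix(x[idx], nrow(idx)))))
  sqrt(mean(avg^2))
}

#' Suppress MRI gradient artifacts by average artifact subtraction (AAS)
#'
#' Each TR epoch (delimited by volume-trigger events with near-constant TR)
#' is corrected by subtracting a sliding template: the mean of the
#' \code{window_trs} surrounding epochs (centered; shrunk at the recording
#' edges). Before subtraction the template is aligned to each epoch by an
#' iterative subsample search: at each accuracy level the fractional shift
#' maximizing the cross-correlation is refined (+/- 1 coarse sample at the
#' first level, then +/- the previous accuracy), using Fourier-domain
#' fractional delays.
#'
#' @param rec a \linkS4class{Recording} with volume_trigger events.
#' @param cfg an \code{\link{aasConfig}}.
#' @return the corrected Recording; per-epoch alignment offsets (samples,
#'   averaged over channels) in \code{attr(, "offsets")}.
#' @export
aasSuppress <- function(rec, cfg = aasConfig()) {
  stopifnot(is(rec, "Recording"))
  trig <- rec@events$sample[rec@events$kind == "volume_trigger"]
  if (length(trig) < cfg$window_trs)
    stop("need at least ", cfg$window_trs, " volume triggers for AAS")
  trs <- diff(trig)
  if ((max(trs) - min(trs)) / stats::median(trs) > 0.01)
    stop("volume triggers have > 1% TR jitter; AAS requires a constant TR")
  len <- as.integer(stats::median(trs))
  nS <- nSamples(rec)
  starts <- trig[trig + len - 1L <= nS]
  nEp <- length(starts)
  half <- (cfg$window_trs - 1L) %/% 2L
  idx <- outer(starts, seq_len(len) - 1L, "+")
  chIdx <- which(channelRoles(rec) != "OTHER")

  freqs <- if (len %% 2 == 0) c(0:(len / 2), -(len / 2 - 1):-1)
           else c(0:((len - 1) / 2), -((len - 1) / 2):-1)
  shiftFT <- function(Ft, delta) Ft * exp(-2i * pi * freqs * delta / len)

  offsets <- matrix(0, nEp, length(chIdx))
  out <- rec
  for (ci in seq_along(chIdx)) {
    x <- rec@data[chIdx[ci], ]
    E0 <- matrix(x[idx], nEp, len)    # raw epochs: templates come from these
    E <- E0
    for (k in seq_len(nEp)) {
      # template: surrounding epochs over a window_trs-TR span, excluding the
      # epoch being corrected (so none of its own signal is subtracted)
      lo <- max(1L, k - half); hi <- min(nEp, k + half)
      win <- setdiff(lo:hi, k)
      tmpl <- colMeans(E0[win, , drop = FALSE])
      Ft <- stats::fft(tmpl)
      Fe <- stats::fft(E0[k, ])
      A <- Conj(Ft) * Fe   # corr(delta) = Re(sum(A * exp(+2i pi f delta/len)))/len
      corrAt <- function(delta)
        Re(sum(A * exp(2i * pi * freqs * delta / len))) / len
      best <- 0; range_ <- 1
      for (accLevel in cfg$align_accuracies) {
        grid <- seq(best - range_, best + range_, by = accLevel)
        vals <- vapply(grid, corrAt, numeric(1))
        best <- grid[which.max(vals)]
        range_ <- accLevel
      }
      offsets[k, ci] <- best
      aligned <- Re(stats::fft(shiftFT(Ft, -best), inverse = TRUE)) / len
      E[k, ] <- E0[k, ] - aligned
    }
    y <- x
    for (k in seq_len(nEp)) y[idx[k, ]] <- E[k, ]
    out@data[chIdx[ci], ] <- y
  }
  attr(out, "offsets") <- rowMeans(offsets)
  out
}
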
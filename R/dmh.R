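#' Configuration for dynamic modeling of heartbeats
#'
#' @param e embedding dimension: number of lagged EKG samples describing the
#'   cardiac dynamics at a latency (default 8).
#' @param tau lag between embedded samples, in samples at the processing rate
#'   (default 10, i.e. 20 ms at 500 Hz).
#' @param n number of neighboring cardiac cycles combined (default 10).
#' @param kernel neighbor weighting: \code{"exp_diff"} uses
#'   u_i = exp(d_1 - d_i) (finite at d_1 = 0); \code{"sugihara"} uses the
#'   simplex-projection convention u_i = exp(-d_i / d_1) with uniform weights
#'   over zero-distance neighbors when d_1 = 0.
#' @param exclusion_radius cycles around the query cycle excluded from its
#'   neighbor set (default 1: the query cycle and its immediate neighbors).
#' @param zscore_ekg z-score the EKG before embedding (default FALSE; the
#'   distance metric is plain Euclidean in microvolts).
#' @return validated list of class "DMHConfig".
#' @export
dmhConfig <- function(e = 8, tau = 10, n = 10,
                      kernel = c("exp_diff", "sugihara"),
                      exclusion_radius = 1, zscore_ekg = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(e >= 2, tau >= 1, n >= 1, exclusion_radius >= 0)
  structure(list(e = as.integer(e), tau = as.integer(tau), n = as.integer(n),
                 kernel = kernel,
                 exclusion_radius = as.integer(exclusion_radius),
                 zscore_ekg = isTRUE(zscore_ekg)),
            class = "DMHConfig")
}

#' Map sample indices to cardiac coordinates
#'
#' Every sample from the first to just before the last detected R peak is
#' assigned a cycle index m and a latency phi (samples since that cycle's R
#' peak, \code{phi} in \code{[0, RR_m)}). Samples before the first peak or at
#' or after the last peak are unassigned (NA). The map is a bijection on its
#' assigned domain: \code{peaks[m] + phi} recovers the sample index.
#'
#' @param qrs a \linkS4class{QRSAnnotations} with >= 2 peaks.
#' @param nSamples number of samples on the timeline.
#' @return list of class "CardiacPhaseMap" with integer vectors \code{cycle}
#'   and \code{phi} of length nSamples (NA where unassigned), the peak
#'   vector, and \code{inverse(m, phi)}.
#' @export
buildPhaseMap <- function(qrs, nSamples) {
  p <- peaks(qrs)
  if (length(p) < 2) stop("need >= 2 R peaks to define a cardiac cycle")
  nSamples <- as.integer(nSamples)
  cycle <- rep(NA_integer_, nSamples)
  phi <- rep(NA_integer_, nSamples)
  t <- seq.int(p[1], min(nSamples, p[length(p)] - 1L))
  m <- findInterval(t, p)
  cycle[t] <- m
  phi[t] <- t - p[m]
  structure(list(cycle = cycle, phi = phi, peaks = p,
                 inverse = function(m, phi) p[m] + phi),
            class = "CardiacPhaseMap")
}

#' Build the delay-embedding manifold of cardiac dynamics at one latency
#'
#' For latency phi, each eligible cardiac cycle m contributes the row
#' \code{ekg[peaks[m] + phi + (0:(e-1)) * tau]}: e EKG samples spaced tau
#' apart starting at that cycle's latency phi, read from the continuous
#' timeline. Cycles whose last lagged sample would fall outside the recording
#' are omitted.
#'
#' @param ekg numeric vector, the (preprocessed) EKG series.
#' @param qrs a \linkS4class{QRSAnnotations}.
#' @param phi latency in samples (>= 0).
#' @param cfg a \code{\link{dmhConfig}}.
#' @return list of class "Manifold" with \code{cycles} (ascending integer
#'   vector) and \code{vectors} (matrix, one row per cycle, e columns).
#' @export
buildManifold <- function(ekg, qrs, phi, cfg = dmhConfig()) {
  stopifnot(phi >= 0)
  p <- peaks(qrs)
  M <- length(p) - 1L
  if (M < 1) stop("need >= 2 R peaks")
  if (cfg$zscore_ekg) ekg <- as.numeric(scale(ekg))
  lags <- (seq_len(cfg$e) - 1L) * cfg$tau
  eligible <- which(p[seq_len(M)] + phi + lags[cfg$e] <= length(ekg))
  vec <- matrix(numeric(0), 0, cfg$e)
  if (length(eligible)) {
    idx <- outer(p[eligible] + as.integer(phi), lags, "+")
    vec <- matrix(ekg[idx], nrow = length(eligible))
  }
  structure(list(cycles = eligible, vectors = vec, phi = as.integer(phi),
                 e = cfg$e, tau = cfg$tau),
            class = "Manifold")
}

#' Find the nearest neighboring cardiac cycles on a manifold
#'
#' Euclidean distances from the query cycle's embedding vector to all other
#' rows, excluding cycles within \code{exclusion_radius} of the query; the n
#' smallest are kept (all, if fewer are eligible), ties broken by ascending
#' cycle index.
#'
#' @param man a manifold from \code{\link{buildManifold}}.
#' @param queryCycle cycle index m (must have a row in the manifold).
#' @param cfg a \code{\link{dmhConfig}}.
#' @return list of class "NeighborSet" with \code{query}, \code{cycles},
#'   \code{distances} (ascending), \code{weights} (sum to 1), and
#'   \code{empty} flag.
#' @export
findNeighbors <- function(man, queryCycle, cfg = dmhConfig()) {
  qi <- match(queryCycle, man$cycles)
  if (is.na(qi)) stop("query cycle ", queryCycle, " not present in manifold")
  keep <- abs(man$cycles - queryCycle) > cfg$exclusion_radius
  if (!any(keep)) {
    return(structure(list(query = queryCycle, cycles = integer(0),
                          distances = numeric(0), weights = numeric(0),
                          empty = TRUE), class = "NeighborSet"))
  }
  dif <- sweep(man$vectors[keep, , drop = FALSE], 2, man$vectors[qi, ])
  d <- sqrt(rowSums(dif^2))
  cand <- man$cycles[keep]
  o <- order(d, cand)
  take <- o[seq_len(min(cfg$n, length(o)))]
  dd <- d[take]
  structure(list(query = queryCycle, cycles = cand[take], distances = dd,
                 weights = computeWeights(dd, cfg$kernel), empty = FALSE),
            class = "NeighborSet")
}

#' Neighbor weights from ascending distances
#'
#' \code{exp_diff}: u_i = exp(d_1 - d_i). \code{sugihara}:
#' u_i = exp(-d_i / d_1), with uniform weights over all zero-distance
#' neighbors when d_1 = 0. Weights are u_i normalized to sum to one.
#'
#' @param distances nonnegative distances sorted ascending.
#' @param kernel "exp_diff" or "sugihara".
#' @return numeric weights, same length, summing to 1.
#' @export
computeWeights <- function(distances, kernel = c("exp_diff", "sugihara")) {
  kernel <- match.arg(kernel)
  if (!length(distances)) stop("empty distance list")
  if (is.unsorted(distances)) stop("distances must be ascending")
  if (any(distances < 0)) stop("distances must be nonnegative")
  if (kernel == "exp_diff") {
    u <- exp(distances[1] - distances)
  } else {
    if (distances[1] == 0) {
      u <- as.numeric(distances == 0)
    } else {
      u <- exp(-distances / distances[1])
    }
  }
  u / sum(u)
}

#' Estimate the BCG artifact by dynamic modeling of heartbeats
#'
#' For every sample with cardiac coordinates (cycle m, latency phi), the
#' artifact is modeled as the weighted sum of the EEG at latency phi in the n
#' cardiac cycles whose delay-embedded EKG at that latency is closest to the
#' query cycle's. Neighbor EEG values are read from the continuous timeline
#' at \code{peaks[m_i] + phi} (even when phi exceeds that neighbor's RR
#' interval), except that neighbors whose read sample falls inside the
#' exclusion zone around the query cycle are dropped, so with
#' \code{exclusion_radius >= 1} the estimate at cycle m never reads EEG from
#' cycles m-1, m, m+1. One neighbor search per (m, phi) serves all EEG
#' channels, since the manifold is built from the EKG alone.
#'
#' @param rec a \linkS4class{Recording} with >= 1 EEG channel and an EKG
#'   channel (already preprocessed; see \code{\link{runSuppression}}).
#' @param qrs \linkS4class{QRSAnnotations} detected on that EKG.
#' @param cfg a \code{\link{dmhConfig}}.
#' @return an \linkS4class{ArtifactEstimate}; samples without coordinates or
#'   without any eligible neighbor have estimate 0 and coverage FALSE.
#' @export
estimateArtifact <- function(rec, qrs, cfg = dmhConfig()) {
  stopifnot(is(rec, "Recording"), is(qrs, "QRSAnnotations"))
  eegIdx <- channelsByRole(rec, "EEG")
  if (!length(eegIdx)) stop("recording has no EEG channels")
  ekg <- ekgChannel(rec)
  if (cfg$zscore_ekg) ekg <- as.numeric(scale(ekg))
  p <- peaks(qrs)
  if (length(p) < 2) stop("need >= 2 R peaks")
  M <- length(p) - 1L
  nS <- nSamples(rec)
  X <- rec@data[eegIdx, , drop = FALSE]
  est <- matrix(0, length(eegIdx), nS)
  covered <- rep(FALSE, nS)
  rr <- diff(p)
  lagMax <- (cfg$e - 1L) * cfg$tau
  r <- cfg$exclusion_radius
  nMissed <- 0L
  # exclusion zone bounds per query cycle (sample ranges of cycles m-r..m+r)
  zoneLo <- p[pmax(seq_len(M) - r, 1L)]
  zoneHi <- p[pmin(seq_len(M) + r + 1L, M + 1L)]

  for (phi in 0:(max(rr) - 1L)) {
    queries <- which(rr > phi)                       # phi inside cycle
    eligible <- which(p[seq_len(M)] + phi + lagMax <= length(ekg))
    if (!length(eligible)) { nMissed <- nMissed + length(queries); next }
    V <- matrix(ekg[outer(p[eligible] + phi, (seq_len(cfg$e) - 1L) * cfg$tau,
                          "+")], nrow = length(eligible))
    qOK <- queries[queries %in% eligible]
    nMissed <- nMissed + length(queries) - length(qOK)
    if (!length(qOK)) next
    qPos <- match(qOK, eligible)
    sq <- rowSums(V^2)
    # squared distances from every query row to every eligible row
    D2 <- outer(sq[qPos], sq, "+") - 2 * V[qPos, , drop = FALSE] %*% t(V)
    reads <- p[eligible] + phi                        # neighbor read samples
    E <- X[, reads, drop = FALSE]                     # nEEG x nEligible
    W <- matrix(0, length(qOK), length(eligible))
    ok <- rep(TRUE, length(qOK))
    for (k in seq_along(qOK)) {
      m <- qOK[k]
      keep <- which(abs(eligible - m) > r &
                      (reads < zoneLo[m] | reads >= zoneHi[m]))
      if (!length(keep)) { ok[k] <- FALSE; next }
      d2 <- D2[k, keep]
      o <- order(d2, eligible[keep])
      take <- keep[o[seq_len(min(cfg$n, length(o)))]]
      W[k, take] <- computeWeights(sqrt(pmax(D2[k, take], 0)), cfg$kernel)
    }
    tIdx <- p[qOK] + phi
    vals <- W %*% t(E)                                # nQ x nEEG
    est[, tIdx[ok]] <- t(vals[ok, , drop = FALSE])
    covered[tIdx[ok]] <- TRUE
    nMissed <- nMissed + sum(!ok)
  }
  if (nMissed > 0)
    warning(nMissed, " in-cycle samples had no usable neighbor set; ",
            "their artifact estimate is zero")
  new("ArtifactEstimate", data = est, coverage = covered,
      channelNames = rec@channelNames[eegIdx])
}

#' Subtract a BCG artifact estimate from a recording
#'
#' EEG channels become \code{data - estimate}; EKG/OTHER channels and events
#' pass through unchanged.
#'
#' @param rec the \linkS4class{Recording} the estimate was computed from.
#' @param art an \linkS4class{ArtifactEstimate} with matching shape.
#' @return the BCG-suppressed Recording.
#' @export
suppressBCG <- function(rec, art) {
  stopifnot(is(rec, "Recording"), is(art, "ArtifactEstimate"))
  eegIdx <- channelsByRole(rec, "EEG")
  if (nrow(art@data) != length(eegIdx) || ncol(art@data) != nSamples(rec))
    stop("artifact estimate shape does not match the recording")
  out <- rec
  out@data[eegIdx, ] <- rec@data[eegIdx, ] - art@data
  out
}

#' One-call DMH suppression
#'
#' Convenience wrapper: estimate the artifact with
#' \code{\link{estimateArtifact}} and subtract it.
#'
#' @inheritParams estimateArtifact
#' @param returnArtifact also return the estimate.
#' @return the suppressed Recording, or (with \code{returnArtifact}) a list
#'   \code{(recording, artifact)}.
#' @export
dmhSuppress <- function(rec, qrs, cfg = dmhConfig(), returnArtifact = FALSE) {
  art <- estimateArtifact(rec, qrs, cfg)
  out <- suppressBCG(rec, art)
  if (returnArtifact) list(recording = out, artifact = art) else out
}
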
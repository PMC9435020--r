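#' Configuration for the synthetic concurrent EEG-MRI generator
#'
#' Defaults emulate a 32-channel EEG recording at 500 Hz with
#' cardiac-cycle-locked BCG artifacts of 150-200 microvolts lasting about
#' 1 s, 15-Hz SSVEP bursts of ~5 microvolts locked to stimulus events with a
#' minimal 2-s inter-stimulus interval, 1/f background noise, and optional
#' TR-periodic gradient artifacts.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param n_eeg_channels number of EEG channels (<= 32 named 10-20 labels).
#' @param mean_rr_s mean RR interval (s).
#' @param rr_jitter_sd_s SD of the AR(1) RR jitter (s).
#' @param rr_resp_amp_s amplitude of respiratory RR modulation (s).
#' @param resp_freq_hz respiration frequency (Hz).
#' @param bcg_amp_uv length-2 range of the channel-max BCG amplitude (uV).
#' @param bcg_delay_s BCG onset delay after the R peak (s).
#' @param bcg_dur_s BCG duration per beat (s).
#' @param bcg_mod strength of the RR/respiration modulation of the BCG
#'   (0 = every beat identical, 1 = full modulation).
#' @param ekg_mod strength of beat-to-beat EKG morphology modulation.
#' @param ekg_amp_uv R-wave amplitude of the synthetic EKG (uV).
#' @param ekg_noise_uv white measurement noise SD on the EKG channel (uV).
#' @param ssvep_freq_hz SSVEP frequency (Hz).
#' @param ssvep_amp_uv SSVEP amplitude at occipital channels (uV).
#' @param stim_dur_s stimulus (burst) duration (s).
#' @param min_isi_s minimal onset-to-onset inter-stimulus interval (s).
#' @param noise_pink_uv RMS of the 1/f background noise per channel (uV).
#' @param noise_white_uv SD of white sensor noise per channel (uV).
#' @param n_spiked_trials number of trials given an injected >700 uV artifact
#'   spike (for rejection tests).
#' @param spike_amp_uv amplitude of the injected spikes (uV).
#' @param ga_enabled add a TR-periodic gradient artifact and volume triggers.
#' @param ga_tr_s TR interval (s).
#' @param ga_amp_uv gradient artifact amplitude (uV).
#' @param ga_epoch_offsets optional numeric vector of per-TR fractional-sample
#'   timing offsets (tests the AAS alignment stage).
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class "SynthConfig".
#' @export
synthConfig <- function(duration_s = 360, fs = 500, n_eeg_channels = 32,
                        mean_rr_s = 1.0, rr_jitter_sd_s = 0.05,
                        rr_resp_amp_s = 0.02, resp_freq_hz = 0.25,
                        bcg_amp_uv = c(150, 200), bcg_delay_s = 0.21,
                        bcg_dur_s = 1.0, bcg_mod = 1, ekg_mod = 1,
                        ekg_amp_uv = 800, ekg_noise_uv = 2,
                        ssvep_freq_hz = 15, ssvep_amp_uv = 5,
                        stim_dur_s = 1.0, min_isi_s = 2.0,
                        noise_pink_uv = 3, noise_white_uv = 1,
                        n_spiked_trials = 0, spike_amp_uv = 900,
                        ga_enabled = FALSE, ga_tr_s = 2.0, ga_amp_uv = 2000,
                        ga_epoch_offsets = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$bcg_amp_uv) == 1) cfg$bcg_amp_uv <- rep(cfg$bcg_amp_uv, 2)
  amps <- c(cfg$bcg_amp_uv, cfg$ssvep_amp_uv, cfg$noise_pink_uv,
            cfg$noise_white_uv, cfg$ga_amp_uv, cfg$ekg_amp_uv)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (cfg$min_isi_s < cfg$stim_dur_s)
    stop("min_isi_s must be >= stim_dur_s")
  if (cfg$mean_rr_s - 4 * cfg$rr_jitter_sd_s - cfg$rr_resp_amp_s <= 0.25)
    stop("RR jitter too large: intervals would violate the refractory period")
  if (cfg$duration_s < 5) stop("duration must be >= 5 s")
  structure(cfg, class = "SynthConfig")
}

.EEG_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1",
               "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
               "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8",
               "PO9", "O1", "Oz", "O2", "PO10")

.synthChannelNames <- function(n) {
  if (n <= length(.EEG_1020)) {
    # keep the occipital electrodes in the montage whatever the count
    nm <- .EEG_1020
    if (n < 32) nm <- unique(c(.EEG_1020[seq_len(max(0, n - 3))],
                               c("O1", "Oz", "O2")))[seq_len(n)]
    return(nm)
  }
  c(.EEG_1020, paste0("X", seq_len(n - length(.EEG_1020))))
}

.gauss <- function(t, mu, sigma) exp(-0.5 * ((t - mu) / sigma)^2)

#' Generate a synthetic EKG trace with known R-peak times
#'
#' Beat train with RR intervals given by the mean RR plus AR(1) jitter plus
#' sinusoidal respiratory modulation; each beat is a sum of Gaussian
#' P/Q/R/S/T waves whose amplitudes and the T latency vary mildly and
#' deterministically with the beat's RR deviation and respiratory phase, so
#' the EKG morphology carries the same dynamical state that modulates the
#' BCG. A respiratory baseline wander and white measurement noise are added.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list with \code{ekg} (numeric vector, uV), \code{r_peaks}
#'   (1-based sample indices), \code{t_r} (R times, s), \code{rr_s},
#'   \code{rr_dev} (relative RR deviation), \code{resp_phase} (radians per
#'   beat).
#' @export
synthEKG <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs

  # beat times: first R at 0.5 s, AR(1) jitter + respiratory modulation
  rho <- 0.4
  tR <- 0.5
  rr <- numeric(0); tRs <- numeric(0); ar <- 0
  repeat {
    tRs <- c(tRs, tR)
    innov <- if (cfg$rr_jitter_sd_s > 0)
      stats::rnorm(1, 0, cfg$rr_jitter_sd_s * sqrt(1 - rho^2)) else 0
    ar <- rho * ar + innov
    thisRR <- cfg$mean_rr_s + ar +
      cfg$rr_resp_amp_s * sin(2 * pi * cfg$resp_freq_hz * tR)
    thisRR <- max(thisRR, 0.3)
    if (tR + thisRR > cfg$duration_s - 0.2) break
    rr <- c(rr, thisRR)
    tR <- tR + thisRR
  }
  nb <- length(tRs)
  rrFull <- c(rr, if (length(rr)) rr[length(rr)] else cfg$mean_rr_s)
  rrDev <- (rrFull - cfg$mean_rr_s) / cfg$mean_rr_s
  respPhase <- 2 * pi * cfg$resp_freq_hz * tRs

  ekg <- numeric(n)
  em <- cfg$ekg_mod
  for (m in seq_len(nb)) {
    t0 <- tRs[m]
    lo <- max(1L, floor((t0 - 0.35) * fs) + 1L)
    hi <- min(n, ceiling((t0 + 0.6 * rrFull[m]) * fs) + 1L)
    u <- tt[lo:hi] - t0
    rAmp <- cfg$ekg_amp_uv * (1 + em * 0.10 * sin(respPhase[m]))
    tAmp <- 0.30 * cfg$ekg_amp_uv *
      (1 + em * (0.15 * sin(respPhase[m]) + 0.30 * rrDev[m]))
    tLat <- 0.30 * sqrt(max(rrFull[m] / cfg$mean_rr_s, 0.25))
    beat <- 0.12 * cfg$ekg_amp_uv * .gauss(u, -0.16, 0.022) -
            0.12 * rAmp * .gauss(u, -0.030, 0.009) +
            rAmp * .gauss(u, 0, 0.011) -
            0.20 * rAmp * .gauss(u, 0.032, 0.009) +
            tAmp * .gauss(u, tLat, 0.05)
    ekg[lo:hi] <- ekg[lo:hi] + beat
  }
  wander <- em * 0.03 * cfg$ekg_amp_uv *
    sin(2 * pi * cfg$resp_freq_hz * tt)
  noise <- if (cfg$ekg_noise_uv > 0) stats::rnorm(n, 0, cfg$ekg_noise_uv)
    else numeric(n)
  list(ekg = ekg + wander + noise,
       r_peaks = round(tRs * fs) + 1L,
       t_r = tRs, rr_s = rrFull, rr_dev = rrDev, resp_phase = respPhase)
}

# single-beat BCG waveform: rise-and-decay envelope times a slow two-cycle
# oscillation plus a faster ripple (sharp deflections give real BCG spectral
# content overlapping the EEG bands of interest); scaled so max |value| = 1
.bcgWaveRaw <- function(u, dur) {
  v <- u / dur
  env <- (v / 0.12) * exp(-(v - 0.12) / 0.22)
  env[v < 0 | v > 1] <- 0
  env * (sin(2 * pi * 2 * v) + 0.35 * sin(2 * pi * 13 * u + 1.0))
}

.bcgWave <- function(u, dur) {
  fine <- seq(0, dur, length.out = 4096)
  .bcgWaveRaw(u, dur) / max(abs(.bcgWaveRaw(fine, dur)))
}

#' Generate the BCG artifact component from an EKG ground truth
#'
#' Each beat contributes a damped two-oscillation waveform starting
#' \code{bcg_delay_s} after its R peak. Per-beat amplitude and time scale are
#' deterministic functions of that beat's RR deviation and respiratory phase
#' (squashed so the channel-max amplitude stays inside \code{bcg_amp_uv}),
#' which makes the artifact dynamics covary with the EKG dynamics. A fixed
#' polarity-reversing topography scales the waveform across channels.
#'
#' @param ekgTruth the list returned by \code{\link{synthEKG}}.
#' @param cfg a \code{\link{synthConfig}}.
#' @param channel_profile optional numeric vector of per-channel gains with
#'   max(abs(.)) == 1; default a smooth polarity-reversing profile.
#' @return matrix [n_eeg_channels x n_samples] in uV.
#' @export
synthBCG <- function(ekgTruth, cfg, channel_profile = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (!length(ekgTruth$r_peaks)) stop("no R peaks in EKG truth")
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  nch <- cfg$n_eeg_channels
  if (is.null(channel_profile)) {
    channel_profile <- cos(pi * (seq_len(nch) - 1) / max(1, nch - 1)) * 0.7 +
      0.3 * sin(2 * pi * (seq_len(nch) - 1) / max(1, nch))
    channel_profile <- channel_profile / max(abs(channel_profile))
  }
  a0 <- mean(cfg$bcg_amp_uv)
  a1 <- diff(range(cfg$bcg_amp_uv)) / 2
  tt <- (seq_len(n) - 1) / fs
  base <- numeric(n)
  for (m in seq_along(ekgTruth$t_r)) {
    mod <- cfg$bcg_mod * tanh(2 * (0.8 * ekgTruth$rr_dev[m] +
                                   0.6 * sin(ekgTruth$resp_phase[m])))
    amp <- a0 + a1 * mod
    t0 <- ekgTruth$t_r[m] + cfg$bcg_delay_s * (1 + 0.05 * mod)
    dur <- cfg$bcg_dur_s * (1 + 0.15 * mod * cfg$bcg_mod)
    lo <- max(1L, floor(t0 * fs) + 1L)
    hi <- min(n, ceiling((t0 + dur) * fs) + 1L)
    if (lo > hi) next
    base[lo:hi] <- base[lo:hi] + amp * .bcgWave(tt[lo:hi] - t0, dur)
  }
  outer(channel_profile, base)
}

#' Generate the neural component: SSVEP bursts plus 1/f and white noise
#'
#' Stimulus onsets are placed with onset-to-onset intervals of at least
#' \code{min_isi_s} (plus uniform jitter); each adds a sinusoidal burst at
#' \code{ssvep_freq_hz} of \code{stim_dur_s} with 100-ms cosine ramps,
#' weighted toward occipital channels. Pink noise is produced by 1/f spectral
#' shaping of white noise.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param channelNames channel labels used to locate occipital channels.
#' @return list with \code{neural} [nch x n] matrix (uV), \code{stim_onsets}
#'   (1-based samples), \code{spiked_trials} (indices into the onset list).
#' @export
synthNeural <- function(cfg, channelNames = .synthChannelNames(cfg$n_eeg_channels)) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  nch <- cfg$n_eeg_channels
  tt <- (seq_len(n) - 1) / fs

  # occipital weighting: O* = 1, PO*/P* = 0.5, others 0.1
  w <- rep(0.1, nch)
  w[grepl("^PO|^P[0-9z]", channelNames[seq_len(nch)])] <- 0.5
  w[grepl("^O", channelNames[seq_len(nch)]) &
      !grepl("^PO", channelNames[seq_len(nch)])] <- 1

  onsets <- numeric(0)
  t0 <- 2.0
  while (t0 + cfg$stim_dur_s + 1.0 < cfg$duration_s) {
    onsets <- c(onsets, t0)
    t0 <- t0 + cfg$min_isi_s + stats::runif(1, 0, 1.0)
  }
  burst <- numeric(n)
  for (on in onsets) {
    lo <- floor(on * fs) + 1L
    hi <- min(n, ceiling((on + cfg$stim_dur_s) * fs) + 1L)
    u <- tt[lo:hi] - on
    env <- rep(1, length(u))
    ramp <- 0.1
    env[u < ramp] <- 0.5 * (1 - cos(pi * u[u < ramp] / ramp))
    dd <- cfg$stim_dur_s - u
    env[dd < ramp & dd >= 0] <- 0.5 * (1 - cos(pi * dd[dd < ramp & dd >= 0] / ramp))
    env[u > cfg$stim_dur_s] <- 0
    burst[lo:hi] <- burst[lo:hi] +
      env * sin(2 * pi * cfg$ssvep_freq_hz * u)
  }
  neural <- outer(w * cfg$ssvep_amp_uv, burst)

  if (cfg$noise_pink_uv > 0 || cfg$noise_white_uv > 0) {
    for (ch in seq_len(nch)) {
      nz <- numeric(n)
      if (cfg$noise_pink_uv > 0) nz <- nz + .pinkNoise(n, cfg$noise_pink_uv)
      if (cfg$noise_white_uv > 0) nz <- nz + stats::rnorm(n, 0, cfg$noise_white_uv)
      neural[ch, ] <- neural[ch, ] + nz
    }
  }

  onsetSamples <- round(onsets * fs) + 1L
  spiked <- integer(0)
  if (cfg$n_spiked_trials > 0) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed + 3L)
    spiked <- sort(sample(seq_along(onsetSamples),
                          min(cfg$n_spiked_trials, length(onsetSamples))))
    for (tr in spiked) {
      at <- onsets[tr] + 0.4
      lo <- floor((at - 0.05) * fs) + 1L
      hi <- min(n, ceiling((at + 0.05) * fs) + 1L)
      neural[1, lo:hi] <- neural[1, lo:hi] +
        cfg$spike_amp_uv * .gauss(tt[lo:hi], at, 0.012)
    }
  }
  list(neural = neural, stim_onsets = onsetSamples, spiked_trials = spiked)
}

.pinkNoise <- function(n, rms) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

# continuous band-limited TR-periodic gradient-artifact template:
# harmonics of 1/TR with 1/h amplitude roll-off and fixed phases
.gaTemplate <- function(t, tr, amp, fs) {
  f0 <- 1 / tr
  hmax <- floor(0.8 * (fs / 2) / f0)
  hs <- seq_len(min(hmax, 400))
  out <- numeric(length(t))
  for (h in hs)
    out <- out + (1 / h) * sin(2 * pi * h * f0 * t + 0.7 * h)
  out * amp / max(abs(out))
}

#' Compose a full synthetic recording with ground truth
#'
#' Sums the neural, BCG and (optionally) gradient-artifact components,
#' appends the EKG channel, and attaches stimulus / volume-trigger events.
#' The stored ground-truth components reconstruct the EEG data exactly:
#' \code{recording == neural + bcg + ga}.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list with \code{recording} (a \linkS4class{Recording}) and
#'   \code{truth} (class "GroundTruth": neural, bcg, ga matrices, ekg series,
#'   r_peaks, stim_onsets, spiked_trials, plus the per-beat dynamics).
#' @export
composeRecording <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  nch <- cfg$n_eeg_channels
  chNames <- .synthChannelNames(nch)

  ekgT <- synthEKG(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  bcg <- synthBCG(ekgT, cfg)
  neu <- synthNeural(cfg, chNames)

  ga <- matrix(0, nch, n)
  events <- data.frame(sample = neu$stim_onsets,
                       kind = rep("stimulus", length(neu$stim_onsets)),
                       stringsAsFactors = FALSE)
  if (cfg$ga_enabled) {
    tt <- (seq_len(n) - 1) / fs
    nTR <- floor(cfg$duration_s / cfg$ga_tr_s)
    offs <- cfg$ga_epoch_offsets
    if (is.null(offs)) offs <- rep(0, nTR)
    offs <- rep_len(offs, nTR)
    gaRow <- numeric(n)
    for (k in seq_len(nTR)) {
      lo <- round((k - 1) * cfg$ga_tr_s * fs) + 1L
      hi <- min(n, round(k * cfg$ga_tr_s * fs))
      u <- tt[lo:hi] - (k - 1) * cfg$ga_tr_s - offs[k] / fs
      gaRow[lo:hi] <- .gaTemplate(u, cfg$ga_tr_s, cfg$ga_amp_uv, fs)
    }
    ga <- matrix(rep(gaRow, each = nch), nch, n)
    trig <- data.frame(sample = round((seq_len(nTR) - 1) * cfg$ga_tr_s * fs) + 1L,
                       kind = rep("volume_trigger", nTR),
                       stringsAsFactors = FALSE)
    events <- rbind(events, trig)
  }
  events <- events[order(events$sample), , drop = FALSE]

  eeg <- neu$neural + bcg + ga
  data <- rbind(eeg, ekgT$ekg)
  rec <- Recording(data, fs = fs,
                   channelNames = c(chNames, "ECG"),
                   channelRoles = c(rep("EEG", nch), "EKG"),
                   events = events)
  truth <- structure(list(
    neural = neu$neural, bcg = bcg, ga = ga, ekg = ekgT$ekg,
    r_peaks = ekgT$r_peaks, stim_onsets = neu$stim_onsets,
    spiked_trials = neu$spiked_trials,
    rr_s = ekgT$rr_s, rr_dev = ekgT$rr_dev, resp_phase = ekgT$resp_phase,
    config = cfg), class = "GroundTruth")
  list(recording = rec, truth = truth)
}
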
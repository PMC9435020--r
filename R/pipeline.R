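#' Pipeline configuration
#'
#' The processing order is fixed: AAS (gradient artifact) -> band-pass ->
#' resample -> QRS detection -> BCG suppression (DMH or OBS). \code{steps}
#' selects an ordered subset; reordering is not supported because the DMH
#' lag/embedding parameters are defined on the post-resampling timeline.
#'
#' @param steps subset of c("aas", "bandpass", "resample", "qrs", "dmh",
#'   "obs") ("dmh" and "obs" are mutually exclusive and require "qrs").
#' @param aas an \code{\link{aasConfig}}.
#' @param band a \code{\link{filterSpec}}.
#' @param targetFs resampling target in Hz (default 500).
#' @param dmh a \code{\link{dmhConfig}}.
#' @param obs an \code{\link{obsConfig}}.
#' @param seed integer recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(steps = c("bandpass", "resample", "qrs", "dmh"),
                           aas = aasConfig(), band = filterSpec(),
                           targetFs = 500, dmh = dmhConfig(),
                           obs = obsConfig(), seed = 1L) {
  known <- c("aas", "bandpass", "resample", "qrs", "dmh", "obs")
  if (!all(steps %in% known))
    stop("unknown step(s): ", paste(setdiff(steps, known), collapse = ", "))
  if (all(c("dmh", "obs") %in% steps))
    stop("choose one of dmh or obs, not both")
  if (any(c("dmh", "obs") %in% steps) && !("qrs" %in% steps))
    stop("dmh/obs require the qrs step")
  steps <- known[known %in% steps]     # canonical order
  structure(list(steps = steps, aas = aas, band = band, targetFs = targetFs,
                 dmh = dmh, obs = obs, seed = seed),
            class = "PipelineConfig")
}

#' Run the artifact-suppression pipeline
#'
#' Applies the configured steps in the fixed order AAS -> band-pass (1-50 Hz)
#' -> resample (500 Hz) -> QRS detection -> DMH or OBS, and records
#' provenance (package version, configs, QRS count, artifact coverage).
#' Prerequisites are checked before any computation.
#'
#' @param rec a \linkS4class{Recording}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{recording} (processed), \code{qrs} (or NULL),
#'   \code{artifact} (DMH estimate or NULL), and \code{provenance} (a list
#'   serializable to JSON).
#' @export
runSuppression <- function(rec, cfg = pipelineConfig()) {
  stopifnot(is(rec, "Recording"), inherits(cfg, "PipelineConfig"))
  if ("aas" %in% cfg$steps &&
      !any(rec@events$kind == "volume_trigger"))
    stop("aas step requires volume_trigger events")
  if (any(c("dmh", "obs") %in% cfg$steps) &&
      !any(channelRoles(rec) == "EKG"))
    stop("BCG suppression requires an EKG channel")

  qrs <- NULL; art <- NULL
  for (step in cfg$steps) {
    rec <- switch(step,
      aas = aasSuppress(rec, cfg$aas),
      bandpass = bandpass(rec, cfg$band),
      resample = resampleRecording(rec, cfg$targetFs),
      qrs = { qrs <- detectQRS(rec); rec },
      dmh = {
        res <- dmhSuppress(rec, qrs, cfg$dmh, returnArtifact = TRUE)
        art <- res$artifact
        res$recording
      },
      obs = obsSuppress(rec, qrs, cfg$obs))
  }
  prov <- list(
    package = "dmhbcg",
    version = as.character(utils::packageVersion("dmhbcg")),
    steps = cfg$steps,
    seed = cfg$seed,
    fs = samplingRate(rec),
    configs = list(
      aas = if ("aas" %in% cfg$steps) unclass(cfg$aas),
      band = if ("bandpass" %in% cfg$steps) unclass(cfg$band),
      targetFs = if ("resample" %in% cfg$steps) cfg$targetFs,
      dmh = if ("dmh" %in% cfg$steps) unclass(cfg$dmh),
      obs = if ("obs" %in% cfg$steps) unclass(cfg$obs)),
    qrs_count = if (!is.null(qrs)) length(peaks(qrs)),
    coverage = if (!is.null(art)) coverageFraction(art),
    mean_rr_s = if (!is.null(qrs) && length(peaks(qrs)) > 1)
      mean(diff(peaks(qrs))) / samplingRate(rec))
  list(recording = rec, qrs = qrs, artifact = art, provenance = prov)
}

#' Compare BCG-suppression methods against synthetic ground truth
#'
#' For each method, the recording is corrected and evaluated: QRS-locked
#' epoch amplitude before/after, residual artifact RMS against the true BCG
#' component, evoked oscillatory power at the SSVEP frequency over occipital
#' channels (raw and noise-normalized), and a channel-level ROC/AUC against
#' the truth's active-channel mask. With two or more methods the report
#' orders them by residual artifact RMS.
#'
#' @param rec a preprocessed \linkS4class{Recording} (500-Hz timeline).
#' @param truth the GroundTruth of \code{\link{composeRecording}} (NULL for
#'   relative metrics only).
#' @param methods character subset of c("dmh", "obs", "template").
#' @param dmh,obs configs for the respective methods.
#' @param freqHz SSVEP frequency (default 15).
#' @return list of class "ComparisonReport".
#' @export
runComparison <- function(rec, truth = NULL, methods = c("dmh", "obs"),
                          dmh = dmhConfig(), obs = obsConfig(),
                          freqHz = 15) {
  stopifnot(is(rec, "Recording"))
  if (!is.null(truth)) {
    if (!inherits(truth, "GroundTruth"))
      stop("truth must be a GroundTruth")
    if (ncol(truth$bcg) != nSamples(rec))
      stop("truth and recording have mismatched lengths")
  }
  qrs <- detectQRS(rec)
  pre <- qrsLockedAmplitude(rec, qrs)
  eegIdx <- channelsByRole(rec, "EEG")
  occ <- intersect(c("O1", "O2", "Oz"), channelNames(rec))
  freqs <- 5:30
  evalOne <- function(cleaned) {
    ep <- epochAndClean(cleaned)
    tfr <- morletTFR(ep, freqs)
    out <- list(
      qrs_locked_amplitude_post = qrsLockedAmplitude(cleaned, qrs),
      evoked_power = evokedPower(tfr, occ, freqHz),
      evoked_power_norm = evokedPower(noiseNormalize(tfr), occ, freqHz))
    if (!is.null(truth)) {
      resid <- cleaned@data[eegIdx, ] -
        (truth$neural + truth$ga)                 # what is left beyond truth
      out$residual_artifact_rms <- sqrt(mean(resid^2))
      chPow <- vapply(seq_along(eegIdx),
                      function(ci) evokedPower(tfr, ci, freqHz), numeric(1))
      mask <- grepl("^O[0-9z]", channelNames(rec)[eegIdx])
      if (any(mask) && !all(mask))
        out$auc <- rocAuc(chPow, mask)$auc
    }
    out
  }
  blocks <- list()
  for (m in methods) {
    cleaned <- switch(m,
      dmh = dmhSuppress(rec, qrs, dmh),
      obs = obsSuppress(rec, qrs, obs),
      template = templateSuppress(rec, qrs),
      stop("unknown method: ", m))
    blocks[[m]] <- evalOne(cleaned)
  }
  rep_ <- list(qrs_locked_amplitude_pre = pre,
               n_qrs = length(peaks(qrs)), methods = blocks)
  if (length(methods) > 1 && !is.null(truth)) {
    rms <- vapply(blocks, function(b) b$residual_artifact_rms, numeric(1))
    rep_$ranking <- names(sort(rms))
  }
  structure(rep_, class = "ComparisonReport")
}
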
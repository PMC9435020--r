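# Shared fixtures, built in code. Sessions are memoized so several test
# files can reuse the same synthetic recording without regenerating it.

.sessCache <- new.env(parent = emptyenv())

cachedSession <- function(..., key = NULL) {
  args <- list(...)
  if (is.null(key))
    key <- paste(deparse(args, width.cutoff = 500), collapse = "")
  key <- digest_key(key)
  if (is.null(.sessCache[[key]]))
    .sessCache[[key]] <- composeRecording(do.call(synthConfig, args))
  .sessCache[[key]]
}

digest_key <- function(x) paste0("k", sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 1e9)

# tiny deterministic multichannel recording for I/O tests
tinyRecording <- function(nch = 3, n = 1000, fs = 250, events = TRUE) {
  set.seed(42)
  data <- matrix(rnorm(nch * n), nch, n)
  ev <- if (events)
    data.frame(sample = c(10L, 500L, 990L),
               kind = c("stimulus", "volume_trigger", "response"))
  else NULL
  Recording(data, fs, channelNames = c(paste0("EEG", seq_len(nch - 1)), "ECG"),
            events = ev)
}

# write a minimal BrainVision file set; independent of the package reader
writeBrainVisionFixture <- function(dir, data, fs, names,
                                    resolutions = rep(1, nrow(data)),
                                    binFormat = c("INT_16", "IEEE_FLOAT_32"),
                                    markers = NULL) {
  binFormat <- match.arg(binFormat)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vhdr <- file.path(dir, "rec.vhdr")
  chLines <- vapply(seq_len(nrow(data)), function(i)
    sprintf("Ch%d=%s,,%g,µV", i, names[i], resolutions[i]), "")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=rec.eeg",
    "MarkerFile=rec.vmrk",
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(data)),
    sprintf("SamplingInterval=%g", 1e6 / fs),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binFormat),
    "[Channel Infos]",
    chLines), vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]")
  if (!is.null(markers))
    mk <- c(mk, vapply(seq_len(nrow(markers)), function(i)
      sprintf("Mk%d=%s,%s,%d,1,0", i, markers$type[i], markers$desc[i],
              markers$sample[i]), ""))
  writeLines(mk, file.path(dir, "rec.vmrk"))
  con <- file(file.path(dir, "rec.eeg"), "wb")
  on.exit(close(con))
  counts <- sweep(data, 1, resolutions, "/")
  if (binFormat == "INT_16")
    writeBin(as.integer(round(as.vector(counts))), con, size = 2L,
             endian = "little")
  else
    writeBin(as.vector(counts), con, size = 4L, endian = "little")
  vhdr
}

# write a minimal one-record-per-second EDF file (16-bit), optionally with an
# EDF+ annotation signal carrying stimulus markers
writeEDFFixture <- function(path, data, fs, names, annotations = NULL) {
  ns <- nrow(data) + if (is.null(annotations)) 0L else 1L
  nRec <- ncol(data) / fs
  stopifnot(nRec == round(nRec))
  physMin <- apply(data, 1, min) - 1
  physMax <- apply(data, 1, max) + 1
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  annSamp <- 32L  # 64 bytes of TAL text per record
  hdr <- paste0(
    pad("0", 8), pad("patient", 80), pad("recording", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(nRec, 8), pad(1, 8), pad(ns, 4))
  lab <- c(names, if (!is.null(annotations)) "EDF Annotations")
  field <- function(vals, w) paste0(vapply(vals, pad, "", w = w), collapse = "")
  hdr <- paste0(hdr,
    field(lab, 16), field(rep("", ns), 80),
    field(c(rep("uV", nrow(data)), if (!is.null(annotations)) ""), 8),
    field(c(physMin, if (!is.null(annotations)) -1), 8),
    field(c(physMax, if (!is.null(annotations)) 1), 8),
    field(c(rep(-32768, nrow(data)), if (!is.null(annotations)) -32768), 8),
    field(c(rep(32767, nrow(data)), if (!is.null(annotations)) 32767), 8),
    field(rep("", ns), 80),
    field(c(rep(fs, nrow(data)), if (!is.null(annotations)) annSamp), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  gain <- (physMax - physMin) / 65535
  for (r in seq_len(nRec)) {
    for (s in seq_len(nrow(data))) {
      seg <- data[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - physMin[s]) / gain[s]) - 32768
      writeBin(as.integer(pmax(pmin(dig, 32767), -32768)), con, size = 2L,
               endian = "little")
    }
    if (!is.null(annotations)) {
      tals <- sprintf("+%g\x14\x14", r - 1)          # record timestamp TAL
      inRec <- annotations[annotations$onset_s >= r - 1 &
                             annotations$onset_s < r, , drop = FALSE]
      for (i in seq_len(nrow(inRec)))
        tals <- c(tals, sprintf("+%g\x14%s\x14", inRec$onset_s[i],
                                inRec$label[i]))
      # each TAL is NUL-terminated
      b <- unlist(lapply(tals, function(s) c(charToRaw(s), raw(1))))
      b <- c(b, raw(2 * annSamp - length(b)))
      writeBin(b, con)
    }
  }
  path
}

expect_recording_equal <- function(a, b) {
  expect_identical(recData(a), recData(b))
  expect_identical(samplingRate(a), samplingRate(b))
  expect_identical(channelNames(a), channelNames(b))
  expect_identical(channelRoles(a), channelRoles(b))
  expect_identical(recEvents(a)$sample, recEvents(b)$sample)
  expect_identical(recEvents(a)$kind, recEvents(b)$kind)
}

# rebuild a Recording around an EEG matrix, reusing session metadata
asRecordingLike <- function(mat, sess) {
  rec <- sess$recording
  Recording(rbind(mat, sess$truth$ekg), samplingRate(rec),
            channelNames = channelNames(rec),
            channelRoles = channelRoles(rec), events = recEvents(rec))
}

evokedPower15 <- function(rec, freqs = c(10, 15, 20)) {
  evokedPower(morletTFR(epochAndClean(rec), freqs))
}
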
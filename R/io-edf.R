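# EDF / EDF+ reader for continuous recordings. 256-byte fixed header,
# 256 bytes of header per signal, then data records of 16-bit little-endian
# integers scaled per-signal by (physMax-physMin)/(digMax-digMin).
# "EDF Annotations" signals are parsed as TALs (onset + label; durations
# ignored) and mapped to events; all ordinary signals must share one rate.

.readEDF <- function(path, ekgPattern = "^(EKG|ECG)") {
  con <- file(path, "rb")
  on.exit(close(con))
  readStr <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  version <- readStr(8)
  readStr(80); readStr(80); readStr(8); readStr(8)  # patient/recording ids, dates
  nHeader <- as.integer(readStr(8))
  readStr(44)                                        # reserved
  nRecords <- as.integer(readStr(8))
  recDur <- as.numeric(readStr(8))
  ns <- as.integer(readStr(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: ", path)
  fieldVec <- function(nbytes) vapply(seq_len(ns), function(i) readStr(nbytes), "")
  labels <- fieldVec(16)
  fieldVec(80)                                       # transducer
  units <- fieldVec(8)
  physMin <- as.numeric(fieldVec(8))
  physMax <- as.numeric(fieldVec(8))
  digMin <- as.numeric(fieldVec(8))
  digMax <- as.numeric(fieldVec(8))
  fieldVec(80)                                       # prefiltering
  nSampPerRec <- as.integer(fieldVec(8))
  fieldVec(32)                                       # reserved
  seek(con, nHeader)

  isAnn <- labels == "EDF Annotations"
  sigIdx <- which(!isAnn)
  if (length(sigIdx) == 0) stop("EDF file has no signal channels: ", path)
  if (length(unique(nSampPerRec[sigIdx])) != 1)
    stop("EDF signals with mixed sampling rates are not supported")
  spr <- nSampPerRec[sigIdx[1]]
  fs <- spr / recDur
  gain <- (physMax - physMin) / (digMax - digMin)
  offset <- physMin - gain * digMin

  perRec <- sum(nSampPerRec)
  if (nRecords < 0) {  # unknown record count: infer from file size
    nRecords <- (file.size(path) - nHeader) %/% (2L * perRec)
  }
  allInt <- readBin(con, "integer", n = perRec * nRecords, size = 2L,
                    signed = TRUE, endian = "little")
  if (length(allInt) < perRec * nRecords)
    stop("EDF data truncated: ", path)
  starts <- c(0L, cumsum(nSampPerRec))
  data <- matrix(0, length(sigIdx), spr * nRecords)
  annText <- character(0)
  for (r in seq_len(nRecords)) {
    base <- (r - 1L) * perRec
    for (k in seq_along(sigIdx)) {
      s <- sigIdx[k]
      seg <- allInt[(base + starts[s] + 1L):(base + starts[s] + nSampPerRec[s])]
      data[k, ((r - 1L) * spr + 1L):(r * spr)] <- gain[s] * seg + offset[s]
    }
    for (s in which(isAnn)) {
      seg <- allInt[(base + starts[s] + 1L):(base + starts[s] + nSampPerRec[s])]
      # annotation samples are raw bytes packed as int16 pairs (little-endian);
      # NUL terminators are rewritten as newlines so the text survives rawToChar
      b <- as.raw(c(rbind(bitwAnd(seg, 255L), bitwAnd(bitwShiftR(bitwAnd(seg, 65535L), 8L), 255L))))
      b[b == as.raw(0)] <- as.raw(10)
      annText <- c(annText, rawToChar(b))
    }
  }
  uscale <- ifelse(tolower(units) %in% c("mv"), 1e3,
            ifelse(tolower(units) %in% c("v"), 1e6, 1))
  data <- data * uscale[sigIdx]

  events <- .parseEDFAnnotations(paste(annText, collapse = ""), fs,
                                 ncol(data))
  Recording(data, fs = fs, channelNames = labels[sigIdx], events = events,
            ekgPattern = ekgPattern)
}

.parseEDFAnnotations <- function(text, fs, nSamples) {
  if (!nzchar(text)) return(.emptyEvents())
  # TALs are separated by \x14 + NUL (NUL already rewritten as \n);
  # each is "+onset[\x15dur]\x14label\x14..."
  tals <- strsplit(gsub("\n+", "\n", text), "\x14\n", fixed = TRUE)[[1]]
  rows <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next   # timekeeping TAL without label
    onset <- suppressWarnings(as.numeric(strsplit(parts[1], "\x15",
                                                  fixed = TRUE)[[1]][1]))
    if (is.na(onset)) next
    labels <- parts[-1][nzchar(parts[-1])]
    for (lab in labels) {
      kind <- if (grepl("^(R128|Volume)", lab, ignore.case = TRUE))
        "volume_trigger"
      else if (grepl("stim", lab, ignore.case = TRUE)) "stimulus"
      else if (grepl("resp", lab, ignore.case = TRUE)) "response"
      else "other"
      rows[[length(rows) + 1L]] <-
        data.frame(sample = as.integer(round(onset * fs)) + 1L, kind = kind,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyEvents())
  ev <- do.call(rbind, rows)
  ev[ev$sample >= 1 & ev$sample <= nSamples, , drop = FALSE]
}
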
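# BrainVision (.vhdr/.vmrk/.eeg) reader. The header is INI-style; the data
# file is raw binary (INT_16 or IEEE_FLOAT_32), multiplexed or vectorized;
# marker positions are 1-based data points.

.parseIni <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "_"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      out[[section]][key] <- val
    }
  }
  out
}

.bvMarkerKind <- function(type, description,
                          volumePattern = "^(R128|T  1|Volume)") {
  type <- tolower(type)
  if (grepl(volumePattern, description) ||
      grepl(volumePattern, type, ignore.case = TRUE)) return("volume_trigger")
  if (type == "stimulus") return("stimulus")
  if (type == "response") return("response")
  "other"
}

.readBrainVision <- function(path, ekgPattern = "^(EKG|ECG)",
                             volumePattern = "^(R128|T  1|Volume)") {
  hdr <- .parseIni(readLines(path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci))
    stop("corrupt BrainVision header (no [Common Infos]): ", path)
  dirn <- dirname(path)
  dataFile <- file.path(dirn, ci[["DataFile"]])
  nCh <- as.integer(ci[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # interval is microseconds
  orientation <- toupper(ci[["DataOrientation"]])
  if (!identical(toupper(ci[["DataFormat"]]), "BINARY"))
    stop("only BINARY BrainVision data are supported")
  bi <- hdr[["Binary Infos"]]
  binFmt <- toupper(if (!is.null(bi)) bi[["BinaryFormat"]] else "INT_16")

  chInfo <- hdr[["Channel Infos"]]
  if (is.null(chInfo) || length(chInfo) < nCh)
    stop("BrainVision header lacks channel declarations")
  names_ <- character(nCh); resol <- rep(1, nCh); units <- rep("µV", nCh)
  for (i in seq_len(nCh)) {
    parts <- strsplit(chInfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    names_[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resol[i] <- as.numeric(parts[3])
    if (length(parts) >= 4 && nzchar(parts[4])) units[i] <- parts[4]
  }
  if (!file.exists(dataFile))
    stop("BrainVision data file missing: ", dataFile)

  sz <- file.size(dataFile)
  con <- file(dataFile, "rb")
  on.exit(close(con))
  if (binFmt == "INT_16") {
    n <- sz %/% 2L
    raw <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                   endian = "little")
  } else if (binFmt %in% c("IEEE_FLOAT_32", "FLOAT_32")) {
    n <- sz %/% 4L
    raw <- readBin(con, "double", n = n, size = 4L, endian = "little")
  } else stop("unsupported BinaryFormat: ", binFmt)
  nSamp <- length(raw) %/% nCh
  raw <- raw[seq_len(nSamp * nCh)]
  data <- if (identical(orientation, "VECTORIZED"))
    t(matrix(raw, nrow = nSamp)) else matrix(raw, nrow = nCh)
  data <- data * resol  # counts -> physical units, row-wise recycling is exact
  scale <- ifelse(tolower(units) %in% c("mv"), 1e3,
           ifelse(tolower(units) %in% c("v"), 1e6, 1))
  data <- data * scale

  events <- .emptyEvents()
  mrkFile <- ci[["MarkerFile"]]
  if (!is.null(mrkFile) && !is.na(mrkFile)) {
    mrkPath <- file.path(dirn, mrkFile)
    if (file.exists(mrkPath)) {
      mrk <- .parseIni(readLines(mrkPath, warn = FALSE))[["Marker Infos"]]
      if (!is.null(mrk) && length(mrk)) {
        rows <- lapply(unname(mrk), function(v) {
          parts <- strsplit(v, ",", fixed = TRUE)[[1]]
          if (length(parts) < 3) return(NULL)
          data.frame(sample = as.integer(parts[3]),
                     kind = .bvMarkerKind(parts[1], parts[2], volumePattern),
                     stringsAsFactors = FALSE)
        })
        events <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
        if (is.null(events)) events <- .emptyEvents()
        events <- events[events$sample >= 1 & events$sample <= nSamp, ,
                         drop = FALSE]
      }
    }
  }
  Recording(data, fs = fs, channelNames = names_, events = events,
            ekgPattern = ekgPattern)
}
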
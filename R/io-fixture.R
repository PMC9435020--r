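#' Write a recording to the package fixture format
#'
#' The fixture is a directory holding \code{recording.json} (sampling rate,
#' channel names and roles, events, array shape, byte order) and
#' \code{data.bin} (the channels-by-samples matrix as little-endian IEEE-754
#' doubles, channel index varying fastest). Round trips through
#' \code{\link{readRecording}} are bit-exact.
#'
#' @param rec a \linkS4class{Recording}.
#' @param path directory to create (conventionally with extension ".fx").
#' @return invisibly, \code{path}.
#' @export
writeFixture <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  validObject(rec)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create fixture directory: ", path)
  meta <- list(
    format = "dmhbcg-fixture",
    version = 1L,
    fs = rec@fs,
    n_channels = nrow(rec@data),
    n_samples = ncol(rec@data),
    channel_names = as.list(rec@channelNames),
    channel_roles = as.list(rec@channelRoles),
    events = if (nrow(rec@events)) rec@events else NULL,
    dtype = "float64",
    byte_order = "little",
    layout = "channel_major"
  )
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec@data), con, size = 8L, endian = "little")
  invisible(path)
}

.readFixture <- function(path) {
  metaPath <- file.path(path, "recording.json")
  binPath <- file.path(path, "data.bin")
  if (!file.exists(metaPath) || !file.exists(binPath))
    stop("not a dmhbcg fixture (missing recording.json or data.bin): ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$format, "dmhbcg-fixture"))
    stop("unrecognized fixture format tag: ", meta$format)
  n <- as.integer(meta$n_channels) * as.integer(meta$n_samples)
  con <- file(binPath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(raw) != n)
    stop("fixture data.bin truncated: expected ", n, " doubles, got ",
         length(raw))
  data <- matrix(raw, nrow = as.integer(meta$n_channels))
  ev <- meta$events
  if (is.null(ev) || length(ev) == 0) ev <- .emptyEvents()
  Recording(data, fs = meta$fs,
            channelNames = unlist(meta$channel_names),
            channelRoles = unlist(meta$channel_roles),
            events = ev)
}

#' Read a recording from disk
#'
#' Supported formats: BrainVision (a .vhdr header referencing .eeg data and
#' .vmrk markers), EDF/EDF+ continuous recordings, and the package fixture
#' format written by \code{\link{writeFixture}}. Amplitudes are converted to
#' microvolts on load. Channels whose label matches \code{ekgPattern}
#' (case-insensitive) are tagged EKG; when none matches a warning is issued
#' (BCG suppression later fails loudly without an EKG channel).
#'
#' @param path file (or fixture directory) to read.
#' @param format one of "auto", "brainvision", "edf", "fixture".
#' @param ekgPattern regular expression for EKG channel labels.
#' @return a \linkS4class{Recording}.
#' @export
readRecording <- function(path, format = c("auto", "brainvision", "edf",
                                           "fixture"),
                          ekgPattern = "^(EKG|ECG)") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "fixture"
      else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
      else if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
      else stop("cannot infer format of ", path,
                " (expected .vhdr, .edf or a fixture directory)")
  }
  rec <- switch(format,
    fixture = .readFixture(path),
    brainvision = .readBrainVision(path, ekgPattern),
    edf = .readEDF(path, ekgPattern))
  if (!any(rec@channelRoles == "EKG"))
    warning("no EKG channel identified in ", path,
            " (pattern '", ekgPattern, "')")
  rec
}
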
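# BrainVision triplet (.vhdr header, .vmrk markers, .eeg binary data)
# reader/writer. The header is an INI-style text file; the data file holds
# either IEEE float32 or int16 samples, multiplexed (channel fastest) or
# vectorized. Units are normalised to microvolts on read.

#' Write a recording as a BrainVision triplet
#'
#' Emits `.vhdr`/`.vmrk`/`.eeg` files with IEEE float32 multiplexed data in
#' microvolts.
#'
#' @param rec a [raw_recording()].
#' @param path path of the header file (`.vhdr`); sibling `.eeg` and
#'   `.vmrk` files are written next to it.
#' @return the header path, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stop_if(!inherits(rec, "raw_recording"), "rec must be a raw_recording")
  stop_if(!grepl("\\.vhdr$", path, ignore.case = TRUE), "path must end in .vhdr")
  base <- sub("\\.vhdr$", "", basename(path), ignore.case = TRUE)
  dir <- dirname(path)
  ns <- nrow(rec$data)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", ns),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(ns), rec$labels)
  )
  writeLines(hdr, file.path(dir, paste0(base, ".vhdr")))
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  ), file.path(dir, paste0(base, ".vmrk")))

  con <- file(file.path(dir, paste0(base, ".eeg")), "wb")
  on.exit(close(con))
  # column-major over a channels x samples matrix == multiplexed order
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(path)
}

bv_parse_header <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  stop_if(!grepl("Brain Vision Data Exchange Header", lines[1L],
                 ignore.case = TRUE), "not a BrainVision header: ", path)
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  section <- ""
  kv <- list(); chans <- character()
  for (ln in lines[-1L]) {
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("\\[|\\]", "", trimws(ln)))
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (section == "channel infos") chans[key] <- val else kv[[tolower(key)]] <- val
    }
  }
  list(kv = kv, chans = chans)
}

read_brainvision <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  h <- bv_parse_header(path)
  kv <- h$kv
  stop_if(is.null(kv$datafile), "BrainVision header lacks DataFile: ", path)
  datafile <- file.path(dirname(path), basename(gsub("\\\\", "/", kv$datafile)))
  stop_if(!file.exists(datafile),
          "BrainVision data file missing (mismatched pair): ", datafile)
  stop_if(!identical(toupper(kv$dataformat %||% "BINARY"), "BINARY"),
          "only binary BrainVision data is supported")

  nchan <- as.integer(kv$numberofchannels)
  si_us <- as.numeric(kv$samplinginterval)
  stop_if(is.na(nchan) || nchan < 1L || is.na(si_us) || si_us <= 0,
          "malformed BrainVision header: ", path)
  fs <- 1e6 / si_us
  fmt <- toupper(kv$binaryformat %||% "IEEE_FLOAT_32")
  orient <- toupper(kv$dataorientation %||% "MULTIPLEXED")

  info <- strsplit(h$chans, ",", fixed = TRUE)
  stop_if(length(info) != nchan, "channel count mismatch in header: ", path)
  labels <- vapply(info, function(f) gsub("\\\\1", ",", f[1L]), "")
  res <- vapply(info, function(f)
    if (length(f) >= 3L && nzchar(f[3L])) as.numeric(f[3L]) else 1, 1)
  unit <- vapply(info, function(f)
    if (length(f) >= 4L && nzchar(f[4L])) f[4L] else "µV", "")

  sz <- file.info(datafile)$size
  bytes <- if (fmt == "INT_16") 2L else 4L
  nval <- sz %/% bytes
  stop_if(nval < nchan || nval %% nchan != 0,
          "BrainVision data size inconsistent with channel count: ", datafile)
  nsamp <- nval %/% nchan

  con <- file(datafile, "rb")
  on.exit(close(con))
  raw <- switch(fmt,
    IEEE_FLOAT_32 = readBin(con, "numeric", n = nval, size = 4L, endian = "little"),
    INT_16 = readBin(con, "integer", n = nval, size = 2L, signed = TRUE,
                     endian = "little"),
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE))
  stop_if(length(raw) != nval, "truncated BrainVision data: ", datafile)

  data <- if (orient == "MULTIPLEXED") matrix(raw, nrow = nchan)
          else if (orient == "VECTORIZED") t(matrix(raw, ncol = nchan))
          else stop("unsupported DataOrientation: ", orient, call. = FALSE)
  data <- data * res
  uscale <- vapply(unit, function(u)
    switch(tolower(u), "mv" = 1e3, "v" = 1e6, 1), 1)
  data <- data * uscale
  raw_recording(data, fs = fs, labels = make.unique(labels))
}

#' Read an EEG recording from disk
#'
#' Dispatches on format (or file extension when `format = "auto"`) to the
#' EDF or BrainVision reader. Data are returned in microvolts; non-finite
#' samples raise an error at ingestion.
#'
#' @param path file path: an `.edf` file or a BrainVision `.vhdr` header.
#' @param format one of `"auto"`, `"edf"`, `"brainvision"`.
#' @return a [raw_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     stop("cannot infer format from extension: ", ext,
                          call. = FALSE))
  }
  switch(format, edf = read_edf(path), brainvision = read_brainvision(path))
}
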
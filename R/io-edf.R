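# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a 256-byte fixed header, one 256-byte header block per signal,
# then data records of little-endian 16-bit integers, signal by signal
# within each record. Values are mapped between physical and digital range
# per signal. The writer emits 1-second records, so it requires an integral
# sampling rate; the reader handles any record duration but requires all
# signals to share a sampling rate (the pipeline assumes a rectangular
# channels x samples matrix).

edf_pad <- function(x, width) {
  x <- as.character(x)
  stop_if(nchar(x) > width, "EDF header field too wide: ", x)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with 1-second data records and per-channel physical
#' scaling in microvolts. Mainly intended for fixtures, round-trip tests and
#' exporting synthetic cohorts; quantisation error is bounded by the
#' per-channel physical range divided by 2^16.
#'
#' @param rec a [raw_recording()]; `rec$fs` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stop_if(!inherits(rec, "raw_recording"), "rec must be a raw_recording")
  fs <- rec$fs
  stop_if(abs(fs - round(fs)) > 1e-9, "EDF writer requires an integral sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  nrec <- ncol(rec$data) %/% fs
  stop_if(nrec < 1L, "recording shorter than one EDF data record (1 s)")

  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmax[flat] + 1
  pmin[flat] <- pmin[flat] - 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad("1", 8), edf_pad(ns, 4),
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad("-32768", 8), ns), collapse = ""),
    paste(rep(edf_pad("32767", 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  gain <- (pmax - pmin) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((rec$data[s, idx] - pmin[s]) / gain[s]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  sz <- file.info(path)$size
  stop_if(sz < 256, "not an EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256L, useBytes = TRUE)
  getf <- function(str, from, len) trimws(substr(str, from, from + len - 1L))
  hdr_bytes <- suppressWarnings(as.integer(getf(fixed, 185, 8)))
  nrec <- suppressWarnings(as.integer(getf(fixed, 237, 8)))
  recdur <- suppressWarnings(as.numeric(getf(fixed, 245, 8)))
  ns <- suppressWarnings(as.integer(getf(fixed, 253, 4)))
  stop_if(is.na(ns) || ns < 1L || is.na(nrec) || is.na(recdur) || recdur <= 0,
          "malformed EDF header: ", path)
  stop_if(sz < 256 * (1 + ns), "truncated EDF signal headers: ", path)

  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  fld <- function(off, len) {
    vapply(seq_len(ns) - 1L, function(i)
      trimws(substr(sig, off + i * len + 1L, off + (i + 1L) * len)), "")
  }
  labels <- fld(0L, 16L)
  units <- fld(ns * (16L + 80L), 8L)
  pminv <- as.numeric(fld(ns * (16L + 80L + 8L), 8L))
  pmaxv <- as.numeric(fld(ns * (16L + 80L + 8L + 8L), 8L))
  dminv <- as.numeric(fld(ns * (16L + 80L + 8L + 8L + 8L), 8L))
  dmaxv <- as.numeric(fld(ns * (16L + 80L + 8L + 8L + 8L + 8L), 8L))
  spr <- as.integer(fld(ns * (16L + 80L + 8L * 5L + 80L), 8L))
  stop_if(any(is.na(c(pminv, pmaxv, dminv, dmaxv, spr))) || any(spr < 1L),
          "malformed EDF signal header: ", path)
  stop_if(length(unique(spr)) != 1L,
          "EDF signals with differing sampling rates are not supported")
  stop_if(any(dmaxv <= dminv), "malformed EDF digital range: ", path)

  expected <- (if (!is.na(hdr_bytes)) hdr_bytes else 256 * (1 + ns)) +
    as.numeric(nrec) * sum(spr) * 2
  stop_if(nrec >= 0 && sz < expected, "truncated EDF data records: ", path)
  if (nrec < 0) nrec <- as.integer((sz - 256 * (1 + ns)) %/% (sum(spr) * 2))

  data <- matrix(0, nrow = ns, ncol = nrec * spr[1L])
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      stop_if(length(dig) != spr[s], "truncated EDF data record: ", path)
      phys <- pminv[s] + (dig - dminv[s]) *
        (pmaxv[s] - pminv[s]) / (dmaxv[s] - dminv[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  scale <- vapply(units, function(u) switch(tolower(u), "mv" = 1e3, "v" = 1e6, 1), 1)
  data <- data * scale
  raw_recording(data, fs = spr[1L] / recdur, labels = make.unique(labels))
}
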
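#' Construct a raw EEG recording
#'
#' The basic container used throughout the pipeline: a channels-by-samples
#' matrix of voltages in microvolts plus its sampling rate and channel
#' labels. Ingestion is strict: non-finite samples are an error rather than
#' being silently imputed, since every downstream feature assumes finite
#' input.
#'
#' @param data numeric matrix, channels in rows, samples in columns (uV).
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of unique channel names; defaults to the
#'   rownames of `data`.
#' @return an object of class `raw_recording` with elements `data`, `fs`
#'   and `labels`.
#' @export
raw_recording <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  stop_if(!is.numeric(data) || nrow(data) < 1L, "data must be a numeric channels x samples matrix")
  stop_if(!is.numeric(fs) || length(fs) != 1L || fs <= 0, "fs must be a positive scalar")
  stop_if(is.null(labels), "channel labels are required")
  labels <- as.character(labels)
  stop_if(length(labels) != nrow(data), "one label per channel is required")
  stop_if(anyDuplicated(labels) > 0L, "channel labels must be unique")
  stop_if(!all(is.finite(data)), "non-finite samples in recording")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, rec_duration(x)))
  cat("  channels:", paste(head(x$labels, 8L), collapse = ", "),
      if (length(x$labels) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [raw_recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Number of channels in a recording
#' @param rec a [raw_recording()].
#' @return integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$data)
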
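#' Construct an EEG recording
#'
#' The in-memory container used throughout the package: a channels x samples
#' matrix in microvolts plus channel labels, sampling rate and free-form
#' provenance. All channels share one sample count; time is indexed by 0-based
#' sample number and intervals are half-open `[start, end)`.
#'
#' @param data_uv Numeric matrix, channels x samples, in microvolts.
#' @param fs_hz Sampling rate in samples/second (> 0).
#' @param labels Character vector of unique channel names (10-20 convention
#'   plus T1/T2 expected for clinical scalp EEG, but arbitrary names are
#'   accepted). Defaults to the rownames of `data_uv`.
#' @param start_time Optional `POSIXct` wall-clock start, or `NULL`.
#' @param reference Free-text montage description; clinical input is expected
#'   to be referential.
#' @param meta Named list of provenance records (processing steps applied,
#'   warnings, source file).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data_uv, fs_hz, labels = rownames(data_uv),
                          start_time = NULL, reference = "referential",
                          meta = list()) {
  data_uv <- as.matrix(data_uv)
  if (is.null(labels)) {
    labels <- paste0("CH", seq_len(nrow(data_uv)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(data_uv)) {
    stop("`labels` must name every row of `data_uv` (",
         nrow(data_uv), " channels, ", length(labels), " labels)")
  }
  if (anyDuplicated(labels)) {
    stop("channel labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive number")
  }
  if (!all(is.finite(data_uv))) {
    stop("`data_uv` must be finite (no NA/NaN/Inf)")
  }
  storage.mode(data_uv) <- "double"
  rownames(data_uv) <- labels
  structure(
    list(data_uv = data_uv, fs_hz = as.numeric(fs_hz), labels = labels,
         start_time = start_time, reference = reference, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- ncol(x$data_uv)
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data_uv), n, x$fs_hz, n / x$fs_hz))
  cat("  labels:", paste(utils::head(x$labels, 8), collapse = " "),
      if (length(x$labels) > 8) "..." else "", "\n")
  cat("  reference:", x$reference, "\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / channels / duration of a recording
#' @param rec An `eeg_recording`.
#' @return Integer sample count, integer channel count, or duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$data_uv)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data_uv)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data_uv) / rec$fs_hz

#' Select (and reorder) channels of a recording
#'
#' @param rec An `eeg_recording`.
#' @param wanted Character vector of labels, a subset of `rec$labels`, in the
#'   desired output order.
#' @return The sub-recording in the requested order, invariants preserved.
#' @export
select_channels <- function(rec, wanted) {
  stopifnot(inherits(rec, "eeg_recording"))
  wanted <- as.character(wanted)
  unknown <- setdiff(wanted, rec$labels)
  if (length(unknown)) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  idx <- match(wanted, rec$labels)
  eeg_recording(rec$data_uv[idx, , drop = FALSE], rec$fs_hz, labels = wanted,
                start_time = rec$start_time, reference = rec$reference,
                meta = rec$meta)
}

# Append a provenance entry to a recording's meta (internal).
add_provenance <- function(rec, step) {
  rec$meta$provenance <- c(rec$meta$provenance, step)
  rec
}
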
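# Artifact-epoch detection and channel-quality screening.
#
# The muscle-artifact epoch is found on a single composite envelope: per
# channel, the Hilbert envelope of the 16-70 Hz band is z-scored over the
# whole record, the z-scores are averaged across channels, and the average is
# smoothed. Suspected high-impedance channels are those whose 16-70 Hz signal
# during that epoch shares (almost) no information with any other electrode,
# measured by normalized mutual information.

#' Composite normalized envelope of a band-passed recording
#'
#' Per channel: Hilbert envelope, then z-score over the whole record
#' (subtract mean, divide by SD); the z-scores are averaged across channels
#' and smoothed with a centered moving average. The result is a single series
#' in SD-of-envelope units, robust to per-channel gain.
#'
#' @param bandpassed The 16-70 Hz filtered [eeg_recording()].
#' @param smooth_window_s Smoothing window in seconds (default 0.5); the
#'   window sample count is forced odd.
#' @return Numeric series, one value per sample, in SD units.
#' @export
composite_envelope <- function(bandpassed, smooth_window_s = 0.5) {
  stopifnot(inherits(bandpassed, "eeg_recording"))
  env <- t(apply(bandpassed$data_uv, 1, hilbert_envelope))
  sds <- apply(env, 1, stats::sd)
  dead <- sds == 0
  if (all(dead)) stop("all channels have zero envelope variance")
  if (any(dead)) {
    warning("channel(s) with zero envelope variance omitted from composite: ",
            paste(bandpassed$labels[dead], collapse = ", "))
    env <- env[!dead, , drop = FALSE]
    sds <- sds[!dead]
  }
  z <- (env - rowMeans(env)) / sds
  comp <- colMeans(z)
  w <- max(1L, round(smooth_window_s * bandpassed$fs_hz))
  if (w %% 2 == 0) w <- w + 1L
  w <- min(w, length(comp) - (1 - length(comp) %% 2))
  if (w %% 2 == 0) w <- w - 1L
  moving_average(comp, w)
}

#' Longest run of the envelope above a threshold
#'
#' Returns the maximal-length run of consecutive samples strictly greater
#' than `threshold_sd`; ties are broken by earliest start. `NULL` when no
#' sample exceeds the threshold.
#'
#' @param envelope Composite envelope in SD units.
#' @param threshold_sd Threshold, default 1 SD.
#' @return An `artifact_epoch` (fields `start_sample`, `end_sample` forming a
#'   0-based half-open interval, and `peak_sd`), or `NULL`.
#' @export
longest_suprathreshold_epoch <- function(envelope, threshold_sd = 1) {
  above <- envelope > threshold_sd
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max -> earliest on ties
  s <- starts[best]; e <- ends[best]
  structure(list(start_sample = s - 1L, end_sample = e,
                 peak_sd = max(envelope[s:e])),
            class = "artifact_epoch")
}

#' @export
print.artifact_epoch <- function(x, ...) {
  cat(sprintf("<artifact_epoch> [%d, %d) (%d samples), peak %.2f SD\n",
              x$start_sample, x$end_sample, x$end_sample - x$start_sample,
              x$peak_sd))
  invisible(x)
}

#' Normalized mutual information of two series
#'
#' Plug-in estimate from a joint histogram with `n_bins` equal-width bins per
#' axis spanning each series' own range; mutual information in nats,
#' normalized as I / sqrt(H(X) H(Y)) and clipped to \[0, 1\]. The binning makes
#' the value invariant to affine rescaling of either input.
#'
#' @param x,y Equal-length numeric series, each non-constant, length >= `n_bins`.
#' @param n_bins Bins per axis (default 16).
#' @return Value in \[0, 1\].
#' @export
normalized_mi <- function(x, y, n_bins = 16) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n < n_bins) stop("need at least `n_bins` samples")
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("zero entropy: constant input series (exclude dead channels first)")
  }
  bin <- function(v) {
    br <- seq(min(v), max(v), length.out = n_bins + 1)
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  ix <- bin(x); iy <- bin(y)
  joint <- tabulate((ix - 1L) * n_bins + iy, nbins = n_bins * n_bins) / n
  px <- tabulate(ix, nbins = n_bins) / n
  py <- tabulate(iy, nbins = n_bins) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py)
  i_xy <- hx + hy - ent(joint)
  min(max(i_xy / sqrt(hx * hy), 0), 1)
}

#' Normalized-MI adjacency matrix over the artifact epoch
#'
#' Entry (i, j), i != j, is the normalized MI between channels i and j of the
#' band-passed recording restricted to the epoch; the diagonal is 0 so that
#' row maxima exclude self-information.
#'
#' @param rec The 16-70 Hz filtered [eeg_recording()].
#' @param epoch An `artifact_epoch` within the record.
#' @param n_bins Histogram bins per axis (default 16).
#' @return Symmetric `n_channels x n_channels` matrix with zero diagonal.
#' @export
mi_adjacency <- function(rec, epoch, n_bins = 16) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- epoch$end_sample - epoch$start_sample
  if (epoch$start_sample < 0 || epoch$end_sample > n_samples(rec)) {
    stop("epoch lies outside the recording")
  }
  if (len < 4 * n_bins) {
    stop("artifact epoch too short for a ", n_bins, "-bin MI histogram (",
         len, " < ", 4 * n_bins, " samples); use a longer epoch or fewer bins")
  }
  seg <- rec$data_uv[, (epoch$start_sample + 1L):epoch$end_sample, drop = FALSE]
  k <- nrow(seg)
  adj <- matrix(0, k, k, dimnames = list(rec$labels, rec$labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      adj[i, j] <- adj[j, i] <- normalized_mi(seg[i, ], seg[j, ], n_bins)
    }
  }
  adj
}

#' Screen channels by their maximum pairwise normalized MI
#'
#' Each channel gets the maximum of its adjacency row; it is included iff
#' that maximum is at least `inclusion_threshold`. If every channel would be
#' excluded the report switches to fallback: all channels included, with the
#' fallback flag set (the same fallback used when no artifact epoch exists).
#'
#' @param adjacency Symmetric MI matrix from [mi_adjacency()].
#' @param inclusion_threshold Inclusion cutoff in \[0, 1\] (default 0.2).
#' @return A `channel_quality_report`: `max_nmi`, `included`, `threshold`,
#'   `epoch_used` (filled by the pipeline), `fallback`.
#' @export
screen_channels <- function(adjacency, inclusion_threshold = 0.2) {
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency matrix must be symmetric")
  }
  max_nmi <- apply(adjacency, 1, max)
  included <- max_nmi >= inclusion_threshold
  fallback <- !any(included)
  if (fallback) included[] <- TRUE
  structure(list(max_nmi = max_nmi, included = included,
                 threshold = inclusion_threshold, epoch_used = NULL,
                 fallback = fallback,
                 estimator = list(kind = "equal-width histogram",
                                  normalization = "I/sqrt(Hx*Hy)")),
            class = "channel_quality_report")
}

#' @export
print.channel_quality_report <- function(x, ...) {
  cat(sprintf("<channel_quality_report> %d/%d channels included (threshold %.2f)%s\n",
              sum(x$included), length(x$included), x$threshold,
              if (x$fallback) " [FALLBACK: all channels]" else ""))
  excl <- names(x$included)[!x$included]
  if (length(excl)) cat("  excluded:", paste(excl, collapse = ", "), "\n")
  invisible(x)
}
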
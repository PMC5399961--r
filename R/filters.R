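# FIR design and zero-phase application, band splitting at 16 Hz, Hilbert
# envelope and moving-average smoothing. Filtering is deliberately restricted
# to even-order linear-phase windowed-sinc designs: the band split is only
# meaningful if both bands stay time-aligned with the raw trace.

#' Design a linear-phase FIR filter (Hamming windowed-sinc)
#'
#' Wraps the classic FIR1 design: an even-order symmetric windowed-sinc with a
#' Hamming window, scaled so a lowpass has unit DC gain and a bandpass has
#' unit gain at the band center.
#'
#' @param kind One of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @param cutoffs_hz One corner frequency (low/high-pass) or two (bandpass),
#'   strictly inside (0, fs/2).
#' @param order Filter order; must be even (taps = order + 1). Default 500,
#'   the order used for both the 16-70 Hz analysis band and the 16 Hz split.
#' @param fs_hz Sampling rate the design is for.
#' @return A `fir_filter` object: `taps`, `kind`, `cutoffs_hz`, `order`, `fs_hz`.
#' @export
design_fir <- function(kind = c("lowpass", "highpass", "bandpass"),
                       cutoffs_hz, order = 500, fs_hz) {
  kind <- match.arg(kind)
  if (order %% 2 != 0 || order < 2) {
    stop("`order` must be an even integer >= 2 (symmetric linear-phase design)")
  }
  nyq <- fs_hz / 2
  if (any(cutoffs_hz <= 0) || any(cutoffs_hz >= nyq)) {
    stop("cutoff(s) must lie strictly inside (0, ", nyq, ") Hz")
  }
  n_cut <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs_hz) != n_cut) {
    stop(kind, " design needs ", n_cut, " cutoff(s), got ", length(cutoffs_hz))
  }
  if (kind == "bandpass" && cutoffs_hz[1] >= cutoffs_hz[2]) {
    stop("bandpass cutoffs must be increasing")
  }
  type <- switch(kind, lowpass = "low", highpass = "high", bandpass = "pass")
  taps <- as.numeric(signal::fir1(order, sort(cutoffs_hz) / nyq, type = type))
  if (kind == "lowpass") taps <- taps / sum(taps)  # exact unit DC gain
  structure(list(taps = taps, kind = kind, cutoffs_hz = cutoffs_hz,
                 order = order, fs_hz = fs_hz),
            class = "fir_filter")
}

#' Frequency response of a FIR filter
#'
#' Direct discrete-frequency evaluation of the taps,
#' H(f) = sum_k taps\[k\] exp(-i 2 pi f k / fs).
#'
#' @param filt A `fir_filter`.
#' @param freqs_hz Frequencies at which to evaluate.
#' @return Complex response vector.
#' @export
fir_response <- function(filt, freqs_hz) {
  k <- seq_along(filt$taps) - 1
  vapply(freqs_hz, function(f) {
    sum(filt$taps * exp(-2i * pi * f * k / filt$fs_hz))
  }, complex(1))
}

# Zero-phase filter of one numeric vector: causal convolution on a
# reflection-padded copy, then advance by the group delay order/2.
zero_phase_one <- function(x, taps) {
  L <- length(taps) - 1L
  h <- L %/% 2L
  n <- length(x)
  if (n <= L) {
    stop("signal length (", n, ") must exceed the filter order (", L,
         "); use a shorter filter")
  }
  xp <- c(x[(L + 1):2], x, x[(n - 1):(n - L)])
  y <- stats::filter(xp, taps, method = "convolution", sides = 1)
  as.numeric(y[(L + h + 1):(L + h + n)])
}

#' Apply a FIR filter with zero-phase alignment
#'
#' Each channel is convolved with the taps and advanced by the group delay
#' (order/2 samples) so the output is time-aligned with the input; edges are
#' padded by signal reflection. Output length equals input length.
#'
#' @param rec An [eeg_recording()].
#' @param filt A [design_fir()] filter with matching `fs_hz`.
#' @return The filtered recording.
#' @export
apply_zero_phase <- function(rec, filt) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(filt, "fir_filter"))
  if (abs(filt$fs_hz - rec$fs_hz) > 1e-9) {
    stop("filter designed for ", filt$fs_hz, " Hz but recording is ",
         rec$fs_hz, " Hz")
  }
  out <- rec
  out$data_uv <- t(apply(rec$data_uv, 1, zero_phase_one, taps = filt$taps))
  dimnames(out$data_uv) <- dimnames(rec$data_uv)
  add_provenance(out, sprintf("%s FIR order %d at %s Hz, zero-phase",
                              filt$kind, filt$order,
                              paste(filt$cutoffs_hz, collapse = "-")))
}

#' Split a recording into complementary <cutoff and >cutoff bands
#'
#' The low band is the zero-phase lowpass at `cutoff_hz`; the high band is the
#' exact remainder `rec - low`, so `low + high` reconstructs the input to
#' machine precision by construction. (The two bands differ from independently
#' designed low/high-pass filters only inside the filter transition band;
#' the construction guarantees perfect reconstitution when nothing is pruned.)
#'
#' @param rec An [eeg_recording()].
#' @param cutoff_hz Split frequency, default 16 Hz.
#' @param order FIR order, default 500.
#' @return List with elements `low` and `high`, both [eeg_recording()]s.
#' @export
split_complementary <- function(rec, cutoff_hz = 16, order = 500) {
  lp <- design_fir("lowpass", cutoff_hz, order, rec$fs_hz)
  low <- apply_zero_phase(rec, lp)
  high <- rec
  high$data_uv <- rec$data_uv - low$data_uv
  high <- add_provenance(high, sprintf(
    "high band = raw - lowpass(%g Hz) complement", cutoff_hz))
  list(low = low, high = high)
}

#' Hilbert envelope (instantaneous amplitude) of one series
#'
#' Modulus of the analytic signal, built in the frequency domain by zeroing
#' negative frequencies and doubling positive ones; length preserved.
#'
#' @param x Finite numeric vector, length >= 4.
#' @return Nonnegative envelope vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for a Hilbert envelope")
  if (!all(is.finite(x))) stop("non-finite input to hilbert_envelope")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Centered moving average with shrinking edge windows
#'
#' @param x Numeric vector.
#' @param window_samples Odd window length, at most `length(x)`.
#' @return Smoothed vector, same length; near the edges the window shrinks to
#'   whatever is available so no samples are dropped.
#' @export
moving_average <- function(x, window_samples) {
  n <- length(x)
  w <- as.integer(window_samples)
  if (w %% 2 == 0) stop("`window_samples` must be odd, got ", w)
  if (w > n) stop("`window_samples` (", w, ") exceeds series length (", n, ")")
  if (w == 1L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
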
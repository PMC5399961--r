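# Shared fixtures and independent oracles used across test files.

# A recording holding given channel waveforms (rows).
mk_rec <- function(mat, fs = 200, labels = NULL) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(mat)))
  eeg_recording(mat, fs, labels = labels)
}

time_axis <- function(n, fs = 200) (seq_len(n) - 1) / fs

# Brute-force oracle: longest maximal run of samples strictly above a
# threshold, scanning sample by sample (independent of the rle-based
# implementation). Returns c(start0, end0) half-open, or NULL.
scan_longest_run <- function(env, thr) {
  best_len <- 0L; best_start <- NA_integer_
  cur_len <- 0L; cur_start <- NA_integer_
  for (i in seq_along(env)) {
    if (env[i] > thr) {
      if (cur_len == 0L) cur_start <- i
      cur_len <- cur_len + 1L
      if (cur_len > best_len) { best_len <- cur_len; best_start <- cur_start }
    } else {
      cur_len <- 0L
    }
  }
  if (best_len == 0L) return(NULL)
  c(best_start - 1L, best_start - 1L + best_len)
}

# Brute-force oracle for normalized MI: explicit double loop over the joint
# count table built from hand-assigned equal-width bins.
enum_nmi <- function(x, y, n_bins) {
  assign_bins <- function(v) {
    lo <- min(v); hi <- max(v)
    w <- (hi - lo) / n_bins
    b <- floor((v - lo) / w) + 1
    b[b > n_bins] <- n_bins
    b
  }
  bx <- assign_bins(x); by <- assign_bins(y)
  n <- length(x)
  counts <- matrix(0, n_bins, n_bins)
  for (k in seq_len(n)) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1
  pj <- counts / n
  px <- rowSums(pj); py <- colSums(pj)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (px[i] * py[j]))
  }
  mi / sqrt(H(px) * H(py))
}

# Hand-build a minimal EDF file from explicit header values and digital
# samples (list of integer vectors, one per signal). Used to test the reader
# against the scaling formula applied by hand.
build_edf_fixture <- function(path, labels, phys_min, phys_max, dig_min,
                              dig_max, spr, record_dur, digital,
                              phys_dim = NULL) {
  ns <- length(labels)
  if (is.null(phys_dim)) phys_dim <- rep("uV", ns)
  n_records <- length(digital[[1]]) / spr[1]
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeBin(charToRaw(formatC(substr(s, 1, w), width = -w)), con)
  put("0", 8); put("X", 80); put("fixture", 80)
  put("01.01.20", 8); put("00.00.00", 8)
  put(as.character(256 * (ns + 1)), 8); put("", 44)
  put(as.character(n_records), 8); put(as.character(record_dur), 8)
  put(as.character(ns), 4)
  for (l in labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (d in phys_dim) put(d, 8)
  for (v in phys_min) put(as.character(v), 8)
  for (v in phys_max) put(as.character(v), 8)
  for (v in dig_min) put(as.character(v), 8)
  for (v in dig_max) put(as.character(v), 8)
  for (i in seq_len(ns)) put("", 80)
  for (v in spr) put(as.character(v), 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- digital[[i]][((r - 1) * spr[i] + 1):(r * spr[i])]
      writeBin(as.integer(seg), con, size = 2, endian = "little")
    }
  }
  path
}

# Small synthetic scene used by pipeline-level unit tests (same generator as
# the full demo scene, shorter so the suite stays quick).
small_scene_config <- function(seed = 1, ...) {
  scene_config(duration_s = 60, ictal = list(onset_s = 25), seed = seed, ...)
}
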
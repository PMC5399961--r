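# Seeded synthetic ictal-EEG scenes with exact ground truth.
#
# A scene is the exact sum of four channels x samples matrices:
#   neurogenic  - a narrowband ictal rhythm with a smooth (distributed)
#                 scalp topography, ramping up at seizure onset;
#   emg         - band-limited noise bursts with a fixed focal topography
#                 (1-2 electrodes over the generating muscle);
#   badnoise    - white noise replacing any "bad" channel entirely;
#   background  - independent per-channel 1/f-weighted noise.
# This emulates exactly the spatial/spectral contrast the cleaning method
# exploits (focal broadband myogenic vs distributed narrowband neurogenic);
# it does not model volume conduction through a head model, ocular/ECG
# artifacts, or nonstationary electrode impedance.

# Schematic 2-D coordinates of the 10-20 montage (plus T1/T2) on a unit head
# radius; a fixture choice used only to compute topography spread.
LAYOUT_1020 <- local({
  deg <- pi / 180
  ring <- function(angle_deg, r = 1) c(-r * sin(angle_deg * deg), r * cos(angle_deg * deg))
  m <- rbind(
    Fp1 = ring(18), Fp2 = ring(-18),
    F7 = ring(54),  F8 = ring(-54),
    T3 = ring(90),  T4 = ring(-90),
    T5 = ring(126), T6 = ring(-126),
    O1 = ring(162), O2 = ring(-162),
    F3 = c(-0.40, 0.50), F4 = c(0.40, 0.50),
    C3 = c(-0.50, 0.00), C4 = c(0.50, 0.00),
    P3 = c(-0.40, -0.50), P4 = c(0.40, -0.50),
    Fz = c(0, 0.50), Cz = c(0, 0), Pz = c(0, -0.50),
    T1 = c(-0.95, 0.25), T2 = c(0.95, 0.25)
  )
  colnames(m) <- c("x", "y")
  m
})

#' Standard 19-channel 10-20 label set
#' @return Character vector of labels in clinical display order.
#' @export
labels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Configure a synthetic ictal scene
#'
#' Defaults describe the scene used throughout the package's tests: a
#' 19-channel 10-20 montage at 200 Hz for 300 s; a 22 Hz ictal rhythm of
#' 50 uV starting at 120 s over F3 with a smooth Gaussian spatial spread
#' (sigma 1.3 head radii, a genuinely distributed topography) that waxes and
#' wanes in 5-s runs (60% duty), as recruiting rhythms do; temporalis EMG
#' bursts on F7/T3 (spatial weights 1 and 0.6) of 20-95 Hz noise at 60 uV
#' occurring during the seizure; and 8 uV RMS of spatially smoothed 1/f
#' background per channel (scalp potentials are volume-conducted, so
#' neighboring electrodes share background).
#'
#' @param labels Channel labels (must exist in the embedded 10-20 layout).
#' @param fs_hz Sampling rate (default 200).
#' @param duration_s Scene length in seconds (default 300).
#' @param ictal List: `onset_s`, `onset_channel`, `freq_hz`, `amplitude_uv`,
#'   `spread_sigma` (head-radius units), `ramp_s`, `burst_period_s`,
#'   `burst_duty` (the waxing/waning run structure of the rhythm).
#' @param emg List: `electrodes` (1-2 labels), `weights`, `band_hz` (above
#'   16 Hz), `amplitude_uv`, `burst_times_s` (centers; `NULL` = every 25 s
#'   during the seizure), `burst_dur_s`.
#' @param background_uv Per-channel background RMS in uV.
#' @param bad_channels Labels replaced entirely by independent white noise.
#' @param bad_noise_uv SD of that white noise.
#' @param seed Integer RNG seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(labels = labels_1020(), fs_hz = 200, duration_s = 300,
                         ictal = list(), emg = list(), background_uv = 8,
                         bad_channels = character(0), bad_noise_uv = 30,
                         seed = 0) {
  ictal <- utils::modifyList(list(
    onset_s = 120, onset_channel = "F3", freq_hz = 22, amplitude_uv = 50,
    spread_sigma = 1.3, ramp_s = 10, burst_period_s = 5, burst_duty = 0.6),
    ictal)
  emg <- utils::modifyList(list(
    electrodes = c("F7", "T3"), weights = c(1, 0.6), band_hz = c(20, 95),
    amplitude_uv = 60, burst_times_s = NULL, burst_dur_s = 6), emg)
  unknown <- setdiff(c(labels, ictal$onset_channel, emg$electrodes,
                       bad_channels), rownames(LAYOUT_1020))
  if (length(unknown)) stop("label(s) not in the 10-20 layout: ",
                            paste(unknown, collapse = ", "))
  if (ictal$onset_s >= duration_s) stop("ictal onset must lie within the scene")
  if (emg$band_hz[1] <= 16) stop("EMG band must lie above 16 Hz")
  if (emg$band_hz[2] >= fs_hz / 2) stop("EMG band exceeds the Nyquist frequency")
  if (ictal$amplitude_uv < 0 || emg$amplitude_uv < 0 || background_uv < 0) {
    stop("amplitudes must be >= 0")
  }
  if (is.null(emg$burst_times_s)) {
    emg$burst_times_s <- seq(ictal$onset_s + 5, duration_s - emg$burst_dur_s,
                             by = 25)
  }
  structure(list(labels = labels, fs_hz = fs_hz, duration_s = duration_s,
                 ictal = ictal, emg = emg, background_uv = background_uv,
                 bad_channels = bad_channels, bad_noise_uv = bad_noise_uv,
                 seed = seed),
            class = "scene_config")
}

# 1/f-weighted noise of length n with unit RMS (frequency floor 1 Hz).
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))
  g[1] <- 0                            # no DC
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Simulate a synthetic ictal scene with exact ground truth
#'
#' Deterministic given `config$seed`. The returned recording is the exact sum
#' of the truth components (`neurogenic_uv + emg_uv + badnoise_uv +
#' background_uv`).
#'
#' @param config A [scene_config()].
#' @return List: `recording` (an [eeg_recording()]) and `truth`
#'   (a `scene_truth` with the four component matrices, the topographies
#'   used, and the config).
#' @export
simulate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  labs <- config$labels
  nch <- length(labs)
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  xy <- LAYOUT_1020[labs, , drop = FALSE]

  # --- neurogenic ictal rhythm: smooth topography, ramped narrowband tone
  ict <- config$ictal
  d2 <- rowSums((xy - matrix(LAYOUT_1020[ict$onset_channel, ], nch, 2,
                             byrow = TRUE))^2)
  topo_ict <- exp(-d2 / (2 * ict$spread_sigma^2))
  ramp <- pmin(pmax((t - ict$onset_s) / ict$ramp_s, 0), 1)
  envel <- ifelse(ramp > 0, (1 - cos(pi * ramp)) / 2, 0)    # raised cosine
  # ictal rhythms wax and wane in runs: a Hann burst train (period
  # burst_period_s, active fraction burst_duty) modulates the oscillation,
  # which also makes the source super-Gaussian, as ictal discharges are
  tb <- (t - ict$onset_s) %% ict$burst_period_s
  active_s <- ict$burst_duty * ict$burst_period_s
  btrain <- ifelse(tb < active_s, 0.5 * (1 - cos(2 * pi * tb / active_s)), 0)
  envel <- envel * btrain
  phase <- stats::runif(1, 0, 2 * pi)
  src_ict <- envel * sin(2 * pi * ict$freq_hz * t + phase)
  neuro <- ict$amplitude_uv * (topo_ict %o% src_ict)

  # --- myogenic bursts: focal topography, band-limited noise source
  emg <- config$emg
  w_emg <- numeric(nch); names(w_emg) <- labs
  present <- intersect(emg$electrodes, labs)
  w_emg[present] <- emg$weights[match(present, emg$electrodes)]
  burst_env <- numeric(n)
  half <- emg$burst_dur_s / 2
  for (bc in emg$burst_times_s) {
    idx <- which(t >= bc - half & t < bc + half)
    if (length(idx)) {
      burst_env[idx] <- pmax(burst_env[idx],
                             0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx))))
    }
  }
  raw <- stats::rnorm(n)
  bp <- design_fir("bandpass", emg$band_hz, 500, fs)
  src_emg <- zero_phase_one(raw, bp$taps) * burst_env
  rms_on <- sqrt(mean(src_emg[burst_env > 0.5]^2))
  if (is.finite(rms_on) && rms_on > 0) src_emg <- src_emg / rms_on
  emg_uv <- emg$amplitude_uv * (w_emg %o% src_emg)

  # --- 1/f background, spatially smoothed: scalp potentials are volume-
  # conducted, so neighboring electrodes share background activity. Mix
  # independent per-channel pink noise through a Gaussian spatial kernel with
  # rows normalized to unit L2 so each channel keeps `background_uv` RMS.
  bg_indep <- t(vapply(seq_len(nch), function(i) pink_noise(n, fs), numeric(n)))
  if (nch > 1) {
    dd <- as.matrix(stats::dist(xy))
    K <- exp(-dd^2 / (2 * 0.6^2))
    K <- K / sqrt(rowSums(K^2))
    bg <- config$background_uv * (K %*% bg_indep)
  } else {
    bg <- config$background_uv * bg_indep
  }

  # --- bad channels: replace everything by independent white noise
  bad <- matrix(0, nch, n)
  bad_idx <- match(config$bad_channels, labs)
  bad_idx <- bad_idx[!is.na(bad_idx)]
  for (i in bad_idx) {
    neuro[i, ] <- 0; emg_uv[i, ] <- 0; bg[i, ] <- 0
    bad[i, ] <- stats::rnorm(n, sd = config$bad_noise_uv)
  }

  data <- neuro + emg_uv + bad + bg
  rec <- eeg_recording(data, fs, labels = labs,
                       reference = "referential (synthetic)",
                       meta = list(provenance = sprintf(
                         "synthetic scene seed=%d", config$seed)))
  truth <- structure(list(neurogenic_uv = neuro, emg_uv = emg_uv,
                          badnoise_uv = bad, background_uv = bg,
                          topographies = list(ictal = topo_ict, emg = w_emg),
                          config = config),
                     class = "scene_truth")
  list(recording = rec, truth = truth)
}

#' Score a cleaned recording against scene ground truth
#'
#' Per channel:
#' * neurogenic retention: Pearson correlation between the cleaned trace and
#'   the neurogenic truth over the ictal interval (onset to end);
#' * EMG suppression in dB:
#'   `10 log10( P>16Hz(scene - neurogenic) / P>16Hz(cleaned - neurogenic) )`,
#'   capped at 60 dB (a zero residual is reported as 60 dB).
#'
#' @param cleaned The cleaned [eeg_recording()] (channel order as the scene).
#' @param truth The `scene_truth` from [simulate_scene()].
#' @return List: `retention` (per channel), `suppression_db` (per channel),
#'   `onset_retention`, `emg_suppression_db` (mean over EMG-active
#'   electrodes), `emg_suppression_pooled_db` (suppression of the summed
#'   artifact power across EMG electrodes), `emg_electrodes`, `ictal_span`.
#' @export
score_cleaning <- function(cleaned, truth) {
  stopifnot(inherits(cleaned, "eeg_recording"), inherits(truth, "scene_truth"))
  cfg <- truth$config
  scene <- truth$neurogenic_uv + truth$emg_uv + truth$badnoise_uv +
    truth$background_uv
  if (!all(dim(cleaned$data_uv) == dim(scene))) stop("shape mismatch")
  fs <- cfg$fs_hz
  n <- ncol(scene)
  ict_idx <- (round(cfg$ictal$onset_s * fs) + 1L):n

  retention <- vapply(seq_len(nrow(scene)), function(i) {
    tr <- truth$neurogenic_uv[i, ict_idx]
    if (stats::sd(tr) == 0) return(NA_real_)
    stats::cor(cleaned$data_uv[i, ict_idx], tr)
  }, 0)
  names(retention) <- cleaned$labels

  highpower <- function(mat) {
    r <- eeg_recording(mat, fs, labels = cleaned$labels)
    h <- split_complementary(r, 16, 500)$high
    rowSums(h$data_uv^2)
  }
  p_art <- highpower(scene - truth$neurogenic_uv)
  p_res <- highpower(cleaned$data_uv - truth$neurogenic_uv)
  supp <- 10 * log10(p_art / p_res)
  supp[p_res == 0] <- 60
  supp <- pmin(supp, 60)
  names(supp) <- cleaned$labels

  emg_ch <- intersect(cfg$emg$electrodes, cleaned$labels)
  pooled <- 10 * log10(sum(p_art[match(emg_ch, cleaned$labels)]) /
                         max(sum(p_res[match(emg_ch, cleaned$labels)]), 1e-300))
  list(retention = retention,
       suppression_db = supp,
       onset_retention = unname(retention[cfg$ictal$onset_channel]),
       emg_suppression_db = mean(supp[emg_ch]),
       emg_suppression_pooled_db = min(pooled, 60),
       emg_electrodes = emg_ch,
       ictal_span = c(ict_idx[1] - 1L, n))
}
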
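test_that("topography z-scoring follows the population-SD convention", {
  # one-hot over 19 electrodes: closed-form z of the hot electrode
  onehot <- matrix(0, 19, 1); onehot[7, 1] <- 1
  z <- normalize_topography(onehot)
  mu <- 1 / 19
  popsd <- sqrt(((1 - mu)^2 + 18 * mu^2) / 19)
  expect_equal(max(z), (1 - mu) / popsd, tolerance = 1e-12)
  expect_equal(max(z), 4.243, tolerance = 1e-3)

  uniform <- matrix(5, 19, 1)
  expect_equal(normalize_topography(uniform), matrix(0, 19, 1))

  set.seed(4)
  col <- matrix(rnorm(19), 19, 1)
  expect_equal(normalize_topography(col), normalize_topography(3.7 * col))
})

test_that("classification implements both decision rules", {
  # build one column per requested max-|z| value
  mk_z <- function(maxima) {
    vapply(maxima, function(m) {
      v <- seq(-1, 1, length.out = 19)
      z <- normalize_topography(cbind(v))[, 1]
      z / max(abs(z)) * m
    }, numeric(19))
  }
  z <- mk_z(c(5, 3, 1.5, 4, 0.5))
  per <- classify_components(z, 2, "per_component")
  expect_equal(which(per$klass == "myogenic"), c(1L, 2L, 4L))
  pre <- classify_components(z, 2, "variance_prefix")
  expect_equal(which(pre$klass == "myogenic"), 1:4)

  all_flat <- matrix(0, 19, 3)
  expect_true(all(classify_components(all_flat, 2)$klass == "neurogenic"))

  onehot <- matrix(0, 19, 1); onehot[3, 1] <- 1
  expect_equal(classify_components(normalize_topography(onehot), 2)$klass,
               "myogenic")
  # sign indeterminacy: a negated column classifies identically
  expect_equal(classify_components(-normalize_topography(onehot), 2)$klass,
               "myogenic")
})

test_that("EMG-like focal topographies exceed 2 SD across configurations", {
  set.seed(31)
  for (i in 1:50) {
    n_active <- sample(1:2, 1)
    w <- numeric(19)
    w[sample(19, n_active)] <- runif(n_active, 0.5, 1)
    z <- normalize_topography(cbind(w))
    expect_gte(max(abs(z)), 2)
  }
})

test_that("pruning removes flagged components and nothing else", {
  set.seed(17)
  fs <- 200; n <- 12000
  t <- time_axis(n, fs)
  burst <- ifelse((t %% 5) < 3, 0.5 * (1 - cos(2 * pi * (t %% 5) / 3)), 0)
  rhythm <- burst * sin(2 * pi * 25 * t)
  d2 <- rowSums((ar2eeg:::LAYOUT_1020[labels_1020(), ] -
                   matrix(ar2eeg:::LAYOUT_1020["F3", ], 19, 2, byrow = TRUE))^2)
  topo <- exp(-d2 / (2 * 1.3^2))
  emg_src <- ar2eeg:::zero_phase_one(rnorm(n), design_fir("bandpass", c(20, 95), 500, fs)$taps) *
    ifelse(t > 20 & t < 40, 1, 0)
  w_emg <- numeric(19); w_emg[3] <- 1
  clean_truth <- 30 * (topo %o% rhythm)
  trial <- clean_truth + 50 * (w_emg %o% emg_src)
  rownames(trial) <- labels_1020()

  dec <- suppressWarnings(infomax_ica(trial, seed = 0))
  labs <- classify_components(normalize_topography(dec$mixing), 2,
                              trial_index = 1L)
  expect_gte(sum(labs$klass == "myogenic"), 1)
  cleaned <- prune_backproject(dec, labs)

  # EMG channel: >16 Hz excess power drops by >= 90%
  hp <- function(v) {
    s <- split_complementary(mk_rec(v, fs), 16, 500)
    sum(s$high$data_uv^2)
  }
  excess_before <- hp(trial[3, ] - clean_truth[3, ])
  excess_after <- hp(cleaned[3, ] - clean_truth[3, ])
  expect_lt(excess_after / excess_before, 0.1)
  # rhythm channel stays faithful
  expect_gte(cor(cleaned["F3", ], clean_truth["F3", ]), 0.9)

  # no-op and full pruning
  none <- labs; none$klass <- "neurogenic"
  full_bp <- prune_backproject(dec, none)
  expect_lt(max(abs(full_bp - trial)) / max(abs(trial)), 1e-6)
  all_myo <- labs; all_myo$klass <- "myogenic"
  expect_true(all(prune_backproject(dec, all_myo) == 0))

  # idempotence: re-decomposing the cleaned trial and pruning again with
  # all-neurogenic labels reproduces it
  again <- prune_backproject(dec, labs)
  expect_equal(again, cleaned, tolerance = 1e-12)

  expect_error(prune_backproject(dec, labs[-1, ]), "cover")
})
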
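test_that("trial segmentation follows the 120-s / half-trial merge rule", {
  fs <- 200
  rec_for <- function(dur_s) mk_rec(matrix(0, 1, dur_s * fs), fs)

  sp <- segment_trials(rec_for(120), 120)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$end - sp[[1]]$start, 24000L)

  sp30 <- segment_trials(rec_for(30), 120)
  expect_equal(sp30, list(list(start = 0L, end = 6000L)))

  # 500 s: remainder 4000 < half a trial, merged into the last full trial
  sp500 <- segment_trials(rec_for(500), 120)
  lens <- vapply(sp500, function(s) s$end - s$start, 0L)
  expect_equal(lens, c(24000L, 24000L, 24000L, 28000L))

  # 300 s: remainder 12000 == half a trial, kept as its own trial
  sp300 <- segment_trials(rec_for(300), 120)
  lens300 <- vapply(sp300, function(s) s$end - s$start, 0L)
  expect_equal(lens300, c(24000L, 24000L, 12000L))

  # spans are consecutive and cover the record
  expect_equal(sp500[[1]]$start, 0L)
  for (i in seq_len(length(sp500) - 1)) {
    expect_equal(sp500[[i]]$end, sp500[[i + 1]]$start)
  }
})

test_that("Infomax recovers super-Gaussian sources from a known mixing", {
  amaris <- vapply(0:2, function(s) {
    set.seed(300 + s)
    S <- matrix(rexp(3 * 24000) * sample(c(-1, 1), 3 * 24000, TRUE), 3)
    A <- matrix(rnorm(9), 3)
    d <- suppressWarnings(infomax_ica(A %*% S, seed = s))
    amari_index(d$unmixing, A)
  }, 0)
  expect_lt(median(amaris), 0.05)
})

test_that("decomposition is deterministic and self-consistent", {
  set.seed(8)
  S <- matrix(rexp(3 * 8000) * sample(c(-1, 1), 3 * 8000, TRUE), 3)
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  d1 <- suppressWarnings(infomax_ica(X, seed = 4))
  d2 <- suppressWarnings(infomax_ica(X, seed = 4))
  expect_identical(d1$unmixing, d2$unmixing)  # bitwise

  # mixing is the pseudoinverse of unmixing
  expect_lt(max(abs(d1$mixing %*% d1$unmixing - diag(3))), 1e-6)

  # back-projection completeness: all components reconstruct the trial
  recon <- d1$mixing %*% d1$sources + rowMeans(X)
  expect_lt(max(abs(recon - X)) / max(abs(X)), 1e-6)

  # explained variance: sorted descending, in [0,1], sums ~ 1
  ev <- d1$explained_var
  expect_true(all(diff(ev) <= 0))
  expect_true(all(ev >= 0 & ev <= 1))
  expect_equal(sum(ev), 1, tolerance = 0.02)
  expect_equal(explained_variance(d1, X), ev)
})

test_that("degenerate and ill-posed inputs are handled", {
  set.seed(2)
  x <- rexp(6000) * sample(c(-1, 1), 6000, TRUE)
  d <- suppressWarnings(infomax_ica(matrix(x, 1), seed = 0))
  expect_equal(d$n_components, 1L)
  expect_equal(d$explained_var, 1.0)
  # sources equal the centered input up to scale
  expect_equal(abs(cor(d$sources[1, ], x)), 1, tolerance = 1e-9)
  recon <- d$mixing %*% d$sources + d$channel_means
  expect_lt(max(abs(recon - x)), 1e-9)

  # duplicated channel -> rank-deficiency warning, reduced component count
  X2 <- rbind(x, x, rexp(6000) * sample(c(-1, 1), 6000, TRUE))
  w <- capture_warnings(d2 <- infomax_ica(X2, seed = 0))
  expect_match(w, "rank deficient", all = FALSE)
  expect_equal(d2$n_components, 2L)

  expect_error(suppressWarnings(infomax_ica(matrix(0, 2, 1000), seed = 0)),
               "zero variance")
})

test_that("equal-power orthogonal sources split explained variance evenly", {
  set.seed(12)
  n <- 20000
  S <- matrix(rexp(2 * n) * sample(c(-1, 1), 2 * n, TRUE), 2)
  S <- S / sqrt(rowMeans(S^2))
  theta <- pi / 7
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  d <- suppressWarnings(infomax_ica(A %*% S, seed = 1))
  expect_equal(unname(d$explained_var), c(0.5, 0.5), tolerance = 0.05)
})
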
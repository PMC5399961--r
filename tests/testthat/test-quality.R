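test_that("composite envelope is ~0 for stationary input and flags bursts", {
  fs <- 200
  t <- time_axis(20 * fs, fs)
  s <- sin(2 * pi * 40 * t)
  rec <- mk_rec(rbind(s, s, s), fs)
  comp <- composite_envelope(rec, 0.5)
  interior <- 200:3800
  # z-scoring a near-constant envelope leaves only small-scale ripple: the
  # composite never sustains a suprathreshold excursion
  expect_lt(max(abs(comp[interior])), 1)
  expect_null(longest_suprathreshold_epoch(comp[interior], 1))

  # 10-s burst of 3x amplitude inside a 60-s record, on all channels
  t2 <- time_axis(60 * fs, fs)
  amp <- ifelse(t2 >= 25 & t2 < 35, 3, 1)
  burst <- rbind(amp * sin(2 * pi * 30 * t2), amp * sin(2 * pi * 35 * t2))
  comp_b <- composite_envelope(mk_rec(burst, fs), 0.5)
  inside <- t2 >= 26 & t2 < 34
  outside <- t2 < 24 | t2 >= 36
  expect_true(all(comp_b[inside] > 1))
  expect_true(all(comp_b[outside] < 0))

  # single channel: identical to its own smoothed z-scored envelope
  one <- mk_rec(burst[1, , drop = FALSE], fs)
  e <- hilbert_envelope(burst[1, ])
  manual <- moving_average((e - mean(e)) / sd(e), 101)
  expect_equal(composite_envelope(one, 0.5), manual, tolerance = 1e-12)
})

test_that("dead channels are dropped from the composite with a warning", {
  fs <- 200
  t <- time_axis(10 * fs, fs)
  rec <- mk_rec(rbind(sin(2 * pi * 30 * t) * (1 + 0.3 * sin(2 * pi * t)),
                      numeric(length(t))), fs)
  expect_warning(composite_envelope(rec, 0.5), "zero envelope variance")
  expect_error(composite_envelope(mk_rec(matrix(0, 2, 2000), fs), 0.5),
               "all channels")
})

test_that("longest suprathreshold epoch matches an exhaustive run scan", {
  env <- rep(0, 600)
  env[101:110] <- 2; env[401:425] <- 1.5
  ep <- longest_suprathreshold_epoch(env, 1)
  expect_equal(c(ep$start_sample, ep$end_sample), c(400L, 425L))

  # tie: two runs of 20 -> earliest wins
  env2 <- rep(0, 300)
  env2[11:30] <- 2; env2[101:120] <- 2
  ep2 <- longest_suprathreshold_epoch(env2, 1)
  expect_equal(ep2$start_sample, 10L)

  expect_null(longest_suprathreshold_epoch(rep(1, 100), 1))  # strictly greater

  set.seed(99)
  for (i in 1:1000) {
    e <- rnorm(sample(50:300, 1))
    got <- longest_suprathreshold_epoch(e, 1)
    want <- scan_longest_run(e, 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(c(got$start_sample, got$end_sample), want)
    }
  }
})

test_that("normalized MI matches joint-histogram enumeration and its symmetries", {
  x <- c(0, 0, 1, 1, 2, 2, 3, 3)
  y <- c(0, 1, 0, 1, 0, 1, 0, 1)
  expect_equal(normalized_mi(x, y, 4), enum_nmi(x, y, 4), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(400); b <- 0.7 * a + rnorm(400)
    expect_equal(normalized_mi(a, b, 16), enum_nmi(a, b, 16), tolerance = 1e-12)
    expect_equal(normalized_mi(a, b, 16), normalized_mi(b, a, 16))
  }

  a <- rnorm(500)
  expect_equal(normalized_mi(a, a, 16), 1.0)
  expect_equal(normalized_mi(a, -3.2 * a + 17, 16), 1.0)  # affine invariance
  b <- rnorm(500)
  expect_equal(normalized_mi(a, b, 16), normalized_mi(2 * a - 1, b, 16))
  expect_error(normalized_mi(rep(1, 100), a[1:100], 16), "zero entropy")
})

test_that("MI adjacency is symmetric, zero-diagonal, and ranks channels", {
  set.seed(21)
  n <- 2000
  src <- sin(2 * pi * 25 * time_axis(n)) * (1 + 0.4 * sin(2 * pi * 0.7 * time_axis(n)))
  ch <- rbind(src + 0.1 * rnorm(n),
              0.8 * src + 0.1 * rnorm(n),
              -src + 0.1 * rnorm(n),
              runif(n, -1, 1))
  rec <- mk_rec(ch, 200)
  ep <- structure(list(start_sample = 0L, end_sample = n, peak_sd = 2),
                  class = "artifact_epoch")
  adj <- mi_adjacency(rec, ep, 16)
  expect_identical(adj, t(adj))
  expect_true(all(diag(adj) == 0))
  rm <- apply(adj, 1, max)
  expect_lt(rm[4], min(rm[1:3]))

  dup <- mk_rec(rbind(src, src), 200)
  adj_dup <- mi_adjacency(dup, ep, 16)
  expect_equal(adj_dup[1, 2], 1.0)

  short_ep <- structure(list(start_sample = 0L, end_sample = 40L, peak_sd = 2),
                        class = "artifact_epoch")
  expect_error(mi_adjacency(rec, short_ep, 16), "too short")
})

test_that("channel screening applies the threshold with the all-channel fallback", {
  adj <- matrix(c(0, 0.9, 0.05, 0.9, 0, 0.03, 0.05, 0.03, 0), 3, 3)
  q <- screen_channels(adj, 0.2)
  expect_equal(unname(q$included), c(TRUE, TRUE, FALSE))
  expect_false(q$fallback)
  expect_equal(unname(q$max_nmi), c(0.9, 0.9, 0.05))

  all_hi <- matrix(1, 4, 4); diag(all_hi) <- 0
  expect_true(all(screen_channels(all_hi, 0.2)$included))

  all_lo <- matrix(0.05, 3, 3); diag(all_lo) <- 0
  q_lo <- screen_channels(all_lo, 0.2)
  expect_true(q_lo$fallback)
  expect_true(all(q_lo$included))
})
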
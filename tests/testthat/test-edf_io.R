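test_that("EDF round-trip reproduces waveforms within one quantization step", {
  fs <- 200
  t <- time_axis(2 * fs, fs)
  rec <- mk_rec(rbind(50 * sin(2 * pi * 10 * t)), fs, "C3")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  rb <- read_edf(f)
  step <- 2 * 50 * 1.02 / 65534  # written range is padded >= 1% (< 2%)
  expect_lt(max(abs(rb$data_uv - rec$data_uv)), step)
  expect_identical(rb$labels, rec$labels)
  expect_equal(rb$fs_hz, 200)

  set.seed(42)
  g <- matrix(rnorm(19 * 60 * fs, sd = 30), nrow = 19)
  rec19 <- mk_rec(g, fs, labels_1020())
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec19, f2)
  rb19 <- read_edf(f2)
  step19 <- apply(abs(g), 1, max) * 1.02 * 2 / 65534
  expect_true(all(abs(rb19$data_uv - g) <= step19))
  expect_identical(rb19$labels, rec19$labels)
})

test_that("reader applies the EDF scaling formula (hand-computed oracle)", {
  f <- withr::local_tempfile(fileext = ".edf")
  build_edf_fixture(f, labels = "SIG", phys_min = -100, phys_max = 100,
                    dig_min = -32768, dig_max = 32767, spr = 200,
                    record_dur = 1, digital = list(0:199))
  rb <- read_edf(f)
  expect_equal(rb$fs_hz, 200)
  # phys = (k - dmin) * (pmax - pmin)/(dmax - dmin) + pmin, by hand
  for (k in c(0, 100, 199)) {
    expect_equal(unname(rb$data_uv[1, k + 1]),
                 (k + 32768) * 200 / 65535 - 100, tolerance = 1e-12)
  }
})

test_that("zero-amplitude channels round-trip exactly with a warning", {
  rec <- mk_rec(matrix(0, 2, 400), 200, c("A", "B"))
  f <- withr::local_tempfile(fileext = ".edf")
  expect_warning(write_edf(rec, f), "zero amplitude")
  rb <- read_edf(f)
  expect_true(all(rb$data_uv == 0))
})

test_that("provenance survives the recording-id header field", {
  rec <- eeg_recording(matrix(rnorm(400), 2, 200), 200, c("A", "B"),
                       meta = list(provenance = "AR2 artifact reduction v0.1"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  expect_match(read_edf(f)$meta$provenance, "AR2 artifact reduction")
})

test_that("reader converts volt-multiple dimensions and rejects others", {
  f <- withr::local_tempfile(fileext = ".edf")
  build_edf_fixture(f, labels = c("A", "B"), phys_min = c(-1, -1),
                    phys_max = c(1, 1), dig_min = rep(-32768, 2),
                    dig_max = rep(32767, 2), spr = c(100, 100),
                    record_dur = 1, digital = list(0:99, 0:99),
                    phys_dim = c("mV", "uV"))
  rb <- read_edf(f)
  expect_equal(unname(rb$data_uv[1, ]), unname(1000 * rb$data_uv[2, ]),
               tolerance = 1e-9)

  f2 <- withr::local_tempfile(fileext = ".edf")
  build_edf_fixture(f2, labels = "P", phys_min = -1, phys_max = 1,
                    dig_min = -32768, dig_max = 32767, spr = 100,
                    record_dur = 1, digital = list(0:99), phys_dim = "degC")
  expect_error(read_edf(f2), "non-voltage")
})

test_that("signals with differing sampling rates are rejected by name", {
  f <- withr::local_tempfile(fileext = ".edf")
  build_edf_fixture(f, labels = c("FAST", "SLOW"), phys_min = c(-1, -1),
                    phys_max = c(1, 1), dig_min = rep(-32768, 2),
                    dig_max = rep(32767, 2), spr = c(200, 100),
                    record_dur = 1, digital = list(0:199, 0:99))
  expect_error(read_edf(f), "differing sampling rates")
  expect_error(read_edf(withr::local_tempfile(fileext = ".edf")), "not found")
})

test_that("select_channels reorders and subsets without touching data", {
  rec <- mk_rec(matrix(rnorm(21 * 100), 21), 200,
                c(labels_1020(), "T1", "T2"))
  expect_equal(select_channels(rec, rec$labels), rec)
  rev_rec <- select_channels(rec, rev(rec$labels))
  expect_identical(rev_rec$labels, rev(rec$labels))
  expect_equal(rev_rec$data_uv["Cz", ], rec$data_uv["Cz", ])
  sub <- select_channels(rec, labels_1020())
  expect_equal(dim(sub$data_uv), c(19L, 100L))
  expect_identical(sub$labels, labels_1020())
  expect_error(select_channels(rec, c("Cz", "XX")), "XX")
})
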
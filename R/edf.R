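# EDF (European Data Format) 16-bit reader/writer.
#
# Layout: 256-byte fixed header, then 256 bytes of signal headers per signal,
# then data records of little-endian int16 samples, one contiguous block per
# signal per record. Physical values are recovered by the linear map
#   phys = (dig - dmin) * (pmax - pmin) / (dmax - dmin) + pmin.
# EDF+ annotation signals ("EDF Annotations") are dropped on read; a single
# provenance string is written into the 80-char recording-id field on export.

edf_field <- function(x, width) {
  x <- as.character(x)[1]
  if (is.na(x)) x <- ""
  x <- iconv(x, to = "ASCII", sub = "?")
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) {
  # shortest decimal representation that fits the fixed-width ASCII field
  for (d in seq(min(width, 7), 1)) {
    s <- formatC(x, format = "fg", digits = d, width = 1)
    if (nchar(s) <= width && abs(as.numeric(s) - x) <= abs(x) * 1e-12) {
      return(formatC(s, width = -width))
    }
  }
  for (d in seq(min(width, 7), 1)) {
    s <- formatC(x, format = "g", digits = d, width = 1)
    if (nchar(s) <= width && abs(as.numeric(s) - x) <= abs(x) * 1e-12) {
      return(formatC(s, width = -width))
    }
  }
  stop("numeric value does not fit EDF field of width ", width, ": ", x)
}

# Round up to `digits` significant digits, so physical ranges survive the
# fixed-width ASCII header fields exactly.
sig_ceiling <- function(v, digits = 4) {
  e <- floor(log10(v)) - (digits - 1)
  ceiling(v / 10^e - 1e-9) * 10^e
}

read_ascii <- function(con, nchars) {
  rawToChar(readBin(con, "raw", n = nchars))
}

trimf <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))

# Multiplier converting a declared physical dimension to microvolts, or NA.
uv_factor <- function(dim) {
  d <- trimf(dim)
  d <- sub("µ", "u", d)
  if (!nzchar(d)) return(1)  # blank dimension: assume microvolts
  switch(tolower(d),
         "uv" = 1, "mv" = 1e3, "v" = 1e6, "nv" = 1e-3,
         NA_real_)
}

#' Read an EDF/EDF+ file into an `eeg_recording`
#'
#' Signals are returned in physical units (microvolts) using each signal's
#' declared physical/digital min/max scaling. Annotation signals are dropped;
#' channel order is preserved as stored. Physical dimensions that are volt
#' multiples (nV/uV/mV/V) are converted to microvolts; anything else is
#' rejected because every downstream threshold is amplitude-sensitive.
#'
#' @param path Path to an existing EDF/EDF+ (16-bit) file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- trimf(read_ascii(con, 8))
  if (version != "0") stop("not an EDF file (version field '", version, "'): ", path)
  patient <- trimf(read_ascii(con, 80))
  recording <- trimf(read_ascii(con, 80))
  startdate <- trimf(read_ascii(con, 8))
  starttime <- trimf(read_ascii(con, 8))
  header_bytes <- as.integer(read_ascii(con, 8))
  reserved <- trimf(read_ascii(con, 44))
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header (no signals): ", path)

  rd_many <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- trimf(rd_many(16))
  rd_many(80)                      # transducer, unused
  phys_dim <- rd_many(8)
  phys_min <- as.numeric(rd_many(8))
  phys_max <- as.numeric(rd_many(8))
  dig_min <- as.numeric(rd_many(8))
  dig_max <- as.numeric(rd_many(8))
  rd_many(80)                      # prefiltering, unused
  spr <- as.integer(rd_many(8))    # samples per record
  rd_many(32)                      # reserved

  if (is.na(n_records) || n_records < 1 || any(is.na(spr)) || any(spr < 1)) {
    stop("zero-length EDF record: ", path)
  }

  samples_per_rec <- sum(spr)
  raw_all <- readBin(con, "integer", n = n_records * samples_per_rec,
                     size = 2, signed = TRUE, endian = "little")
  if (length(raw_all) < n_records * samples_per_rec) {
    stop("corrupt/truncated EDF data section: ", path)
  }

  keep <- !(labels %in% c("EDF Annotations", "BDF Annotations"))
  if (!any(keep)) stop("EDF file contains only annotation signals: ", path)

  fs_all <- spr / record_dur
  fs_keep <- fs_all[keep]
  if (length(unique(fs_keep)) != 1L) {
    bad <- labels[keep][fs_keep != stats::median(fs_keep)]
    stop("signals recorded at differing sampling rates: ",
         paste(bad, collapse = ", "))
  }
  fs <- fs_keep[1]

  # slice the interleaved record blocks into per-signal sample streams
  offsets <- c(0L, cumsum(spr))
  data <- matrix(0, nrow = sum(keep), ncol = n_records * spr[which(keep)[1]])
  row <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    row <- row + 1L
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_records) - 1L) * samples_per_rec, "+"))
    dig <- raw_all[idx]
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    fac <- uv_factor(phys_dim[i])
    if (is.na(fac)) {
      stop("signal '", labels[i], "' has non-voltage physical dimension '",
           trimf(phys_dim[i]), "'; cannot convert to microvolts")
    }
    data[row, ] <- ((dig - dig_min[i]) * scale + phys_min[i]) * fac
  }
  if (!all(is.finite(data))) stop("non-finite samples after EDF scaling: ", path)

  labs <- labels[keep]
  if (anyDuplicated(labs)) {
    warning("duplicate channel labels made unique on read")
    labs <- make.unique(labs)
  }

  st <- tryCatch(
    as.POSIXct(paste(startdate, starttime), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  if (length(st) && is.na(st)) st <- NULL

  eeg_recording(data, fs, labels = labs, start_time = st,
                reference = "referential",
                meta = list(source_file = path, patient = patient,
                            provenance = if (nzchar(recording)) recording else NULL))
}

#' Write an `eeg_recording` to a 16-bit EDF file
#'
#' Per-channel physical min/max are set symmetric about zero, padded by 1%
#' beyond the observed amplitude, so a read-back reproduces the data within
#' one digital quantization step (physical range / 65535). A channel with zero
#' amplitude range is written with a default +/-1 uV range and a warning. The
#' first provenance entry in `rec$meta$provenance` is stored in the 80-char
#' recording-id header field.
#'
#' When the sample count is a whole multiple of an integer sampling rate the
#' file uses 1-second data records; otherwise the whole signal is written as a
#' single data record so no padding ever alters the round-trip length.
#'
#' @param rec An [eeg_recording()] with finite amplitudes.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data_uv
  if (!all(is.finite(x))) stop("cannot write non-finite amplitudes to EDF")
  nch <- nrow(x); n <- ncol(x)
  if (n < 1) stop("cannot write a zero-length recording")

  fs <- rec$fs_hz
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- as.integer(round(fs)); n_records <- n %/% spr; record_dur <- 1
  } else {
    spr <- n; n_records <- 1L; record_dur <- n / fs
  }

  pm <- apply(abs(x), 1, max)
  flat <- pm == 0
  if (any(flat)) {
    warning("channel(s) with zero amplitude range written with default +/-1 uV: ",
            paste(rec$labels[flat], collapse = ", "))
  }
  # symmetric range padded >= 1%, rounded up to fit the 8-char header field
  pm <- ifelse(flat, 1, vapply(pm * 1.01, sig_ceiling, 0))
  # symmetric digital range so 0 uV is exactly representable
  dmin <- -32767; dmax <- 32767

  st <- rec$start_time
  if (is.null(st)) st <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  prov <- rec$meta$provenance
  rec_field <- if (length(prov)) paste(prov, collapse = "; ") else "ar2eeg export"

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(s), con)

  put(edf_field("0", 8))
  put(edf_field("X X X X", 80))
  put(edf_field(rec_field, 80))
  put(edf_field(format(st, "%d.%m.%y"), 8))
  put(edf_field(format(st, "%H.%M.%S"), 8))
  put(edf_field(256 * (nch + 1), 8))
  put(edf_field("", 44))
  put(edf_field(n_records, 8))
  put(edf_num(record_dur, 8))
  put(edf_field(nch, 4))

  for (lab in rec$labels) put(edf_field(lab, 16))
  for (i in seq_len(nch)) put(edf_field("AgAgCl electrode", 80))
  for (i in seq_len(nch)) put(edf_field("uV", 8))
  for (i in seq_len(nch)) put(edf_num(-pm[i], 8))
  for (i in seq_len(nch)) put(edf_num(pm[i], 8))
  for (i in seq_len(nch)) put(edf_field(dmin, 8))
  for (i in seq_len(nch)) put(edf_field(dmax, 8))
  for (i in seq_len(nch)) put(edf_field("", 80))
  for (i in seq_len(nch)) put(edf_field(spr, 8))
  for (i in seq_len(nch)) put(edf_field("", 32))

  # digitize: phys range [-pm, pm] -> [dmin, dmax]
  dig <- matrix(0L, nrow = nch, ncol = n)
  for (i in seq_len(nch)) {
    d <- round((x[i, ] + pm[i]) / (2 * pm[i]) * (dmax - dmin) + dmin)
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nch)) {
      writeBin(dig[i, cols], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
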
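# Minimal European Data Format (EDF) writer/reader for two-channel
# recordings: 16-bit samples, one-second data records, labels "Fp1"/"Fp2",
# physical unit uV. Covers only what this package writes; it is not a
# general EDF implementation.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)           # left-justified, space padded
}

#' Write / read a recording in European Data Format
#'
#' Stores the two channels as 16-bit EDF signals labelled `Fp1` and `Fp2`
#' (physical unit uV) in one-second data records; the last record is padded
#' by repeating the final sample, and the pad is trimmed again on read.
#' Requires an integer sampling rate. Voltages are quantized to the 16-bit
#' digital range, so a round trip is exact only to about
#' `physical_range / 65534`.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @param patient,recording Free-text EDF header fields.
#' @return `write_edf` returns `path` invisibly; `read_edf` an
#'   [eeg_recording()].
#' @export
write_edf <- function(rec, path, patient = "X", recording = "simulated") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stopf("EDF export needs an integer sampling rate; got %g", fs)
  fs <- as.integer(round(fs))
  n <- length(rec$fp1)
  n_rec <- as.integer(ceiling(n / fs))
  pad <- n_rec * fs - n
  sig <- list(Fp1 = c(rec$fp1, rep(rec$fp1[n], pad)),
              Fp2 = c(rec$fp2, rep(rec$fp2[n], pad)))
  pm <- max(1, max(abs(unlist(sig))))
  dig <- lapply(sig, function(x) as.integer(round(x / pm * 32767)))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field(patient, 80), edf_field(recording, 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 + 2 * 256, 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(2, 4))
  sf <- function(vals, width)
    paste(vapply(vals, edf_field, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    sf(c("Fp1", "Fp2"), 16), sf(rep("dry electrode", 2), 80),
    sf(rep("uV", 2), 8),
    sf(rep(formatC(-pm, format = "g", digits = 7), 2), 8),
    sf(rep(formatC(pm, format = "g", digits = 7), 2), 8),
    sf(rep(-32767L, 2), 8), sf(rep(32767L, 2), 8),
    sf(rep("none", 2), 80), sf(rep(fs, 2), 8), sf(rep("", 2), 32))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    i <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(dig$Fp1[i], con, size = 2L, endian = "little")
    writeBin(dig$Fp2[i], con, size = 2L, endian = "little")
  }
  attr(path, "n_samples") <- n
  invisible(path)
}

#' @rdname write_edf
#' @param n_samples Optional true sample count to trim the final padded
#'   record (defaults to all stored samples).
#' @export
read_edf <- function(path, n_samples = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                 # header length
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != 2L) stopf("expected a two-signal EDF file, found %d signals", ns)
  labels <- c(rd(16), rd(16))
  rd(80); rd(80)                        # transducers
  rd(8); rd(8)                          # units
  pmin <- as.numeric(c(rd(8), rd(8)))
  pmax <- as.numeric(c(rd(8), rd(8)))
  dmin <- as.numeric(c(rd(8), rd(8)))
  dmax <- as.numeric(c(rd(8), rd(8)))
  rd(80); rd(80)                        # prefilter
  spr <- as.integer(c(rd(8), rd(8)))
  rd(32); rd(32)
  if (spr[1] != spr[2]) stopf("differing per-signal sampling rates unsupported")
  fs <- spr[1] / rec_dur
  x1 <- x2 <- numeric(0)
  for (r in seq_len(n_rec)) {
    x1 <- c(x1, readBin(con, "integer", spr[1], size = 2L, signed = TRUE,
                        endian = "little"))
    x2 <- c(x2, readBin(con, "integer", spr[2], size = 2L, signed = TRUE,
                        endian = "little"))
  }
  tophys <- function(d, i)
    pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  fp1 <- tophys(x1, 1); fp2 <- tophys(x2, 2)
  if (!is.null(n_samples)) {
    fp1 <- fp1[seq_len(n_samples)]
    fp2 <- fp2[seq_len(n_samples)]
  }
  rec <- eeg_recording(fp1, fp2, fs = fs)
  attr(rec, "labels") <- labels
  rec
}
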
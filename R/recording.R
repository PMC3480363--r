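#' Construct a two-channel frontal EEG recording
#'
#' Container for a two-channel (Fp1, Fp2) voltage series sampled at a fixed
#' rate. All downstream screening, feature extraction and scoring functions
#' operate on this class. Time is 0-based: sample `i` sits at
#' `start_time + (i - 1) / fs` seconds.
#'
#' @param fp1,fp2 Numeric vectors of equal length, channel voltages in
#'   microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Start time of the first sample, seconds (default 0).
#'
#' @return An object of class `eeg_recording`: a list with elements `fp1`,
#'   `fp2`, `fs`, `start_time`.
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * (0:255) / 128), rep(0, 256), fs = 128)
#' rec
#' @export
eeg_recording <- function(fp1, fp2, fs, start_time = 0) {
  if (!is.numeric(fp1) || !is.numeric(fp2))
    stopf("channel samples must be numeric")
  if (length(fp1) != length(fp2))
    stopf("Fp1 and Fp2 must have the same length (got %d and %d)",
          length(fp1), length(fp2))
  if (length(fp1) < 1L) stopf("recording must contain at least one sample")
  check_number(fs, "fs", 0, strict = TRUE)
  structure(list(fp1 = as.numeric(fp1), fp2 = as.numeric(fp2),
                 fs = fs, start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x 2 channels (Fp1, Fp2), fs = %g Hz, %.2f s\n",
              length(x$fp1), x$fs, duration(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$fp1) / rec$fs

#' @export
as.data.frame.eeg_recording <- function(x, ...) {
  data.frame(time_s = x$start_time + (seq_along(x$fp1) - 1) / x$fs,
             fp1_uV = x$fp1, fp2_uV = x$fp2)
}

#' Read / write a recording as CSV
#'
#' The CSV dialect has columns `time_s`, `fp1_uV`, `fp2_uV`; the sampling
#' rate is recovered from the time column on read.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `read_eeg_csv` returns an [eeg_recording()]; `write_eeg_csv`
#'   returns `path` invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "fp1_uV", "fp2_uV")
  if (!all(need %in% names(d)))
    stopf("EEG CSV must have columns %s", paste(need, collapse = ", "))
  if (nrow(d) < 2L) stopf("EEG CSV must contain at least two samples")
  dt <- diff(d$time_s)
  fs <- 1 / stats::median(dt)
  eeg_recording(d$fp1_uV, d$fp2_uV, fs = fs, start_time = d$time_s[1])
}
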
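#' Spectral state profile for the synthetic EEG generator
#'
#' Describes the stationary spectral content of a simulated attentional state.
#' Oscillatory amplitudes are RMS values in microvolts of band-limited noise in
#' the canonical theta (4-8 Hz), alpha (8-12 Hz) and beta (13-30 Hz) bands;
#' `pink_noise_amp` is the RMS of the 1/f background. Blink transients are
#' shared by both frontal channels (common-mode), at `blink_rate` events per
#' minute with peak amplitude `blink_amp`.
#'
#' The attention contrast the pipeline exploits is the theta/beta balance:
#' an inattentive state has elevated theta and reduced beta relative to the
#' attentive state.
#'
#' @param theta_amp,alpha_amp,beta_amp RMS amplitude (microvolts) of the
#'   band-limited oscillation in each band; >= 0.
#' @param pink_noise_amp RMS amplitude (microvolts) of the pink background.
#' @param blink_rate Blink events per minute; >= 0.
#' @param blink_amp Peak blink amplitude in microvolts.
#' @return An object of class `state_profile`.
#' @seealso [attentive_profile()], [inattentive_profile()], [simulate_eeg()]
#' @export
state_profile <- function(theta_amp = 0, alpha_amp = 0, beta_amp = 0,
                          pink_noise_amp = 0, blink_rate = 0, blink_amp = 0) {
  for (nm in c("theta_amp", "alpha_amp", "beta_amp", "pink_noise_amp",
               "blink_rate", "blink_amp"))
    check_number(get(nm), nm, 0)
  structure(list(theta_amp = theta_amp, alpha_amp = alpha_amp,
                 beta_amp = beta_amp, pink_noise_amp = pink_noise_amp,
                 blink_rate = blink_rate, blink_amp = blink_amp),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf(paste0("<state_profile> theta %g, alpha %g, beta %g uV RMS; ",
                     "pink %g uV; blinks %g/min x %g uV\n"),
              x$theta_amp, x$alpha_amp, x$beta_amp, x$pink_noise_amp,
              x$blink_rate, x$blink_amp))
  invisible(x)
}

#' Default attentive / inattentive state profiles
#'
#' The default pair realises a theta/beta amplitude ratio of 0.5 (attentive)
#' versus 4 (inattentive), the contrast reported for ADHD resting EEG
#' (elevated slow-wave theta, reduced fast-wave beta in the inattentive
#' state), with identical alpha, background and blink parameters so only the
#' discriminative bands differ.
#'
#' @return A `state_profile`.
#' @export
attentive_profile <- function() {
  state_profile(theta_amp = 3, alpha_amp = 5, beta_amp = 6,
                pink_noise_amp = 3, blink_rate = 10, blink_amp = 80)
}

#' @rdname attentive_profile
#' @export
inattentive_profile <- function() {
  state_profile(theta_amp = 12, alpha_amp = 5, beta_amp = 3,
                pink_noise_amp = 3, blink_rate = 10, blink_amp = 80)
}

# Band-limited Gaussian noise of unit RMS: white noise spectrally masked to
# [lo, hi) Hz by a brick-wall in the frequency domain.
band_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # fold to one-sided frequency
  X[!(f >= lo & f < hi)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) return(numeric(n))
  y / r
}

# Pink (1/f) noise of unit RMS via spectral shaping of white noise.
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  g <- ifelse(f > 0, 1 / sqrt(f), 0)       # power ~ 1/f, zero DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) return(numeric(n))
  y / r
}

# 300 ms half-sine blink transients at Poisson-distributed onsets,
# returned as a single additive waveform.
blink_train <- function(n, fs, rate_per_min, amp, duration) {
  w <- numeric(n)
  if (rate_per_min <= 0 || amp <= 0) return(w)
  blink_len <- 0.3
  k <- stats::rpois(1, rate_per_min * duration / 60)
  if (k == 0) return(w)
  onsets <- stats::runif(k, 0, max(0, duration - blink_len))
  m <- round(blink_len * fs)
  shape <- amp * sin(pi * seq(0, 1, length.out = m))
  for (t0 in onsets) {
    i0 <- floor(t0 * fs) + 1L
    idx <- i0:min(n, i0 + m - 1L)
    w[idx] <- w[idx] + shape[seq_along(idx)]
  }
  w
}

#' Simulate a two-channel frontal EEG recording
#'
#' Generates Fp1/Fp2 voltage series from a [state_profile()]: each channel
#' receives independent band-limited theta/alpha/beta oscillations and pink
#' background noise, while blink transients (300 ms half-sines) are added
#' identically to both channels, as frontal ocular artifacts are common-mode.
#' Band oscillations are realised as brick-wall band-passed white noise so
#' their power spreads realistically over the band rather than sitting in a
#' single FFT bin.
#'
#' @param profile A [state_profile()].
#' @param duration Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz; must exceed 60 Hz (Nyquist for the 30 Hz
#'   band edge). Default 128 so one 2-s block is exactly 256 samples.
#' @param seed Optional integer; identical seeds and arguments give
#'   bit-identical recordings. The caller's RNG stream is left untouched.
#' @return An [eeg_recording()].
#' @examples
#' rec <- simulate_eeg(attentive_profile(), duration = 4, seed = 1)
#' rec
#' @export
simulate_eeg <- function(profile, duration, fs = 128, seed = NULL) {
  stopifnot(inherits(profile, "state_profile"))
  check_number(duration, "duration", 0, strict = TRUE)
  if (fs <= 60)
    stopf("fs must exceed 60 Hz (twice the 30 Hz band edge); got %g", fs)
  n <- round(duration * fs)
  if (n < 1) stopf("duration too short for one sample at fs = %g", fs)
  with_seed(seed, {
    blinks <- blink_train(n, fs, profile$blink_rate, profile$blink_amp, duration)
    ch <- function() {
      x <- numeric(n)
      if (profile$theta_amp > 0) x <- x + profile$theta_amp * band_noise(n, fs, 4, 8)
      if (profile$alpha_amp > 0) x <- x + profile$alpha_amp * band_noise(n, fs, 8, 12)
      if (profile$beta_amp > 0)  x <- x + profile$beta_amp  * band_noise(n, fs, 13, 30)
      if (profile$pink_noise_amp > 0)
        x <- x + profile$pink_noise_amp * pink_noise(n, fs)
      x + blinks
    }
    eeg_recording(ch(), ch(), fs = fs)
  })
}

#' Inject saturation and disconnection defects into a recording
#'
#' Produces the two abnormality classes the screening stage must detect:
#' saturated digital samples (clamped to the ADC rail) and disconnected
#' electrodes (flatlined intervals). All other samples are unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param saturation_times Numeric vector of times (s); the sample nearest
#'   each time is clamped to `+rail_value` or `-rail_value` (following the
#'   sample's sign; non-negative samples clamp high).
#' @param flatline_intervals List of length-2 numeric vectors `c(start, end)`
#'   in seconds; samples in each half-open interval are replaced by the
#'   channel value at the interval start.
#' @param rail_value ADC rail in microvolts (default 512).
#' @return The modified [eeg_recording()].
#' @export
inject_artifacts <- function(rec, saturation_times = numeric(),
                             flatline_intervals = list(),
                             rail_value = 512) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_number(rail_value, "rail_value", 0, strict = TRUE)
  n <- length(rec$fp1); dur <- duration(rec)
  for (t in saturation_times) {
    if (t < 0 || t >= dur)
      stopf("saturation time %g s outside recording span [0, %g)", t, dur)
    i <- round(t * rec$fs) + 1L
    i <- min(max(i, 1L), n)
    rec$fp1[i] <- ifelse(rec$fp1[i] < 0, -rail_value, rail_value)
    rec$fp2[i] <- ifelse(rec$fp2[i] < 0, -rail_value, rail_value)
  }
  for (iv in flatline_intervals) {
    if (length(iv) != 2L || iv[1] >= iv[2])
      stopf("flatline intervals must be c(start, end) with start < end")
    if (iv[1] < 0 || iv[2] > dur)
      stopf("flatline interval [%g, %g) outside recording span [0, %g)",
            iv[1], iv[2], dur)
    i0 <- floor(iv[1] * rec$fs) + 1L
    i1 <- min(n, ceiling(iv[2] * rec$fs))
    rec$fp1[i0:i1] <- rec$fp1[i0]
    rec$fp2[i0:i1] <- rec$fp2[i0]
  }
  rec
}

#' Simulate a labeled calibration dataset
#'
#' Emulates the calibration run in which the participant alternates between a
#' demanding attention task ("attentive" epochs) and rest ("relaxed" epochs).
#' Attentive epochs are drawn from the attentive profile and relaxed epochs
#' from the inattentive profile, in balanced numbers.
#'
#' @param attentive,inattentive [state_profile()]s for the two states. The
#'   attentive profile must have a strictly lower theta/beta amplitude ratio.
#' @param n_epochs_per_label Epochs per label (>= 2).
#' @param epoch_len Epoch length in seconds; must be an integer multiple of
#'   `block_len`.
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @param block_len Analysis block length in seconds (default 2).
#' @param subject_id Identifier stored with the dataset.
#' @return An object of class `calibration_dataset`: list with `epochs`
#'   (each a list with `rec`, an [eeg_recording()], and `label`,
#'   `"attentive"` or `"relaxed"`) and `subject_id`.
#' @export
simulate_calibration <- function(attentive = attentive_profile(),
                                 inattentive = inattentive_profile(),
                                 n_epochs_per_label = 20, epoch_len = 10,
                                 fs = 128, seed = NULL, block_len = 2,
                                 subject_id = "sim") {
  stopifnot(inherits(attentive, "state_profile"),
            inherits(inattentive, "state_profile"))
  if (n_epochs_per_label < 2) stopf("need at least 2 epochs per label")
  if (abs(epoch_len / block_len - round(epoch_len / block_len)) > 1e-9)
    stopf("epoch_len (%g s) must be an integer multiple of block_len (%g s)",
          epoch_len, block_len)
  ratio <- function(p) if (p$beta_amp > 0) p$theta_amp / p$beta_amp else Inf
  if (!(ratio(attentive) < ratio(inattentive)))
    stopf("attentive profile must have a lower theta/beta ratio than the inattentive profile")
  with_seed(seed, {
    epochs <- vector("list", 2L * n_epochs_per_label)
    labels <- rep(c("attentive", "relaxed"), each = n_epochs_per_label)
    labels <- labels[order(rep(seq_len(n_epochs_per_label), 2L))]  # interleave
    for (i in seq_along(labels)) {
      p <- if (labels[i] == "attentive") attentive else inattentive
      epochs[[i]] <- list(rec = simulate_eeg(p, epoch_len, fs), label = labels[i])
    }
    structure(list(epochs = epochs, subject_id = subject_id,
                   block_len = block_len),
              class = "calibration_dataset")
  })
}

#' @export
print.calibration_dataset <- function(x, ...) {
  lab <- vapply(x$epochs, `[[`, "", "label")
  cat(sprintf("<calibration_dataset> subject %s: %d epochs (%d attentive, %d relaxed)\n",
              x$subject_id, length(lab), sum(lab == "attentive"),
              sum(lab == "relaxed")))
  invisible(x)
}

#' Calibration labels CSV
#'
#' Writes/reads the epoch labels of a calibration dataset as
#' `epoch_start_s, epoch_end_s, label`, treating the epochs as laid out
#' back-to-back in time.
#'
#' @param cal A `calibration_dataset`.
#' @param path File path.
#' @return `write_calibration_labels_csv` returns `path` invisibly;
#'   `read_calibration_labels_csv` returns the labels data frame.
#' @export
write_calibration_labels_csv <- function(cal, path) {
  lens <- vapply(cal$epochs, function(e) duration(e$rec), 0)
  ends <- cumsum(lens)
  d <- data.frame(epoch_start_s = c(0, ends[-length(ends)]),
                  epoch_end_s = ends,
                  label = vapply(cal$epochs, `[[`, "", "label"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_labels_csv
#' @export
read_calibration_labels_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("epoch_start_s", "epoch_end_s", "label")
  if (!all(need %in% names(d)))
    stopf("labels CSV must have columns %s", paste(need, collapse = ", "))
  d
}

#' Assemble a calibration dataset from a recording plus labels table
#'
#' Cuts labeled epochs out of a continuous recording using a labels table
#' (as read by [read_calibration_labels_csv()]).
#'
#' @param rec An [eeg_recording()].
#' @param labels Data frame with `epoch_start_s`, `epoch_end_s`, `label`.
#' @param block_len Analysis block length (s).
#' @param subject_id Identifier.
#' @return A `calibration_dataset`.
#' @export
calibration_from_recording <- function(rec, labels, block_len = 2,
                                       subject_id = "unknown") {
  epochs <- lapply(seq_len(nrow(labels)), function(i) {
    i0 <- floor(labels$epoch_start_s[i] * rec$fs) + 1L
    i1 <- floor(labels$epoch_end_s[i] * rec$fs)
    list(rec = eeg_recording(rec$fp1[i0:i1], rec$fp2[i0:i1], rec$fs),
         label = labels$label[i])
  })
  structure(list(epochs = epochs, subject_id = subject_id,
                 block_len = block_len),
            class = "calibration_dataset")
}
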
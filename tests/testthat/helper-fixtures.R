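# shared fixtures, all generated in code

# one 256-sample block matrix from two channel vectors
make_block <- function(fp1, fp2 = rep(0, length(fp1)), fs = 128) {
  m <- cbind(Fp1 = fp1, Fp2 = fp2)
  attr(m, "t0") <- 0
  attr(m, "fs") <- fs
  m
}

# unit cosine at an exact FFT bin frequency
cosine_block <- function(freq_hz, n = 256, fs = 128, amp = 1)
  amp * cos(2 * pi * freq_hz * (0:(n - 1)) / fs)

# a deterministic ramp recording (unused by artifact screening tests)
ramp_recording <- function(dur = 20, fs = 128)
  eeg_recording(2 * seq_len(dur * fs), 2 * seq_len(dur * fs) + 1, fs = fs)

# deterministic period-3 recording (-amp, 0, +amp repeating): any window
# containing even one non-flatlined sample differs from the flat constant,
# so flatline detection is exact to the sample, and |x| stays far below the
# rail; the period-3 pattern never re-matches the constant at the flatline
# edges for the intervals used in tests
alt_recording <- function(dur = 20, fs = 128, amp = 5) {
  i <- seq_len(dur * fs)
  eeg_recording(amp * ((i %% 3) - 1), amp * (((i + 1) %% 3) - 1), fs = fs)
}

# small complete ratings table: two visits, chosen group means
paired_table <- function(n, mean0, mean8, subscale = "IA", sd_dev = 2) {
  dev <- seq(-1, 1, length.out = n) * sd_dev   # mean-zero deviations
  d <- data.frame(subject_id = rep(sprintf("S%02d", 1:n), 2),
                  week = rep(c(0, 8), each = n))
  d[[subscale]] <- c(mean0 + dev, mean8 + dev)
  d
}
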
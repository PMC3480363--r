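#' Filter bank over the 4-30 Hz range
#'
#' An ordered list of contiguous, non-overlapping half-open frequency bands
#' `[low, high)` whose union covers 4-30 Hz. The default bank splits the
#' range into 8 equal-width bands of 3.25 Hz; [classical_filter_bank()]
#' offers a preset aligned with the traditional theta / alpha / beta
#' subdivisions.
#'
#' @param edges Increasing numeric vector of band edges (Hz); band `i` is
#'   `[edges[i], edges[i+1])`.
#' @return An object of class `filter_bank`: a data frame with columns
#'   `low_Hz`, `high_Hz`.
#' @examples
#' default_filter_bank()
#' @export
filter_bank <- function(edges) {
  if (!is.numeric(edges) || length(edges) < 2L || any(diff(edges) <= 0))
    stopf("`edges` must be an increasing numeric vector of length >= 2")
  structure(data.frame(low_Hz = edges[-length(edges)], high_Hz = edges[-1]),
            class = c("filter_bank", "data.frame"))
}

#' @rdname filter_bank
#' @export
default_filter_bank <- function() filter_bank(seq(4, 30, length.out = 9))

#' @rdname filter_bank
#' @export
classical_filter_bank <- function()
  filter_bank(c(4, 8, 10, 12, 15, 18, 21, 25, 30))

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d bands covering [%g, %g) Hz\n",
              nrow(x), x$low_Hz[1], x$high_Hz[nrow(x)]))
  print(as.data.frame(unclass(x)))
  invisible(x)
}

#' Read a filter bank from a YAML/JSON-style config
#'
#' Accepts a JSON file holding a list of `[low, high]` pairs.
#' @param path File path.
#' @return A [filter_bank()].
#' @export
read_filter_bank <- function(path) {
  m <- jsonlite::fromJSON(path)
  m <- as.matrix(m)
  if (any(m[-1, 1] != m[-nrow(m), 2]))
    stopf("bands in `%s` are not contiguous", path)
  filter_bank(c(m[, 1], m[nrow(m), 2]))
}

#' Virtual differential channel
#'
#' The fixed bipolar spatial filter Fp1 - Fp2. Signals common to both
#' frontal channels — notably ocular (blink) artifacts — cancel, while
#' independent cortical activity is retained.
#'
#' @param fp1,fp2 Numeric vectors of equal length.
#' @return The elementwise difference `fp1 - fp2`.
#' @export
virtual_channel <- function(fp1, fp2) {
  if (length(fp1) != length(fp2))
    stopf("channel length mismatch (%d vs %d)", length(fp1), length(fp2))
  fp1 - fp2
}

#' One-sided power spectrum of a single analysis block
#'
#' Computes the 256-point FFT power spectrum of one 2-second block. Power is
#' normalised so that the sum of the one-sided spectrum equals the mean
#' square of the block (Parseval's identity): bin `k` carries
#' `|X_k|^2 / N^2`, doubled for `0 < k < N/2`. An optional Hann window is
#' compensated by its mean-square gain so broadband power is preserved.
#'
#' @param block Numeric vector whose length equals `nfft`.
#' @param fs Sampling rate (Hz).
#' @param window `"rectangular"` (default) or `"hann"`.
#' @param nfft FFT length (default 256).
#' @return Numeric vector of length `nfft/2 + 1` of one-sided power, with
#'   attribute `freq` (Hz).
#' @export
block_spectrum <- function(block, fs = 128, window = c("rectangular", "hann"),
                           nfft = 256L) {
  window <- match.arg(window)
  n <- length(block)
  if (n != nfft)
    stopf("block length must equal the FFT length (%d); got %d — resample upstream",
          nfft, n)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n) else rep(1, n)
  X <- stats::fft(block * w)
  p <- Mod(X[1:(n / 2 + 1)])^2 / (n^2 * mean(w^2))
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]
  structure(p, freq = (0:(n / 2)) * fs / n)
}

#' Band power from a one-sided spectrum
#'
#' Sums the one-sided spectral power over bins whose frequency satisfies
#' `low <= f < high` (half-open, so contiguous bands never double-count a
#' bin).
#'
#' @param spectrum Output of [block_spectrum()].
#' @param band Length-2 numeric `c(low, high)` in Hz.
#' @return Summed power (same units as the spectrum).
#' @export
band_power <- function(spectrum, band) {
  f <- attr(spectrum, "freq")
  if (is.null(f)) stopf("`spectrum` must carry a `freq` attribute")
  sel <- f >= band[1] & f < band[2]
  if (!any(sel))
    stopf("band [%g, %g) Hz contains no spectral bins at this resolution",
          band[1], band[2])
  sum(spectrum[sel])
}

# linear resampling of a block to the FFT length (used when fs != 128)
resample_block <- function(x, n_out) {
  if (length(x) == n_out) return(x)
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Extract the band-power feature vector from clean blocks
#'
#' For every clean block the one-sided power spectrum is computed for Fp1,
#' Fp2 and the virtual differential channel (Fp1 - Fp2); band powers over
#' the filter bank are summed per channel and averaged across blocks. The
#' feature layout is channel-major, band-minor: features 1-8 are the Fp1
#' band powers in bank order, 9-16 Fp2, 17-24 the differential channel
#' (with the default 8-band bank). A `log10(x + eps)` transform is applied
#' by default to stabilise the variance of band powers.
#'
#' @param blocks List of blocks as produced by [apply_mask()] (each an
#'   `n x 2` matrix with columns Fp1, Fp2). Blocks whose length differs
#'   from `nfft` are linearly resampled.
#' @param bank A [filter_bank()].
#' @param log_scale Apply `log10(x + eps)`? Default `TRUE`.
#' @param window FFT window, see [block_spectrum()].
#' @param eps Offset inside the log (default `1e-10` uV^2).
#' @param nfft FFT length (default 256).
#' @return An object of class `feature_vector`: a named numeric vector of
#'   length `3 * nrow(bank)` with attributes `n_blocks`, `log_scale`,
#'   `bank`.
#' @export
extract_features <- function(blocks, bank = default_filter_bank(),
                             log_scale = TRUE,
                             window = c("rectangular", "hann"),
                             eps = 1e-10, nfft = 256L) {
  window <- match.arg(window)
  if (length(blocks) < 1L)
    stopf("no clean blocks to extract features from (fully-masked recording?)")
  nb <- nrow(bank)
  acc <- matrix(0, nrow = 3L, ncol = nb)
  for (blk in blocks) {
    fs <- attr(blk, "fs")
    if (is.null(fs)) fs <- 128
    fp1 <- resample_block(blk[, 1], nfft)
    fp2 <- resample_block(blk[, 2], nfft)
    # after resampling to nfft samples per block the effective rate is
    # nfft / block duration; bands stay aligned because the original 2-s
    # block maps to 128 Hz exactly
    fs_eff <- nfft / (nrow(blk) / fs)
    chans <- list(fp1, fp2, virtual_channel(fp1, fp2))
    for (ci in 1:3) {
      sp <- block_spectrum(chans[[ci]], fs = fs_eff, window = window, nfft = nfft)
      for (bi in seq_len(nb))
        acc[ci, bi] <- acc[ci, bi] +
          band_power(sp, c(bank$low_Hz[bi], bank$high_Hz[bi]))
    }
  }
  acc <- acc / length(blocks)
  v <- as.numeric(t(acc))           # channel-major, band-minor
  if (log_scale) v <- log10(v + eps)
  names(v) <- paste0(rep(c("Fp1", "Fp2", "diff"), each = nb), "_",
                     sprintf("%g-%g", bank$low_Hz, bank$high_Hz))
  structure(v, n_blocks = length(blocks), log_scale = log_scale,
            bank = bank, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features, averaged over %d block%s (%s scale)\n",
              length(x), attr(x, "n_blocks"),
              if (attr(x, "n_blocks") == 1) "" else "s",
              if (attr(x, "log_scale")) "log10" else "raw"))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Feature vector(s) for a whole recording
#'
#' Convenience wrapper: screens the recording for artifacts, tiles it into
#' clean blocks and extracts one feature vector.
#'
#' @param rec An [eeg_recording()].
#' @param bank A [filter_bank()].
#' @param block_len Block length (s).
#' @param screen Run [detect_artifacts()] first? Default `TRUE`.
#' @param ... Passed to [extract_features()].
#' @return A `feature_vector`.
#' @export
recording_features <- function(rec, bank = default_filter_bank(),
                               block_len = 2, screen = TRUE, ...) {
  mask <- if (screen) detect_artifacts(rec) else artifact_mask()
  extract_features(apply_mask(rec, mask, block_len), bank = bank, ...)
}

#' Write feature vectors as CSV
#'
#' One row per recording/epoch: the feature columns plus `n_blocks`.
#'
#' @param fvs A `feature_vector` or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fvs, path) {
  if (inherits(fvs, "feature_vector")) fvs <- list(fvs)
  d <- do.call(rbind, lapply(fvs, function(f)
    c(as.numeric(f), n_blocks = attr(f, "n_blocks"))))
  colnames(d) <- c(names(fvs[[1]]), "n_blocks")
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}
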
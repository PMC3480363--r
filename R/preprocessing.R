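#' Artifact mask
#'
#' A set of half-open excluded time intervals `[start_s, end_s)` with a
#' reason tag per interval (`"saturation"`, `"disconnection"`, or a `+`-joined
#' combination where events of both kinds merged). Intervals are sorted,
#' merged and clipped to the recording span on construction.
#'
#' @param start_s,end_s Numeric vectors of interval edges (seconds).
#' @param reason Character vector of per-interval tags.
#' @param span Recording span in seconds used for clipping (optional).
#' @return An object of class `artifact_mask` wrapping a data frame with
#'   columns `start_s`, `end_s`, `reason`.
#' @export
artifact_mask <- function(start_s = numeric(), end_s = numeric(),
                          reason = rep("artifact", length(start_s)),
                          span = NULL) {
  if (any(end_s <= start_s)) stopf("mask intervals must have start < end")
  d <- merge_intervals(start_s, end_s, reason)
  if (!is.null(span)) {
    d$start_s <- pmax(d$start_s, 0)
    d$end_s <- pmin(d$end_s, span)
    d <- d[d$end_s > d$start_s, , drop = FALSE]
    rownames(d) <- NULL
  }
  structure(list(excluded = d), class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  n <- nrow(x$excluded)
  cat(sprintf("<artifact_mask> %d excluded interval%s, %.2f s total\n",
              n, if (n == 1) "" else "s",
              sum(x$excluded$end_s - x$excluded$start_s)))
  if (n) print(x$excluded)
  invisible(x)
}

#' @export
as.data.frame.artifact_mask <- function(x, ...) x$excluded

#' Serialize an artifact mask as CSV (`start_s, end_s, reason`)
#' @param mask An [artifact_mask()].
#' @param path File path.
#' @return `write_mask_csv` returns `path` invisibly; `read_mask_csv` an
#'   [artifact_mask()].
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(mask$excluded, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  d <- utils::read.csv(path)
  artifact_mask(d$start_s, d$end_s, as.character(d$reason))
}

# rolling sd over windows of w samples, one window per start index
rolling_sd <- function(x, w) {
  n <- length(x)
  if (w > n) return(numeric(0))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - w + 1L)
  s1 <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- (s2 - s1^2 / w) / (w - 1)
  sqrt(pmax(v, 0))
}

#' Screen a recording for saturation and disconnection artifacts
#'
#' Implements the two abnormality classes of the screening stage: a sample
#' whose magnitude reaches the ADC rail on either channel marks a saturation
#' event, and any window of `flat_window` seconds whose per-channel sample
#' standard deviation falls below `flat_eps` marks a disconnection
#' (flatline) event. Every event is expanded by the guard interval — the
#' excluded region extends `guard` seconds on both sides of the abnormal
#' samples — and overlapping exclusions are merged.
#'
#' @param rec An [eeg_recording()].
#' @param rail Saturation threshold in microvolts (default 512).
#' @param flat_eps Flatline standard-deviation threshold in microvolts
#'   (default 0.1).
#' @param flat_window Flatline detection window in seconds (default 1).
#' @param guard Guard interval in seconds excluded around each abnormality
#'   (default 2, symmetric).
#' @return An [artifact_mask()].
#' @examples
#' rec <- simulate_eeg(attentive_profile(), 20, seed = 1)
#' rec <- inject_artifacts(rec, saturation_times = 10)
#' detect_artifacts(rec)
#' @export
detect_artifacts <- function(rec, rail = 512, flat_eps = 0.1,
                             flat_window = 1, guard = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_number(rail, "rail", 0, strict = TRUE)
  check_number(flat_window, "flat_window", 0, strict = TRUE)
  check_number(guard, "guard", 0)
  n <- length(rec$fp1)
  if (n == 0L) stopf("empty recording")
  fs <- rec$fs
  dur <- duration(rec)

  starts <- numeric(0); ends <- numeric(0); reasons <- character(0)

  sat <- which(abs(rec$fp1) >= rail | abs(rec$fp2) >= rail)
  if (length(sat)) {
    t <- (sat - 1) / fs
    starts <- c(starts, t - guard)
    ends <- c(ends, t + pmax(guard, 1 / fs))  # at least the sample itself
    reasons <- c(reasons, rep("saturation", length(t)))
  }

  w <- max(2L, round(flat_window * fs))
  if (w <= n) {
    sd1 <- rolling_sd(rec$fp1, w)
    sd2 <- rolling_sd(rec$fp2, w)
    flat <- which(sd1 < flat_eps | sd2 < flat_eps)
    if (length(flat)) {
      t0 <- (flat - 1) / fs
      starts <- c(starts, t0 - guard)
      ends <- c(ends, t0 + w / fs + guard)
      reasons <- c(reasons, rep("disconnection", length(flat)))
    }
  }
  artifact_mask(starts, ends, reasons, span = dur)
}

#' Segment a recording into clean analysis blocks
#'
#' Tiles the recording into consecutive non-overlapping blocks of
#' `block_len` seconds anchored at the recording start, drops every block
#' that overlaps an excluded interval of the mask, and drops a trailing
#' partial block. Blocks are returned in time order.
#'
#' @param rec An [eeg_recording()].
#' @param mask An [artifact_mask()] (default: empty mask).
#' @param block_len Block length in seconds (default 2).
#' @return A list of clean blocks, each an `n x 2` matrix with columns
#'   `Fp1`, `Fp2` and attributes `t0` (block start, s) and `fs`. The list
#'   carries attributes `n_total` (number of tiled blocks) and `kept`
#'   (logical vector over all tiled blocks). The list is empty when the mask
#'   covers everything; callers must handle that case.
#' @export
apply_mask <- function(rec, mask = artifact_mask(), block_len = 2) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(mask, "artifact_mask"))
  check_number(block_len, "block_len", 0, strict = TRUE)
  fs <- rec$fs
  bl_n <- round(block_len * fs)
  n_blocks <- floor(length(rec$fp1) / bl_n)
  ex <- mask$excluded
  kept <- logical(n_blocks)
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    t0 <- (b - 1) * block_len
    t1 <- t0 + block_len
    hit <- nrow(ex) > 0 && any(ex$start_s < t1 & ex$end_s > t0)
    kept[b] <- !hit
    if (!hit) {
      i0 <- (b - 1L) * bl_n + 1L
      m <- cbind(Fp1 = rec$fp1[i0:(i0 + bl_n - 1L)],
                 Fp2 = rec$fp2[i0:(i0 + bl_n - 1L)])
      attr(m, "t0") <- t0
      attr(m, "fs") <- fs
      out[[b]] <- m
    }
  }
  out <- out[kept]
  attr(out, "n_total") <- n_blocks
  attr(out, "kept") <- kept
  out
}
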
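#' Avatar speed from the display score
#'
#' The game avatar moves at a speed proportional to the trainee's attention
#' level: `speed = v_max * score / 100`.
#'
#' @param score Display score(s) in `[0, 100]`.
#' @param v_max Maximum avatar speed (track units per second, > 0).
#' @return Speed(s) in the same length as `score`.
#' @export
avatar_speed <- function(score, v_max = 2) {
  check_number(v_max, "v_max", 0, strict = TRUE)
  if (any(score < 0 | score > 100))
    stopf("display scores must lie in [0, 100] (scorer contract)")
  v_max * score / 100
}

# distance integration shared by run_session and the coupling checks:
# trailing moving average of width `smoothing` over scored blocks, zero
# speed on masked blocks
session_kinematics <- function(display, kept, smoothing, v_max, block_len) {
  n <- length(kept)
  smoothed <- rep(NA_real_, n)
  speed <- numeric(n)
  hist <- numeric(0)
  j <- 0L
  for (i in seq_len(n)) {
    if (kept[i]) {
      j <- j + 1L
      hist <- c(hist, display[j])
      w <- utils::tail(hist, smoothing)
      smoothed[i] <- mean(w)
      speed[i] <- avatar_speed(smoothed[i], v_max)
    }
  }
  list(smoothed = smoothed, speed = speed,
       distance = cumsum(speed * block_len))
}

#' Simulate one closed-loop training session
#'
#' Streams a recording through the full pipeline the way the game does:
#' the signal is screened for artifacts, tiled into 2-s blocks, each clean
#' block is scored with the calibrated model, the display score is smoothed
#' by a trailing moving average, and the avatar integrates distance at a
#' speed proportional to the smoothed score. Blocks removed by artifact
#' screening contribute zero movement (they also stand in for breaks).
#'
#' @param model An [fit_attention_model()] object.
#' @param eeg An [eeg_recording()] covering the session, or a generator
#'   `function(duration)` returning one (e.g. wrapping [simulate_eeg()]).
#' @param duration Session length in seconds; defaults to 1800 (a 30-minute
#'   session) when `eeg` is a generator, else to the recording length.
#' @param smoothing Trailing moving-average width in blocks (default 3,
#'   i.e. 6 s).
#' @param v_max Maximum avatar speed (units/s).
#' @param level Game level 1-3; levels 2-3 add fruit collection, modelled
#'   as one Bernoulli fruit opportunity per clean block with success
#'   probability `smoothed score / 100`.
#' @param screen Run artifact screening (default `TRUE`).
#' @param seed Seed for the fruit draws.
#' @return An object of class `session_trace`: data frame with columns
#'   `time_s` (block end), `score` (per-block display score, `NA` when
#'   masked), `smoothed`, `speed`, `distance`, plus attributes `level` and
#'   `fruits_collected`.
#' @export
run_session <- function(model, eeg, duration = NULL, smoothing = 3,
                        v_max = 2, level = 1, screen = TRUE, seed = NULL) {
  stopifnot(inherits(model, "attention_model"))
  if (is.function(eeg)) {
    if (is.null(duration)) duration <- 1800
    eeg <- eeg(duration)
  }
  stopifnot(inherits(eeg, "eeg_recording"))
  if (is.null(duration)) duration <- duration(eeg)
  check_number(duration, "duration", 0, strict = TRUE)
  if (!level %in% 1:3) stopf("level must be 1, 2 or 3")
  block_len <- model$block_len
  mask <- if (screen) detect_artifacts(eeg) else artifact_mask()
  blocks <- apply_mask(eeg, mask, block_len)
  kept <- attr(blocks, "kept")
  n <- attr(blocks, "n_total")
  display <- if (length(blocks)) {
    F <- t(vapply(blocks, function(b)
      as.numeric(extract_features(list(b), bank = model$bank,
                                  log_scale = model$log_scale)),
      numeric(length(model$mu))))
    basm_score(model, F)$display
  } else numeric(0)
  kin <- session_kinematics(display, kept, smoothing, v_max, block_len)
  score_full <- rep(NA_real_, n)
  score_full[kept] <- display
  fruits <- 0L
  if (level >= 2 && any(kept)) {
    p <- kin$smoothed[kept] / 100
    fruits <- with_seed(seed, sum(stats::rbinom(length(p), 1, p)))
  }
  tr <- data.frame(time_s = seq_len(n) * block_len,
                   score = score_full, smoothed = kin$smoothed,
                   speed = kin$speed, distance = kin$distance)
  structure(tr, level = level, fruits_collected = fruits,
            class = c("session_trace", "data.frame"))
}

#' @export
print.session_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<session_trace> %d blocks (%.0f s), level %d\n",
              n, if (n) max(x$time_s) else 0, attr(x, "level")))
  cat(sprintf("  mean display score %.1f, final distance %.1f units",
              mean(x$score, na.rm = TRUE), if (n) x$distance[n] else 0))
  if (attr(x, "level") >= 2)
    cat(sprintf(", %d fruits collected", attr(x, "fruits_collected")))
  cat("\n")
  invisible(x)
}

#' @export
plot.session_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time_s, x$score, type = "p", pch = ".", cex = 2,
                 xlab = "time (s)", ylab = "display score", ylim = c(0, 100),
                 main = "attention score")
  graphics::lines(x$time_s, x$smoothed, col = "steelblue", lwd = 2)
  graphics::plot(x$time_s, x$distance, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "distance (units)",
                 main = "avatar progress")
  invisible(x)
}

#' Write a session trace as CSV
#' @param trace A `session_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Build the training-program schedule
#'
#' The program comprises an intensive phase of 3 sessions weekly for 8
#' weeks (24 sessions, here on days 0/2/4 of each week) followed by a
#' maintenance phase of once-monthly booster sessions for 3 consecutive
#' months.
#'
#' @param start_date First session date (`Date` or string).
#' @return An object of class `program_schedule`: data frame with columns
#'   `session`, `date`, `phase`.
#' @export
build_schedule <- function(start_date = Sys.Date()) {
  d0 <- as.Date(start_date)
  if (is.na(d0)) stopf("invalid start date")
  intensive <- d0 + as.vector(outer(c(0, 2, 4), 7 * (0:7), "+"))
  maintenance <- d0 + 7 * 8 + 28 * (1:3)
  out <- data.frame(session = seq_len(27),
                    date = c(sort(intensive), maintenance),
                    phase = rep(c("intensive", "maintenance"), c(24, 3)))
  structure(out, class = c("program_schedule", "data.frame"))
}

#' @export
print.program_schedule <- function(x, ...) {
  cat(sprintf("<program_schedule> %d intensive + %d maintenance sessions, %s to %s\n",
              sum(x$phase == "intensive"), sum(x$phase == "maintenance"),
              min(x$date), max(x$date)))
  invisible(x)
}
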
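test_that("silent profile yields an all-zero recording and seeds reproduce", {
  p0 <- state_profile()
  rec <- simulate_eeg(p0, 5, 128, seed = 1)
  expect_equal(rec$fp1, rep(0, 5 * 128))
  expect_equal(rec$fp2, rep(0, 5 * 128))

  p <- attentive_profile()
  a <- simulate_eeg(p, 3, 128, seed = 42)
  b <- simulate_eeg(p, 3, 128, seed = 42)
  expect_identical(a$fp1, b$fp1)
  expect_identical(a$fp2, b$fp2)
  c <- simulate_eeg(p, 3, 128, seed = 43)
  expect_false(identical(a$fp1, c$fp1))
})

test_that("generator leaves the caller's RNG stream untouched", {
  set.seed(7)
  before <- .Random.seed
  invisible(simulate_eeg(attentive_profile(), 2, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("single-band profiles concentrate spectral power in their band", {
  # independent periodogram oracle: raw FFT of the whole recording
  periodogram_band_fraction <- function(x, fs, lo, hi) {
    n <- length(x)
    p <- Mod(stats::fft(x))^2
    f <- (0:(n - 1)) * fs / n
    half <- f <= fs / 2
    sum(p[half & f >= lo & f < hi]) / sum(p[half])
  }
  cases <- list(list(state_profile(beta_amp = 10), 13, 30),
                list(state_profile(theta_amp = 10), 4, 8),
                list(state_profile(alpha_amp = 10), 8, 12))
  for (cs in cases) {
    rec <- simulate_eeg(cs[[1]], 10, 128, seed = 11)
    frac <- periodogram_band_fraction(rec$fp1, 128, cs[[2]], cs[[3]])
    expect_gte(frac, 0.90)
  }
})

test_that("oscillation RMS matches the profile amplitude", {
  rec <- simulate_eeg(state_profile(beta_amp = 10), 10, 128, seed = 2)
  expect_equal(sqrt(mean(rec$fp1^2)), 10, tolerance = 1e-6)
})

test_that("blinks are common-mode; oscillations are channel-independent", {
  rec <- simulate_eeg(state_profile(blink_rate = 30, blink_amp = 100),
                      20, 128, seed = 3)
  expect_equal(rec$fp1, rec$fp2)          # blink-only: identical channels
  expect_gt(max(rec$fp1), 50)             # blinks actually present
  rec2 <- simulate_eeg(state_profile(beta_amp = 10), 10, 128, seed = 3)
  expect_lt(abs(stats::cor(rec2$fp1, rec2$fp2)), 0.2)
})

test_that("generator rejects bad duration and sampling rate", {
  expect_error(simulate_eeg(attentive_profile(), 0), "duration")
  expect_error(simulate_eeg(attentive_profile(), 10, fs = 50), "60 Hz")
  expect_error(state_profile(theta_amp = -1), "theta_amp")
})

test_that("artifact injection clamps, flattens, and leaves the rest alone", {
  rec <- ramp_recording(20)
  expect_identical(inject_artifacts(rec), rec)   # empty lists: identity

  out <- inject_artifacts(rec, saturation_times = 10.0, rail_value = 512)
  i <- round(10 * 128) + 1
  expect_true(out$fp1[i] %in% c(-512, 512))
  expect_equal(out$fp1[-i], rec$fp1[-i])

  out2 <- inject_artifacts(rec, flatline_intervals = list(c(3, 5)))
  idx <- (floor(3 * 128) + 1):ceiling(5 * 128)
  expect_equal(stats::var(out2$fp1[idx]), 0)
  expect_equal(stats::var(out2$fp2[idx]), 0)
  expect_equal(out2$fp1[-idx], rec$fp1[-idx])

  expect_error(inject_artifacts(rec, saturation_times = 25), "span")
  expect_error(inject_artifacts(rec, flatline_intervals = list(c(18, 21))),
               "span")
})

test_that("calibration datasets are balanced, sized and validated", {
  cal <- simulate_calibration(n_epochs_per_label = 5, epoch_len = 4, seed = 1)
  expect_length(cal$epochs, 10)
  labs <- vapply(cal$epochs, `[[`, "", "label")
  expect_equal(sum(labs == "attentive"), 5)
  expect_equal(sum(labs == "relaxed"), 5)
  durs <- vapply(cal$epochs, function(e) basm::duration(e$rec), 0)
  expect_true(all(durs == 4))

  expect_error(simulate_calibration(n_epochs_per_label = 1), "at least 2")
  expect_error(simulate_calibration(epoch_len = 3), "multiple")
  expect_error(
    simulate_calibration(attentive = inattentive_profile(),
                         inattentive = attentive_profile()),
    "theta/beta")
})

test_that("trial generator honours its degenerate contracts", {
  # no effect, no noise, no dropout: follow-ups equal baseline
  cfg <- trial_sim_config(n_subjects = 10, effect_slope = 0, residual_sd = 0,
                          dropout = numeric(), seed = 5)
  tb <- simulate_trial(cfg)
  r <- tb$ratings
  base <- r[r$week == 0, c("subject_id", "IA", "HI", "COM")]
  for (w in c(4, 8, 20, 24)) {
    m <- merge(base, r[r$week == w, c("subject_id", "IA", "HI", "COM")],
               by = "subject_id")
    expect_equal(m$IA.x, m$IA.y)
    expect_equal(m$COM.x, m$COM.y)
  }

  # certain dropout at week 4: everyone missing from week 4 onward
  tb2 <- simulate_trial(trial_sim_config(n_subjects = 8,
                                         dropout = c("4" = 1), seed = 6))
  r2 <- tb2$ratings
  expect_true(all(is.na(r2$IA[r2$week >= 4])))
  expect_true(all(!is.na(r2$IA[r2$week == 0])))

  # invariants of the table: COM = IA + HI, legal ranges
  tb3 <- simulate_trial(trial_sim_config(n_subjects = 50, seed = 7))
  r3 <- tb3$ratings[stats::complete.cases(tb3$ratings), ]
  expect_equal(r3$COM, r3$IA + r3$HI)
  expect_true(all(r3$IA >= 0 & r3$IA <= 27))
  expect_true(all(r3$COM >= 0 & r3$COM <= 54))
})

test_that("trial generator config is validated", {
  expect_error(trial_sim_config(n_subjects = 1), "n_subjects")
  expect_error(trial_sim_config(baseline_sd = c(IA = 0, HI = 1)), "baseline_sd")
  expect_error(trial_sim_config(dropout = c("4" = 1.2)), "dropout")
})
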
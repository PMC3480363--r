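test_that("item scoring matches a brute-force summation oracle", {
  expect_equal(score_items(rep(0, 18)), c(IA = 0, HI = 0, COM = 0))
  expect_equal(score_items(rep(3, 18)), c(IA = 27, HI = 27, COM = 54))

  set.seed(1)
  for (r in 1:20) {
    items <- sample(0:3, 18, replace = TRUE)
    s <- score_items(items)
    # oracle: direct sums
    expect_equal(unname(s["IA"]), sum(items[1:9]))
    expect_equal(unname(s["HI"]), sum(items[10:18]))
    expect_equal(unname(s["COM"]), sum(items))
  }
  expect_equal(score_items(rep(c(1, 2), 9)),
               c(IA = 13, HI = 14, COM = 27))  # alternating 1/2 by hand

  expect_error(score_items(rep(1, 17)), "18")
  expect_error(score_items(c(rep(1, 17), 4)), "\\{0, 1, 2, 3\\}")
})

test_that("LOCF fills from strictly earlier weeks and never edits observations", {
  # complete table: identity
  tb <- simulate_trial(trial_sim_config(n_subjects = 10, dropout = numeric(),
                                        seed = 2))
  expect_equal(locf(tb$ratings), tb$ratings[order(tb$ratings$subject_id), ],
               ignore_attr = TRUE)

  # subject observed at weeks 0 and 8 only: weeks 20/24 carry week 8
  r <- data.frame(subject_id = "A", week = c(0, 4, 8, 20, 24),
                  IA = c(20, NA, 12, NA, NA), HI = c(15, NA, 10, NA, NA))
  r$COM <- r$IA + r$HI
  f <- locf(r)
  expect_equal(f$IA, c(20, 20, 12, 12, 12))
  expect_equal(f$COM, c(35, 35, 22, 22, 22))

  # baseline-only subject dropped under the no-followup rule, kept otherwise
  r2 <- rbind(r, data.frame(subject_id = "B", week = c(0, 4, 8, 20, 24),
                            IA = c(18, NA, NA, NA, NA), HI = NA, COM = NA))
  expect_false("B" %in% locf(r2, drop_no_followup = TRUE)$subject_id)
  f2 <- locf(r2, drop_no_followup = FALSE)
  expect_equal(f2$IA[f2$subject_id == "B"], rep(18, 5))

  # missing baseline: subject removed with a warning
  r3 <- data.frame(subject_id = "C", week = c(0, 8), IA = c(NA, 10),
                   HI = c(NA, 8), COM = c(NA, 18))
  expect_warning(out <- locf(rbind(r, r3)), "baseline")
  expect_false("C" %in% out$subject_id)

  # fills come only from earlier weeks; observed values untouched
  set.seed(3)
  tb2 <- simulate_trial(trial_sim_config(n_subjects = 30, seed = 3))
  f3 <- locf(tb2$ratings)
  obs <- merge(tb2$ratings, f3, by = c("subject_id", "week"),
               suffixes = c("_raw", "_locf"))
  keep <- !is.na(obs$IA_raw)
  expect_equal(obs$IA_locf[keep], obs$IA_raw[keep])
})

test_that("paired changes recover simulated shifts and guard degeneracy", {
  # mean of paired differences equals difference of group means
  tb <- simulate_trial(trial_sim_config(n_subjects = 50, dropout = numeric(),
                                        seed = 4))
  ch <- mean_change(tb$ratings, "IA", 0, 8)
  g <- visit_summary(tb$ratings)
  m0 <- g$mean[g$subscale == "IA" & g$week == 0]
  m8 <- g$mean[g$subscale == "IA" & g$week == 8]
  expect_equal(ch$mean_change, m8 - m0, tolerance = 1e-12)

  # parameter recovery of a pure shift: slope 0, intercept delta = -5
  cfg <- trial_sim_config(n_subjects = 200, effect_slope = 0,
                          change_intercept = -5, residual_sd = 3,
                          dropout = numeric(), seed = 5)
  ch2 <- mean_change(simulate_trial(cfg)$ratings, "IA", 0, 8)
  expect_equal(ch2$mean_change, -5, tolerance = 0.5)
  expect_lt(ch2$p_value, 0.001)

  # identical columns: degenerate flag, p = 1
  r <- data.frame(subject_id = rep(c("A", "B", "C"), 2),
                  week = rep(c(0, 8), each = 3), IA = rep(c(10, 12, 14), 2),
                  HI = 1, COM = 1)
  ch3 <- mean_change(r, "IA", 0, 8)
  expect_true(ch3$degenerate)
  expect_equal(ch3$mean_change, 0)
  expect_equal(ch3$p_value, 1)

  expect_error(mean_change(r[r$subject_id == "A", ], "IA"), "paired")
})

test_that("baseline-predicts-change regression recovers its slope", {
  cfg <- trial_sim_config(n_subjects = 200, effect_slope = -0.7,
                          residual_sd = 3, seed = 6)
  fit <- baseline_predicts_change(simulate_trial(cfg)$ratings, "IA")
  expect_equal(fit$beta, -0.7, tolerance = 0.1)
  expect_lt(fit$p, 0.001)

  # perfect linear relation: exact slope, zero standard error
  r <- data.frame(subject_id = sprintf("S%d", 1:6), week = 0,
                  IA = c(5, 8, 11, 14, 17, 20), HI = 1, COM = 1)
  r8 <- r; r8$week <- 8; r8$IA <- r$IA - 0.5 * r$IA
  fit2 <- suppressWarnings(baseline_predicts_change(rbind(r, r8), "IA"))
  expect_equal(fit2$beta, -0.5, tolerance = 1e-12)
  expect_lt(fit2$se, 1e-8)

  # type-I behaviour: with no baseline effect the slope is rarely "significant"
  flat <- vapply(1:100, function(s) {
    cfg0 <- trial_sim_config(n_subjects = 40, effect_slope = 0,
                             residual_sd = 3, dropout = numeric(), seed = s)
    f <- baseline_predicts_change(simulate_trial(cfg0)$ratings, "IA")
    abs(f$beta) < 2 * f$se
  }, TRUE)
  expect_gte(mean(flat), 0.9)

  r0 <- data.frame(subject_id = c("A", "B", "C"), week = 0, IA = 10,
                   HI = 1, COM = 1)
  r08 <- r0; r08$week <- 8
  expect_error(baseline_predicts_change(rbind(r0, r08), "IA"),
               "baseline variance")
})

test_that("Spearman change correlation has exact anchors and sign recovery", {
  # strictly decreasing functional relation: rho = -1
  r <- data.frame(subject_id = sprintf("S%d", 1:6),
                  week = rep(0, 6), IA = 1, HI = 1, COM = 10 + (1:6))
  r20 <- r; r20$week <- 20; r20$COM <- r$COM + c(-1, -3, -5, -8, -11, -13)
  basm <- data.frame(subject_id = rep(sprintf("S%d", 1:6), each = 2),
                     week = rep(c(0, 20), 6), basm = 0)
  basm$basm[basm$week == 20] <- c(1, 3, 5, 8, 11, 13)  # reversed ranks
  out <- basm_change_correlation(rbind(r, r20), basm, "COM")
  expect_equal(out$rho, -1)

  # permuted pairing is consistent with the null
  set.seed(7)
  tb <- simulate_trial(trial_sim_config(n_subjects = 60, dropout = numeric(),
                                        seed = 8))
  shuffled <- tb$basm
  w20 <- shuffled$week == 20
  shuffled$basm[w20] <- shuffled$basm[w20][sample(sum(w20))]
  rhos <- replicate(50, {
    s2 <- tb$basm
    s2$basm[w20] <- s2$basm[w20][sample(sum(w20))]
    basm_change_correlation(tb$ratings, s2, "COM")$rho
  })
  expect_lt(stats::quantile(abs(rhos), 0.95), 0.4)

  # constant vector rejected
  const <- tb$basm; const$basm <- 1
  expect_error(basm_change_correlation(tb$ratings, const, "COM"), "constant")
})

test_that("completion accounting reproduces the disposition arithmetic", {
  expect_equal(completion_summary(c(rep(NA, 17), 3, 6, 6)),
               list(n_enrolled = 20, n_completed = 17, pct = 85.0))
  expect_equal(completion_summary(rep(NA, 12))$pct, 100.0)
  expect_equal(completion_summary(c(4, 8, 20))$pct, 0.0)
})

test_that("the multiple-imputation route is interface-only", {
  tb <- simulate_trial(trial_sim_config(n_subjects = 5, seed = 9))
  expect_error(impute_missing(tb$ratings, method = "mi"), "interface only")
  expect_equal(impute_missing(tb$ratings, method = "locf"), locf(tb$ratings))
})
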
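test_that("mutual information hits its closed-form anchors", {
  # perfectly separating feature, balanced labels: MI = H(label) = 1 bit
  y <- rep(c("attentive", "relaxed"), each = 20)
  x <- c(stats::rnorm(20, 10, 0.1), stats::rnorm(20, -10, 0.1))
  expect_equal(mutual_information(x, y), 1.0, tolerance = 0.05)

  # constant feature carries nothing
  expect_equal(mutual_information(rep(1, 40), y), 0)

  # symmetry under label relabelling
  y_flipped <- ifelse(y == "attentive", "relaxed", "attentive")
  set.seed(1); x2 <- stats::rnorm(40)
  expect_equal(mutual_information(x2, y), mutual_information(x2, y_flipped))

  # invariance under strictly monotone transforms (equal-frequency bins)
  x3 <- stats::runif(40, 1, 2)
  expect_equal(mutual_information(x3, y), mutual_information(exp(x3), y))

  # MI bounded for binary labels
  expect_gte(mutual_information(x2, y), 0)
  expect_lte(mutual_information(x, y), 1 + 1e-9)
})

test_that("independent features sit inside their permutation null", {
  set.seed(2)
  n <- 200
  y <- rep(c("attentive", "relaxed"), each = n / 2)
  x <- stats::rnorm(n)
  observed <- mutual_information(x, y)
  null <- replicate(1000, mutual_information(x, sample(y)))
  expect_lt(observed, stats::quantile(null, 0.95))
})

test_that("feature selection ranks by MI with stable index tie-breaks", {
  set.seed(3)
  y <- rep(c("attentive", "relaxed"), each = 20)
  strong <- c(stats::rnorm(20, 5), stats::rnorm(20, -5))
  weak <- stats::rnorm(40)
  X <- cbind(weak, strong, weak + 0.01)
  sel <- select_features(X, y, k = 1)
  expect_equal(as.integer(sel), 2L)
  # exhaustive k returns all columns, MI-sorted
  sel_all <- select_features(X, y, k = 3)
  expect_setequal(as.integer(sel_all), 1:3)
  mi <- attr(sel_all, "mi")
  expect_equal(as.integer(sel_all), order(-mi, seq_along(mi)))

  # exact ties break toward the lower index
  X_tie <- cbind(a = strong, b = strong)
  expect_equal(as.integer(select_features(X_tie, y, k = 2)), c(1L, 2L))

  expect_error(select_features(X, y, k = 0), "positive")
})

test_that("identical-state calibration shows no feature significantly informative", {
  # both labels drawn from the same profile: every feature's MI should be
  # indistinguishable from its label-permutation null
  cal <- simulate_calibration(attentive = state_profile(3, 5, 6.0001, 3, 10, 80),
                              inattentive = state_profile(3, 5, 6, 3, 10, 80),
                              n_epochs_per_label = 20, seed = 4)
  ef <- basm:::epoch_feature_matrix(cal, default_filter_bank())
  set.seed(5)
  mi_obs <- apply(ef$X, 2, mutual_information, labels = ef$y)
  null_max <- replicate(200, {
    ys <- sample(ef$y)
    max(apply(ef$X, 2, mutual_information, labels = ys))
  })
  expect_lt(max(mi_obs), stats::quantile(null_max, 0.99))
})

test_that("well-separated profiles calibrate to an accurate, deterministic model", {
  cal <- simulate_calibration(n_epochs_per_label = 20, seed = 6)
  m1 <- fit_attention_model(cal)
  m2 <- fit_attention_model(cal)
  expect_identical(m1$weights, m2$weights)            # no internal randomness
  expect_identical(m1$selected, m2$selected)

  expect_gte(loo_accuracy(cal), 0.90)

  # the discriminative bands: theta (4-8) and beta (13-30) differ between
  # profiles, so no selected feature should sit wholly inside alpha
  bank <- m1$bank
  band_idx <- (m1$selected - 1) %% nrow(bank) + 1
  in_alpha <- bank$low_Hz[band_idx] >= 8 & bank$high_Hz[band_idx] <= 12
  expect_false(any(in_alpha))

  expect_error(fit_attention_model(
    structure(list(epochs = cal$epochs[1:3][c(1, 1, 1)], subject_id = "x"),
              class = "calibration_dataset")), "both labels")
})

test_that("shuffled labels drop leave-one-out accuracy to chance", {
  # a single permutation can retain sizeable overlap with the true labels
  # at n = 40, so estimate the chance level as the mean over shuffles
  cal <- simulate_calibration(n_epochs_per_label = 20, seed = 7)
  set.seed(8)
  labs <- vapply(cal$epochs, `[[`, "", "label")
  acc <- mean(vapply(1:5, function(i)
    loo_accuracy(cal, labels = sample(labs)), 0))
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("scores respect the display-map construction and logistic limits", {
  cal <- simulate_calibration(n_epochs_per_label = 10, seed = 9)
  m <- fit_attention_model(cal)
  ef <- basm:::epoch_feature_matrix(cal, m$bank)
  att_mean <- colMeans(ef$X[ef$y == "attentive", ])
  rel_mean <- colMeans(ef$X[ef$y == "relaxed", ])
  s_att <- basm_score(m, att_mean)
  s_rel <- basm_score(m, rel_mean)
  expect_gte(s_att$display, 50)
  expect_lte(s_rel$display, 50)
  # anchoring: class means map near 75 / 25
  expect_equal(s_att$display, 75, tolerance = 10)
  expect_equal(s_rel$display, 25, tolerance = 10)

  # monotone display in raw, with logistic limits
  raws <- seq(-50, 50, length.out = 11)
  disp <- 100 * stats::plogis((raws - m$display_map["center"]) /
                                m$display_map["scale"])
  expect_true(all(diff(disp) >= 0))
  expect_true(all(basm_score(m, ef$X)$display >= 0 &
                    basm_score(m, ef$X)$display <= 100))

  expect_error(basm_score(m, rep(0, 5)), "feature length mismatch")
})

test_that("model methods and JSON round trip are consistent", {
  cal <- simulate_calibration(n_epochs_per_label = 10, seed = 10)
  m <- fit_attention_model(cal)
  expect_length(coef(m), m$k + 1)
  expect_equal(length(fitted(m)), 20)
  expect_equal(fitted(m) + residuals(m),
               ifelse(vapply(cal$epochs, `[[`, "", "label") == "attentive",
                      1, -1))
  s <- summary(m)
  expect_gte(s$train_accuracy, 0.9)

  f <- withr::local_tempfile(fileext = ".json")
  write_attention_model(m, f)
  m2 <- read_attention_model(f)
  ef <- basm:::epoch_feature_matrix(cal, m$bank)
  expect_equal(basm_score(m2, ef$X)$raw, basm_score(m, ef$X)$raw,
               tolerance = 1e-12)
  expect_equal(basm_score(m2, ef$X)$display, basm_score(m, ef$X)$display,
               tolerance = 1e-12)

  # predict dispatch on recordings and datasets
  rec <- simulate_eeg(attentive_profile(), 10, seed = 11)
  expect_length(predict(m, rec), 1)
  both <- predict(m, cal, type = "both")
  expect_equal(nrow(both), 20)
})
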
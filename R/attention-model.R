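#' Mutual information between a feature and a binary label
#'
#' Plug-in estimate of the mutual information (in bits) between a
#' discretized feature and the epoch label. The feature is discretized into
#' `n_bins` equal-frequency bins (quantile cut points), which makes the
#' estimate invariant under strictly monotone transforms of the feature. A
#' constant feature carries no information and returns 0.
#'
#' @param feature Numeric vector, one value per epoch.
#' @param labels Vector of two classes (factor, character or logical), same
#'   length.
#' @param n_bins Number of bins (>= 2, default 8).
#' @return Mutual information in bits, in `[0, 1]` for binary labels up to
#'   estimator noise.
#' @export
mutual_information <- function(feature, labels, n_bins = 8) {
  if (length(feature) != length(labels))
    stopf("feature and labels differ in length")
  if (n_bins < 2) stopf("n_bins must be >= 2")
  y <- as.factor(labels)
  if (nlevels(y) != 2L) stopf("labels must have exactly two classes")
  if (min(table(y)) < 2L) stopf("need at least 2 epochs per label")
  br <- unique(stats::quantile(feature, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(0)          # constant feature
  xb <- cut(feature, breaks = br, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Rank and select features by mutual information
#'
#' Scores every feature column by its mutual information with the label and
#' returns the indices of the top `k`, in descending MI order; exact MI ties
#' are broken by ascending feature index so selection is stable.
#'
#' @param features Numeric matrix, epochs in rows, features in columns.
#' @param labels Binary label vector (length `nrow(features)`).
#' @param k Number of features to keep (default 6; `k = ncol` ranks all).
#' @param n_bins Bins for the MI estimate.
#' @return Integer vector of selected column indices with attribute `mi`
#'   (the MI of every column, in column order).
#' @export
select_features <- function(features, labels, k = 6, n_bins = 8) {
  features <- as.matrix(features)
  if (k <= 0) stopf("k must be positive")
  if (k > ncol(features))
    stopf("k (%d) exceeds the number of features (%d)", k, ncol(features))
  mi <- apply(features, 2, mutual_information, labels = labels, n_bins = n_bins)
  ord <- order(-mi, seq_along(mi))
  structure(ord[seq_len(k)], mi = unname(mi))
}

# per-epoch feature matrix for a calibration dataset
epoch_feature_matrix <- function(cal, bank, block_len = 2, log_scale = TRUE,
                                 window = "rectangular") {
  X <- t(vapply(cal$epochs, function(e)
    as.numeric(extract_features(apply_mask(e$rec, block_len = block_len),
                                bank = bank, log_scale = log_scale,
                                window = window)),
    numeric(3L * nrow(bank))))
  colnames(X) <- names(extract_features(
    apply_mask(cal$epochs[[1]]$rec, block_len = block_len),
    bank = bank, log_scale = log_scale, window = window))
  list(X = X, y = vapply(cal$epochs, `[[`, "", "label"))
}

# ridge fit of y (+1/-1) on Z[, sel]; unpenalised intercept
ridge_fit <- function(Z, y, ridge) {
  A <- cbind(1, Z)
  P <- diag(c(0, rep(ridge, ncol(Z))))
  as.numeric(solve(crossprod(A) + P, crossprod(A, y)))
}

#' Calibrate a subject-specific attention model
#'
#' The core fitting routine. From a labeled calibration dataset it
#' (1) extracts the band-power feature vector of every epoch, (2)
#' standardizes features to the calibration mean and standard deviation,
#' (3) selects the `k` most discriminative features by mutual information
#' with the attentive/relaxed label, (4) fits a ridge-regularized linear
#' regression of the label coding (attentive = +1, relaxed = -1) on the
#' selected features, and (5) anchors a logistic display transform so that
#' the mean attentive calibration epoch maps near 75 and the mean relaxed
#' epoch near 25 on the 0-100 display scale.
#'
#' The raw score is unbounded (higher = more attentive); only the display
#' score is squashed into `[0, 100]`.
#'
#' @param cal A `calibration_dataset` (see [simulate_calibration()]), with
#'   both labels present.
#' @param bank A [filter_bank()].
#' @param k Number of features to select (default 6).
#' @param ridge Ridge penalty (default 1).
#' @param n_bins MI bins (default 8, equal-frequency).
#' @param block_len Analysis block length in seconds (default 2).
#' @param log_scale Log-transform band powers (default `TRUE`).
#' @param visit Optional tag recording which calibration visit produced the
#'   model (calibration is repeated over the program; scheduling is the
#'   caller's concern).
#' @return An object of class `attention_model` with components `selected`
#'   (feature indices), `weights` (intercept + coefficients), `mu`/`sigma`
#'   (standardizer), `display_map` (`center`, `scale` of the logistic
#'   squashing), `mi` (per-feature MI), and the calibration scores used to
#'   anchor the display map.
#' @examples
#' cal <- simulate_calibration(n_epochs_per_label = 5, seed = 1)
#' m <- fit_attention_model(cal)
#' m
#' @export
fit_attention_model <- function(cal, bank = default_filter_bank(), k = 6,
                                ridge = 1, n_bins = 8, block_len = 2,
                                log_scale = TRUE, visit = NULL) {
  stopifnot(inherits(cal, "calibration_dataset"))
  ef <- epoch_feature_matrix(cal, bank, block_len, log_scale)
  X <- ef$X; y <- ef$y
  if (length(unique(y)) < 2L)
    stopf("calibration dataset must contain both labels")
  fit_attention_core(X, y, bank = bank, k = k, ridge = ridge, n_bins = n_bins,
                     block_len = block_len, log_scale = log_scale,
                     subject_id = cal$subject_id, visit = visit)
}

# fit from a precomputed feature matrix (also used for cross-validation)
fit_attention_core <- function(X, y, bank, k, ridge, n_bins, block_len,
                               log_scale, subject_id = "unknown",
                               visit = NULL) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  sigma[sigma < 1e-12] <- 1            # constant feature: carries no signal
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  sel <- select_features(Z, y, k = k, n_bins = n_bins)
  yc <- ifelse(y == "attentive", 1, -1)
  w <- ridge_fit(Z[, sel, drop = FALSE], yc, ridge)
  raw <- as.numeric(cbind(1, Z[, sel, drop = FALSE]) %*% w)
  m_att <- mean(raw[yc == 1]); m_rel <- mean(raw[yc == -1])
  center <- (m_att + m_rel) / 2
  # logistic((m_att - center)/scale) = 0.75  =>  scale = (m_att - m_rel)/(2 log 3)
  scale <- max((m_att - m_rel) / (2 * log(3)), 1e-6)
  structure(list(
    selected = as.integer(sel),
    weights = w,
    mu = mu, sigma = sigma,
    display_map = c(center = center, scale = scale),
    mi = attr(sel, "mi"),
    bank = bank, k = k, ridge = ridge, n_bins = n_bins,
    block_len = block_len, log_scale = log_scale,
    feature_names = colnames(X),
    subject_id = subject_id, visit = visit,
    calibration = list(raw = raw, labels = y),
    schema_version = "1.0"
  ), class = "attention_model")
}

#' Score a feature vector with a calibrated model
#'
#' Computes the raw attention score (regression output; unbounded, higher =
#' more attentive) and the display score
#' `100 * logistic((raw - center) / scale)` in `[0, 100]` shown to the
#' trainee. The display transform is non-decreasing in the raw score by
#' construction.
#'
#' @param model An [fit_attention_model()] object.
#' @param fv A `feature_vector`, or a numeric vector/matrix of features with
#'   the model's feature length (rows = observations).
#' @return A data frame with columns `raw` and `display`.
#' @export
basm_score <- function(model, fv) {
  stopifnot(inherits(model, "attention_model"))
  F <- if (is.matrix(fv)) fv else matrix(as.numeric(fv), nrow = 1)
  if (ncol(F) != length(model$mu))
    stopf("feature length mismatch: model expects %d features, got %d",
          length(model$mu), ncol(F))
  Z <- sweep(sweep(F, 2, model$mu), 2, model$sigma, "/")
  raw <- as.numeric(cbind(1, Z[, model$selected, drop = FALSE]) %*% model$weights)
  display <- 100 * stats::plogis((raw - model$display_map["center"]) /
                                   model$display_map["scale"])
  data.frame(raw = raw, display = as.numeric(display))
}

#' @export
print.attention_model <- function(x, ...) {
  cat(sprintf("<attention_model> subject %s%s\n", x$subject_id,
              if (is.null(x$visit)) "" else paste0(" (visit ", x$visit, ")")))
  cat(sprintf("  %d of %d features selected by mutual information:\n",
              length(x$selected), length(x$mu)))
  cat("   ", paste(x$feature_names[x$selected], collapse = ", "), "\n")
  cat(sprintf("  display map: center %.3f, scale %.3f\n",
              x$display_map["center"], x$display_map["scale"]))
  invisible(x)
}

#' @export
summary.attention_model <- function(object, ...) {
  raw <- object$calibration$raw
  y <- object$calibration$labels
  acc <- mean((raw > 0) == (y == "attentive"))
  out <- list(model = object,
              mi_table = data.frame(feature = object$feature_names,
                                    mi_bits = object$mi,
                                    selected = seq_along(object$mi) %in%
                                      object$selected),
              train_accuracy = acc,
              class_means = c(attentive = mean(raw[y == "attentive"]),
                              relaxed = mean(raw[y == "relaxed"])))
  class(out) <- "summary.attention_model"
  out
}

#' @export
print.summary.attention_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training accuracy (raw > 0): %.1f%%\n", 100 * x$train_accuracy))
  cat(sprintf("  mean raw score: attentive %.3f, relaxed %.3f\n",
              x$class_means["attentive"], x$class_means["relaxed"]))
  tab <- x$mi_table[order(-x$mi_table$mi_bits), ]
  print(utils::head(tab, 8), row.names = FALSE)
  invisible(x)
}

#' @export
coef.attention_model <- function(object, ...) {
  stats::setNames(object$weights,
                  c("(Intercept)", object$feature_names[object$selected]))
}

#' @export
fitted.attention_model <- function(object, ...) object$calibration$raw

#' @export
residuals.attention_model <- function(object, ...) {
  y <- ifelse(object$calibration$labels == "attentive", 1, -1)
  y - object$calibration$raw
}

#' Predict attention scores for new data
#'
#' @param object An `attention_model`.
#' @param newdata A `feature_vector`, feature matrix, [eeg_recording()]
#'   (screened, tiled and reduced to one feature vector), or
#'   `calibration_dataset` (one score per epoch).
#' @param type `"display"` (default), `"raw"`, or `"both"` (data frame).
#' @param ... Unused.
#' @return Numeric vector of scores, or a data frame for `type = "both"`.
#' @export
predict.attention_model <- function(object, newdata,
                                    type = c("display", "raw", "both"), ...) {
  type <- match.arg(type)
  fv <- if (inherits(newdata, "eeg_recording")) {
    recording_features(newdata, bank = object$bank,
                       block_len = object$block_len,
                       log_scale = object$log_scale)
  } else if (inherits(newdata, "calibration_dataset")) {
    epoch_feature_matrix(newdata, object$bank, object$block_len,
                         object$log_scale)$X
  } else newdata
  s <- basm_score(object, if (is.matrix(fv)) fv else as.numeric(fv))
  switch(type, display = s$display, raw = s$raw, both = s)
}

#' @export
plot.attention_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- ifelse(seq_along(x$mi) %in% x$selected, "steelblue", "grey70")
  graphics::barplot(x$mi, names.arg = x$feature_names, las = 2,
                    col = cols, cex.names = 0.6,
                    ylab = "mutual information (bits)",
                    main = "feature discriminability")
  raw <- x$calibration$raw
  y <- factor(x$calibration$labels)
  graphics::stripchart(raw ~ y, vertical = TRUE, pch = 16, method = "jitter",
                       col = c("forestgreen", "orange"),
                       ylab = "raw score", main = "calibration separation")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Leave-one-out calibration accuracy
#'
#' Refits the full selection + regression pipeline with each epoch held out
#' in turn and reports the fraction of held-out epochs whose raw score sign
#' matches their label (raw > 0 for attentive).
#'
#' @inheritParams fit_attention_model
#' @param labels Optional label vector overriding the dataset labels (e.g.
#'   shuffled labels for a chance-level check).
#' @return Accuracy in `[0, 1]`.
#' @export
loo_accuracy <- function(cal, bank = default_filter_bank(), k = 6, ridge = 1,
                         n_bins = 8, block_len = 2, log_scale = TRUE,
                         labels = NULL) {
  ef <- epoch_feature_matrix(cal, bank, block_len, log_scale)
  X <- ef$X
  y <- if (is.null(labels)) ef$y else labels
  n <- nrow(X)
  ok <- logical(n)
  for (i in seq_len(n)) {
    m <- fit_attention_core(X[-i, , drop = FALSE], y[-i], bank = bank, k = k,
                            ridge = ridge, n_bins = n_bins,
                            block_len = block_len, log_scale = log_scale)
    s <- basm_score(m, X[i, , drop = FALSE])
    ok[i] <- (s$raw > 0) == (y[i] == "attentive")
  }
  mean(ok)
}

#' Persist / restore an attention model as JSON
#'
#' Models serialize losslessly (full double precision) to a structured-text
#' JSON file carrying a schema version.
#'
#' @param model An `attention_model`.
#' @param path File path.
#' @return `write_attention_model` returns `path` invisibly;
#'   `read_attention_model` returns the model.
#' @export
write_attention_model <- function(model, path) {
  stopifnot(inherits(model, "attention_model"))
  x <- unclass(model)
  x$bank <- as.data.frame(unclass(model$bank))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_attention_model
#' @export
read_attention_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$schema_version))
    stopf("`%s` is not a serialized attention model", path)
  x$bank <- structure(as.data.frame(x$bank), class = c("filter_bank", "data.frame"))
  x$display_map <- stats::setNames(unlist(x$display_map), c("center", "scale"))
  x$mu <- unlist(x$mu); x$sigma <- unlist(x$sigma)
  x$selected <- as.integer(x$selected)
  x$calibration <- list(raw = as.numeric(x$calibration$raw),
                        labels = as.character(x$calibration$labels))
  structure(x, class = "attention_model")
}
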
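#' Configuration for the synthetic-trial generator
#'
#' Defaults reproduce the single-arm study conditions: 20 children, baseline
#' inattentive (IA) and hyperactive-impulsive (HI) subscores with means
#' 17.7 and 15.6 and SDs 5.0 and 3.9 points, improvement proportional to
#' baseline severity with slope -0.7 change points per baseline point,
#' dropout hazards of 5% before week 4 and 10% between weeks 4 and 8, and a
#' negative coupling of -0.6 between the change in the EEG-derived attention
#' score (BASM) and the change in the rating-scale score. BASM moments
#' default to a week-0 mean (SD) of 60.9 (81.0) and a change of 32.5 (60.8).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param baseline_mean,baseline_sd Named vectors `c(IA = , HI = )` of
#'   baseline subscore means / SDs (points); SDs > 0.
#' @param effect_slope Change in subscore per baseline point (negative =
#'   larger improvement with higher baseline severity).
#' @param change_intercept Baseline-independent component of the follow-up
#'   change (points). The default 0 keeps the change purely proportional to
#'   baseline; a positive value reproduces cohorts where the mean change is
#'   smaller than `effect_slope * baseline_mean` would imply.
#' @param residual_sd Residual SD of follow-up changes (points).
#' @param dropout Named numeric vector: probability of dropping out before
#'   each named week (all in `[0, 1]`), e.g. `c("4" = 0.05, "8" = 0.10)`.
#' @param basm_coupling Target correlation between the BASM change and the
#'   combined-score change (negative in the study).
#' @param basm_baseline_mean,basm_baseline_sd BASM score moments at week 0.
#' @param basm_change_mean,basm_change_sd Moments of the week-20 BASM change.
#' @param weeks Visit weeks (default `c(0, 4, 8, 20, 24)`).
#' @param seed Optional integer seed.
#' @return An object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_subjects = 20,
                             baseline_mean = c(IA = 17.7, HI = 15.6),
                             baseline_sd = c(IA = 5.0, HI = 3.9),
                             effect_slope = -0.7,
                             change_intercept = 0,
                             residual_sd = 4.7,
                             dropout = c("4" = 0.05, "8" = 0.10),
                             basm_coupling = -0.6,
                             basm_baseline_mean = 60.9,
                             basm_baseline_sd = 81.0,
                             basm_change_mean = 32.5,
                             basm_change_sd = 60.8,
                             weeks = c(0, 4, 8, 20, 24),
                             seed = NULL) {
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (any(baseline_sd <= 0)) stopf("baseline_sd must be > 0")
  if (length(dropout) && (any(dropout < 0) || any(dropout > 1)))
    stopf("dropout probabilities must lie in [0, 1]")
  check_number(residual_sd, "residual_sd", 0)
  structure(as.list(environment()), class = "trial_sim_config")
}

# normal truncated to [lo, hi] by rejection
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a training-trial outcome table
#'
#' Generates per-subject rating-scale trajectories and attention-score
#' (BASM) changes with the statistical structure the outcome analysis
#' assumes: baseline IA/HI subscores drawn from truncated normals on their
#' legal ranges; follow-up subscores equal to
#' `baseline + effect_slope * baseline + noise` (the week-4 visit carries
#' half the effect, as mid-treatment), clamped to the legal range, with the
#' combined score COM = IA + HI; dropout applied at the configured weeks
#' (a subject missing from that week onward); and a BASM change generated
#' with the configured (negative) correlation with the combined-score
#' change.
#'
#' @param cfg A [trial_sim_config()].
#' @return A list with `ratings` (data frame `subject_id`, `week`, `IA`,
#'   `HI`, `COM`; `NA` = missing) and `basm` (data frame `subject_id`,
#'   `week`, `basm` at weeks 0 and 20).
#' @examples
#' tb <- simulate_trial(trial_sim_config(seed = 1))
#' head(tb$ratings)
#' @export
simulate_trial <- function(cfg = trial_sim_config()) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_subjects
    ia0 <- rtruncnorm(n, cfg$baseline_mean["IA"], cfg$baseline_sd["IA"], 0, 27)
    hi0 <- rtruncnorm(n, cfg$baseline_mean["HI"], cfg$baseline_sd["HI"], 0, 27)
    fw <- cfg$weeks[cfg$weeks > 0]
    frac <- ifelse(fw < 8, 0.5, 1)       # mid-treatment visits: half effect
    ia <- matrix(NA_real_, n, length(cfg$weeks),
                 dimnames = list(NULL, cfg$weeks))
    hi <- ia
    ia[, "0"] <- ia0; hi[, "0"] <- hi0
    for (j in seq_along(fw)) {
      wk <- as.character(fw[j])
      ia[, wk] <- pmin(pmax(ia0 + frac[j] * (cfg$change_intercept +
                                               cfg$effect_slope * ia0) +
                              stats::rnorm(n, 0, cfg$residual_sd), 0), 27)
      hi[, wk] <- pmin(pmax(hi0 + frac[j] * (cfg$change_intercept +
                                               cfg$effect_slope * hi0) +
                              stats::rnorm(n, 0, cfg$residual_sd), 0), 27)
    }
    com <- ia + hi

    # BASM change coupled to the combined-score change at week 20
    dcom <- com[, "20"] - com[, "0"]
    z <- if (stats::sd(dcom) > 0) (dcom - mean(dcom)) / stats::sd(dcom)
         else rep(0, n)
    rho <- cfg$basm_coupling
    eps <- stats::rnorm(n)
    dbasm <- cfg$basm_change_mean +
      cfg$basm_change_sd * (rho * z + sqrt(max(0, 1 - rho^2)) * eps)
    basm0 <- stats::rnorm(n, cfg$basm_baseline_mean, cfg$basm_baseline_sd)

    # dropout: subject vanishes from the configured week onward
    drop_week <- rep(Inf, n)
    if (length(cfg$dropout)) {
      wks <- as.numeric(names(cfg$dropout))
      for (j in order(wks)) {
        at_risk <- drop_week == Inf
        hit <- at_risk & stats::runif(n) < cfg$dropout[j]
        drop_week[hit] <- wks[j]
      }
    }
    for (i in seq_len(n)) {
      gone <- cfg$weeks >= drop_week[i]
      ia[i, gone] <- NA; hi[i, gone] <- NA; com[i, gone] <- NA
    }

    ids <- sprintf("S%03d", seq_len(n))
    ratings <- data.frame(
      subject_id = rep(ids, each = length(cfg$weeks)),
      week = rep(cfg$weeks, n),
      IA = round(as.vector(t(ia)), 1),
      HI = round(as.vector(t(hi)), 1))
    ratings$COM <- ratings$IA + ratings$HI
    basm <- data.frame(
      subject_id = rep(ids, each = 2),
      week = rep(c(0, 20), n),
      basm = as.vector(rbind(basm0, basm0 + dbasm)))
    basm$basm[which(basm$week == 20)[drop_week <= 20]] <- NA
    attr(ratings, "dropout_week") <- stats::setNames(drop_week, ids)
    list(ratings = ratings, basm = basm)
  })
}

#' Trial tables CSV I/O
#'
#' Ratings CSV columns: `subject_id`, `week`, `IA`, `HI`, `COM` (blank =
#' missing). BASM CSV columns: `subject_id`, `week`, `basm`.
#'
#' @param ratings,basm Data frames as produced by [simulate_trial()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers the data frame.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = c("", "NA"))
  need <- c("subject_id", "week")
  if (!all(need %in% names(d)) || !any(c("IA", "HI", "COM") %in% names(d)))
    stopf("ratings CSV needs subject_id, week and at least one of IA/HI/COM")
  d
}

#' @rdname write_ratings_csv
#' @export
write_basm_csv <- function(basm, path) {
  utils::write.csv(basm, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_basm_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = c("", "NA"))
  if (!all(c("subject_id", "week", "basm") %in% names(d)))
    stopf("BASM CSV needs columns subject_id, week, basm")
  d
}
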
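# evaluate a piecewise-linear knot map, clamped to the knot range then [0,10]
pwl_eval <- function(knots, x) {
  if (is.na(x) || is.nan(x)) return(NA_real_)
  y <- stats::approx(knots[, "x"], knots[, "score"], xout = x, rule = 2)$y
  min(10, max(0, y))
}

#' Score one facial feature for one window
#'
#' Maps a window's metrics to the 0-10 stress scale through the
#' piecewise-linear calibration:
#' \itemize{
#'   \item `EYE_*`: max of the squint-coverage map (fraction of the window
#'     inside squint-kind epochs) and the relative-aperture map (sustained
#'     narrowing without a detected epoch still scores).
#'   \item `NOSE`: inverted activity-index map (immobility scores high).
#'   \item `EAR_*`: inverted activity-index map, plus `delta_fold` when the
#'     ear is flagged folded and `delta_asym * asymmetry`.
#' }
#' Results are clamped to \[0, 10\]; a feature whose landmarks are fully
#' missing in the window scores `NA`.
#'
#' @param metrics One row of a [windowed_metrics()] data frame.
#' @param feature One of [feature_names()].
#' @param calibration Calibration list ([default_calibration()]).
#' @return Score in \[0, 10\], or `NA`.
#' @export
feature_score <- function(metrics, feature, calibration = default_calibration()) {
  feature <- match.arg(feature, feature_names())
  clamp10 <- function(v) min(10, max(0, v))
  if (feature %in% c("EYE_LEFT", "EYE_RIGHT")) {
    side <- if (feature == "EYE_LEFT") "left" else "right"
    sq <- metrics[[paste0("squint_fraction_", side)]]
    ra <- metrics[[paste0("rel_aperture_", side)]]
    if (is.na(ra) || is.nan(ra)) return(NA_real_)
    s1 <- pwl_eval(calibration$eye$squint_knots, sq)
    s2 <- pwl_eval(calibration$eye$aperture_knots, ra)
    return(clamp10(max(s1, s2)))
  }
  if (feature == "NOSE") {
    a <- metrics$nose_activity_index
    if (is.na(a)) return(NA_real_)
    return(pwl_eval(calibration$nose$activity_knots, a))
  }
  side <- if (feature == "EAR_LEFT") "left" else "right"
  a <- metrics[[paste0("ear_activity_", side)]]
  if (is.na(a)) return(NA_real_)
  s <- pwl_eval(calibration$ear$activity_knots, a)
  fold <- metrics[[paste0("ear_fold_", side)]]
  if (isTRUE(fold)) s <- s + calibration$ear$delta_fold
  asym <- metrics$ear_asymmetry
  if (!is.na(asym)) s <- s + calibration$ear$delta_asym * asym
  clamp10(s)
}

#' Aggregate per-feature scores into a total
#'
#' Weighted mean over features with positive weight and non-missing score:
#' `total = sum(w_i * s_i) / sum(w_i)`. Setting a feature's weight to 0 is
#' exactly equivalent to deleting it; missing-feature windows renormalise
#' over the remaining features.
#'
#' @param scores Named numeric vector of per-feature scores in \[0, 10\]
#'   (`NA` allowed), names from [feature_names()].
#' @param weights Named non-negative weights (default all 1).
#' @return Weighted mean in \[0, 10\].
#' @export
aggregate_score <- function(scores, weights = NULL) {
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(feature_names())), feature_names())
  if (any(weights < 0)) stop("weights must be non-negative")
  feats <- intersect(names(scores), names(weights))
  w <- weights[feats]
  s <- scores[feats]
  use <- w > 0 & !is.na(s)
  if (!any(use)) stop("no feature with positive weight and non-missing score")
  sum(w[use] * s[use]) / sum(w[use])
}

#' Three-level status from a total score
#'
#' `okay` below the caution threshold, `caution` from the caution threshold
#' up to (excluding) the stressed threshold, `stressed` at or above it.
#' Defaults split the 0-10 scale into even terciles.
#'
#' @param total Score(s) in \[0, 10\].
#' @param thresholds `c(t_caution, t_stressed)` with
#'   `0 <= t_caution < t_stressed <= 10`.
#' @return Character vector in `{"okay", "caution", "stressed"}`.
#' @export
status_level <- function(total, thresholds = c(10 / 3, 20 / 3)) {
  if (length(thresholds) != 2 || !(thresholds[1] >= 0) ||
      !(thresholds[1] < thresholds[2]) || !(thresholds[2] <= 10))
    stop("thresholds must satisfy 0 <= t_caution < t_stressed <= 10")
  ifelse(total < thresholds[1], "okay",
         ifelse(total < thresholds[2], "caution", "stressed"))
}

#' Score a full session
#'
#' The end-to-end batch pipeline: clean the table, compute per-window
#' metrics, score the five features per window, aggregate them with the
#' feature weights, and attach the three-level status. The session mean is
#' the mean of window totals weighted by each window's `valid_fraction`.
#'
#' @param table A [trajectory_table()] (cleaning is applied internally and
#'   is idempotent, so pre-cleaned tables are fine).
#' @param weights Named feature weights (default all 1).
#' @param calibration Calibration list (default [default_calibration()]).
#' @param config Configuration list (default [default_config()]).
#' @return An object of class `stress_report`: list with `windows` (per
#'   window metrics, feature scores, `total`, `status`), `session_mean`,
#'   `session_status`, `weights`, `scale`, `fps`, `config_hash`.
#' @export
score_session <- function(table, weights = NULL,
                          calibration = NULL, config = default_config()) {
  if (is.null(weights)) weights <- config$scoring$weights
  if (is.null(calibration)) calibration <- config$scoring$calibration
  clean <- clean_trajectories(table,
                              config$cleaning$likelihood_threshold,
                              config$cleaning$max_gap_frames)
  wm <- windowed_metrics(clean, config)
  rep <- score_windows(wm, weights, calibration, config)
  sm <- stats::weighted.mean(rep$total, rep$valid_fraction, na.rm = TRUE)
  structure(list(
    windows = rep,
    session_mean = sm,
    session_status = status_level(sm, config$scoring$status_thresholds),
    weights = weights,
    scale = attr(wm, "scale"),
    fps = fps(table),
    config_hash = config_hash(list(config = config, weights = weights,
                                   calibration = calibration))
  ), class = "stress_report")
}

# score every window of a window_metrics frame; returns the frame with
# per-feature score columns, total and status appended
score_windows <- function(wm, weights, calibration, config) {
  feats <- feature_names()
  sc <- vapply(seq_len(nrow(wm)), function(i) {
    vapply(feats, function(f) feature_score(wm[i, ], f, calibration), numeric(1))
  }, numeric(length(feats)))
  sc <- t(sc)
  colnames(sc) <- paste0("score_", feats)
  total <- vapply(seq_len(nrow(wm)), function(i)
    aggregate_score(stats::setNames(sc[i, ], feats), weights), numeric(1))
  out <- cbind(as.data.frame(wm), as.data.frame(sc))
  out$total <- total
  out$status <- status_level(total, config$scoring$status_thresholds)
  out
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf("<stress_report> %d windows, session mean %.2f / 10 [%s]\n",
              nrow(x$windows), x$session_mean, x$session_status))
  tab <- table(factor(x$windows$status, c("okay", "caution", "stressed")))
  cat("window status:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.stress_report <- function(object, ...) {
  w <- object$windows
  feats <- feature_names()
  means <- vapply(paste0("score_", feats),
                  function(cn) mean(w[[cn]], na.rm = TRUE), numeric(1))
  out <- list(session_mean = object$session_mean,
              session_status = object$session_status,
              n_windows = nrow(w),
              feature_means = stats::setNames(means, feats),
              freezing_fraction = mean(w$freezing, na.rm = TRUE),
              status_counts = table(factor(w$status,
                                           c("okay", "caution", "stressed"))))
  class(out) <- "summary.stress_report"
  out
}

#' @export
print.summary.stress_report <- function(x, ...) {
  cat(sprintf("Session stress: %.2f / 10 [%s] over %d windows\n",
              x$session_mean, x$session_status, x$n_windows))
  cat("Mean feature scores:\n")
  print(round(x$feature_means, 2))
  cat(sprintf("Freezing in %.0f%% of windows\n", 100 * x$freezing_fraction))
  cat("Status counts:", paste(names(x$status_counts), x$status_counts,
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Plot a stress report
#'
#' Per-window total stress over time with the status bands shaded.
#'
#' @param x A `stress_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stress_report <- function(x, ...) {
  w <- x$windows
  t_mid <- (w$start_frame + w$end_frame) / 2 / x$fps
  thr <- c(10 / 3, 20 / 3)
  graphics::plot(t_mid, w$total, type = "n", ylim = c(0, 10),
                 xlab = "time (s)", ylab = "stress score (0-10)", ...)
  usr <- graphics::par("usr")
  graphics::rect(usr[1], 0, usr[2], thr[1],
                 col = grDevices::adjustcolor("green", 0.15), border = NA)
  graphics::rect(usr[1], thr[1], usr[2], thr[2],
                 col = grDevices::adjustcolor("yellow", 0.15), border = NA)
  graphics::rect(usr[1], thr[2], usr[2], 10,
                 col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::lines(t_mid, w$total, type = "b", pch = 16)
  graphics::abline(h = x$session_mean, lty = 2)
  invisible(x)
}

#' Feature-ablation analysis
#'
#' Measures how much the per-window total depends on each subset of
#' features. The baseline uses all five features; every proper subset of
#' features is then removed (weight set to 0) and the deviation recorded as
#' the mean absolute difference of per-window totals against the baseline.
#'
#' @param table A [trajectory_table()].
#' @param weights Baseline feature weights (default all 1).
#' @param calibration,config As in [score_session()].
#' @return A data frame of class `ablation_analysis`: one row per removed
#'   subset with `removed` (comma-joined feature names, `""` for none),
#'   `n_removed`, `deviation`.
#' @export
ablation_analysis <- function(table, weights = NULL,
                              calibration = NULL, config = default_config()) {
  if (is.null(weights)) weights <- config$scoring$weights
  if (is.null(calibration)) calibration <- config$scoring$calibration
  clean <- clean_trajectories(table,
                              config$cleaning$likelihood_threshold,
                              config$cleaning$max_gap_frames)
  wm <- windowed_metrics(clean, config)
  base <- score_windows(wm, weights, calibration, config)
  feats <- feature_names()
  subsets <- unlist(lapply(0:length(feats), function(k)
    utils::combn(feats, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(rm) {
    if (length(rm) == length(feats)) {
      warning("skipping removal of all features (nothing left to score)")
      return(NULL)
    }
    w2 <- weights
    w2[rm] <- 0
    tot <- vapply(seq_len(nrow(wm)), function(i) {
      sc <- stats::setNames(as.numeric(base[i, paste0("score_", feats)]), feats)
      aggregate_score(sc, w2)
    }, numeric(1))
    data.frame(removed = paste(rm, collapse = ","),
               n_removed = length(rm),
               deviation = mean(abs(tot - base$total), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ablation_analysis", "data.frame"))
}

#' Mean ablation deviation by subset size
#'
#' @param ablation An [ablation_analysis()] result.
#' @return Data frame with `n_removed` and mean `deviation`.
#' @export
ablation_by_size <- function(ablation) {
  stats::aggregate(deviation ~ n_removed, data = as.data.frame(ablation),
                   FUN = mean)
}
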
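#' Euclidean distance between two points
#'
#' Plane distance in pixels; missing coordinates propagate to a missing
#' result.
#'
#' @param p1,p2 Numeric length-2 vectors `(x, y)` or n x 2 matrices.
#' @return Non-negative distance(s), `NA` where either point is missing.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
euclidean_distance <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  sqrt((p2[, 1] - p1[, 1])^2 + (p2[, 2] - p1[, 2])^2)
}

#' Eyelid aperture series for one eye
#'
#' Per-frame Euclidean distance between the upper and lower eyelid, plus a
#' smoothed companion series (centred moving average over one second of
#' frames, shrinking at the edges). Epoch detection operates on the raw
#' series because closure durations are the classification criterion; the
#' smoothed series is for display and trend summaries.
#'
#' @param table A cleaned [trajectory_table()].
#' @param eye `"left"` or `"right"`.
#' @return List with `raw` and `smoothed` numeric vectors (one value per
#'   frame; `NA` where an eyelid is missing).
#' @export
eye_aperture_series <- function(table, eye = c("left", "right")) {
  eye <- match.arg(eye)
  up <- landmark_xy(table, paste0("eyelid_upper_", eye))
  lo <- landmark_xy(table, paste0("eyelid_lower_", eye))
  raw <- euclidean_distance(up, lo)
  list(raw = raw, smoothed = moving_average(raw, max(1L, round(fps(table)))))
}

# centred moving average with NA removal; window shrinks at the edges
moving_average <- function(x, width) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  half <- floor(width / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, lo + width - 1L)
    lo <- max(1L, hi - width + 1L)
    v <- x[lo:hi]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Open-eye aperture baseline
#'
#' A robust reference for the open eye: the 75th percentile of the
#' non-missing aperture series (high enough to ignore the closures being
#' detected, low enough to ignore wide-eye outliers).
#'
#' @param aperture Per-frame aperture in pixels.
#' @param probs Quantile used (default 0.75).
#' @return Baseline aperture in pixels.
#' @export
compute_aperture_baseline <- function(aperture, probs = 0.75) {
  a <- aperture[!is.na(aperture)]
  if (!length(a)) stop("aperture series has no non-missing values")
  unname(stats::quantile(a, probs = probs, type = 7))
}

#' Detect blink and squint epochs in an aperture series
#'
#' Maximal runs of consecutive frames whose aperture falls below
#' `closure_fraction * baseline` become closure epochs. Epochs shorter than
#' `blink_max_s` are blinks (reward- or reflex-associated rapid closures);
#' epochs of at least `blink_max_s` are squints, the sustained closures that
#' indicate stress. A run of exactly `blink_max_s` is a squint. Missing
#' apertures never extend a closure run.
#'
#' @param aperture Per-frame aperture in pixels.
#' @param fps Frames per second.
#' @param baseline Open-eye reference aperture (> 0), e.g. from
#'   [compute_aperture_baseline()].
#' @param closure_fraction Closure threshold as a fraction of baseline.
#' @param blink_max_s Blink/squint duration boundary in seconds.
#' @return Data frame with one row per epoch: `start_frame`, `end_frame`
#'   (0-based, inclusive), `duration_s`, `kind` (`"blink"`/`"squint"`).
#' @export
detect_squint_epochs <- function(aperture, fps, baseline,
                                 closure_fraction = 0.4, blink_max_s = 1.0) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be a positive number")
  closed <- !is.na(aperture) & aperture < closure_fraction * baseline
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE)
  if (!any(closed)) return(empty)
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dur <- r$lengths[keep] / fps
  data.frame(start_frame = starts[keep] - 1L,
             end_frame = ends[keep] - 1L,
             duration_s = dur,
             kind = ifelse(dur < blink_max_s, "blink", "squint"),
             stringsAsFactors = FALSE)
}

#' Maximum range of motion of a point within a window
#'
#' The largest displacement observed in the window, implemented as the
#' diameter of the visited point set (maximum pairwise Euclidean distance),
#' which does not depend on which frame the window starts on and is always
#' bounded above by the travel distance.
#'
#' @param positions n x 2 matrix of `(x, y)` in pixels; `NA` rows are
#'   ignored.
#' @return Maximum pairwise distance in pixels.
#' @export
max_range_of_motion <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  ok <- stats::complete.cases(positions)
  p <- positions[ok, , drop = FALSE]
  if (nrow(p) == 0) stop("window contains no non-missing positions")
  if (nrow(p) == 1) return(0)
  max(stats::dist(p))
}

#' Cumulative travel distance of a point within a window
#'
#' Sum of Euclidean distances between consecutive non-missing positions;
#' a run of missing frames is bridged by a single segment.
#'
#' @param positions n x 2 matrix of `(x, y)` in pixels.
#' @return Total path length in pixels.
#' @export
travel_distance <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  ok <- stats::complete.cases(positions)
  p <- positions[ok, , drop = FALSE]
  if (nrow(p) == 0) stop("window contains no non-missing positions")
  if (nrow(p) == 1) return(0)
  sum(euclidean_distance(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE]))
}

#' Activity index
#'
#' Dimensionless motion measure combining the maximum range of motion and
#' the travel distance, each normalised by the body scale, as their
#' arithmetic mean. Strictly increasing in both inputs, zero only for a
#' stationary point, and invariant when range, travel and scale are
#' rescaled together.
#'
#' @param max_range Maximum range of motion (pixels).
#' @param travel Travel distance (pixels).
#' @param scale Normalising body-scale length in pixels (> 0); by default
#'   the session-median inter-ear distance.
#' @return Unitless activity index (>= 0).
#' @export
activity_index <- function(max_range, travel, scale) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  (max_range / scale + travel / scale) / 2
}

#' Session body scale
#'
#' Median inter-ear distance over all frames where both ears are present:
#' the only stable large baseline among the 7 landmarks. Normalising by it
#' makes every metric invariant to camera distance.
#'
#' @param table A cleaned [trajectory_table()].
#' @return Scale in pixels.
#' @export
body_scale <- function(table) {
  d <- euclidean_distance(landmark_xy(table, "ear_left"),
                          landmark_xy(table, "ear_right"))
  d <- d[!is.na(d)]
  if (!length(d)) stop("cannot estimate body scale: ears never jointly visible")
  stats::median(d)
}

#' Ear metrics for one window
#'
#' Per-ear activity indices (same construction as the nose), left/right
#' asymmetry, and fold flags. Asymmetry is `|aL - aR| / (aL + aR)`, defined
#' as 0 when both activities are 0 (two still ears are symmetric). An ear
#' is flagged folded when it is simultaneously immobile (window range below
#' `fold_range_threshold * scale`) and displaced (window-mean position more
#' than `fold_displacement_threshold * scale` from its session-median
#' position).
#'
#' @param table A cleaned [trajectory_table()] (full session; the fold test
#'   needs session-median ear positions).
#' @param rows Integer vector of window row indices.
#' @param scale Body scale in pixels.
#' @param fold_range_threshold,fold_displacement_threshold Fold test
#'   thresholds as fractions of `scale`.
#' @return List with `ear_activity_left`, `ear_activity_right`,
#'   `ear_asymmetry`, `ear_fold_left`, `ear_fold_right` (NA when an ear is
#'   fully missing in the window).
#' @export
ear_metrics <- function(table, rows, scale,
                        fold_range_threshold = 0.05,
                        fold_displacement_threshold = 0.15) {
  one_ear <- function(side) {
    all_pos <- landmark_xy(table, paste0("ear_", side))
    pos <- all_pos[rows, , drop = FALSE]
    ok <- stats::complete.cases(pos)
    if (!any(ok)) {
      return(list(activity = NA_real_, fold = NA))
    }
    rng <- max_range_of_motion(pos)
    trav <- travel_distance(pos)
    act <- activity_index(rng, trav, scale)
    med <- apply(all_pos, 2, stats::median, na.rm = TRUE)
    ctr <- colMeans(pos[ok, , drop = FALSE])
    displaced <- euclidean_distance(ctr, med) > fold_displacement_threshold * scale
    fold <- (rng < fold_range_threshold * scale) && displaced
    list(activity = act, fold = fold)
  }
  l <- one_ear("left"); r <- one_ear("right")
  asym <- if (is.na(l$activity) || is.na(r$activity)) {
    NA_real_
  } else if (l$activity + r$activity == 0) {
    0
  } else {
    abs(l$activity - r$activity) / (l$activity + r$activity)
  }
  list(ear_activity_left = l$activity, ear_activity_right = r$activity,
       ear_asymmetry = asym, ear_fold_left = l$fold, ear_fold_right = r$fold)
}

#' Freezing flags for a sequence of windows
#'
#' A window is frozen when the nose activity index and both ear activity
#' indices all fall below `freeze_activity_threshold` (near-total facial
#' immobility).
#'
#' @param metrics A window-metrics data frame from [windowed_metrics()], or
#'   any data frame with `nose_activity_index`, `ear_activity_left`,
#'   `ear_activity_right`.
#' @param freeze_activity_threshold Activity cutoff (unitless).
#' @return Logical vector, one flag per window (`NA` where activities are
#'   missing).
#' @export
detect_freezing <- function(metrics, freeze_activity_threshold = 0.25) {
  metrics$nose_activity_index < freeze_activity_threshold &
    metrics$ear_activity_left < freeze_activity_threshold &
    metrics$ear_activity_right < freeze_activity_threshold
}

#' Per-window heuristic metrics
#'
#' Splits the session into consecutive non-overlapping windows of
#' `window_s` seconds (a final partial window is kept when at least half
#' full, its shortfall reflected in `valid_fraction`) and computes, per
#' window: mean eyelid apertures, squint-epoch coverage per eye, nose
#' maximum range / travel / activity index, per-ear activity, asymmetry
#' and fold flags, the freezing flag, and the fraction of frames with all
#' landmarks present.
#'
#' @param table A cleaned [trajectory_table()].
#' @param config Configuration list ([default_config()]); the `metrics`
#'   block supplies all thresholds.
#' @param scale Body scale in pixels; computed from the table by default.
#' @return A data frame of class `window_metrics`, one row per window,
#'   with attributes `fps`, `scale`, `baseline_left`, `baseline_right`.
#' @export
windowed_metrics <- function(table, config = default_config(),
                             scale = body_scale(table)) {
  m <- config$metrics
  f <- fps(table)
  wlen <- max(1L, as.integer(round(m$window_s * f)))
  n <- nrow(table)
  if (n < wlen / 2)
    stop("table is shorter than half a window (", n, " frames < ", wlen / 2, ")")
  n_full <- n %/% wlen
  rem <- n - n_full * wlen
  starts <- seq(0L, by = wlen, length.out = n_full)
  lens <- rep(wlen, n_full)
  if (rem >= wlen / 2) {
    starts <- c(starts, n_full * wlen)
    lens <- c(lens, rem)
  }
  ap_l <- eye_aperture_series(table, "left")$raw
  ap_r <- eye_aperture_series(table, "right")$raw
  base_l <- compute_aperture_baseline(ap_l, m$baseline_quantile)
  base_r <- compute_aperture_baseline(ap_r, m$baseline_quantile)
  ep_l <- detect_squint_epochs(ap_l, f, base_l, m$closure_fraction, m$blink_max_s)
  ep_r <- detect_squint_epochs(ap_r, f, base_r, m$closure_fraction, m$blink_max_s)
  squint_mask <- function(ep) {
    msk <- rep(FALSE, n)
    sq <- ep[ep$kind == "squint", , drop = FALSE]
    for (i in seq_len(nrow(sq)))
      msk[(sq$start_frame[i]:sq$end_frame[i]) + 1L] <- TRUE
    msk
  }
  sq_l <- squint_mask(ep_l); sq_r <- squint_mask(ep_r)
  nose <- landmark_xy(table, "nose")
  present <- rep(TRUE, n)
  for (lm in landmark_names())
    present <- present & !is.na(table[[paste0(lm, ".x")]])
  rows_list <- lapply(seq_along(starts), function(i)
    (starts[i] + 1L):(starts[i] + lens[i]))
  out <- do.call(rbind, lapply(seq_along(rows_list), function(i) {
    rows <- rows_list[[i]]
    np <- nose[rows, , drop = FALSE]
    nose_ok <- any(stats::complete.cases(np))
    nr <- if (nose_ok) max_range_of_motion(np) else NA_real_
    nt <- if (nose_ok) travel_distance(np) else NA_real_
    na_idx <- if (nose_ok) activity_index(nr, nt, scale) else NA_real_
    em <- ear_metrics(table, rows, scale,
                      m$fold_range_threshold, m$fold_displacement_threshold)
    data.frame(
      start_frame = starts[i], end_frame = starts[i] + lens[i] - 1L,
      aperture_left = mean(ap_l[rows], na.rm = TRUE),
      aperture_right = mean(ap_r[rows], na.rm = TRUE),
      rel_aperture_left = mean(ap_l[rows], na.rm = TRUE) / base_l,
      rel_aperture_right = mean(ap_r[rows], na.rm = TRUE) / base_r,
      squint_fraction_left = mean(sq_l[rows]),
      squint_fraction_right = mean(sq_r[rows]),
      nose_max_range = nr, nose_travel = nt, nose_activity_index = na_idx,
      ear_activity_left = em$ear_activity_left,
      ear_activity_right = em$ear_activity_right,
      ear_asymmetry = em$ear_asymmetry,
      ear_fold_left = em$ear_fold_left, ear_fold_right = em$ear_fold_right,
      valid_fraction = sum(present[rows]) / wlen,
      stringsAsFactors = FALSE)
  }))
  out$freezing <- detect_freezing(out, m$freeze_activity_threshold)
  structure(out, fps = f, scale = scale,
            baseline_left = base_l, baseline_right = base_r,
            class = c("window_metrics", "data.frame"))
}
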
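# ---- shared single-window scoring core -------------------------------------
# Metrics + score for one window of already likelihood-masked frames, with
# externally supplied open-eye baselines, body scale and ear reference
# positions. Both the batch trailing-window scorer and the live monitor call
# this, which is what makes them provably consistent.

mask_low_likelihood <- function(df, threshold) {
  for (lm in landmark_names()) {
    lik <- df[[paste0(lm, ".likelihood")]]
    bad <- is.na(lik) | lik < threshold
    df[[paste0(lm, ".x")]][bad] <- NA_real_
    df[[paste0(lm, ".y")]][bad] <- NA_real_
  }
  df
}

window_core <- function(dfw, f, wlen, baseline_l, baseline_r, scale,
                        ear_med_l, ear_med_r, m) {
  ap <- function(side) {
    up <- cbind(dfw[[paste0("eyelid_upper_", side, ".x")]],
                dfw[[paste0("eyelid_upper_", side, ".y")]])
    lo <- cbind(dfw[[paste0("eyelid_lower_", side, ".x")]],
                dfw[[paste0("eyelid_lower_", side, ".y")]])
    euclidean_distance(up, lo)
  }
  ap_l <- ap("left"); ap_r <- ap("right")
  sq_frac <- function(a, base) {
    ep <- detect_squint_epochs(a, f, base, m$closure_fraction, m$blink_max_s)
    msk <- rep(FALSE, length(a))
    sq <- ep[ep$kind == "squint", , drop = FALSE]
    for (i in seq_len(nrow(sq)))
      msk[(sq$start_frame[i]:sq$end_frame[i]) + 1L] <- TRUE
    mean(msk)
  }
  nose <- cbind(dfw$nose.x, dfw$nose.y)
  nose_ok <- any(stats::complete.cases(nose))
  nr <- if (nose_ok) max_range_of_motion(nose) else NA_real_
  nt <- if (nose_ok) travel_distance(nose) else NA_real_
  ear <- function(side, med) {
    p <- cbind(dfw[[paste0("ear_", side, ".x")]],
               dfw[[paste0("ear_", side, ".y")]])
    ok <- stats::complete.cases(p)
    if (!any(ok)) return(list(activity = NA_real_, fold = NA))
    rng <- max_range_of_motion(p)
    act <- activity_index(rng, travel_distance(p), scale)
    ctr <- colMeans(p[ok, , drop = FALSE])
    fold <- (rng < m$fold_range_threshold * scale) &&
      (euclidean_distance(ctr, med) > m$fold_displacement_threshold * scale)
    list(activity = act, fold = fold)
  }
  el <- ear("left", ear_med_l); er <- ear("right", ear_med_r)
  asym <- if (is.na(el$activity) || is.na(er$activity)) NA_real_
    else if (el$activity + er$activity == 0) 0
    else abs(el$activity - er$activity) / (el$activity + er$activity)
  present <- rep(TRUE, nrow(dfw))
  for (lm in landmark_names())
    present <- present & !is.na(dfw[[paste0(lm, ".x")]])
  out <- data.frame(
    start_frame = 0L, end_frame = nrow(dfw) - 1L,
    aperture_left = mean(ap_l, na.rm = TRUE),
    aperture_right = mean(ap_r, na.rm = TRUE),
    rel_aperture_left = mean(ap_l, na.rm = TRUE) / baseline_l,
    rel_aperture_right = mean(ap_r, na.rm = TRUE) / baseline_r,
    squint_fraction_left = sq_frac(ap_l, baseline_l),
    squint_fraction_right = sq_frac(ap_r, baseline_r),
    nose_max_range = nr, nose_travel = nt,
    nose_activity_index = if (nose_ok) activity_index(nr, nt, scale) else NA_real_,
    ear_activity_left = el$activity, ear_activity_right = er$activity,
    ear_asymmetry = asym,
    ear_fold_left = el$fold, ear_fold_right = er$fold,
    valid_fraction = sum(present) / wlen,
    stringsAsFactors = FALSE)
  out$freezing <- detect_freezing(out, m$freeze_activity_threshold)
  out
}

# rolling references from a masked history of frames
rolling_refs <- function(hist, wlen, live_cfg, q = 0.75) {
  ap <- function(side) {
    euclidean_distance(
      cbind(hist[[paste0("eyelid_upper_", side, ".x")]],
            hist[[paste0("eyelid_upper_", side, ".y")]]),
      cbind(hist[[paste0("eyelid_lower_", side, ".x")]],
            hist[[paste0("eyelid_lower_", side, ".y")]]))
  }
  base_of <- function(a) {
    a <- a[!is.na(a)]
    if (length(a) >= wlen) unname(stats::quantile(a, q, type = 7))
    else live_cfg$fallback_baseline_px
  }
  d_ear <- euclidean_distance(cbind(hist$ear_left.x, hist$ear_left.y),
                              cbind(hist$ear_right.x, hist$ear_right.y))
  d_ear <- d_ear[!is.na(d_ear)]
  scale <- if (length(d_ear) >= wlen) stats::median(d_ear)
    else live_cfg$fallback_scale_px
  med <- function(side) {
    x <- hist[[paste0("ear_", side, ".x")]]
    y <- hist[[paste0("ear_", side, ".y")]]
    if (all(is.na(x))) c(NA_real_, NA_real_)
    else c(stats::median(x, na.rm = TRUE), stats::median(y, na.rm = TRUE))
  }
  list(baseline_l = base_of(ap("left")), baseline_r = base_of(ap("right")),
       scale = scale, ear_med_l = med("left"), ear_med_r = med("right"))
}

score_one_window <- function(dfw, f, wlen, refs, weights, calibration, config) {
  wm <- window_core(dfw, f, wlen, refs$baseline_l, refs$baseline_r,
                    refs$scale, refs$ear_med_l, refs$ear_med_r,
                    config$metrics)
  feats <- feature_names()
  sc <- stats::setNames(vapply(feats, function(ft)
    feature_score(wm, ft, calibration), numeric(1)), feats)
  total <- tryCatch(aggregate_score(sc, weights), error = function(e) NA_real_)
  list(metrics = wm, scores = sc, total = total)
}

#' Score the trailing window of a session (batch reference)
#'
#' The batch counterpart of the live evaluator: applies live-mode cleaning
#' (likelihood masking, no interpolation), derives the rolling references
#' (open-eye baselines as the 75th percentile of the aperture over the
#' trailing baseline horizon, body scale as the median inter-ear distance
#' over the same horizon, ear reference positions as medians), and scores
#' the final trailing window of `window_s` seconds ending at `end_frame`.
#' A live monitor fed the same frames emits exactly this score.
#'
#' @param table A [trajectory_table()].
#' @param end_frame 0-based index of the last frame of the window
#'   (default: last frame of the table).
#' @param weights,calibration,config As in [score_session()].
#' @return List with `total`, `status`, `scores`, `metrics`.
#' @export
score_trailing_window <- function(table, end_frame = nrow(table) - 1L,
                                  weights = NULL, calibration = NULL,
                                  config = default_config()) {
  if (is.null(weights)) weights <- config$scoring$weights
  if (is.null(calibration)) calibration <- config$scoring$calibration
  f <- fps(table)
  wlen <- max(1L, as.integer(round(config$metrics$window_s * f)))
  blen <- max(wlen, as.integer(round(config$live$baseline_window_s * f)))
  i_end <- end_frame + 1L
  if (i_end < wlen) stop("not enough frames before end_frame for one window")
  df <- mask_low_likelihood(as.data.frame(table),
                            config$cleaning$likelihood_threshold)
  hist <- df[max(1L, i_end - blen + 1L):i_end, , drop = FALSE]
  refs <- rolling_refs(hist, wlen, config$live, config$metrics$baseline_quantile)
  dfw <- df[(i_end - wlen + 1L):i_end, , drop = FALSE]
  res <- score_one_window(dfw, f, wlen, refs, weights, calibration, config)
  res$status <- if (is.na(res$total)) NA_character_
    else status_level(res$total, config$scoring$status_thresholds)
  res
}

#' Create a live stress monitor
#'
#' A stateful streaming evaluator: per-frame landmark messages are pushed
#' with [ingest_frame()] and the current score and colour-coded status are
#' read with [emit_status()]. The monitor keeps exactly one trailing
#' evaluation window of frames plus a bounded rolling history (default
#' 60 s) for the open-eye baseline and body scale, so memory is bounded
#' regardless of stream length. The displayed status changes only after
#' `hysteresis_frames` consecutive frames agree on the new status, which
#' keeps the indicator from flickering.
#'
#' @param weights,calibration,config As in [score_session()].
#' @param fps Frame rate of the stream.
#' @return Object of class `live_monitor` (an environment).
#' @export
live_monitor <- function(weights = NULL, calibration = NULL,
                         config = default_config(), fps = config$fps) {
  if (is.null(weights)) weights <- config$scoring$weights
  if (is.null(calibration)) calibration <- config$scoring$calibration
  wlen <- max(1L, as.integer(round(config$metrics$window_s * fps)))
  blen <- max(wlen, as.integer(round(config$live$baseline_window_s * fps)))
  mon <- new.env(parent = emptyenv())
  mon$weights <- weights; mon$calibration <- calibration; mon$config <- config
  mon$fps <- fps; mon$wlen <- wlen; mon$blen <- blen
  mon$buffer <- empty_frame_df(0)     # trailing window (masked)
  mon$history <- empty_frame_df(0)    # rolling reference horizon (masked)
  mon$last_idx <- -1L
  mon$n_seen <- 0L                    # slots since stream start (incl. gaps)
  mon$displayed <- NA_character_
  mon$pending <- NA_character_
  mon$pending_n <- 0L
  class(mon) <- "live_monitor"
  mon
}

empty_frame_df <- function(n) {
  df <- data.frame(frame = integer(n))
  for (cn in all_landmark_cols()) df[[cn]] <- rep(NA_real_, n)
  for (lm in landmark_names()) df[[paste0(lm, ".likelihood")]] <- rep(0, n)
  df
}

frame_msg_to_row <- function(msg) {
  row <- empty_frame_df(1)
  row$frame <- as.integer(msg$frame_idx)
  for (lm in names(msg$landmarks)) {
    v <- msg$landmarks[[lm]]
    row[[paste0(lm, ".x")]] <- as.numeric(v[[1]])
    row[[paste0(lm, ".y")]] <- as.numeric(v[[2]])
    row[[paste0(lm, ".likelihood")]] <- as.numeric(v[[3]])
  }
  row
}

#' Push one frame message into a live monitor
#'
#' Out-of-order frames (index not greater than the last seen) are dropped
#' with a warning; gaps in the frame index register the skipped frames as
#' missing, which lowers the window's `valid_fraction`.
#'
#' @param mon A [live_monitor()].
#' @param msg List with `frame_idx` (integer), optional `timestamp`
#'   (seconds), and `landmarks`: a named list mapping each landmark name to
#'   `c(x, y, likelihood)` (missing landmarks may be encoded with
#'   likelihood 0).
#' @return The monitor, invisibly.
#' @export
ingest_frame <- function(mon, msg) {
  stopifnot(inherits(mon, "live_monitor"))
  idx <- as.integer(msg$frame_idx)
  if (idx <= mon$last_idx) {
    warning("out-of-order frame ", idx, " dropped (last seen ",
            mon$last_idx, ")")
    return(invisible(mon))
  }
  n_gap <- if (mon$last_idx < 0) 0L else idx - mon$last_idx - 1L
  rows <- frame_msg_to_row(msg)
  rows <- mask_low_likelihood(rows, mon$config$cleaning$likelihood_threshold)
  if (n_gap > 0) {
    gap <- empty_frame_df(n_gap)
    gap$frame <- (mon$last_idx + 1L):(idx - 1L)
    rows <- rbind(gap, rows)
  }
  mon$buffer <- tail_df(rbind(mon$buffer, rows), mon$wlen)
  mon$history <- tail_df(rbind(mon$history, rows), mon$blen)
  mon$n_seen <- mon$n_seen + n_gap + 1L
  mon$last_idx <- idx
  invisible(mon)
}

tail_df <- function(df, n) {
  if (nrow(df) > n) df <- df[(nrow(df) - n + 1L):nrow(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Current score and status of a live monitor
#'
#' Returns `warming_up` until one full evaluation window of stream slots
#' has been seen; afterwards computes the trailing-window score. The
#' `status` field applies display hysteresis; `status_raw` is the
#' instantaneous classification.
#'
#' @param mon A [live_monitor()].
#' @return List with `frame_idx`, `score` (`NA` while warming up),
#'   `status_raw`, and `status`.
#' @export
emit_status <- function(mon) {
  stopifnot(inherits(mon, "live_monitor"))
  if (mon$n_seen < mon$wlen) {
    return(list(frame_idx = mon$last_idx, score = NA_real_,
                status_raw = "warming_up", status = "warming_up"))
  }
  refs <- rolling_refs(mon$history, mon$wlen, mon$config$live,
                       mon$config$metrics$baseline_quantile)
  res <- score_one_window(mon$buffer, mon$fps, mon$wlen, refs,
                          mon$weights, mon$calibration, mon$config)
  raw <- if (is.na(res$total)) "warming_up"
    else status_level(res$total, mon$config$scoring$status_thresholds)
  k <- mon$config$live$hysteresis_frames
  if (is.na(mon$displayed)) {
    mon$displayed <- raw
  } else if (raw == mon$displayed) {
    mon$pending <- NA_character_; mon$pending_n <- 0L
  } else {
    if (identical(raw, mon$pending)) {
      mon$pending_n <- mon$pending_n + 1L
    } else {
      mon$pending <- raw; mon$pending_n <- 1L
    }
    if (mon$pending_n >= k) {
      mon$displayed <- raw; mon$pending <- NA_character_; mon$pending_n <- 0L
    }
  }
  list(frame_idx = mon$last_idx, score = res$total,
       status_raw = raw, status = mon$displayed)
}

#' @export
print.live_monitor <- function(x, ...) {
  cat(sprintf("<live_monitor> last frame %d, %d/%d window slots seen\n",
              x$last_idx, min(x$n_seen, x$wlen), x$wlen))
  invisible(x)
}

#' Replay a trajectory table through the live monitor
#'
#' Converts each row of the table to a frame message, ingests it, and
#' records the emission after every frame. Replaying the same table with
#' the same configuration reproduces the emission log exactly (live
#' scoring is a pure function of the trailing window contents).
#'
#' @param table A [trajectory_table()].
#' @param weights,calibration,config As in [score_session()].
#' @return Data frame with one row per frame: `frame_idx`, `score`,
#'   `status_raw`, `status`.
#' @export
replay_stream <- function(table, weights = NULL, calibration = NULL,
                          config = default_config()) {
  mon <- live_monitor(weights, calibration, config, fps = fps(table))
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    msg <- list(frame_idx = table$frame[i], timestamp = table$frame[i] / fps(table),
                landmarks = lapply(stats::setNames(nm = landmark_names()),
                                   function(lm) c(table[[paste0(lm, ".x")]][i],
                                                  table[[paste0(lm, ".y")]][i],
                                                  table[[paste0(lm, ".likelihood")]][i])))
    ingest_frame(mon, msg)
    em <- emit_status(mon)
    out[[i]] <- data.frame(frame_idx = em$frame_idx, score = em$score,
                           status_raw = em$status_raw, status = em$status,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
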
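#' Simulation configuration
#'
#' Parameters of the synthetic session generator. Defaults emulate a
#' 1080p front-camera framing (inter-ear distance about 200 px, open-eye
#' aperture 24 px) at 30 frames/s, with Poisson-timed sub-second blinks in
#' relaxed epochs, sustained (1.5-4 s) intermittent squints in squinting
#' epochs, near-zero nose/ear step noise when frozen, one pinned displaced
#' ear when folded, isotropic Gaussian landmark jitter, and independent
#' Bernoulli low-likelihood dropouts whose coordinates are scattered (as a
#' confused tracker's are).
#'
#' @param fps Frames per second (default 30).
#' @param duration_s Session length in seconds (default 30). If
#'   `state_schedule` is supplied its durations must sum to `duration_s`.
#' @param state_schedule List of `list(state=, duration_s=)` entries;
#'   states are `relaxed`, `stressed_squint`, `stressed_freeze`,
#'   `stressed_ear_fold`, `stressed_combined`. Default: relaxed throughout.
#' @param geometry Baseline landmark positions and bounds (pixels).
#' @param blink_rate Blink events per minute in non-squinting epochs.
#' @param blink_duration_s Range of blink durations (must stay below 1 s).
#' @param blink_refractory_s Minimum open time between blinks.
#' @param squint_duration_s Range of squint durations (must be >= 1 s).
#' @param squint_gap_s Range of open gaps between squints.
#' @param nose_step_sd,ear_step_sd Named per-state random-walk step
#'   standard deviations (pixels/frame).
#' @param blink_closure,squint_closure Aperture during closure as a
#'   fraction of the open aperture.
#' @param jitter_sd Isotropic Gaussian landmark jitter sd (pixels).
#' @param dropout_rate Probability a landmark-frame is a low-likelihood
#'   dropout.
#' @param dropout_scatter_sd Coordinate scatter added to dropout points.
#' @param seed RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(fps = 30, duration_s = 30, state_schedule = NULL,
                       geometry = NULL,
                       blink_rate = 6, blink_duration_s = c(0.2, 0.5),
                       blink_refractory_s = 0.5,
                       squint_duration_s = c(1.5, 4), squint_gap_s = c(1, 2.5),
                       nose_step_sd = c(relaxed = 2.5, stressed_squint = 2.5,
                                        stressed_freeze = 0.05,
                                        stressed_ear_fold = 2.5,
                                        stressed_combined = 0.05),
                       ear_step_sd = c(relaxed = 1.0, stressed_squint = 1.0,
                                       stressed_freeze = 0.05,
                                       stressed_ear_fold = 1.0,
                                       stressed_combined = 0.05),
                       blink_closure = 0.1, squint_closure = 0.2,
                       jitter_sd = 0.3, dropout_rate = 0.02,
                       dropout_scatter_sd = 40, seed = 1) {
  geo <- list(nose = c(960, 700), ear_left = c(860, 420),
              ear_right = c(1060, 420), eye_left = c(900, 530),
              eye_right = c(1020, 530), open_aperture = 24,
              nose_bound = 40, ear_bound = 12,
              fold_offset = c(30, 50), fold_bound = 2, fold_step_sd = 0.02)
  if (!is.null(geometry)) geo <- merge_config(geo, geometry)
  if (is.null(state_schedule))
    state_schedule <- list(list(state = "relaxed", duration_s = duration_s))
  states <- c("relaxed", "stressed_squint", "stressed_freeze",
              "stressed_ear_fold", "stressed_combined")
  durs <- vapply(state_schedule, function(s) s$duration_s, numeric(1))
  nm <- vapply(state_schedule, function(s) s$state, character(1))
  if (!all(nm %in% states))
    stop("unknown state(s): ", paste(setdiff(nm, states), collapse = ", "))
  if (any(durs <= 0)) stop("all schedule durations must be > 0")
  if (abs(sum(durs) - duration_s) > 1e-9)
    stop("state_schedule durations sum to ", sum(durs),
         " s but duration_s is ", duration_s, " s")
  stopifnot(fps > 0, duration_s > 0,
            all(blink_duration_s > 0), max(blink_duration_s) < 1,
            min(squint_duration_s) >= 1, all(squint_gap_s > 0),
            jitter_sd >= 0, dropout_rate >= 0, dropout_rate <= 1)
  structure(list(fps = fps, duration_s = duration_s,
                 state_schedule = state_schedule, geometry = geo,
                 blink_rate = blink_rate, blink_duration_s = blink_duration_s,
                 blink_refractory_s = blink_refractory_s,
                 squint_duration_s = squint_duration_s,
                 squint_gap_s = squint_gap_s,
                 nose_step_sd = nose_step_sd, ear_step_sd = ear_step_sd,
                 blink_closure = blink_closure, squint_closure = squint_closure,
                 jitter_sd = jitter_sd, dropout_rate = dropout_rate,
                 dropout_scatter_sd = dropout_scatter_sd, seed = seed),
            class = "sim_config")
}

# reflect a free walk into [center - bound, center + bound] (triangle fold)
reflect_walk <- function(free, center, bound) {
  if (bound <= 0) return(rep(center, length(free)))
  lo <- center - bound
  z <- (free - lo) %% (2 * bound)
  lo + ifelse(z > bound, 2 * bound - z, z)
}

# reflected random walk: start position, per-frame step sds, box around center
walk_segment <- function(n, start, sd_vec, center, bound) {
  steps <- stats::rnorm(n, 0, sd_vec)
  steps[1] <- 0
  reflect_walk(start + cumsum(steps), center, bound)
}

#' Simulate a tracked session
#'
#' Generates a full 7-landmark trajectory table frame by frame according
#' to the state schedule, together with the per-frame ground-truth state
#' and an event log (blinks, squints, freezing epochs, ear folds). Fully
#' reproducible from the seed in the configuration.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulated_session`: list with `table`
#'   ([trajectory_table()]), `truth` (character, one state per frame), and
#'   `event_log` (data frame `event`, `start_frame`, `end_frame`, 0-based
#'   inclusive).
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  f <- config$fps
  geo <- config$geometry
  n <- as.integer(round(config$duration_s * f))

  seg_len <- vapply(config$state_schedule,
                    function(s) as.integer(round(s$duration_s * f)), integer(1))
  seg_len[length(seg_len)] <- n - sum(seg_len[-length(seg_len)])
  seg_state <- vapply(config$state_schedule, function(s) s$state, character(1))
  truth <- rep(seg_state, seg_len)
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L

  events <- list()
  add_event <- function(type, i0, i1)
    events[[length(events) + 1L]] <<- data.frame(
      event = type, start_frame = i0 - 1L, end_frame = i1 - 1L,
      stringsAsFactors = FALSE)

  # --- nose and ear walks, segment by segment ------------------------------
  walks <- list(
    nose = list(base = geo$nose, bound = geo$nose_bound, sd = config$nose_step_sd),
    ear_left = list(base = geo$ear_left, bound = geo$ear_bound,
                    sd = config$ear_step_sd),
    ear_right = list(base = geo$ear_right, bound = geo$ear_bound,
                     sd = config$ear_step_sd))
  pos <- list()
  for (lm in names(walks)) {
    wk <- walks[[lm]]
    xs <- numeric(n); ys <- numeric(n)
    cur <- wk$base
    for (k in seq_along(seg_len)) {
      idx <- seg_start[k]:seg_end[k]
      st <- seg_state[k]
      folded <- lm == "ear_left" &&
        st %in% c("stressed_ear_fold", "stressed_combined")
      if (folded) {
        ctr <- wk$base + geo$fold_offset
        xs[idx] <- walk_segment(length(idx), ctr[1], geo$fold_step_sd,
                                ctr[1], geo$fold_bound)
        ys[idx] <- walk_segment(length(idx), ctr[2], geo$fold_step_sd,
                                ctr[2], geo$fold_bound)
        add_event("ear_fold", seg_start[k], seg_end[k])
      } else {
        sdv <- unname(wk$sd[st])
        xs[idx] <- walk_segment(length(idx), cur[1], sdv, wk$base[1], wk$bound)
        ys[idx] <- walk_segment(length(idx), cur[2], sdv, wk$base[2], wk$bound)
      }
      cur <- c(xs[seg_end[k]], ys[seg_end[k]])
      # re-enter the box after a fold so the next segment walks around base
      if (folded) cur <- wk$base
    }
    pos[[lm]] <- cbind(xs, ys)
  }

  # --- eyelid closure schedule ---------------------------------------------
  closure <- rep(1, n)  # aperture multiplier per frame
  for (k in seq_along(seg_len)) {
    st <- seg_state[k]
    t0 <- (seg_start[k] - 1) / f
    t_end <- seg_end[k] / f
    if (st %in% c("stressed_squint", "stressed_combined")) {
      t <- t0
      repeat {
        t <- t + stats::runif(1, config$squint_gap_s[1], config$squint_gap_s[2])
        dur <- stats::runif(1, config$squint_duration_s[1],
                            config$squint_duration_s[2])
        i0 <- floor(t * f) + 1L
        i1 <- min(floor((t + dur) * f), seg_end[k])
        if (i0 > seg_end[k]) break
        if ((i1 - i0 + 1L) / f >= 1) {   # keep the truth consistent: squints >= 1 s
          closure[i0:i1] <- config$squint_closure
          add_event("squint", i0, i1)
        }
        t <- t + dur
      }
    } else {
      t <- t0
      repeat {
        t <- t + config$blink_refractory_s + stats::rexp(1, config$blink_rate / 60)
        dur <- stats::runif(1, config$blink_duration_s[1],
                            config$blink_duration_s[2])
        i0 <- floor(t * f) + 1L
        i1 <- min(floor((t + dur) * f), seg_end[k])
        if (i0 > seg_end[k]) break
        if (i1 >= i0) {
          closure[i0:i1] <- config$blink_closure
          add_event("blink", i0, i1)
        }
        t <- t + dur
      }
    }
    if (st %in% c("stressed_freeze", "stressed_combined"))
      add_event("freeze", seg_start[k], seg_end[k])
  }

  half_ap <- geo$open_aperture / 2
  eye <- function(center, sign) {
    cbind(rep(center[1], n), center[2] + sign * half_ap * closure)
  }
  lm_pos <- list(
    ear_left = pos$ear_left, ear_right = pos$ear_right,
    eyelid_upper_left = eye(geo$eye_left, -1),
    eyelid_lower_left = eye(geo$eye_left, +1),
    eyelid_upper_right = eye(geo$eye_right, -1),
    eyelid_lower_right = eye(geo$eye_right, +1),
    nose = pos$nose)

  # --- jitter, dropouts, likelihoods ---------------------------------------
  df <- data.frame(frame = 0:(n - 1))
  for (lm in landmark_names()) {
    p <- lm_pos[[lm]]
    p <- p + matrix(stats::rnorm(2 * n, 0, config$jitter_sd), ncol = 2)
    drop <- stats::runif(n) < config$dropout_rate
    lik <- stats::runif(n, 0.9, 1)
    lik[drop] <- stats::runif(sum(drop), 0, 0.5)
    p[drop, ] <- p[drop, , drop = FALSE] +
      matrix(stats::rnorm(2 * sum(drop), 0, config$dropout_scatter_sd), ncol = 2)
    df[[paste0(lm, ".x")]] <- p[, 1]
    df[[paste0(lm, ".y")]] <- p[, 2]
    df[[paste0(lm, ".likelihood")]] <- lik
  }

  event_log <- if (length(events)) {
    el <- do.call(rbind, events)
    el[order(el$start_frame, el$event), , drop = FALSE]
  } else {
    data.frame(event = character(0), start_frame = integer(0),
               end_frame = integer(0), stringsAsFactors = FALSE)
  }
  rownames(event_log) <- NULL
  structure(list(
    table = trajectory_table(df, fps = f, source = "simulated"),
    truth = truth,
    event_log = event_log,
    config = config
  ), class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("<simulated_session> %d frames @ %g fps; states: %s\n",
              nrow(x$table), fps(x$table),
              paste(unique(x$truth), collapse = ", ")))
  if (nrow(x$event_log))
    print(table(x$event_log$event))
  invisible(x)
}

#' Simulate a cohort with graded stress levels
#'
#' One session per mouse; mouse `i` spends a fraction `stress_levels[i]` of
#' the session in the combined stressed state (squinting + freezing + one
#' folded ear) and the rest relaxed, so the expected stress score is
#' monotone in the assigned true level.
#'
#' @param n_mice Number of mice; must equal `length(stress_levels)`.
#' @param stress_levels True stressed-time fractions in \[0, 1\].
#' @param seed RNG seed; per-mouse seeds are derived from it.
#' @param duration_s Session length (default 30 s).
#' @param fps Frames per second (default 30).
#' @return List with `sessions` (list of `simulated_session`) and
#'   `truth` (the `stress_levels` vector).
#' @export
make_validation_cohort <- function(n_mice, stress_levels, seed = 1,
                                   duration_s = 30, fps = 30) {
  if (n_mice != length(stress_levels))
    stop("n_mice (", n_mice, ") != length(stress_levels) (",
         length(stress_levels), ")")
  if (any(stress_levels < 0 | stress_levels > 1))
    stop("stress_levels must lie in [0, 1]")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_mice)
  sessions <- lapply(seq_len(n_mice), function(i) {
    l <- stress_levels[i]
    sched <- if (l <= 0) {
      list(list(state = "relaxed", duration_s = duration_s))
    } else if (l >= 1) {
      list(list(state = "stressed_combined", duration_s = duration_s))
    } else {
      list(list(state = "relaxed", duration_s = (1 - l) * duration_s / 2),
           list(state = "stressed_combined", duration_s = l * duration_s),
           list(state = "relaxed", duration_s = (1 - l) * duration_s / 2))
    }
    simulate_session(sim_config(fps = fps, duration_s = duration_s,
                                state_schedule = sched, seed = seeds[i]))
  })
  list(sessions = sessions, truth = stress_levels)
}
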
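#' Default analysis configuration
#'
#' All tunable parameters of the pipeline in one nested list. Values can be
#' overridden from a YAML file ([read_config()]) or by editing the list.
#'
#' \describe{
#'   \item{fps}{Frame rate of the recording (frames/s, default 30; the
#'     supported acquisition range is 30-60).}
#'   \item{cleaning}{`likelihood_threshold` (confidence cutoff, default
#'     0.6) and `max_gap_frames` (longest interpolated gap, default 5).}
#'   \item{metrics}{`window_s` evaluation window (default 2 s);
#'     `blink_max_s` blink/squint duration boundary (default 1 s, closures
#'     shorter than this are blinks); `closure_fraction` aperture threshold
#'     as a fraction of the open-eye baseline (default 0.4);
#'     `baseline_quantile` for the open-eye reference (default 0.75);
#'     `freeze_activity_threshold` on the scale-normalised activity index;
#'     `fold_range_threshold` and `fold_displacement_threshold` as
#'     fractions of the body scale.}
#'   \item{scoring}{feature `weights` (default all 1), `status_thresholds`
#'     (caution/stressed cutoffs, default even terciles 10/3 and 20/3) and
#'     the piecewise-linear `calibration` (see [default_calibration()]).}
#'   \item{live}{`baseline_window_s` rolling-baseline horizon (default
#'     60 s), `hysteresis_frames` consecutive frames required before the
#'     displayed status switches (default 15), and fallback baseline /
#'     scale in pixels used during warm-up.}
#' }
#'
#' @return A nested list of parameters.
#' @export
default_config <- function() {
  list(
    fps = 30,
    cleaning = list(likelihood_threshold = 0.6, max_gap_frames = 5L),
    landmark_aliases = NULL,
    metrics = list(
      window_s = 2.0,
      blink_max_s = 1.0,
      closure_fraction = 0.4,
      baseline_quantile = 0.75,
      freeze_activity_threshold = 0.145,
      fold_range_threshold = 0.05,
      fold_displacement_threshold = 0.15
    ),
    scoring = list(
      weights = stats::setNames(rep(1, 5), feature_names()),
      status_thresholds = c(10 / 3, 20 / 3),
      calibration = default_calibration()
    ),
    live = list(
      baseline_window_s = 60,
      hysteresis_frames = 15L,
      fallback_baseline_px = 24,
      fallback_scale_px = 200
    )
  )
}

#' Default score calibration
#'
#' Piecewise-linear maps from each feature's driving metric to the 0-10
#' stress scale. Eyes are driven by the fraction of the window spent inside
#' squint-kind closure epochs, with a secondary map on the window-mean
#' aperture relative to the open-eye baseline (sustained narrow eyes raise
#' the score even between detected epochs); the two are combined by max.
#' Nose and ears are driven by the inverted, scale-normalised activity
#' index (immobility scores high). Ear scores additionally receive a fixed
#' bump when a fold is detected and a proportional bump for left/right
#' asymmetry. All outputs are clamped to [0, 10].
#'
#' Activity-map knots were placed so that a textbook relaxed session under
#' the default simulator geometry scores below 2 and a textbook combined
#' stressed session above 8; they are fully overridable.
#'
#' @return A nested list of knot matrices and bump sizes.
#' @export
default_calibration <- function() {
  list(
    scale_definition = "inter_ear_median",
    eye = list(
      squint_knots = cbind(x = c(0, 0.2, 0.5), score = c(0, 5, 10)),
      aperture_knots = cbind(x = c(0, 0.2, 0.5, 0.8), score = c(9.5, 8.5, 2, 0))
    ),
    nose = list(
      activity_knots = cbind(x = c(0, 0.13, 0.30, 0.45), score = c(10, 8.5, 1, 0))
    ),
    ear = list(
      activity_knots = cbind(x = c(0, 0.13, 0.175, 0.30), score = c(10, 8.5, 1, 0)),
      delta_fold = 4,
      delta_asym = 2
    )
  )
}

# recursive list merge: values in `over` win
merge_config <- function(base, over) {
  if (is.null(over)) return(base)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default. Calibration knot lists given as two-column
#' `[metric, score]` row lists are converted to knot matrices.
#'
#' @param path YAML file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  cal <- cfg$scoring$calibration
  fix_knots <- function(k) {
    if (is.matrix(k)) return(k)
    m <- do.call(rbind, lapply(k, unlist))
    colnames(m) <- c("x", "score")
    m
  }
  for (blk in c("eye", "nose", "ear")) {
    for (nm in names(cal[[blk]])) {
      if (grepl("_knots$", nm)) cal[[blk]][[nm]] <- fix_knots(cal[[blk]][[nm]])
    }
  }
  cfg$scoring$calibration <- cal
  if (!is.null(cfg$scoring$weights)) {
    cfg$scoring$weights <- unlist(cfg$scoring$weights)
  }
  cfg
}

# stable hash of a configuration (md5 of its canonical YAML dump)
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config, precision = 12), f)
  unname(tools::md5sum(f))
}
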
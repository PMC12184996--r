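#' Construct a trajectory table
#'
#' A trajectory table holds per-frame (x, y, likelihood) records for the 7
#' facial landmarks, plus the acquisition frame rate. Coordinates follow the
#' image convention: origin top-left, x rightward, y downward, units pixels.
#' The table format itself never stores fps; it is supplied out of band
#' (config or argument) and defaults to 30 (the supported acquisition range
#' is 30-60 frames/s).
#'
#' @param data A data.frame with one row per frame and columns
#'   `<landmark>.x`, `<landmark>.y`, `<landmark>.likelihood` for each of the
#'   7 landmarks (see [landmark_names()]). An optional `frame` column must
#'   be contiguous from 0.
#' @param fps Frames per second (> 0).
#' @param source Free-text provenance string.
#' @return An object of class `trajectory_table` (a data.frame with a
#'   leading `frame` column and `fps`/`source` attributes).
#' @export
trajectory_table <- function(data, fps = 30, source = "") {
  stopifnot(is.data.frame(data))
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- all_landmark_cols()
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing landmark columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  if (!"frame" %in% names(data)) {
    data$frame <- if (n) 0:(n - 1) else integer(0)
  } else if (n && !identical(as.integer(data$frame), 0:(n - 1))) {
    stop("frame indices must be contiguous from 0")
  }
  data <- data[, c("frame", need)]
  for (lm in landmark_names()) {
    lik <- data[[paste0(lm, ".likelihood")]]
    bad <- !is.na(lik) & (lik < 0 | lik > 1)
    if (any(bad))
      stop("likelihood outside [0,1] for landmark ", lm)
  }
  structure(data,
            fps = fps, source = source,
            class = c("trajectory_table", "data.frame"))
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> %d frames, 7 landmarks, %.6g fps (%.2f s)\n",
              nrow(x), attr(x, "fps"), nrow(x) / attr(x, "fps")))
  src <- attr(x, "source")
  if (nzchar(src)) cat("source:", src, "\n")
  miss <- vapply(landmark_names(), function(lm) {
    sum(is.na(x[[paste0(lm, ".x")]]))
  }, integer(1))
  if (any(miss > 0)) {
    cat("missing frames per landmark:\n")
    print(miss[miss > 0])
  }
  invisible(x)
}

#' Frame rate of a trajectory table
#' @param table A `trajectory_table`.
#' @return Frames per second.
#' @export
fps <- function(table) {
  f <- attr(table, "fps")
  if (is.null(f)) stop("object carries no fps attribute")
  f
}

# n x 2 matrix of (x, y) for one landmark
landmark_xy <- function(table, landmark, rows = NULL) {
  xs <- table[[paste0(landmark, ".x")]]
  ys <- table[[paste0(landmark, ".y")]]
  if (!is.null(rows)) {
    xs <- xs[rows]; ys <- ys[rows]
  }
  cbind(x = xs, y = ys)
}

# subset rows while keeping class/attributes
slice_table <- function(table, rows) {
  out <- as.data.frame(table)[rows, , drop = FALSE]
  out$frame <- if (nrow(out)) 0:(nrow(out) - 1) else integer(0)
  rownames(out) <- NULL
  trajectory_table(out, fps = attr(table, "fps"), source = attr(table, "source"))
}
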
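#' Read a landmark trajectory table
#'
#' Reads the two standard markerless-tracking export dialects:
#' \describe{
#'   \item{`csv3header`}{Text CSV with 3 header rows (`scorer`, `bodyparts`,
#'     `coords`), a leading frame-index column, then `x`, `y`, `likelihood`
#'     triplets per landmark.}
#'   \item{`h5`}{HDF5 file with one table group carrying the same column
#'     hierarchy (datasets `values`, `bodyparts`, `coords`, `scorer`).}
#' }
#' The file format stores no frame rate; supply `fps` (default 30).
#'
#' @param path File to read.
#' @param dialect `"csv3header"` or `"h5"`.
#' @param fps Frames per second of the recording.
#' @param aliases Optional named character vector mapping landmark names as
#'   they appear in the file to the canonical names in [landmark_names()],
#'   e.g. `c(LeftEar = "ear_left")`.
#' @return A [trajectory_table()].
#' @export
read_trajectories <- function(path, dialect = c("csv3header", "h5"),
                              fps = 30, aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv3header") {
    read_trajectories_csv(path, fps = fps, aliases = aliases)
  } else {
    read_trajectories_h5(path, fps = fps, aliases = aliases)
  }
}

canonicalise_landmarks <- function(bodyparts, aliases) {
  if (!is.null(aliases)) {
    hit <- bodyparts %in% names(aliases)
    bodyparts[hit] <- unname(aliases[bodyparts[hit]])
  }
  bodyparts
}

check_landmark_set <- function(parts) {
  want <- landmark_names()
  missing <- setdiff(want, parts)
  extra <- setdiff(parts, want)
  if (length(missing) || length(extra))
    stop("landmark schema mismatch",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  invisible(TRUE)
}

read_trajectories_csv <- function(path, fps, aliases) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed header: expected 3 header rows, file has ",
                              length(lines), " lines (line ", length(lines), ")")
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- vapply(hdr, `[`, "", 1)
  expect <- c("scorer", "bodyparts", "coords")
  bad <- which(tolower(labels) != expect)
  if (length(bad))
    stop("malformed header at line ", bad[1], ": expected row label '",
         expect[bad[1]], "', found '", labels[bad[1]], "'")
  bodyparts_row <- hdr[[2]][-1]
  coords_row <- hdr[[3]][-1]
  if (length(bodyparts_row) != length(coords_row))
    stop("malformed header at line 3: bodyparts and coords rows differ in length")
  if (length(coords_row) %% 3 != 0 ||
      !all(coords_row == rep(c("x", "y", "likelihood"),
                             length(coords_row) / 3)))
    stop("malformed header at line 3: coords must repeat x,y,likelihood")
  parts <- canonicalise_landmarks(bodyparts_row[seq(1, length(bodyparts_row), by = 3)],
                                  aliases)
  rep_ok <- rep(parts, each = 3) == canonicalise_landmarks(bodyparts_row, aliases)
  if (!all(rep_ok))
    stop("malformed header at line 2: each bodypart must span one x,y,likelihood triplet")
  check_landmark_set(parts)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  n <- length(body)
  vals <- if (n) {
    con <- textConnection(body)
    on.exit(close(con), add = TRUE)
    as.matrix(utils::read.csv(con, header = FALSE,
                              colClasses = "numeric", na.strings = c("", "NA")))
  } else {
    matrix(numeric(0), 0, length(coords_row) + 1)
  }
  df <- as.data.frame(vals[, -1, drop = FALSE])
  names(df) <- unlist(lapply(parts, landmark_cols), use.names = FALSE)
  df <- df[, all_landmark_cols(), drop = FALSE]
  trajectory_table(df, fps = fps, source = path)
}

read_trajectories_h5 <- function(path, fps, aliases) {
  grp <- "trajectories"
  values <- rhdf5::h5read(path, file.path(grp, "values"))
  bodyparts <- as.character(rhdf5::h5read(path, file.path(grp, "bodyparts")))
  coords <- as.character(rhdf5::h5read(path, file.path(grp, "coords")))
  rhdf5::h5closeAll()
  if (length(coords) %% 3 != 0 ||
      !all(coords == rep(c("x", "y", "likelihood"), length(coords) / 3)))
    stop("malformed h5 column hierarchy: coords must repeat x,y,likelihood")
  parts <- canonicalise_landmarks(bodyparts[seq(1, length(bodyparts), by = 3)],
                                  aliases)
  check_landmark_set(parts)
  df <- as.data.frame(values)
  names(df) <- unlist(lapply(parts, landmark_cols), use.names = FALSE)
  df <- df[, all_landmark_cols(), drop = FALSE]
  trajectory_table(df, fps = fps, source = path)
}

#' Write a landmark trajectory table
#'
#' Numeric text in the CSV dialect is written at full IEEE double
#' round-trip precision (17 significant digits), so a read-back table is
#' value-exact. Missing coordinates are written as empty fields.
#'
#' @param table A [trajectory_table()].
#' @param path Output file.
#' @param dialect `"csv3header"` or `"h5"`.
#' @param scorer Scorer label placed in the header.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(table, path, dialect = c("csv3header", "h5"),
                               scorer = "facestress") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "trajectory_table"))
  vals <- as.matrix(as.data.frame(table)[, all_landmark_cols(), drop = FALSE])
  if (dialect == "csv3header") {
    ncols <- ncol(vals)
    hdr <- c(paste(c("scorer", rep(scorer, ncols)), collapse = ","),
             paste(c("bodyparts", rep(landmark_names(), each = 3)), collapse = ","),
             paste(c("coords", rep(c("x", "y", "likelihood"), 7)), collapse = ","))
    fmt <- function(v) {
      s <- formatC(v, digits = 17, format = "g")
      s[is.na(v)] <- ""
      s
    }
    rows <- if (nrow(vals)) {
      body <- apply(vals, 2, fmt)
      if (is.null(dim(body))) body <- matrix(body, nrow = 1)
      apply(cbind(table$frame, body), 1, paste, collapse = ",")
    } else character(0)
    ok <- tryCatch({
      writeLines(c(hdr, rows), path); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  } else {
    if (file.exists(path)) unlink(path)
    ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
    if (!isTRUE(ok)) stop("cannot write ", path)
    rhdf5::h5createGroup(path, "trajectories")
    rhdf5::h5write(vals, path, "trajectories/values")
    rhdf5::h5write(rep(landmark_names(), each = 3), path, "trajectories/bodyparts")
    rhdf5::h5write(rep(c("x", "y", "likelihood"), 7), path, "trajectories/coords")
    rhdf5::h5write(scorer, path, "trajectories/scorer")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Clean a trajectory table
#'
#' Points whose likelihood falls below `likelihood_threshold` are replaced
#' by linear interpolation (per coordinate, independently for x and y) from
#' the nearest confident neighbours, provided the run of consecutive
#' low-likelihood frames is at most `max_gap_frames` and confident frames
#' exist on both sides. Longer runs, and runs touching the session edges,
#' are flagged missing (`NA` coordinates). Confident points are never
#' altered, and cleaning is idempotent.
#'
#' @param table A [trajectory_table()].
#' @param likelihood_threshold Confidence cutoff in \[0,1\] (default 0.6).
#' @param max_gap_frames Longest gap, in frames, that is interpolated
#'   rather than flagged missing (default 5).
#' @return A cleaned [trajectory_table()] of the same length.
#' @export
clean_trajectories <- function(table, likelihood_threshold = 0.6,
                               max_gap_frames = 5L) {
  stopifnot(inherits(table, "trajectory_table"),
            likelihood_threshold >= 0, likelihood_threshold <= 1,
            max_gap_frames >= 0)
  out <- as.data.frame(table)
  n <- nrow(out)
  for (lm in landmark_names()) {
    xc <- paste0(lm, ".x"); yc <- paste0(lm, ".y")
    lc <- paste0(lm, ".likelihood")
    lik <- out[[lc]]
    confident <- !is.na(lik) & lik >= likelihood_threshold &
      is.finite(out[[xc]]) & is.finite(out[[yc]])
    if (!any(confident))
      stop("landmark '", lm, "' has no confident frames at threshold ",
           likelihood_threshold)
    if (all(confident)) next
    r <- rle(!confident)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    conf_idx <- which(confident)
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      interior <- i0 > 1 && i1 < n
      if (interior && r$lengths[k] <= max_gap_frames) {
        lo <- i0 - 1; hi <- i1 + 1
        w <- (i0:i1 - lo) / (hi - lo)
        out[[xc]][i0:i1] <- out[[xc]][lo] + w * (out[[xc]][hi] - out[[xc]][lo])
        out[[yc]][i0:i1] <- out[[yc]][lo] + w * (out[[yc]][hi] - out[[yc]][lo])
      } else {
        out[[xc]][i0:i1] <- NA_real_
        out[[yc]][i0:i1] <- NA_real_
      }
    }
  }
  trajectory_table(out, fps = attr(table, "fps"), source = attr(table, "source"))
}
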
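# Build a trajectory table from per-landmark position functions.
# `positions` maps landmark name -> function(frame_index_0based) -> c(x, y);
# unlisted landmarks sit at fixed default spots. Likelihood defaults to 1.
make_table <- function(n, positions = list(), fps = 30, likelihood = 1) {
  defaults <- list(
    ear_left = c(100, 40), ear_right = c(300, 40),
    eyelid_upper_left = c(140, 100), eyelid_lower_left = c(140, 124),
    eyelid_upper_right = c(260, 100), eyelid_lower_right = c(260, 124),
    nose = c(200, 250))
  idx <- seq_len(n) - 1L
  df <- data.frame(frame = idx)
  for (lm in landmark_names()) {
    if (!is.null(positions[[lm]])) {
      xy <- t(vapply(idx, positions[[lm]], numeric(2)))
    } else if (n == 0) {
      xy <- matrix(numeric(0), 0, 2)
    } else {
      xy <- matrix(defaults[[lm]], n, 2, byrow = TRUE)
    }
    df[[paste0(lm, ".x")]] <- xy[, 1]
    df[[paste0(lm, ".y")]] <- xy[, 2]
    df[[paste0(lm, ".likelihood")]] <- rep(likelihood, length.out = n)
  }
  trajectory_table(df, fps = fps, source = "helper")
}

# an aperture trace: open value with closed runs inserted at given frames
make_aperture <- function(n, open = 10, closed = 2, runs = list()) {
  a <- rep(open, n)
  for (r in runs) a[r] <- closed
  a
}

expect_tables_equal <- function(a, b, tolerance = 0) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
  expect_equal(attr(a, "fps"), attr(b, "fps"))
}
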
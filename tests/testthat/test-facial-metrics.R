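test_that("euclidean distance behaves as plane geometry demands", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 1), c(1, 1)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(1, 1)), sqrt(2))
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)),
               euclidean_distance(c(3, 4), c(0, 0)))
  expect_true(is.na(euclidean_distance(c(NA, 0), c(3, 4))))
})

test_that("eye aperture series has one value per frame and smooths correctly", {
  tab <- make_table(50)  # left eyelids at (140,100)/(140,124): aperture 24
  ap <- eye_aperture_series(tab, "left")
  expect_length(ap$raw, 50)
  expect_equal(ap$raw, rep(24, 50))
  expect_equal(ap$smoothed, rep(24, 50))

  # sinusoidal closure: smoothed must equal a brute-force moving average
  n <- 120; f <- 30
  tab2 <- make_table(n, list(
    eyelid_lower_left = function(i) c(140, 100 + 12 + 10 * sin(i / 8))), fps = f)
  ap2 <- eye_aperture_series(tab2, "left")
  brute <- sapply(seq_len(n), function(i) {
    half <- floor(f / 2)
    lo <- max(1, i - half); hi <- min(n, lo + f - 1); lo <- max(1, hi - f + 1)
    mean(ap2$raw[lo:hi])
  })
  expect_equal(ap2$smoothed, brute)
})

test_that("aperture baseline is the 75th percentile, robust to closures", {
  expect_equal(compute_aperture_baseline(rep(6, 10)), 6)
  # 90 open frames at 6 px, 10 closed at 1 px: brute-force 75th percentile
  a <- c(rep(6, 90), rep(1, 10))
  srt <- sort(a)
  h <- (100 - 1) * 0.75 + 1
  brute <- srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  expect_equal(brute, 6)
  expect_equal(compute_aperture_baseline(a), brute)
  # homogeneity under rescaling
  set.seed(7)
  x <- runif(40, 2, 9)
  expect_equal(compute_aperture_baseline(3.7 * x),
               3.7 * compute_aperture_baseline(x))
  expect_error(compute_aperture_baseline(c(NA_real_, NA_real_)), "non-missing")
})

test_that("closure epochs classify by duration: sub-second blinks, else squints", {
  f <- 30
  ap <- make_aperture(300, open = 10, closed = 2,
                      runs = list(11:25,      # 15 frames = 0.5 s -> blink
                                  101:129,    # 29 frames < 1 s  -> blink
                                  151:180,    # 30 frames = 1 s  -> squint (tie)
                                  201:260))   # 60 frames = 2 s  -> squint
  ep <- detect_squint_epochs(ap, f, baseline = 10)
  expect_equal(nrow(ep), 4)
  expect_equal(ep$kind, c("blink", "blink", "squint", "squint"))
  expect_equal(ep$duration_s, c(0.5, 29 / 30, 1, 2))
  expect_equal(ep$start_frame, c(10, 100, 150, 200))
  expect_equal(ep$end_frame, c(24, 128, 179, 259))
  # open eye throughout -> no epochs
  expect_equal(nrow(detect_squint_epochs(rep(10, 100), f, 10)), 0)
  expect_error(detect_squint_epochs(ap, f, baseline = 0), "baseline")
})

test_that("epochs are disjoint, maximal, ordered, and blinks never last 1 s", {
  set.seed(99)
  for (rep in 1:40) {
    n <- 200 + sample(200, 1)
    ap <- make_aperture(n)
    k <- sample(5, 1)
    for (j in seq_len(k)) {
      st <- sample(n - 80, 1)
      ap[st:(st + sample(75, 1))] <- 2
    }
    ep <- detect_squint_epochs(ap, 30, 10)
    if (nrow(ep) > 1) {
      expect_true(all(diff(ep$start_frame) > 0))
      expect_true(all(ep$start_frame[-1] > ep$end_frame[-nrow(ep)] + 1))
    }
    for (i in seq_len(nrow(ep))) {
      run <- (ep$start_frame[i]:ep$end_frame[i]) + 1
      expect_true(all(ap[run] < 0.4 * 10))
      expect_equal(ep$duration_s[i] < 1, ep$kind[i] == "blink")
    }
  }
})

test_that("max range of motion equals the exhaustive pairwise maximum", {
  expect_equal(max_range_of_motion(matrix(c(5, 5), 1)), 0)
  expect_equal(max_range_of_motion(rbind(c(0, 0), c(3, 4))), 5)
  set.seed(3)
  p <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  brute <- max(sqrt(outer(p[, 1], p[, 1], "-")^2 + outer(p[, 2], p[, 2], "-")^2))
  expect_equal(max_range_of_motion(p), brute)
  expect_error(max_range_of_motion(matrix(NA_real_, 3, 2)), "no non-missing")
})

test_that("travel distance sums consecutive segments, bridging missing frames", {
  expect_equal(travel_distance(rbind(c(1, 1), c(1, 1))), 0)
  expect_equal(travel_distance(rbind(c(0, 0), c(1, 0), c(1, 1))), 2)
  set.seed(4)
  p <- cbind(runif(50), runif(50))
  brute <- 0
  for (i in 2:50) brute <- brute + sqrt(sum((p[i, ] - p[i - 1, ])^2))
  expect_equal(travel_distance(p), brute)
  # one missing row bridged by a single segment
  p2 <- rbind(c(0, 0), c(NA, NA), c(3, 4))
  expect_equal(travel_distance(p2), 5)
})

test_that("activity index is the mean of scale-normalised range and travel", {
  expect_equal(activity_index(0, 0, 10), 0)
  expect_equal(activity_index(5, 5, 10), 0.5)
  expect_equal(activity_index(3, 7, 5), activity_index(6, 14, 10))
  expect_error(activity_index(1, 1, 0), "scale")
  expect_gt(activity_index(2, 5, 10), activity_index(1, 5, 10))
  expect_gt(activity_index(2, 6, 10), activity_index(2, 5, 10))
})

test_that("ear metrics capture asymmetry and the immobile-and-displaced fold", {
  n <- 60
  walk <- function(i) c(100 + 3 * sin(i / 2), 40 + 3 * cos(i / 3))
  # identical movement (shifted to the right base) -> asymmetry 0
  tab <- make_table(n, list(ear_left = walk,
                            ear_right = function(i) walk(i) + c(200, 0)))
  em <- ear_metrics(tab, 1:n, scale = 200)
  expect_equal(em$ear_asymmetry, 0)
  expect_false(em$ear_fold_left)

  # one ear moving, the other frozen at its median -> asymmetry 1, no fold
  tab2 <- make_table(n, list(ear_left = walk))
  em2 <- ear_metrics(tab2, 1:n, scale = 200)
  expect_equal(em2$ear_asymmetry, 1)
  expect_false(em2$ear_fold_right)

  # two still ears are symmetric by convention
  em3 <- ear_metrics(make_table(n), 1:n, scale = 200)
  expect_equal(em3$ear_asymmetry, 0)

  # pinned 0.3*scale from the session median with zero motion -> fold
  # (session = 4 windows at base, last window displaced)
  pin <- function(i) if (i >= 180) c(100 + 60, 40) else c(100, 40)
  tab4 <- make_table(240, list(ear_left = pin))
  em4 <- ear_metrics(tab4, 181:240, scale = 200,
                     fold_range_threshold = 0.02,
                     fold_displacement_threshold = 0.1)
  expect_true(em4$ear_fold_left)
  em4b <- ear_metrics(tab4, 1:60, scale = 200,
                      fold_range_threshold = 0.02,
                      fold_displacement_threshold = 0.1)
  expect_false(em4b$ear_fold_left)  # immobile but not displaced
})

test_that("freezing requires nose and both ears to be still", {
  m <- data.frame(nose_activity_index = c(0, 0.5, 0.1, 0.1),
                  ear_activity_left = c(0, 0.5, 0.1, 0.5),
                  ear_activity_right = c(0, 0.5, 0.1, 0.1))
  expect_equal(detect_freezing(m, 0.145), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("freezing alternates with the constructed still/active pattern", {
  n <- 30 * 12  # 12 s -> 6 windows; odd windows still, even windows active
  mover <- function(base) function(i) {
    w <- (i %/% 60) %% 2
    if (w == 1) base + c(6 * sin(i), 6 * cos(1.3 * i)) else base
  }
  tab <- make_table(n, list(nose = mover(c(200, 250)),
                            ear_left = mover(c(100, 40)),
                            ear_right = mover(c(300, 40))))
  wm <- windowed_metrics(tab, scale = 200)
  expect_equal(wm$freezing, rep(c(TRUE, FALSE), 3))
})

test_that("windowing splits sessions as specified and keeps half windows", {
  tab <- make_table(300, list(nose = function(i) c(200 + sin(i), 250)))
  expect_equal(nrow(windowed_metrics(tab, scale = 200)), 5)   # 10 s / 2 s
  tab11 <- make_table(330, list(nose = function(i) c(200 + sin(i), 250)))
  wm <- windowed_metrics(tab11, scale = 200)
  expect_equal(nrow(wm), 6)                                   # 5 full + 1 half
  expect_equal(wm$valid_fraction[6], 0.5)
  expect_true(all(wm$nose_travel >= wm$nose_max_range))
  expect_error(windowed_metrics(make_table(20), scale = 200), "half a window")
})

test_that("windowed metrics on a boundary-aligned concatenation concatenate", {
  mk <- function() make_table(240, list(
    nose = function(i) c(200 + 5 * sin(i / 5), 250 + 5 * cos(i / 7)),
    ear_left = function(i) c(100 + 2 * sin(i / 9), 40),
    ear_right = function(i) c(300 + 2 * cos(i / 11), 40)))
  a <- mk()
  both <- as.data.frame(a)[c(1:240, 1:240), ]
  both$frame <- 0:479
  ab <- trajectory_table(both, fps = 30)
  wa <- windowed_metrics(a, scale = 200)
  wab <- windowed_metrics(ab, scale = 200)
  cols <- c("nose_max_range", "nose_travel", "nose_activity_index",
            "ear_activity_left", "ear_activity_right", "ear_asymmetry",
            "squint_fraction_left", "valid_fraction", "freezing")
  expect_equal(as.data.frame(wab)[1:4, cols],
               as.data.frame(wa)[1:4, cols], ignore_attr = TRUE)
  expect_equal(as.data.frame(wab)[5:8, cols],
               as.data.frame(wa)[1:4, cols], ignore_attr = TRUE)
})

test_that("per-window metrics are translation- and scale-invariant after
           normalisation", {
  set.seed(12)
  s <- simulate_session(sim_config(duration_s = 8, seed = 5))
  base <- clean_trajectories(s$table)
  wm0 <- windowed_metrics(base)
  for (tf in list(c(2, 0), c(0.5, 0), c(1, 117.3))) {
    df <- as.data.frame(base)
    for (lm in landmark_names()) {
      for (cc in c(".x", ".y"))
        df[[paste0(lm, cc)]] <- df[[paste0(lm, cc)]] * tf[1] + tf[2]
    }
    wm1 <- windowed_metrics(trajectory_table(df, fps = 30))
    for (col in c("nose_activity_index", "ear_activity_left",
                  "ear_activity_right", "ear_asymmetry",
                  "rel_aperture_left", "rel_aperture_right",
                  "squint_fraction_left", "squint_fraction_right"))
      expect_equal(wm1[[col]], wm0[[col]], tolerance = 1e-9)
    expect_identical(wm1$freezing, wm0$freezing)
  }
})
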
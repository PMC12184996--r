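fake_metrics <- function(...) {
  base <- data.frame(
    start_frame = 0L, end_frame = 59L,
    aperture_left = 24, aperture_right = 24,
    rel_aperture_left = 1, rel_aperture_right = 1,
    squint_fraction_left = 0, squint_fraction_right = 0,
    nose_max_range = 20, nose_travel = 100, nose_activity_index = 0.5,
    ear_activity_left = 0.2, ear_activity_right = 0.2,
    ear_asymmetry = 0, ear_fold_left = FALSE, ear_fold_right = FALSE,
    valid_fraction = 1, freezing = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("feature scores hit the calm and stressed clamps and knots exactly", {
  cal <- default_calibration()
  # fully open eye, no squint coverage -> calm end of the map
  expect_equal(feature_score(fake_metrics(), "EYE_LEFT", cal), 0)
  # entire window inside a squint epoch -> 10
  expect_equal(feature_score(fake_metrics(squint_fraction_left = 1,
                                          rel_aperture_left = 0.2),
                             "EYE_LEFT", cal), 10)
  # nose activity exactly at an interior knot -> that knot's score
  k <- cal$nose$activity_knots
  expect_equal(feature_score(fake_metrics(nose_activity_index = k[2, "x"]),
                             "NOSE", cal), unname(k[2, "score"]))
  expect_equal(feature_score(fake_metrics(nose_activity_index = k[3, "x"]),
                             "NOSE", cal), unname(k[3, "score"]))
  # fold and asymmetry bumps add onto the ear activity score
  s0 <- feature_score(fake_metrics(ear_activity_left = 0.16), "EAR_LEFT", cal)
  s_fold <- feature_score(fake_metrics(ear_activity_left = 0.16,
                                       ear_fold_left = TRUE), "EAR_LEFT", cal)
  expect_equal(s_fold, min(10, s0 + cal$ear$delta_fold))
  s_asym <- feature_score(fake_metrics(ear_activity_left = 0.16,
                                       ear_asymmetry = 0.5), "EAR_LEFT", cal)
  expect_equal(s_asym, min(10, s0 + 0.5 * cal$ear$delta_asym))
  # missing landmarks give a missing score
  expect_true(is.na(feature_score(fake_metrics(nose_activity_index = NA_real_),
                                  "NOSE", cal)))
})

test_that("aggregation is the weighted mean over available features", {
  feats <- feature_names()
  expect_equal(aggregate_score(setNames(rep(5, 5), feats)), 5)
  expect_equal(aggregate_score(setNames(c(10, 0, 0, 0, 0), feats)), 2)
  sc <- setNames(c(8, 2, 4, 6, 0), feats)
  w <- setNames(c(2, 1, 1, 1, 0), feats)
  expect_equal(aggregate_score(sc, w), (2 * 8 + 2 + 4 + 6) / 5)  # by hand
  expect_error(aggregate_score(setNames(rep(NA_real_, 5), feats)), "no feature")
  expect_error(aggregate_score(setNames(rep(1, 5), feats),
                               setNames(rep(0, 5), feats)), "no feature")
})

test_that("aggregation matches brute force, respects bounds and deletion", {
  set.seed(10)
  feats <- feature_names()
  for (i in 1:300) {
    sc <- setNames(runif(5, 0, 10), feats)
    w <- setNames(rexp(5), feats)
    drop <- sample(5, sample(0:3, 1))
    w[drop] <- 0
    if (all(w == 0)) w[1] <- 1
    got <- aggregate_score(sc, w)
    brute <- sum(sc[w > 0] * w[w > 0]) / sum(w[w > 0])
    expect_equal(got, brute, tolerance = 1e-12)
    expect_gte(got, min(sc[w > 0]))
    expect_lte(got, max(sc[w > 0]))
    # zero weight is exactly feature deletion
    sc2 <- sc; sc2[drop] <- NA_real_
    expect_identical(got, aggregate_score(sc2, w))
    # monotone in any single score
    j <- sample(which(w > 0), 1)
    sc3 <- sc; sc3[j] <- min(10, sc3[j] + 1)
    expect_gte(aggregate_score(sc3, w), got)
  }
})

test_that("status splits the scale at the configured thresholds", {
  expect_equal(status_level(0), "okay")
  expect_equal(status_level(10), "stressed")
  expect_equal(status_level(10 / 3), "caution")       # boundary is caution
  expect_equal(status_level(20 / 3), "stressed")      # boundary is stressed
  expect_equal(status_level(c(1, 5, 9)), c("okay", "caution", "stressed"))
  expect_error(status_level(5, c(7, 3)), "thresholds")
  expect_error(status_level(5, c(3, 12)), "thresholds")
})

test_that("relaxed sessions score in the okay band, combined stress in the
           stressed band", {
  relaxed <- simulate_session(sim_config(duration_s = 20, seed = 21))
  rep_r <- score_session(relaxed$table)
  expect_equal(rep_r$session_status, "okay")
  expect_lt(rep_r$session_mean, 2)

  stressed <- simulate_session(sim_config(
    duration_s = 20, seed = 22,
    state_schedule = list(list(state = "stressed_combined", duration_s = 20))))
  rep_s <- score_session(stressed$table)
  expect_equal(rep_s$session_status, "stressed")
  expect_gt(rep_s$session_mean, 8)
})

test_that("session totals are invariant under coordinate doubling", {
  s <- simulate_session(sim_config(duration_s = 10, seed = 23))
  r1 <- score_session(s$table)
  df <- as.data.frame(s$table)
  for (lm in landmark_names())
    for (cc in c(".x", ".y"))
      df[[paste0(lm, cc)]] <- 2 * df[[paste0(lm, cc)]]
  r2 <- score_session(trajectory_table(df, fps = 30))
  expect_equal(r2$windows$total, r1$windows$total, tolerance = 1e-9)
  expect_equal(r2$session_mean, r1$session_mean, tolerance = 1e-9)
})

test_that("scoring is deterministic: identical runs give identical reports", {
  s <- simulate_session(sim_config(duration_s = 8, seed = 24))
  r1 <- score_session(s$table)
  r2 <- score_session(s$table)
  expect_identical(r1$windows, r2$windows)
  expect_identical(r1$session_mean, r2$session_mean)
  expect_identical(r1$config_hash, r2$config_hash)
})

test_that("session mean weights windows by their valid fraction", {
  s <- simulate_session(sim_config(duration_s = 11, seed = 25))
  r <- score_session(s$table)
  expect_equal(r$session_mean,
               weighted.mean(r$windows$total, r$windows$valid_fraction))
})

test_that("ablation: empty removal deviates by zero, groups cover sizes 0-4", {
  s <- simulate_session(sim_config(
    duration_s = 12, seed = 26,
    state_schedule = list(list(state = "relaxed", duration_s = 6),
                          list(state = "stressed_combined", duration_s = 6))))
  ab <- suppressWarnings(ablation_analysis(s$table))
  expect_equal(nrow(ab), 2^5 - 1)  # all subsets except removing everything
  expect_equal(ab$deviation[ab$removed == ""], 0)
  expect_true(all(ab$deviation >= 0))
  by_size <- ablation_by_size(ab)
  expect_equal(by_size$n_removed, 0:4)
  expect_warning(ablation_analysis(s$table), "all features")
})

test_that("removing a feature whose score equals the total leaves it unchanged", {
  feats <- feature_names()
  sc <- setNames(c(4, 4, 4, 4, 4), feats)
  w <- setNames(rep(1, 5), feats)
  total <- aggregate_score(sc, w)
  for (f in feats) {
    w2 <- w; w2[f] <- 0
    expect_equal(aggregate_score(sc, w2), total)
  }
})

test_that("stress report methods print and plot without error", {
  s <- simulate_session(sim_config(duration_s = 8, seed = 27))
  r <- score_session(s$table)
  expect_output(print(r), "stress_report")
  expect_output(print(summary(r)), "Session stress")
  pdf(NULL)
  expect_silent(plot(r))
  dev.off()
})
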
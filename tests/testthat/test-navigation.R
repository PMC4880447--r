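# Gradient arena geometry, bearing, run segmentation, curving bias,
# bearing-binned statistics, shallow-turn events and population profiles.

test_that("arena O2 mapping is linear with the documented endpoints", {
  a <- gradient_arena()
  expect_equal(o2_at_position(a, 0), 4)
  expect_equal(o2_at_position(a, a$length), 21)
  expect_equal(o2_at_position(a, a$length / 2), 12.5)
  expect_error(o2_at_position(a, -1), "outside")
  expect_error(gradient_arena(o2_low = 18, optimum = 16), "optimum")
})

test_that("bearing hits the three canonical orientations and folds sides", {
  a <- gradient_arena()
  fr <- 10
  n <- 100
  t <- (0:(n - 1)) / fr
  mk <- function(dx, dy, x0 = 5, y0 = 7)
    worm_track(cbind(x0 + dx * 0.2 * t, y0 + dy * 0.2 * t), fr)
  ## from the low side, the optimum lies toward +x
  expect_equal(stats::median(bearing(mk(1, 0), a)$bearing_deg,
                             na.rm = TRUE), 0, tolerance = 1)
  expect_equal(stats::median(bearing(mk(-1, 0), a)$bearing_deg,
                             na.rm = TRUE), 180, tolerance = 1)
  expect_equal(stats::median(bearing(mk(0, 1), a)$bearing_deg,
                             na.rm = TRUE), 90, tolerance = 1)
  ## reflection across the gradient axis leaves bearing unchanged
  b_up <- bearing(mk(0.3, 1), a)$bearing_deg
  b_dn <- bearing(mk(0.3, -1), a)$bearing_deg
  expect_equal(stats::median(b_up, na.rm = TRUE),
               stats::median(b_dn, na.rm = TRUE), tolerance = 1)
})

test_that("run segmentation drops short and short-displacement runs", {
  fr <- 10
  n <- 200
  xy <- cbind(0.2 * (0:(n - 1)) / fr, 0)
  tr <- worm_track(xy, fr)
  lab <- state_labels(rep("forward", n))
  runs <- segment_runs(tr, lab)
  expect_equal(nrow(runs), 1)      # 20 s, 4 mm: kept
  ## 2.5 s run: dropped
  lab2 <- rep("pause", n)
  lab2[1:25] <- "forward"
  expect_equal(nrow(segment_runs(tr, state_labels(lab2))), 0)
  ## 5 s run with 0.8 mm displacement: dropped
  slow <- worm_track(cbind(0.016 * (0:(n - 1)), 0), fr)
  lab3 <- rep("pause", n)
  lab3[1:50] <- "forward"
  expect_equal(nrow(segment_runs(slow, state_labels(lab3))), 0)
})

test_that("curving bias is zero on straight runs and negative when curving toward the optimum", {
  a <- gradient_arena()
  fr <- 10
  t <- (0:599) / fr
  ## a straight diagonal run whose bearing (~69 deg) lies inside the
  ## 40-150 degree summary range
  th0 <- -1.2
  straight <- worm_track(cbind(5 + 0.2 * cos(th0) * t,
                               13 + 0.2 * sin(th0) * t), fr)
  lab <- state_labels(rep("forward", 600))
  b <- bearing(straight, a)
  cb <- curving_bias(segment_runs(straight, lab), b)
  expect_lt(abs(cb$summary_bias), 1e-6)
  ## an arc that rotates the heading from away-ish toward the optimum
  th0 <- 2.4
  th <- th0 - 0.04 * t                      # heading rotating toward 0
  xy <- 0.02 * cbind(cumsum(cos(th)), cumsum(sin(th))) + 5
  arc <- worm_track(xy, fr)
  barc <- bearing(arc, a)
  cbarc <- curving_bias(segment_runs(arc, lab), barc)
  expect_lt(cbarc$summary_bias, -0.05)
  expect_error(curving_bias(segment_runs(arc, lab)[0, ], barc), "runs")
})

test_that("binned_vs_bearing returns flat bins and zero contrast for a constant series", {
  a <- gradient_arena()
  fr <- 10
  t <- (0:599) / fr
  th <- 0.7 + 1.5 * sin(0.05 * t)   # bearing sweeps both sides of 90 deg
  xy <- 0.02 * cbind(cumsum(cos(th)), cumsum(sin(th))) + 8
  tr <- worm_track(xy, fr)
  b <- bearing(tr, a, restrict_below_optimum = FALSE)
  res <- binned_vs_bearing(rep(0.2, 600), b)
  occupied <- !is.na(res$bins$mean)
  expect_true(all(abs(res$bins$mean[occupied] - 0.2) < 1e-12))
  expect_equal(res$contrast, 0)
})

test_that("injected shallow-turn bumps are recovered at their amplitude", {
  p <- kinematic_params(turn_event_rate = 0, reversal_rate = 0,
                        pause_rate = 0, omega_rate = 0,
                        angle_noise_sd = 0.02, seed = 31)
  rec <- generate_posture_series(p, duration = 120)
  fr <- 10
  n <- n_frames(rec$posture)
  t <- (seq_len(n) - 1) / fr
  basis <- fit_eigenworms(rec$posture, min_frames = 500)
  ## inject bumps whose turning-mode #11 peak is exactly 0.5 rad
  shape <- wormgait:::turn_shape(11, 12, p$phase_per_segment)
  U <- basis$vectors[, 1:2]
  resid_shape <- shape - U %*% crossprod(U, shape)
  scale11 <- abs(resid_shape[11])
  ang <- rec$posture$angles
  onsets <- seq(10, 110, by = 10)
  for (o in onsets)
    ang <- ang + (0.5 / scale11 *
                    wormgait:::raised_cosine_env(t, o, 1)) %o% shape
  dec <- decompose(posture_series(ang, fr), basis)
  lab <- state_labels(rep("forward", n))
  fakeb <- list(bearing_deg = rep(45, n), db_dx = rep(NA_real_, n))
  ev <- detect_shallow_turn_events(dec, lab, fakeb,
                                   min_prominence = 0.25)
  expect_gte(nrow(ev$events), length(onsets))
  big <- ev$events$amplitude[ev$events$amplitude > 0.3]
  expect_equal(length(big), length(onsets))
  expect_equal(mean(big), 0.5, tolerance = 0.05)
  ## turning mode identically zero: no events
  flat <- decompose(posture_series(
    matrix(basis$means, 50, 24, byrow = TRUE), fr), basis)
  ev0 <- detect_shallow_turn_events(flat, state_labels(rep("forward", 50)),
                                    list(bearing_deg = rep(45, 50)))
  expect_equal(nrow(ev0$events), 0)
  expect_true(is.na(ev0$slope))
})

test_that("population profiles normalize, subtract controls, and index correctly", {
  a <- gradient_arena()
  x <- runif(120, 0, a$length)
  ctrl <- population_profile(x, a)
  expect_equal(sum(ctrl$bin_fractions), 1, tolerance = 1e-9)
  ## identical gradient and control counts: all indices zero
  same <- population_profile(x, a, control = ctrl)
  expect_true(all(abs(same$index) < 1e-12))
  expect_equal(same$cumulative_low_o2_index, 0)
  ## all animals in one bin
  one <- population_profile(rep(5, 30), a)
  expect_equal(max(one$bin_fractions), 1)
  expect_equal(sum(one$bin_fractions > 0), 1)
  ## 13 bins spanning 4-21 % O2 are 1.3 % wide
  expect_equal(diff(ctrl$bin_centers_o2)[1], 17 / 13, tolerance = 1e-9)
  ## mismatched geometry rejected
  ctrl9 <- population_profile(x, a, n_bins = 9)
  expect_error(population_profile(x, a, control = ctrl9), "geometry")
  expect_error(population_profile(numeric(0), a), "no animals")
})

test_that("a gain-0 population is uniform away from the edges and weathervaning steers toward the optimum", {
  a <- gradient_arena()
  ## final positions of independent worms are iid draws from the
  ## stationary distribution (mixing time ~ one arena crossing, 165 s)
  null_pop <- generate_gradient_population(a, 60, navigation_gains(),
                                           duration = 600, seed = 7000)
  xf <- vapply(null_pop, function(w)
    w$track$xy[nrow(w$track$xy), 1], numeric(1))
  inner <- xf[xf > 2 & xf < a$length - 2]
  counts <- table(cut(inner, seq(2, a$length - 2, length.out = 7)))
  pval <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(pval, 0.01)
  ## per-bin time-averaged occupancy within 3 SE of uniform
  edges <- seq(2, a$length - 2, length.out = 11)
  F <- t(vapply(null_pop, function(w) {
    x <- w$track$xy[, 1]
    x <- x[x > 2 & x < a$length - 2]
    as.numeric(table(cut(x, edges))) / length(x)
  }, numeric(10)))
  tt <- (colMeans(F) - 0.1) / (apply(F, 2, stats::sd) / sqrt(nrow(F)))
  expect_lt(max(abs(tt)), 3)
  ## weathervaning alone pulls the final positions toward the optimum O2
  wv_pop <- generate_gradient_population(
    a, 20, navigation_gains(weathervane = 0.15), duration = 240,
    seed = 60)
  ctrl_pop <- generate_gradient_population(
    a, 20, navigation_gains(), duration = 240, seed = 60)
  xopt <- wormgait:::position_of_o2(a, a$optimum)
  dist_null <- stats::median(vapply(ctrl_pop, function(w)
    abs(w$track$xy[nrow(w$track$xy), 1] - xopt), numeric(1)))
  dist_wv <- stats::median(vapply(wv_pop, function(w)
    abs(w$track$xy[nrow(w$track$xy), 1] - xopt), numeric(1)))
  expect_lt(dist_wv, dist_null)
  expect_error(generate_gradient_population(a, 0), "n_worms")
})
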
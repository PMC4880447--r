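# Track metrics (speed, curvature, displacement) and behavioral-state
# detection.

make_track <- function(xy, fr = 10) worm_track(xy, fr)

test_that("centroid speed: stationary, uniform, and artifact masking", {
  n <- 200
  still <- make_track(matrix(0, n, 2))
  expect_lt(max(centroid_speed(still), na.rm = TRUE), 1e-12)
  t <- (0:(n - 1)) / 10
  uni <- make_track(cbind(0.2 * t, 0))
  sp <- centroid_speed(uni)
  expect_equal(stats::median(sp, na.rm = TRUE), 0.2, tolerance = 1e-9)
  fast <- make_track(cbind(0.9 * t, 0))
  expect_true(all(is.na(centroid_speed(fast))))
  expect_error(centroid_speed(make_track(matrix(0, 5, 2))), "window")
})

test_that("track curvature matches the analytic circle value and masks slow frames", {
  ## circle of radius 2 mm at 0.2 mm/s: curvature 1/r = 0.5 rad/mm
  fr <- 10
  t <- seq(0, 120, by = 1 / fr)
  w <- 0.2 / 2
  circ <- make_track(cbind(2 * cos(w * t), 2 * sin(w * t)), fr)
  curv <- track_curvature(circ)
  expect_equal(stats::median(curv, na.rm = TRUE), 0.5,
               tolerance = 0.02 * 0.5)
  ## straight path: zero curvature
  straight <- make_track(cbind(0.2 * t, 0), fr)
  expect_lt(stats::median(track_curvature(straight), na.rm = TRUE), 1e-6)
  ## crawling slower than 0.03 mm/s is masked
  slow <- make_track(cbind(0.02 * t, 0), fr)
  expect_true(all(is.na(track_curvature(slow))))
})

test_that("displacement bins use start-to-end distance only", {
  fr <- 10
  t <- seq(0, 90 - 1 / fr, by = 1 / fr)
  straight <- make_track(cbind(0.1 * t, 0), fr)
  d <- displacement_binned(straight, bin = 30)
  expect_equal(nrow(d), 3)
  expect_equal(d$displacement_mm[1], 3, tolerance = 1e-6)
  expect_equal(displacement_binned(make_track(matrix(0, 900, 2)), 30)
               $displacement_mm, rep(0, 3))
  ## a closed loop inside one bin scores 0 despite its path length
  th <- seq(0, 2 * pi, length.out = 300)
  loop <- make_track(cbind(cos(th) - 1, sin(th)), fr)
  expect_lt(displacement_binned(loop, bin = 29.9)$displacement_mm[1], 1e-6)
  expect_error(displacement_binned(straight, bin = 1000), "longer")
})

test_that("pause detection applies threshold, minimum duration and gap rules", {
  fr <- 10
  mk <- function(speeds) detect_pauses(speeds, fr)
  ## constant 0.1 mm/s: no pause
  expect_equal(nrow(mk(rep(0.1, 300))$events), 0)
  ## 3 s at 0: one pause of 3 s
  sp <- c(rep(0.1, 100), rep(0, 30), rep(0.1, 100))
  ev <- mk(sp)$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 3, tolerance = 0.11)
  ## two 1.5 s stops separated by 0.8 s merge into one pause
  sp2 <- c(rep(0.1, 100), rep(0, 15), rep(0.1, 8), rep(0, 15),
           rep(0.1, 100))
  expect_equal(nrow(mk(sp2)$events), 1)
  ## a single 1.5 s stop is below the minimum duration
  sp3 <- c(rep(0.1, 100), rep(0, 15), rep(0.1, 100))
  expect_equal(nrow(mk(sp3)$events), 0)
  ## separated by 1.5 s: stays two distinct sub-minimum stops, no pause
  sp4 <- c(rep(0.1, 100), rep(0, 15), rep(0.1, 15), rep(0, 15),
           rep(0.1, 100))
  expect_equal(nrow(mk(sp4)$events), 0)
})

test_that("an injected wave-direction flip is detected as one reversal of the right length", {
  p <- kinematic_params(turn_event_rate = 0, reversal_rate = 0,
                        pause_rate = 0, omega_rate = 0, seed = 8)
  rec <- generate_posture_series(p, duration = 60)
  basis <- fit_eigenworms(rec$posture, min_frames = 500)
  ## splice a 2 s time-reversed segment into the angle series
  ang <- rec$posture$angles
  i0 <- 301
  i1 <- i0 + 19
  ang[i0:i1, ] <- ang[seq(i1, i0), ]
  tr <- worm_track(rec$track$xy, 10, posture = posture_series(ang, 10))
  det <- detect_reversals(tr, basis)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$duration_s, 2, tolerance = 0.2)
  expect_equal(det$method, "phase_velocity")
  ## forward-only recording: no reversals
  det0 <- detect_reversals(rec$track, basis)
  expect_equal(nrow(det0$events), 0)
})

test_that("an injected deep coil is detected as one omega event", {
  p <- kinematic_params(turn_event_rate = 0, reversal_rate = 0,
                        pause_rate = 0, omega_rate = 0, seed = 12)
  rec <- generate_posture_series(p, duration = 60)
  ang <- rec$posture$angles
  fr <- 10
  t <- (seq_len(nrow(ang)) - 1) / fr
  env <- wormgait:::plateau_env(t, 30, 1.5)
  prof <- wormgait:::raised_cosine_env(1:24, 2, 22)
  prof <- prof / sum(prof)
  ang <- ang * (1 - env) + (5.5 * env) %o% prof
  tr <- worm_track(rec$track$xy, fr, posture = posture_series(ang, fr))
  det <- detect_omega_turns(tr)
  expect_equal(nrow(det$events), 1)
  expect_gt(det$events$onset_s, 29)
  expect_lt(det$events$onset_s, 32)
  ## straight worm throughout: no events
  det0 <- detect_omega_turns(rec$track)
  expect_equal(nrow(det0$events), 0)
})

test_that("state labels partition frames and rates equal counts per bin", {
  rec <- event_ensemble()[[1]]
  cs <- classify_states(rec$track, event_basis())
  expect_equal(length(cs$state), nrow(rec$track$xy))
  expect_false(anyNA(cs$state))
  rates <- cs$reversals$rates
  expect_equal(sum(rates$rate_per_min) / 6, nrow(cs$reversals$events),
               tolerance = 1e-9)
})

test_that("track curvature grades with turning amplitude across bins", {
  ## the binned curvature-versus-turning-amplitude curve rises
  ## monotonically, the graded relation the relation plots show; a
  ## frame-level rank correlation is diluted by the turning-mode noise
  ## floor and is not the figure's statistic
  ens <- generate_ensemble(
    8, kinematic_params(seed = 210),
    stimulus = protocol_ramp(start = 30, ramp_duration = 180,
                             duration = 240),
    duration = 240)
  basis <- fit_eigenworms(lapply(ens, function(r) r$posture))
  decs <- lapply(ens, function(r) decompose(r$posture, basis))
  ta <- lapply(seq_along(ens), function(i) {
    x <- decs[[i]]$turning_amp
    x[ens[[i]]$labels != "forward"] <- NA
    x
  })
  cv <- lapply(seq_along(ens), function(i) {
    x <- track_curvature(ens[[i]]$track)
    x[ens[[i]]$labels != "forward"] <- NA
    x
  })
  rel <- binned_relation(ta, cv, bin_width_x = 0.3, frame_rate = 10,
                         min_count = 20)
  expect_gte(nrow(rel), 6)
  expect_gt(stats::cor(rel$bin_mid, rel$median, method = "spearman"), 0.5)
  expect_gt(rel$median[nrow(rel)], 2 * rel$median[1])
})
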
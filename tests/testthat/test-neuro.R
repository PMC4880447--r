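# Ratiometric calcium-trace processing and activity/behavior coupling.

test_that("dR/R normalization matches its definition and masks invalid frames", {
  n <- 300
  tr <- calcium_trace(rep(100, n), rep(100, n))
  tr <- normalize_ratio(tr)
  expect_true(all(abs(tr$dr_over_r) < 1e-12))
  ## a single +10 % ratio excursion reads +10 % there (up to the mean shift)
  sig <- rep(100, n)
  sig[150] <- 110
  tr2 <- normalize_ratio(calcium_trace(sig, rep(100, n)))
  expect_equal(tr2$dr_over_r[150], 10, tolerance = 0.05)
  expect_equal(mean(tr2$dr_over_r[tr2$valid]), 0, tolerance = 1e-9)
  ## excluded frames leave the remaining mean at zero (mask oracle)
  v <- rep(TRUE, n)
  v[1:50] <- FALSE
  tr3 <- normalize_ratio(calcium_trace(100 + rnorm(n), 100 + rnorm(n),
                                       valid = v))
  expect_equal(mean(tr3$dr_over_r[tr3$valid]), 0, tolerance = 1e-9)
  expect_true(all(is.na(tr3$dr_over_r[1:50])))
  expect_error(normalize_ratio(calcium_trace(rep(1, 5), rep(1, 5),
                                             valid = rep(FALSE, 5))),
               "valid")
})

test_that("dR/R is invariant to rescaling both channels by a common factor", {
  set.seed(2)
  s <- 100 + cumsum(rnorm(400, sd = 0.5))
  r <- 95 + cumsum(rnorm(400, sd = 0.3))
  a <- normalize_ratio(calcium_trace(s, r))
  b <- normalize_ratio(calcium_trace(3.7 * s, 3.7 * r))
  expect_equal(a$dr_over_r, b$dr_over_r, tolerance = 1e-9)
})

test_that("artifact exclusion flags injected drops and spikes, never revalidates", {
  set.seed(5)
  n <- 900
  sig <- 100 + rnorm(n, sd = 0.3)
  ref <- 100 + rnorm(n, sd = 0.3)
  clean <- exclude_artifacts(normalize_ratio(calcium_trace(sig, ref)))
  expect_gt(mean(clean$valid), 0.995)
  ## 50 % reference drop for 5 frames
  ref2 <- ref
  ref2[500:504] <- 50
  tr2 <- exclude_artifacts(normalize_ratio(calcium_trace(sig, ref2)))
  expect_true(all(!tr2$valid[500:504]))
  ## single-frame 10x ratio spike
  sig3 <- sig
  sig3[700] <- 1000
  tr3 <- exclude_artifacts(normalize_ratio(calcium_trace(sig3, ref)))
  expect_false(tr3$valid[700])
  ## exclusion is monotone: no new valid frames
  pre <- normalize_ratio(calcium_trace(sig3, ref2))
  pre$valid[10:20] <- FALSE
  post <- exclude_artifacts(pre)
  expect_true(all(!post$valid[10:20]))
})

test_that("event-triggered averages align events and report pre/post means", {
  fr <- 10
  n <- 1200
  ## constant series: flat average, zero pre/post difference
  flat <- event_triggered_average(rep(2, n), c(30, 60, 90), fr)
  expect_true(all(abs(flat$mean - 2) < 1e-12))
  expect_equal(mean(flat$pre_post$post - flat$pre_post$pre), 0)
  ## unit impulses at event times on a zero baseline peak at lag 0
  sig <- rep(0, n)
  ev <- c(25, 50, 75)
  sig[round(ev * fr) + 1] <- 1
  eta <- event_triggered_average(sig, ev, fr)
  expect_equal(eta$mean[eta$lag_s == 0], 1)
  expect_lt(max(eta$mean[eta$lag_s != 0]), 1e-12)
  expect_equal(eta$n_events, 3)
  expect_error(event_triggered_average(sig, 1e4, fr), "events")
})

test_that("activity-triggered behavior shows the generator's coupling structure", {
  ## activity events are followed by turning bumps and undulation dips:
  ## triggered turning rises post-event, undulation falls
  p <- kinematic_params(seed = 17)
  rec <- generate_posture_series(
    p, stimulus = protocol_shift(21, 10, at = 60, duration = 120),
    duration = 120)
  basis <- fit_eigenworms(rec$posture, min_frames = 500)
  dec <- decompose(rec$posture, basis)
  ev <- 60   # the downshift drives the state change
  eta_t <- event_triggered_average(dec$turning_amp, ev, 10,
                                   window = c(30, 30))
  eta_u <- event_triggered_average(dec$undulation_amp, ev, 10,
                                   window = c(30, 30))
  expect_gt(mean(eta_t$pre_post$post - eta_t$pre_post$pre), 0)
  expect_lt(mean(eta_u$pre_post$post - eta_u$pre_post$pre), 0)
})

test_that("moving/pausing means respect the 60 s cohort rule", {
  fr <- 30
  n <- 120 * fr
  lab <- rep("forward", n)
  lab[1:(70 * fr)] <- "pause"
  act <- rep(0, n)
  act[lab == "pause"] <- 1
  tr <- normalize_ratio(calcium_trace(100 + act, rep(100, n),
                                      frame_rate = fr))
  mp <- moving_pausing_means(tr, state_labels(lab))
  expect_true(mp$included)
  expect_gt(mp$pausing, mp$moving)
  ## only 50 s of pausing: excluded
  lab2 <- rep("forward", n)
  lab2[1:(50 * fr)] <- "pause"
  expect_false(moving_pausing_means(tr, state_labels(lab2))$included)
})

test_that("lag estimation recovers zero, flags boundaries and flat signals", {
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(3000), rep(1, 10) / 10, sides = 2))
  x[is.na(x)] <- 0
  same <- lag_estimate(x, x, max_lag = 2, frame_rate = 30)
  expect_equal(same$lag_s, 0)
  ## slowly varying signal with a lag just beyond max_lag: the peak sits
  ## on the boundary of the searched range and is flagged
  xs <- as.numeric(stats::filter(rnorm(3000), rep(1, 30) / 30, sides = 2))
  xs[is.na(xs)] <- 0
  y <- c(rep(0, 75), xs[1:(3000 - 75)])   # 2.5 s delay
  far <- lag_estimate(y, xs, max_lag = 2, frame_rate = 30)
  expect_true(far$boundary)
  expect_error(lag_estimate(rep(1, 100), rnorm(100), 1, 30), "flat")
})

test_that("binned activity-vs-behavior is exact on a linear relation and small on noise", {
  fr <- 30
  set.seed(6)
  speed <- abs(as.numeric(stats::filter(rnorm(6000, 0.2, 0.05),
                                        rep(1, 30) / 30, sides = 2)))
  speed[is.na(speed)] <- 0.2
  act <- 2 * speed
  res <- binned_activity_vs_behavior(act, speed, bin_width = 0.01,
                                     frame_rate = fr)
  expect_equal(res$r, 1, tolerance = 1e-9)
  occ <- res$bins[!is.na(res$bins$median) & res$bins$n > 3, ]
  expect_true(all(abs(occ$median - 2 * occ$bin_mid) < 0.01))
  ## independent noise: |r| below 0.1 at n = 10^4
  r0 <- binned_activity_vs_behavior(rnorm(1e4), rnorm(1e4),
                                    bin_width = 0.5, frame_rate = fr)$r
  expect_lt(abs(r0), 0.1)
})
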
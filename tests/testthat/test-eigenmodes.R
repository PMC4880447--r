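# Eigenworm basis fitting, mode decomposition, amplitudes, phase
# velocity, cross-correlation and the variance resampling test.

test_that("basis fitting returns an orthonormal, variance-ordered basis", {
  basis <- wt_basis()
  gram <- crossprod(basis$vectors)
  expect_lt(max(abs(gram - diag(24))), 1e-8)
  expect_true(all(diff(basis$variance_fractions) <= 1e-12))
  expect_equal(sum(basis$variance_fractions), 1, tolerance = 1e-8)
  ## independent cross-check of the leading subspace against prcomp
  X <- do.call(rbind, lapply(wt_ensemble(), function(r)
    r$posture$angles[r$posture$valid, ]))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:4)
    expect_equal(abs(sum(pc$rotation[, j] * basis$vectors[, j])), 1,
                 tolerance = 1e-6)
})

test_that("rank-2 input concentrates all variance in the first two eigenworms", {
  set.seed(1)
  u <- qr.Q(qr(matrix(rnorm(48), 24, 2)))
  scores <- matrix(rnorm(2 * 1500), 1500, 2)
  series <- posture_series(scores %*% t(u), frame_rate = 10)
  basis <- fit_eigenworms(series)
  expect_equal(cumsum(basis$variance_fractions)[2], 1, tolerance = 1e-10)
})

test_that("basis fitting requires sufficient sampling and matching dims", {
  short <- posture_series(matrix(rnorm(24 * 50), 50, 24), 10)
  expect_error(fit_eigenworms(short), "insufficient sampling")
  expect_error(decompose(posture_series(matrix(0, 10, 24), 10), wt_basis()),
               NA)  # dims match: no error
})

test_that("decomposition is exactly additive and handles degenerate input", {
  basis <- wt_basis()
  rec <- wt_ensemble()[[3]]
  dec <- decompose(rec$posture, basis)
  resid <- dec$undulation$angles + dec$turning$angles - rec$posture$angles
  expect_lt(max(abs(resid), na.rm = TRUE), 1e-10)
  expect_true(all(dec$body_amp <= dec$undulation_amp + dec$turning_amp +
                    1e-9, na.rm = TRUE))
  ## posture equal to the per-angle means: turning 0, undulation = means
  n <- 20
  flat <- posture_series(matrix(basis$means, n, 24, byrow = TRUE), 10)
  dflat <- decompose(flat, basis)
  expect_lt(max(abs(dflat$turning$angles)), 1e-10)
  expect_lt(max(abs(sweep(dflat$undulation$angles, 2, basis$means))), 1e-10)
  ## posture inside span(EW1, EW2): turning amplitude 0 everywhere
  sc <- matrix(rnorm(2 * n), n, 2)
  inplane <- posture_series(
    sweep(sc %*% t(basis$vectors[, 1:2]), 2, basis$means, `+`), 10)
  expect_lt(max(decompose(inplane, basis)$turning_amp), 1e-10)
})

test_that("basis is invariant to series order and eigenvector sign flips downstream", {
  series <- lapply(wt_ensemble()[1:6], function(r) r$posture)
  b1 <- fit_eigenworms(series)
  b2 <- fit_eigenworms(rev(series))
  expect_equal(b1$variance_fractions, b2$variance_fractions,
               tolerance = 1e-9)
  expect_equal(abs(b1$vectors), abs(b2$vectors), tolerance = 1e-7)
  ## flipping an eigenvector's sign leaves the decomposition unchanged
  b3 <- b1
  b3$vectors[, 1] <- -b3$vectors[, 1]
  d1 <- decompose(series[[1]], b1)
  d3 <- decompose(series[[1]], b3)
  expect_equal(d1$undulation$angles, d3$undulation$angles,
               tolerance = 1e-10)
  expect_equal(d1$turning_amp, d3$turning_amp, tolerance = 1e-10)
})

test_that("amplitude sums absolute angles; traveling-wave time-mean matches the analytic value", {
  expect_equal(amplitude(rep(0, 24)), 0)
  expect_equal(amplitude(rep(0.1, 24)), 2.4)
  expect_true(is.na(amplitude(c(NA, rep(0.1, 23)))))
  ## independent oracle: time-mean of sum_k |A sin(psi - k phi)| equals
  ## 24 A <|sin|> = 24 A (2/pi) for incommensurate phase sampling
  A <- 0.2
  phi <- 2 * pi * 1.5 / 24
  t <- seq(0, 200, by = 0.0997)
  amp_t <- vapply(t, function(tt)
    amplitude(A * sin(2 * pi * 0.45 * tt - (1:24) * phi)), numeric(1))
  oracle <- 24 * A * (2 / pi)
  expect_equal(mean(amp_t), oracle, tolerance = 0.02 * oracle)
})

test_that("phase velocity is exact on pure rotation and antisymmetric under time reversal", {
  f <- 0.3
  fr <- 10
  t <- (0:599) / fr
  proj <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  pv <- phase_velocity(proj, fr, smooth_s = 0)
  interior <- 5:595
  expect_equal(unname(pv[interior]), rep(f, length(interior)),
               tolerance = 1e-9)
  pv_rev <- phase_velocity(proj[600:1, ], fr, smooth_s = 0)
  expect_equal(unname(pv_rev[interior]), rep(-f, length(interior)),
               tolerance = 1e-9)
  ## zero-magnitude frames are masked
  proj0 <- proj
  proj0[100, ] <- 0
  expect_true(is.na(phase_velocity(proj0, fr, smooth_s = 0,
                                   mask_frac = 0.01)[100]))
})

test_that("phase-velocity magnitude matches a spectrogram peak on noiseless waves", {
  p <- kinematic_params(turn_event_rate = 0, reversal_rate = 0,
                        pause_rate = 0, omega_rate = 0,
                        angle_noise_sd = 0, seed = 2)
  rec <- generate_posture_series(p, duration = 60)
  basis <- fit_eigenworms(rec$posture, min_frames = 500)
  dec <- decompose(rec$posture, basis)
  est <- median(abs(dec$phase_velocity), na.rm = TRUE)
  ## independent estimate: periodogram peak of a mid-body angle
  sig <- rec$posture$angles[, 12]
  spec <- stats::spec.pgram(stats::ts(sig, frequency = 10), plot = FALSE,
                            taper = 0)
  f_peak <- spec$freq[which.max(spec$spec)]
  expect_equal(est, f_peak, tolerance = 0.05 * f_peak)
})

test_that("cross-correlation reports the correct peak and lag conventions", {
  set.seed(4)
  fr <- 10
  x <- as.numeric(stats::filter(rnorm(2000), rep(1, 5) / 5, sides = 2))
  x[is.na(x)] <- 0
  cc <- mode_crosscorrelation(x, x, max_lag = 2, frame_rate = fr)
  expect_equal(cc$peak_lag, 0)
  expect_equal(cc$peak_r, 1, tolerance = 1e-9)
  ## y lagging x by +0.6 s peaks at +0.6 s
  y <- c(rep(0, 6), x[1:(length(x) - 6)])
  cc2 <- mode_crosscorrelation(x, y, max_lag = 2, frame_rate = fr)
  expect_equal(cc2$peak_lag, 0.6)
  ## agreement with stats::ccf as an independent implementation
  cc3 <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc3$lag[which.max(cc3$acf)] / fr, cc2$peak_lag)
  ## independent noise: small peak over 10^4 frames
  a <- rnorm(1e4)
  b <- rnorm(1e4)
  cc4 <- mode_crosscorrelation(a, b, max_lag = 1, frame_rate = fr)
  expect_lt(abs(cc4$peak_r), 0.1)
  ## constant signal flagged
  expect_error(mode_crosscorrelation(rep(1, 500), rnorm(500), 1, fr),
               "constant")
})

test_that("variance resampling test: null statistic, bound formula, error paths", {
  series <- lapply(wt_ensemble()[1:8], function(r) r$posture)
  ga <- series[1:4]
  ## identical groups: statistic exactly 0
  res0 <- variance_resampling_test(ga, ga, n_iter = 100, seed = 1)
  expect_equal(res0$statistic, 0)
  expect_error(variance_resampling_test(ga[1], ga, n_iter = 100),
               "at least 2")
  expect_error(variance_resampling_test(ga, ga, n_iter = 50), "n_iter")
  ## the reported p is an upper bound: never 0, 1/n_iter at 0 exceedances
  expect_equal(p_upper_bound(0, 1000), 1e-3)
  expect_equal(p_upper_bound(0, 1e6), 1e-6)
  expect_equal(p_upper_bound(42, 1000), 0.042)
})

test_that("resampling p-values are uniform under label exchangeability", {
  ## 200 simulated nulls at n_iter = 200: p should be uniform on
  ## {1/200, ..., 1}; check mean and a chi-square on quintiles
  set.seed(11)
  make_series <- function()
    posture_series(matrix(rnorm(24 * 50), 50, 24) %*% diag(24) *
                     rep(exp(-(1:24) / 6), each = 50), 10)
  n_iter <- 200
  pvals <- vapply(1:200, function(i) {
    gs <- replicate(8, make_series(), simplify = FALSE)
    variance_resampling_test(gs[1:4], gs[5:8], n_iter = n_iter,
                             seed = 1000 + i)$p_upper_bound
  }, numeric(1))
  expect_gt(mean(pvals), 0.45)
  expect_lt(mean(pvals), 0.56)
  counts <- table(cut(pvals, seq(0, 1, by = 0.2)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
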
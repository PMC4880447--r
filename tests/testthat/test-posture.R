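# Rendering, cleaning, skeletonization, head assignment and angle
# extraction.

test_that("rendering validates inputs and produces sane silhouettes", {
  expect_error(render_worm(rep(0, 23)), "24")
  expect_error(render_worm(c(NA, rep(0, 23))), "finite")
  expect_error(render_worm(rep(0, 24), scale = 0), "scale")
  img <- render_worm(rep(0, 24))
  expect_s3_class(img, "worm_image")
  expect_gt(sum(img$pixels), 1000)
  ## straight worm: bilaterally symmetric silhouette
  m <- img$pixels
  rowmass <- rowSums(m)
  mid <- sum(rowmass * seq_along(rowmass)) / sum(rowmass)
  top <- sum(m[seq_len(floor(mid)), ])
  bot <- sum(m[(ceiling(mid) + 1):nrow(m), ])
  expect_lt(abs(top - bot) / (top + bot), 0.04)
})

test_that("rotating the orientation by pi rotates the silhouette by 180 degrees", {
  a <- random_smooth_frame_seeded(42)
  i1 <- render_worm(a, orientation = 0.3)
  i2 <- render_worm(a, orientation = 0.3 + pi)
  ## the 180 degree rotated image has identical dimensions and mass
  expect_equal(dim(i1$pixels), dim(i2$pixels))
  r1 <- i1$pixels
  r2 <- i2$pixels[nrow(i2$pixels):1, ncol(i2$pixels):1]
  ## overlap up to rasterization error of the boundary pixels
  expect_gt(sum(r1 & r2) / sum(r1 | r2), 0.88)
})

test_that("clean_binarize fills holes and flags multi-component frames", {
  img <- render_worm(rep(0, 24))
  ## solid worm: unchanged up to border pixels
  ci <- clean_binarize(img)
  expect_true(ci$valid)
  expect_gt(sum(ci$pixels & img$pixels) / sum(img$pixels), 0.97)
  ## a punched hole is filled
  holed <- img
  fg <- which(holed$pixels, arr.ind = TRUE)
  c0 <- round(colMeans(fg))
  holed$pixels[c0[1], c0[2]] <- FALSE
  ch <- clean_binarize(holed)
  expect_true(ch$valid)
  expect_true(ch$pixels[c0[1], c0[2]])
  ## two disjoint blobs: invalid
  two <- matrix(0, 60, 60)
  two[10:20, 10:20] <- 1
  two[40:50, 40:50] <- 1
  expect_false(clean_binarize(two, scale = 0.003)$valid)
  expect_error(clean_binarize(matrix(0, 5, 5), scale = 0.003), "empty")
})

test_that("skeletons of straight and known-angle worms recover the midline", {
  sk <- extract_skeleton(clean_binarize(render_worm(rep(0, 24))))
  expect_true(sk$valid)
  expect_equal(nrow(sk$points), 26)
  ## exactly collinear points give exactly zero angles
  collinear <- structure(list(points = cbind(seq(0, 1, length.out = 26), 0),
                              length_mm = 1, valid = TRUE),
                         class = "worm_skeleton")
  expect_equal(angles_from_skeleton(collinear)$angles, rep(0, 24))
  ## the extracted straight worm is near-straight up to pixel noise
  af <- angles_from_skeleton(sk)
  expect_true(af$valid)
  expect_lt(max(abs(af$angles)), 0.05)
  ## known smooth posture: roundtrip within tolerance
  a <- random_smooth_frame_seeded(7)
  sk2 <- extract_skeleton(clean_binarize(render_worm(a, orientation = 1)))
  b <- align_to_reference(angles_from_skeleton(sk2)$angles, a)
  expect_lt(max(abs(b - a)), 0.1)
})

test_that("a 26-point semicircular arc has 24 equal angles of pi/25", {
  ## analytic oracle: equally spaced points on a semicircle produce 25
  ## chords whose direction advances by pi/25 between neighbours
  theta <- seq(0, pi, length.out = 26)
  pts <- cbind(cos(theta), sin(theta))
  sk <- structure(list(points = pts, length_mm = NA, valid = TRUE),
                  class = "worm_skeleton")
  af <- angles_from_skeleton(sk)
  expect_equal(af$angles, rep(pi / 25, 24), tolerance = 1e-10)
})

test_that("angle extraction is invariant to rotation and translation", {
  a <- random_smooth_frame_seeded(3)
  pts <- wormgait:::midline_from_angles(a)
  sk <- structure(list(points = pts, length_mm = 1, valid = TRUE),
                  class = "worm_skeleton")
  base <- angles_from_skeleton(sk)$angles
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  skt <- sk
  skt$points <- sweep(pts %*% R, 2, c(5, -3), `+`)
  expect_equal(angles_from_skeleton(skt)$angles, base, tolerance = 1e-10)
})

test_that("coiled silhouettes are flagged invalid", {
  ## a ring-like deep coil: midline closes on itself
  coil <- 2 * pi * 1.05 * rep(1 / 24, 24) * 24 / 24
  coil <- rep(2 * pi * 1.05 / 24, 24)
  img <- render_worm(coil)
  sk <- extract_skeleton(clean_binarize(img))
  expect_false(sk$valid)
})

test_that("artificially short skeletons are rejected against a reference length", {
  img <- clean_binarize(render_worm(rep(0, 24)))
  sk_ok <- extract_skeleton(img, ref_length_mm = 1)
  expect_true(sk_ok$valid)
  sk_short <- extract_skeleton(img, ref_length_mm = 2)
  expect_false(sk_short$valid)
})

test_that("head assignment follows motion, repairs flips, and reverses with time", {
  ## a forward-moving synthetic worm: head = leading endpoint everywhere
  a <- rep(0, 24)
  n <- 12
  xs <- seq(0, 2, length.out = n)
  skels <- lapply(xs, function(x0) {
    pts <- wormgait:::midline_from_angles(a, centroid = c(x0, 0))
    structure(list(points = pts[26:1, ], length_mm = 1, valid = TRUE),
              class = "worm_skeleton")   # stored tail-first on purpose
  })
  track <- worm_track(cbind(xs, 0), frame_rate = 2)
  oriented <- orient_head(skels, track)
  for (s in oriented)
    expect_gt(s$points[1, 1], s$points[26, 1])  # head leads +x motion
  ## inject a flipped frame: proximity rule repairs it
  flipped <- oriented
  flipped[[6]]$points <- flipped[[6]]$points[26:1, ]
  repaired <- orient_head(flipped, track)
  expect_gt(repaired[[6]]$points[1, 1], repaired[[6]]$points[26, 1])
  ## time-reversed recording: head assignment flips
  rev_oriented <- orient_head(rev(skels), worm_track(cbind(rev(xs), 0), 2))
  expect_lt(rev_oriented[[1]]$points[1, 1], rev_oriented[[1]]$points[26, 1])
  ## all-invalid input warns and returns unchanged
  bad <- lapply(1:3, function(i)
    structure(list(points = matrix(NA, 26, 2), length_mm = NA,
                   valid = FALSE), class = "worm_skeleton"))
  expect_warning(orient_head(bad, worm_track(cbind(1:3, 0), 2)), "valid")
})

test_that("full extraction pipeline recovers a rendered sequence", {
  p <- kinematic_params(turn_event_rate = 2, reversal_rate = 0,
                        pause_rate = 0, omega_rate = 0,
                        angle_noise_sd = 0.02, seed = 5)
  rec <- generate_posture_series(p, duration = 12)
  idx <- seq(1, 120, by = 10)
  fr_sub <- 1
  imgs <- lapply(idx, function(i)
    render_worm(rec$posture$angles[i, ], orientation = 0.5,
                centroid = c(0, 0)))
  track <- worm_track(cbind(seq_along(idx) * 0.1, 0), fr_sub)
  ps <- extract_posture_series(imgs, track, fr_sub)
  expect_s3_class(ps, "posture_series")
  expect_equal(ncol(ps$angles), 24)
  expect_gt(mean(ps$valid), 0.9)
  ## angles match the generated ones up to the global sign convention
  ok <- which(ps$valid)
  errs <- vapply(ok, function(j) {
    b <- align_to_reference(ps$angles[j, ], rec$posture$angles[idx[j], ])
    max(abs(b - rec$posture$angles[idx[j], ]))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
})
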
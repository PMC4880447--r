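# Centroid-track metrics (speed, track curvature, displacement) and
# behavioral-state detection: reversals, omega turns, pauses, with binned
# event rates.

#' Centroid speed by symmetric differencing
#'
#' Speed of frame i is the distance between the smoothed centroid
#' positions of frames `i - half_window` and `i + half_window` divided by
#' the elapsed time. The default half-window spans 0.5 s on either side
#' (+-5 frames at 10 frames/s, +-15 at 30 frames/s). Artificially high
#' values (> `max_speed`, default 0.6 mm/s, lost tracking) are masked.
#'
#' @param track a [worm_track()]
#' @param half_window half-width of the differencing window (frames);
#'   default `round(frame_rate / 2)`
#' @param smooth_s centroid smoothing window before differencing (s)
#' @param max_speed artifact threshold (mm/s); values above are set `NA`
#' @return speed series (mm/s), `NA` at the edges and masked frames
#' @export
centroid_speed <- function(track, half_window = NULL, smooth_s = 0.5,
                           max_speed = 0.6) {
  fr <- track$frame_rate
  if (is.null(half_window)) half_window <- as.integer(round(fr / 2))
  n <- nrow(track$xy)
  if (2 * half_window >= n)
    stop("differencing window does not fit inside the recording",
         call. = FALSE)
  w <- max(1L, as.integer(round(smooth_s * fr)))
  sx <- moving_average(track$xy[, 1], w)
  sy <- moving_average(track$xy[, 2], w)
  sp <- rep(NA_real_, n)
  i <- (half_window + 1L):(n - half_window)
  dx <- sx[i + half_window] - sx[i - half_window]
  dy <- sy[i + half_window] - sy[i - half_window]
  sp[i] <- sqrt(dx^2 + dy^2) / (2 * half_window / fr)
  sp[!is.na(sp) & sp > max_speed] <- NA_real_
  sp
}

# Smoothed heading (rad) from displacement between frames i-h and i+h.
track_heading <- function(track, half_window = NULL, smooth_s = 0.5) {
  fr <- track$frame_rate
  if (is.null(half_window)) half_window <- as.integer(round(fr / 2))
  n <- nrow(track$xy)
  w <- max(1L, as.integer(round(smooth_s * fr)))
  sx <- moving_average(track$xy[, 1], w)
  sy <- moving_average(track$xy[, 2], w)
  hd <- rep(NA_real_, n)
  i <- (half_window + 1L):(n - half_window)
  hd[i] <- atan2(sy[i + half_window] - sy[i - half_window],
                 sx[i + half_window] - sx[i - half_window])
  hd
}

#' Track curvature: heading change per distance travelled
#'
#' Heading is taken from the four-quadrant angle of the displacement
#' between frames i-h and i+h (a 1 s interval at the default half-window);
#' the absolute per-frame heading change is divided by the mean distance
#' crossed per frame during the same interval. Frames moving slower than
#' `min_speed` (0.03 mm/s: centroid wobble dominates) are masked, and
#' values above `max_curv` (31 rad/mm, the 99.5th percentile of real
#' tracks) are removed.
#'
#' @param track a [worm_track()]
#' @param half_window heading half-window (frames); default
#'   `round(frame_rate / 2)`
#' @param speed optional precomputed [centroid_speed()] series
#' @param min_speed low-speed mask (mm/s)
#' @param max_curv artifact ceiling (rad/mm)
#' @return curvature series (rad/mm)
#' @export
track_curvature <- function(track, half_window = NULL, speed = NULL,
                            min_speed = 0.03, max_curv = 31) {
  fr <- track$frame_rate
  if (is.null(half_window)) half_window <- as.integer(round(fr / 2))
  if (is.null(speed)) speed <- centroid_speed(track, half_window)
  hd <- track_heading(track, half_window)
  dhead <- c(NA_real_, abs(wrap_angle(diff(hd))))
  dist_per_frame <- speed / fr
  curv <- dhead / dist_per_frame
  curv[!is.na(speed) & speed < min_speed] <- NA_real_
  curv[is.na(speed)] <- NA_real_
  curv[!is.na(curv) & curv > max_curv] <- NA_real_
  curv
}

#' Straight-line displacement per time bin
#'
#' Distance between the centroid positions at the start and end of each
#' bin (reverse movement is not excluded; a closed loop scores 0).
#'
#' @param track a [worm_track()]
#' @param bin bin length (s), default 30
#' @return data.frame with `bin_start_s` and `displacement_mm`
#' @export
displacement_binned <- function(track, bin = 30) {
  fr <- track$frame_rate
  n <- nrow(track$xy)
  if (bin > n / fr) stop("bin longer than the track", call. = FALSE)
  per <- as.integer(round(bin * fr))
  starts <- seq(1L, n - per + 1L, by = per)
  data.frame(
    bin_start_s = (starts - 1L) / fr,
    displacement_mm = vapply(starts, function(i)
      sqrt(sum((track$xy[min(i + per, n), ] - track$xy[i, ])^2)),
      numeric(1)))
}

# Merge sub-threshold gaps and apply a minimum duration to a logical
# event series; returns the cleaned logical vector.
clean_bouts <- function(flag, frame_rate, min_dur_s, max_gap_s) {
  r <- rle(flag)
  ## close gaps shorter than max_gap between two flagged bouts
  if (length(r$lengths) >= 3) {
    for (j in 2:(length(r$lengths) - 1)) {
      if (!r$values[j] && r$values[j - 1] && r$values[j + 1] &&
          r$lengths[j] <= max_gap_s * frame_rate)
        r$values[j] <- TRUE
    }
    flag <- inverse.rle(r)
    r <- rle(flag)
  }
  ## drop bouts shorter than min_dur
  r$values <- r$values & r$lengths >= min_dur_s * frame_rate
  inverse.rle(r)
}

# Event table (onset/duration in s) from a logical series.
bouts_to_events <- function(flag, frame_rate) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(onset_s = (starts[keep] - 1L) / frame_rate,
             duration_s = r$lengths[keep] / frame_rate)
}

# Events per minute in consecutive bins of `bin_s` seconds, counting an
# event in the bin containing its onset.
rate_per_bin <- function(events, duration_s, bin_s = 10) {
  edges <- seq(0, duration_s, by = bin_s)
  if (length(edges) < 2) edges <- c(0, duration_s)
  counts <- if (nrow(events))
    table(cut(events$onset_s, edges, right = FALSE))
  else rep(0L, length(edges) - 1L)
  data.frame(bin_start_s = edges[-length(edges)],
             rate_per_min = as.numeric(counts) / diff(edges) * 60)
}

#' Detect reversals (backward crawling)
#'
#' Primary detector (posture available): crawl direction is the direction
#' of wave propagation, so a reversal is a sustained flip of the
#' undulation phase-velocity sign against the recording's dominant sign
#' for at least `min_dur_s`. Fallback detector (centroid only): frames
#' where the centroid heading reverses by more than 120 degrees within
#' half a second while speed stays above the pause floor; this heuristic
#' is marked low-confidence.
#'
#' @param track a [worm_track()] (posture attached for the primary
#'   detector)
#' @param basis an [eigenworm_basis()]; fitted on the track's own posture
#'   when omitted
#' @param min_dur_s minimum sustained duration (s)
#' @param rate_bin_s bin width for the reported rates (s), default 10
#' @return list with `labels` (logical reverse flag per frame), `events`,
#'   `rates` (per `rate_bin_s` bin), `method`, `low_confidence`
#' @export
detect_reversals <- function(track, basis = NULL, min_dur_s = 0.3,
                             rate_bin_s = 10) {
  fr <- track$frame_rate
  n <- nrow(track$xy)
  if (n / fr < 20) stop("track shorter than 20 s", call. = FALSE)
  low_conf <- FALSE
  if (!is.null(track$posture)) {
    if (is.null(basis))
      basis <- fit_eigenworms(track$posture,
                              min_frames = min(1000L, sum(track$posture$valid)))
    dec <- decompose(track$posture, basis)
    pv <- dec$phase_velocity
    ## when the wave is suspended (deep coils) the phase is undefined;
    ## require a healthy projection magnitude
    mag <- sqrt(dec$proj[, 1]^2 + dec$proj[, 2]^2)
    mag <- moving_average(mag, max(1L, as.integer(round(fr / 2))))
    weak <- !is.finite(mag) | mag < 0.3 * stats::median(mag, na.rm = TRUE)
    dom <- sign(stats::median(pv, na.rm = TRUE))
    rev_flag <- !is.na(pv) & sign(pv) == -dom & abs(pv) > 0.05 & !weak
    method <- "phase_velocity"
  } else {
    hd <- track_heading(track)
    h <- max(1L, as.integer(round(fr / 2)))
    flip <- abs(wrap_angle(c(rep(NA, h), diff(hd, lag = h)))) > 2 * pi / 3
    sp <- centroid_speed(track)
    rev_flag <- !is.na(flip) & flip & !is.na(sp) & sp > 0.02
    method <- "heading_flip"
    low_conf <- TRUE
  }
  rev_flag <- clean_bouts(rev_flag, fr, min_dur_s, max_gap_s = 0.2)
  events <- bouts_to_events(rev_flag, fr)
  list(labels = rev_flag, events = events,
       rates = rate_per_bin(events, n / fr, rate_bin_s),
       method = method, low_confidence = low_conf)
}

# Posture-derived body point cloud (unit-length midline) per frame.
body_points <- function(angles_row) {
  dirs <- cumsum(c(0, angles_row))
  cbind(cumsum(c(0, cos(dirs))) / 25, cumsum(c(0, sin(dirs))) / 25)
}

#' Detect omega turns from posture shape
#'
#' An omega turn is a deep body bend: the midline point cloud becomes
#' compact (eccentricity below `e_min`) while the body axis swings fast
#' (angular speed of the head-to-tail vector above `omega_min`), sustained
#' for at least `min_dur_s`.
#'
#' @param track a [worm_track()] with posture
#' @param e_min eccentricity threshold; the 0.7 default was calibrated on
#'   synthetic injected coils against shallow-turn C-shapes
#' @param omega_min body-axis angular speed threshold (rad/s) applied to
#'   the wobble-cancelled (1 s signed-mean) axis swing near the event
#' @param min_dur_s minimum duration (s)
#' @param rate_bin_s rate bin width (s)
#' @return list with `labels`, `events`, `rates`, and the per-frame
#'   `eccentricity` and `axis_speed` series
#' @export
detect_omega_turns <- function(track, e_min = 0.7, omega_min = 1.5,
                               min_dur_s = 0.3, rate_bin_s = 10) {
  if (is.null(track$posture))
    stop("omega detection needs posture", call. = FALSE)
  fr <- track$frame_rate
  ang <- track$posture$angles
  n <- nrow(ang)
  ratio <- rep(NA_real_, n)
  axang <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!track$posture$valid[i]) next
    p <- body_points(ang[i, ])
    ev <- eigen(stats::cov(p), symmetric = TRUE, only.values = TRUE)$values
    ratio[i] <- ev[2] / ev[1]
    v <- p[26, ] - p[1, ]
    axang[i] <- atan2(v[2], v[1])
  }
  ## the eigenvalue ratio of a near-circular coil is noise-degenerate on
  ## a single frame; a 0.5 s average of the ratio is stable and monotone
  ## in coil depth
  ratio <- moving_average(ratio, max(1L, as.integer(round(fr / 2))))
  ecc <- sqrt(pmax(0, 1 - ratio))
  ok <- is.finite(axang)
  axu <- axang
  axu[ok] <- unwrap_phase(axang[ok])
  ## signed derivative smoothed over 1 s cancels the oscillatory wobble
  ## the undulation wave imposes on the body axis but keeps the monotone
  ## swing of a forming omega coil
  axspeed <- abs(moving_average(c(NA, diff(axu)) * fr,
                                max(1L, as.integer(round(fr)))))
  ## low eccentricity times the event; the angular-speed condition is
  ## confirmed within +-0.75 s of the bout (coil formation and release
  ## swing the axis just before/after maximal compactness)
  flag <- clean_bouts(!is.na(ecc) & ecc < e_min, fr, min_dur_s,
                      max_gap_s = 0.5)
  events <- bouts_to_events(flag, fr)
  if (nrow(events)) {
    keep <- vapply(seq_len(nrow(events)), function(j) {
      i0 <- max(1L, as.integer(round((events$onset_s[j] - 0.75) * fr)))
      i1 <- min(n, as.integer(round((events$onset_s[j] +
                                       events$duration_s[j] + 0.75) * fr)))
      any(axspeed[i0:i1] > omega_min, na.rm = TRUE)
    }, logical(1))
    drop <- which(!keep)
    for (j in drop) {
      i0 <- as.integer(round(events$onset_s[j] * fr)) + 1L
      i1 <- min(n, i0 + as.integer(round(events$duration_s[j] * fr)) - 1L)
      flag[i0:i1] <- FALSE
    }
    events <- events[keep, , drop = FALSE]
  }
  list(labels = flag, events = events,
       rates = rate_per_bin(events, n / fr, rate_bin_s),
       eccentricity = ecc, axis_speed = axspeed)
}

#' Detect pauses from the speed series
#'
#' A pause is a phase of at least `min_dur_s` below `threshold` mm/s,
#' tolerating above-threshold gaps of at most `max_gap_s`.
#'
#' @param speed speed series (mm/s) from [centroid_speed()]
#' @param frame_rate frames per second
#' @param threshold speed threshold (mm/s, default 0.05)
#' @param min_dur_s minimum phase duration (s, default 2)
#' @param max_gap_s tolerated gap (s, default 1)
#' @return list with `labels` (logical pause flag) and `events`
#' @export
detect_pauses <- function(speed, frame_rate, threshold = 0.05,
                          min_dur_s = 2, max_gap_s = 1) {
  below <- !is.na(speed) & speed < threshold
  flag <- clean_bouts(below, frame_rate, min_dur_s, max_gap_s)
  list(labels = flag, events = bouts_to_events(flag, frame_rate))
}

#' Combined per-frame behavioral-state labels
#'
#' Runs the reversal, omega and pause detectors and combines them into one
#' exclusive label per frame with precedence omega > reverse > pause >
#' forward; invalid posture frames are labelled `invalid`.
#'
#' @param track a [worm_track()] with posture
#' @param basis optional [eigenworm_basis()] for the reversal detector
#' @param ... thresholds passed on to the detectors
#' @return list with `state` ([state_labels()]), and the three detector
#'   results `reversals`, `omegas`, `pauses`
#' @export
classify_states <- function(track, basis = NULL, ...) {
  fr <- track$frame_rate
  rev <- detect_reversals(track, basis)
  omg <- detect_omega_turns(track)
  sp <- centroid_speed(track)
  pse <- detect_pauses(sp, fr)
  n <- nrow(track$xy)
  ## the undulation phase is meaningless while the body coils, so
  ## reversal calls within +-0.75 s of an omega are coil artifacts
  dil <- as.integer(round(0.75 * fr))
  omega_near <- omg$labels
  if (any(omg$labels)) {
    idx <- which(omg$labels)
    lo <- pmax(1L, idx - dil)
    hi <- pmin(n, idx + dil)
    for (j in seq_along(idx)) omega_near[lo[j]:hi[j]] <- TRUE
  }
  st <- rep("forward", n)
  st[pse$labels] <- "pause"
  st[rev$labels & !omega_near] <- "reverse"
  st[omg$labels] <- "omega"
  if (!is.null(track$posture)) st[!track$posture$valid] <- "invalid"
  st <- state_labels(st)
  events <- list(
    reverse = bouts_to_events(clean_bouts(st == "reverse", fr, 0.3, 0.2),
                              fr),
    omega = omg$events,
    pause = pse$events)
  list(state = st, events = events, reversals = rev, omegas = omg,
       pauses = pse)
}
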
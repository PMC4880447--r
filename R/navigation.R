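# O2-gradient navigation analysis: arena geometry, bearing to the
# preferred isoline, run segmentation, curving bias (weathervaning),
# bearing-binned statistics, shallow-turn event amplitudes, and population
# distribution profiles with chemotaxis indices.

#' Linear O2 gradient arena geometry
#'
#' A rectangular arena with a linear O2 gradient along its length:
#' `o2_low` at x = 0 rising to `o2_high` at x = `length`. Worms prefer the
#' `optimum` isoline (16 % O2 by default).
#'
#' @param length,width arena dimensions (mm); defaults 33 x 15
#' @param inlet_margin margin at the gas inlets (mm)
#' @param o2_low,o2_high O2 at the two ends (%)
#' @param optimum preferred O2 concentration (%)
#' @param edge_margin trajectory exclusion margin at the arena edges (mm);
#'   default 0.55 (20 px at 0.0276 mm/px)
#' @return an object of class `gradient_arena`
#' @export
gradient_arena <- function(length = 33, width = 15, inlet_margin = 3,
                           o2_low = 4, o2_high = 21, optimum = 16,
                           edge_margin = 0.55) {
  check_pos(length, "length")
  check_pos(width, "width")
  if (!(o2_low < optimum && optimum <= o2_high))
    stop("need o2_low < optimum <= o2_high", call. = FALSE)
  structure(list(length = length, width = width,
                 inlet_margin = inlet_margin, o2_low = o2_low,
                 o2_high = o2_high, optimum = optimum,
                 edge_margin = edge_margin), class = "gradient_arena")
}

#' O2 concentration at a position along the gradient
#' @param arena a [gradient_arena()]
#' @param x position along the gradient axis (mm), in `[0, length]`
#' @return O2 (%)
#' @export
o2_at_position <- function(arena, x) {
  if (any(x < 0 | x > arena$length))
    stop("position outside the arena", call. = FALSE)
  arena$o2_low + (arena$o2_high - arena$o2_low) * x / arena$length
}

# x position of an O2 isoline (mm).
position_of_o2 <- function(arena, o2)
  (o2 - arena$o2_low) / (arena$o2_high - arena$o2_low) * arena$length

#' Bearing of a track relative to the preferred O2 isoline
#'
#' The folded angle in \[0, 180\] degrees between the smoothed centroid
#' heading and the direction toward the `optimum` isoline: 0 = straight
#' toward it, 180 = straight away, 90 = parallel to the isolines. Frames
#' within `edge_margin` of the arena edges, frames moving below
#' `min_speed`, and (optionally) frames in the above-optimum region are
#' masked. The signed per-frame bearing change over distance (dB/dX,
#' rad/mm) is returned alongside.
#'
#' @param track a [worm_track()] positioned in arena coordinates
#' @param arena a [gradient_arena()]
#' @param min_speed heading floor (mm/s)
#' @param restrict_below_optimum mask frames at O2 above the optimum
#'   (default TRUE, matching the weathervaning analysis region)
#' @param after_s drop frames before this time (s), default 0
#' @return list with `bearing_deg`, `db_dx` (rad/mm, negative = turning
#'   toward the optimum), `o2` per frame, and the exclusion `mask`
#' @export
bearing <- function(track, arena, min_speed = 0.03,
                    restrict_below_optimum = TRUE, after_s = 0) {
  fr <- track$frame_rate
  hd <- track_heading(track)
  sp <- centroid_speed(track)
  x <- track$xy[, 1]
  y <- track$xy[, 2]
  xopt <- position_of_o2(arena, arena$optimum)
  to_opt <- ifelse(x <= xopt, 0, pi)        # direction toward the isoline
  signed <- wrap_angle(hd - to_opt)
  bdeg <- abs(signed) * 180 / pi
  o2 <- arena$o2_low + (arena$o2_high - arena$o2_low) *
    pmin(pmax(x / arena$length, 0), 1)
  mask <- is.na(hd) | is.na(sp) | sp < min_speed |
    x < arena$edge_margin | x > arena$length - arena$edge_margin |
    y < arena$edge_margin | y > arena$width - arena$edge_margin |
    track$timestamps < after_s | track$margin_mask
  if (restrict_below_optimum) mask <- mask | o2 > arena$optimum
  bdeg[mask] <- NA_real_
  db <- c(NA_real_, diff(abs(signed))) # rad, folded so left/right agree
  dist <- sp / fr
  db_dx <- db / dist
  db_dx[mask | dist < 1e-9] <- NA_real_
  ## the same artifact ceiling as track curvature: near-stationary frames
  ## produce arbitrarily large bearing change per distance
  db_dx[!is.na(db_dx) & abs(db_dx) > 31] <- NA_real_
  list(bearing_deg = bdeg, db_dx = db_dx, o2 = o2, mask = mask)
}

#' Segment continuous forward runs
#'
#' Maximal forward phases of the state labels; runs shorter than
#' `min_dur_s` (3 s) or with total displacement under `min_disp_mm` (1 mm)
#' are dropped.
#'
#' @param track a [worm_track()]
#' @param labels per-frame [state_labels()]
#' @param min_dur_s,min_disp_mm exclusion thresholds
#' @return data.frame with `start_frame`, `end_frame`, `duration_s`,
#'   `displacement_mm`
#' @export
segment_runs <- function(track, labels, min_dur_s = 3, min_disp_mm = 1) {
  fr <- track$frame_rate
  fwd <- labels == "forward"
  r <- rle(as.logical(fwd))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(), displacement_mm = numeric()))
  out <- data.frame(start_frame = starts[keep], end_frame = ends[keep])
  out$duration_s <- (out$end_frame - out$start_frame + 1L) / fr
  out$displacement_mm <- vapply(seq_len(nrow(out)), function(j)
    sqrt(sum((track$xy[out$end_frame[j], ] -
                track$xy[out$start_frame[j], ])^2)), numeric(1))
  out[out$duration_s >= min_dur_s & out$displacement_mm >= min_disp_mm, ,
      drop = FALSE]
}

# Frame indices covered by a run table.
run_frames <- function(runs) {
  if (!nrow(runs)) return(integer())
  unlist(lapply(seq_len(nrow(runs)), function(j)
    runs$start_frame[j]:runs$end_frame[j]))
}

#' Curving bias (weathervaning) from forward runs
#'
#' The instantaneous change of bearing over distance travelled (dB/dX,
#' rad/mm) within forward runs, binned by bearing (`bin_deg` wide bins)
#' and summarized as the mean over the 40-150 degree bearing range.
#' Negative values indicate steering toward the optimum isoline.
#'
#' @param runs run table from [segment_runs()]
#' @param bearings result of [bearing()]
#' @param bin_deg bearing bin width (degrees), default 20
#' @param summary_range bearing range for the scalar summary, default
#'   `c(40, 150)`
#' @return list with per-bin `bins` (data.frame: bin_lo, bin_hi, mean, sem,
#'   n) and the scalar `summary_bias` (rad/mm)
#' @export
curving_bias <- function(runs, bearings, bin_deg = 20,
                         summary_range = c(40, 150)) {
  if (!nrow(runs)) stop("no runs to analyse", call. = FALSE)
  idx <- run_frames(runs)
  b <- bearings$bearing_deg[idx]
  v <- bearings$db_dx[idx]
  ok <- is.finite(b) & is.finite(v)
  b <- b[ok]; v <- v[ok]
  edges <- seq(0, 180, by = bin_deg)
  bin <- cut(b, edges, right = FALSE, include.lowest = TRUE)
  bins <- data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    mean = as.numeric(tapply(v, bin, mean)),
    sem = as.numeric(tapply(v, bin, sem)),
    n = as.numeric(table(bin)))
  insum <- b >= summary_range[1] & b <= summary_range[2]
  list(bins = bins,
       summary_bias = if (any(insum)) mean(v[insum]) else NA_real_)
}

#' Bearing-binned means of an arbitrary per-frame series
#'
#' Bins a per-frame series by bearing (default 20 degree bins) and reports
#' per-bin mean and SEM plus the below-minus-above-90-degree contrast.
#'
#' @param values per-frame numeric series
#' @param bearings result of [bearing()]
#' @param bin_deg bin width (degrees)
#' @param frames optional frame subset (e.g. forward-run frames)
#' @return list with `bins` (data.frame) and scalar `contrast`
#'   (mean below 90 deg minus mean above 90 deg)
#' @export
binned_vs_bearing <- function(values, bearings, bin_deg = 20,
                              frames = NULL) {
  b <- bearings$bearing_deg
  v <- values
  if (!is.null(frames)) {
    keep <- rep(FALSE, length(b)); keep[frames] <- TRUE
    b[!keep] <- NA_real_
  }
  ok <- is.finite(b) & is.finite(v)
  b <- b[ok]; v <- v[ok]
  edges <- seq(0, 180, by = bin_deg)
  bin <- cut(b, edges, right = FALSE, include.lowest = TRUE)
  bins <- data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    mean = as.numeric(tapply(v, bin, mean)),
    sem = as.numeric(tapply(v, bin, sem)),
    n = as.numeric(table(bin)))
  below <- b < 90
  contrast <- if (any(below) && any(!below))
    mean(v[below]) - mean(v[!below]) else NA_real_
  list(bins = bins, contrast = contrast)
}

#' Shallow-turn event amplitudes versus bearing
#'
#' Detects local peaks of the absolute mid-body turning-mode angle
#' (segment angle #11) during forward, non-omega frames, averages peak
#' amplitudes over 5 degree bearing bins, and fits a line across bins
#' (slope, correlation r).
#'
#' @param decomp a [decompose()] result on the same frames
#' @param labels per-frame [state_labels()]
#' @param bearings result of [bearing()]
#' @param bin_deg bin width (degrees), default 5
#' @param min_prominence minimum peak prominence (rad) over the local
#'   baseline
#' @param min_events fits are suppressed below this event count
#' @return list with `events` (frame, bearing_deg, amplitude), `bins`,
#'   `slope` (rad per degree), `r`; slope/r are `NA` when suppressed
#' @export
detect_shallow_turn_events <- function(decomp, labels, bearings,
                                       bin_deg = 5, min_prominence = 0.05,
                                       min_events = 10) {
  sig <- abs(decomp$turning$angles[, 11])
  n <- length(sig)
  eligible <- labels == "forward"
  pk <- which(c(FALSE, diff(sig) > 0) & c(sig[-n] > sig[-1], FALSE) &
                sig > min_prominence & eligible)
  bdeg <- bearings$bearing_deg[pk]
  ok <- is.finite(bdeg)
  events <- data.frame(frame = pk[ok], bearing_deg = bdeg[ok],
                       amplitude = sig[pk][ok])
  edges <- seq(0, 180, by = bin_deg)
  bin <- cut(events$bearing_deg, edges, right = FALSE, include.lowest = TRUE)
  bins <- data.frame(
    bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
    mean = as.numeric(tapply(events$amplitude, bin, mean)),
    n = as.numeric(table(bin)))
  slope <- r <- NA_real_
  if (nrow(events) >= min_events && sum(is.finite(bins$mean)) >= 3) {
    ok2 <- is.finite(bins$mean)
    fit <- stats::lm(mean ~ bin_mid, data = bins[ok2, ])
    slope <- unname(stats::coef(fit)[2])
    r <- stats::cor(bins$bin_mid[ok2], bins$mean[ok2])
  }
  list(events = events, bins = bins, slope = slope, r = r)
}

#' Per-track navigation strategy statistics
#'
#' Computes the four bearing-coupled summary statistics that separate the
#' navigation strategies, for one worm of a gradient population:
#' * `curving_bias` - mean dB/dX over the 40-150 degree bearing range
#'   within forward runs (weathervaning; computed in the sub-optimum
#'   region, where the analysis is defined);
#' * `reversal_contrast` - reversal initiation rate (events/min) below
#'   minus above 90 degrees bearing, events attributed to the bearing 1 s
#'   before onset, forward frames only (biased random walk);
#' * `speed_contrast` - forward-run speed below minus above 90 degrees,
#'   run edges trimmed by 1 s (area-restricted-search slowing);
#' * `turn_slope` - slope of shallow-turn peak amplitude versus bearing
#'   (area-restricted-search turning).
#'
#' Unlike the weathervaning statistic, the event/speed statistics use the
#' full gradient region (`restrict_below_optimum = FALSE`): attributing
#' events across the hard sub-optimum boundary skews their bearing
#' otherwise.
#'
#' @param worm a `gradient_worm` (or a list with `track`) from
#'   [generate_gradient_population()]
#' @param arena the [gradient_arena()]
#' @param basis an [eigenworm_basis()] for decomposition and state calls
#' @return named numeric vector with the four statistics
#' @export
navigation_run_stats <- function(worm, arena, basis) {
  tr <- worm$track
  fr <- tr$frame_rate
  n <- nrow(tr$xy)
  cs <- classify_states(tr, basis)
  runs <- segment_runs(tr, cs$state)
  b_all <- bearing(tr, arena, restrict_below_optimum = FALSE)

  dec <- decompose(tr$posture, basis)
  turns <- detect_shallow_turn_events(dec, cs$state, b_all)
  ts <- turns$slope
  big_turns <- turns$events$frame[turns$events$amplitude > 0.2]
  near_turn <- if (length(big_turns))
    unique(unlist(lapply(big_turns, function(f)
      max(1L, f - as.integer(round(fr))):min(n, f + as.integer(round(fr))))))
  else integer(0)

  ## curving bias measures the continuous steering between discrete turn
  ## maneuvers: frames around large turn transients are excluded (the
  ## fold of the bearing makes large random kicks look like systematic
  ## steering near 0 and 180 degrees)
  b_wv <- bearing(tr, arena, restrict_below_optimum = TRUE)
  b_wv$db_dx[near_turn] <- NA_real_
  cb <- tryCatch(curving_bias(runs, b_wv)$summary_bias,
                 error = function(e) NA_real_)
  rev_ind <- rep(0, n)
  ro <- as.integer(round((cs$events$reverse$onset_s - 1) * fr)) + 1L
  rev_ind[ro[ro >= 1 & ro <= n]] <- 1
  fwd <- which(cs$state == "forward")
  rc <- binned_vs_bearing(rev_ind * fr * 60, b_all, frames = fwd)$contrast

  ## forward-crawl speed between turns: trim run edges by 1 s and drop
  ## frames within +-1 s of a detected turn peak, where path curling
  ## depresses displacement-based speed
  spd <- centroid_speed(tr)
  tw <- as.integer(round(fr))
  core <- unlist(lapply(seq_len(nrow(runs)), function(j) {
    a <- runs$start_frame[j] + tw
    z <- runs$end_frame[j] - tw
    if (z >= a) a:z else integer(0)
  }))
  core <- setdiff(core, near_turn)
  sc <- binned_vs_bearing(spd, b_all, frames = core)$contrast
  c(curving_bias = cb, reversal_contrast = rc, speed_contrast = sc,
    turn_slope = ts)
}

#' Population distribution profile and chemotaxis index
#'
#' Fractions of animals in 13 equal bins along the gradient axis, the
#' per-bin index (gradient fraction minus control fraction), and the
#' cumulative low-O2 index: the summed index over all bins whose center
#' O2 lies below `zero_cross_o2` (default 13.8 %, the bin where wild-type
#' gradient and control accumulations balance).
#'
#' @param x_positions animal x positions (mm), one per animal (e.g. the
#'   final frame of each track), or a list of [worm_track()]s from which
#'   final positions are taken
#' @param arena a [gradient_arena()]
#' @param control optional control profile (same class) to subtract
#' @param n_bins number of bins (default 13)
#' @param zero_cross_o2 zero-crossing concentration (%)
#' @return an object of class `distribution_profile`: `bin_fractions`,
#'   `bin_centers_o2`, `bin_centers_mm`, `counts`, and (with a control)
#'   `index` and `cumulative_low_o2_index`
#' @export
population_profile <- function(x_positions, arena, control = NULL,
                               n_bins = 13, zero_cross_o2 = 13.8) {
  if (is.list(x_positions) && all(vapply(x_positions, inherits, logical(1),
                                         "worm_track")))
    x_positions <- vapply(x_positions, function(tr)
      tr$xy[nrow(tr$xy), 1], numeric(1))
  x_positions <- x_positions[is.finite(x_positions)]
  if (!length(x_positions)) stop("no animals counted", call. = FALSE)
  edges <- seq(0, arena$length, length.out = n_bins + 1)
  counts <- as.numeric(table(cut(pmin(pmax(x_positions, 0), arena$length),
                                 edges, include.lowest = TRUE)))
  fr <- counts / sum(counts)
  centers_mm <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  out <- structure(list(
    bin_fractions = fr,
    bin_centers_mm = centers_mm,
    bin_centers_o2 = o2_at_position(arena, centers_mm),
    counts = counts, n_bins = n_bins,
    index = NULL, cumulative_low_o2_index = NULL),
    class = "distribution_profile")
  if (!is.null(control)) {
    if (!inherits(control, "distribution_profile") ||
        control$n_bins != n_bins)
      stop("control profile has a different bin geometry", call. = FALSE)
    out$index <- fr - control$bin_fractions
    low <- out$bin_centers_o2 < zero_cross_o2
    out$cumulative_low_o2_index <- sum(out$index[low])
  }
  out
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat(sprintf("<distribution_profile> %d bins, %d animals%s\n", x$n_bins,
              sum(x$counts),
              if (!is.null(x$cumulative_low_o2_index))
                sprintf(", cumulative low-O2 index %.3f",
                        x$cumulative_low_o2_index) else ""))
  invisible(x)
}
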
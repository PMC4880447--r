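# Ratiometric calcium-trace processing and neural-activity/behavior
# coupling: dR/R normalization, artifact exclusion, event-triggered
# averages, moving/pausing activity, lag estimation, and binned
# activity-versus-behavior relations.

#' Two-channel calcium trace container
#'
#' @param signal signal-channel fluorescence (a.u., e.g. GCaMP)
#' @param reference reference-channel fluorescence (a.u., e.g. mCherry)
#' @param frame_rate frames per second (default 30)
#' @param valid per-frame validity flag
#' @return an object of class `calcium_trace`; `ratio` and `dr_over_r`
#'   are filled by [normalize_ratio()]
#' @export
calcium_trace <- function(signal, reference, frame_rate = 30,
                          valid = NULL) {
  n <- length(signal)
  stopifnot(length(reference) == n)
  check_pos(frame_rate, "frame_rate")
  if (is.null(valid)) valid <- is.finite(signal) & is.finite(reference)
  structure(list(signal = as.numeric(signal),
                 reference = as.numeric(reference),
                 frame_rate = frame_rate,
                 timestamps = (seq_len(n) - 1L) / frame_rate,
                 valid = as.logical(valid),
                 ratio = rep(NA_real_, n),
                 dr_over_r = rep(NA_real_, n)), class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d frames @ %g fps, %d valid%s\n",
              length(x$signal), x$frame_rate, sum(x$valid),
              if (all(is.na(x$dr_over_r))) "" else ", normalized"))
  invisible(x)
}

#' Normalize a calcium trace to dR/R (%)
#'
#' R is the signal/reference ratio per frame; dR/R is
#' `(R - mean(R)) / mean(R)` in percent, with the mean taken over valid
#' frames only, so the valid-frame mean of dR/R is zero by construction.
#'
#' @param trace a [calcium_trace()]
#' @return the trace with `ratio` and `dr_over_r` filled
#' @export
normalize_ratio <- function(trace) {
  ok <- trace$valid & is.finite(trace$signal) & is.finite(trace$reference) &
    trace$reference > 0
  if (!any(ok)) stop("no valid frames to normalize", call. = FALSE)
  r <- rep(NA_real_, length(trace$signal))
  r[ok] <- trace$signal[ok] / trace$reference[ok]
  mr <- mean(r[ok])
  if (!is.finite(mr) || mr <= 0)
    stop("mean ratio must be positive", call. = FALSE)
  trace$ratio <- r
  trace$dr_over_r <- (r - mr) / mr * 100
  trace$valid <- ok
  trace
}

#' Exclude movement and ratio artifacts from a calcium trace
#'
#' Marks invalid: frames where the reference channel drops more than
#' `ref_drop_frac` below its rolling 1 s median (out-of-focus movement),
#' frames whose ratio deviates more than `ratio_mads` median absolute
#' deviations from the trace median, and single-frame relative ratio jumps
#' larger than `jump_frac`. Exclusion never creates new valid frames;
#' dR/R is renormalized over the surviving frames.
#'
#' @param trace a normalized [calcium_trace()]
#' @param ref_drop_frac reference-drop threshold (default 0.3)
#' @param ratio_mads extreme-ratio threshold in MADs (default 5)
#' @param jump_frac single-frame relative jump threshold (default 0.5)
#' @return the trace with updated `valid` and renormalized dR/R
#' @export
exclude_artifacts <- function(trace, ref_drop_frac = 0.3, ratio_mads = 5,
                              jump_frac = 0.5) {
  fr <- trace$frame_rate
  w <- max(3L, as.integer(round(fr)))
  if (w %% 2L == 0L) w <- w + 1L
  refmed <- as.numeric(zoo::rollmedian(zoo::zoo(trace$reference), w,
                                       fill = stats::median(trace$reference,
                                                            na.rm = TRUE)))
  drop <- trace$reference < (1 - ref_drop_frac) * refmed
  r <- trace$ratio
  med <- stats::median(r, na.rm = TRUE)
  madv <- stats::mad(r, na.rm = TRUE)
  extreme <- !is.na(r) & madv > 0 & abs(r - med) > ratio_mads * madv
  jump <- c(FALSE, !is.na(r[-1]) & !is.na(r[-length(r)]) &
              abs(diff(r)) / pmax(abs(r[-length(r)]), 1e-12) > jump_frac)
  trace$valid <- trace$valid & !drop & !extreme & !jump
  if (!any(trace$valid)) stop("all frames excluded", call. = FALSE)
  normalize_ratio(trace)
}

#' Event-triggered average of a per-frame signal
#'
#' Aligns windows around event times, averages frame-wise across events,
#' and returns per-event pre/post interval means for paired testing.
#' Events whose window leaves the recording are dropped.
#'
#' @param series per-frame numeric signal
#' @param events event times (s)
#' @param frame_rate frames per second
#' @param window `c(pre, post)` window half-lengths (s), default 8 s each
#' @return list with `lag_s`, `mean`, `sem`, `n_events`, and `pre_post`
#'   (data.frame of per-event interval means)
#' @export
event_triggered_average <- function(series, events, frame_rate,
                                    window = c(8, 8)) {
  n <- length(series)
  pre <- as.integer(round(window[1] * frame_rate))
  post <- as.integer(round(window[2] * frame_rate))
  centers <- as.integer(round(events * frame_rate)) + 1L
  centers <- centers[centers - pre >= 1 & centers + post <= n]
  if (!length(centers)) stop("no usable events", call. = FALSE)
  segs <- vapply(centers, function(c0) series[(c0 - pre):(c0 + post)],
                 numeric(pre + post + 1L))
  segs <- matrix(segs, nrow = pre + post + 1L)
  pre_means <- colMeans(segs[seq_len(pre), , drop = FALSE], na.rm = TRUE)
  post_means <- colMeans(segs[(pre + 2L):(pre + post + 1L), , drop = FALSE],
                         na.rm = TRUE)
  list(lag_s = (seq_len(pre + post + 1L) - pre - 1L) / frame_rate,
       mean = rowMeans(segs, na.rm = TRUE),
       sem = apply(segs, 1, sem),
       n_events = length(centers),
       pre_post = data.frame(pre = pre_means, post = post_means))
}

#' Mean activity during moving versus pausing
#'
#' Means of dR/R over moving and pausing frames; recordings with less than
#' `min_pause_s` of total pausing are excluded from the cohort (flag).
#'
#' @param trace a normalized [calcium_trace()]
#' @param labels per-frame [state_labels()] on the same time base
#' @param min_pause_s minimum total pausing (s), default 60
#' @return list with `moving`, `pausing` (mean dR/R, %), `pause_total_s`,
#'   `included`
#' @export
moving_pausing_means <- function(trace, labels, min_pause_s = 60) {
  stopifnot(length(labels) == length(trace$dr_over_r))
  pausing <- labels == "pause" & trace$valid
  moving <- labels %in% c("forward", "reverse") & trace$valid
  pause_total <- sum(pausing) / trace$frame_rate
  list(moving = mean(trace$dr_over_r[moving], na.rm = TRUE),
       pausing = mean(trace$dr_over_r[pausing], na.rm = TRUE),
       pause_total_s = pause_total,
       included = pause_total >= min_pause_s)
}

#' Lag between neural activity and a behavior feature
#'
#' The lag of the peak cross-correlation between the two series. Positive
#' lags mean the activity lags behind the behavior. A peak on the boundary
#' of the lag range raises `boundary` (the true lag may exceed `max_lag`).
#'
#' @param activity dR/R series
#' @param behavior per-frame behavior series (same time base)
#' @param max_lag maximum lag searched (s)
#' @param frame_rate frames per second
#' @return list with `lag_s`, `peak_r`, `boundary`
#' @export
lag_estimate <- function(activity, behavior, max_lag, frame_rate) {
  if (stats::sd(activity, na.rm = TRUE) == 0 ||
      stats::sd(behavior, na.rm = TRUE) == 0)
    stop("flat signal: lag undefined", call. = FALSE)
  cc <- mode_crosscorrelation(behavior, activity, max_lag, frame_rate,
                              min_track_s = 0)
  list(lag_s = cc$peak_lag, peak_r = cc$peak_r,
       boundary = abs(abs(cc$peak_lag) - max_lag) < 1e-9)
}

#' Binned activity versus behavior with per-recording correlation
#'
#' Both series are first averaged in 0.5 s blocks, then the activity is
#' sorted into equal-width bins of the behavior feature; per-bin medians
#' and interquartile ranges are reported together with the per-recording
#' Pearson correlation of the block-averaged series.
#'
#' @param trace a normalized [calcium_trace()] (or a numeric activity
#'   series)
#' @param behavior per-frame behavior series
#' @param bin_width bin width in behavior units (e.g. 0.01 mm/s for
#'   speed, 0.2 rad for turning amplitude)
#' @param frame_rate frames per second (taken from the trace if omitted)
#' @param block_s pre-binning block length (s), default 0.5
#' @return list with `bins` (data.frame: bin_mid, median, q25, q75, n)
#'   and `r` (per-recording correlation)
#' @export
binned_activity_vs_behavior <- function(trace, behavior, bin_width,
                                        frame_rate = NULL, block_s = 0.5) {
  if (inherits(trace, "calcium_trace")) {
    activity <- trace$dr_over_r
    frame_rate <- trace$frame_rate
  } else activity <- as.numeric(trace)
  if (is.null(frame_rate)) stop("frame_rate required", call. = FALSE)
  per <- max(1L, as.integer(round(block_s * frame_rate)))
  n <- min(length(activity), length(behavior))
  blk <- (seq_len(n) - 1L) %/% per
  a <- tapply(activity[seq_len(n)], blk, mean, na.rm = TRUE)
  b <- tapply(behavior[seq_len(n)], blk, mean, na.rm = TRUE)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  lo <- floor(min(b) / bin_width) * bin_width
  edges <- seq(lo, max(b) + bin_width, by = bin_width)
  bin <- cut(b, edges, right = FALSE, include.lowest = TRUE)
  bins <- data.frame(
    bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
    median = as.numeric(tapply(a, bin, stats::median)),
    q25 = as.numeric(tapply(a, bin, stats::quantile, probs = 0.25)),
    q75 = as.numeric(tapply(a, bin, stats::quantile, probs = 0.75)),
    n = as.numeric(table(bin)))
  list(bins = bins,
       r = if (length(a) > 2) stats::cor(a, b) else NA_real_)
}
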
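# Core S3 containers used throughout the pipeline.

#' Posture series: per-frame inter-segment angles with validity mask
#'
#' The universal currency of the pipeline: a matrix of 24 signed
#' inter-segment bend angles (rad) per frame, ordered head (#1) to tail
#' (#24), with a per-frame validity flag and a uniform time base.
#'
#' @param angles numeric matrix, frames x 24, radians
#' @param frame_rate frames per second
#' @param valid logical vector, one flag per frame; invalid frames keep
#'   their row but are skipped by all downstream statistics
#' @param t0 time of the first frame (s)
#' @return an object of class `posture_series`
#' @export
posture_series <- function(angles, frame_rate, valid = NULL, t0 = 0) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 24L)
    stop("a posture series has exactly 24 inter-segment angles per frame",
         call. = FALSE)
  check_pos(frame_rate, "frame_rate")
  n <- nrow(angles)
  if (is.null(valid)) valid <- rowSums(!is.finite(angles)) == 0L
  stopifnot(length(valid) == n)
  structure(list(
    angles = unname(angles),
    valid = as.logical(valid),
    frame_rate = frame_rate,
    timestamps = t0 + (seq_len(n) - 1L) / frame_rate
  ), class = "posture_series")
}

#' @export
print.posture_series <- function(x, ...) {
  cat(sprintf("<posture_series> %d frames @ %g fps, %d valid (%.1f%%)\n",
              nrow(x$angles), x$frame_rate, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

n_frames <- function(series) nrow(series$angles)

#' Centroid track
#'
#' A worm centroid trajectory on a uniform time base, optionally carrying
#' the matching posture series and a near-boundary exclusion mask.
#'
#' @param xy numeric matrix, frames x 2, centroid coordinates (mm)
#' @param frame_rate frames per second
#' @param posture optional [posture_series()] sharing the frame count
#' @param margin_mask logical per-frame flag; `TRUE` marks frames near the
#'   arena boundary that population statistics exclude
#' @param t0 time of the first frame (s)
#' @return an object of class `worm_track`
#' @export
worm_track <- function(xy, frame_rate, posture = NULL, margin_mask = NULL,
                       t0 = 0) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  check_pos(frame_rate, "frame_rate")
  n <- nrow(xy)
  if (!is.null(posture) && n_frames(posture) != n)
    stop("posture series and track must share the frame count", call. = FALSE)
  if (is.null(margin_mask)) margin_mask <- rep(FALSE, n)
  structure(list(
    xy = unname(xy),
    frame_rate = frame_rate,
    timestamps = t0 + (seq_len(n) - 1L) / frame_rate,
    posture = posture,
    margin_mask = as.logical(margin_mask)
  ), class = "worm_track")
}

#' @export
print.worm_track <- function(x, ...) {
  cat(sprintf("<worm_track> %d frames @ %g fps (%.1f s)%s\n",
              nrow(x$xy), x$frame_rate, nrow(x$xy) / x$frame_rate,
              if (!is.null(x$posture)) ", with posture" else ""))
  invisible(x)
}

track_duration <- function(track) nrow(track$xy) / track$frame_rate

# Behavioral state labels: one exclusive tag per frame.
STATE_LEVELS <- c("forward", "reverse", "pause", "omega", "invalid")

#' Per-frame behavioral state labels
#' @param state character or factor vector with values among
#'   `forward`, `reverse`, `pause`, `omega`, `invalid`
#' @return factor with the canonical level set
#' @export
state_labels <- function(state) {
  f <- factor(as.character(state), levels = STATE_LEVELS)
  if (anyNA(f)) stop("unknown state label", call. = FALSE)
  f
}
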
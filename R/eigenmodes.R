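# Eigenworm analysis: PCA basis over inter-segment angles, decomposition
# of posture into undulation (EW1-2) and turning (EW3-24) modes, mode
# amplitudes, undulation phase velocity, cross-correlation, and the
# resampling test on variance spectra.

collect_valid_angles <- function(series_list) {
  if (inherits(series_list, "posture_series")) series_list <- list(series_list)
  mats <- lapply(series_list, function(s) s$angles[s$valid, , drop = FALSE])
  do.call(rbind, mats)
}

#' Fit an eigenworm basis by PCA on concatenated angle series
#'
#' Valid frames of all series are concatenated, each of the 24 angles is
#' centered by its time-mean, and the eigenvectors of the covariance matrix
#' give the eigenworms EW1..EW24, ordered by decreasing variance. Each
#' eigenvector's sign is fixed by making its first nonzero component
#' positive, so the basis is reproducible; downstream statistics are
#' invariant to these sign choices.
#'
#' @param series_list a [posture_series()] or list of them
#' @param min_frames minimum pooled valid frames (default 1000)
#' @return an object of class `eigenworm_basis`: orthonormal `vectors`
#'   (24 x 24, columns EW1..EW24), per-angle `means`, `variance_fractions`
#'   (non-increasing, summing to 1), and `n_frames`
#' @export
fit_eigenworms <- function(series_list, min_frames = 1000L) {
  X <- collect_valid_angles(series_list)
  if (is.null(X) || nrow(X) < min_frames)
    stop(sprintf("insufficient sampling: %d valid frames (< %d)",
                 if (is.null(X)) 0L else nrow(X), min_frames), call. = FALSE)
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  ed <- eigen(cv, symmetric = TRUE)
  V <- ed$vectors
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  lam <- pmax(ed$values, 0)
  structure(list(vectors = V, means = means,
                 variance_fractions = lam / sum(lam),
                 n_frames = nrow(X)), class = "eigenworm_basis")
}

#' @export
print.eigenworm_basis <- function(x, ...) {
  cf <- cumsum(x$variance_fractions)
  cat(sprintf(
    "<eigenworm_basis> fitted on %d frames; EW1-2 %.1f%%, EW1-4 %.1f%% of variance\n",
    x$n_frames, 100 * cf[2], 100 * cf[4]))
  invisible(x)
}

#' Decompose posture into undulation and turning modes
#'
#' The centered angles are projected onto EW1-2; the undulation mode is the
#' per-angle means plus that rank-2 reconstruction, and the turning mode is
#' the residual (identically the EW3-24 reconstruction of the centered
#' angles), so `undulation + turning = posture` holds exactly. Mode
#' amplitudes are the per-frame sums of absolute angles. The projection
#' pair (a1, a2) is gently smoothed (moving average, `phase_smooth_s`) and
#' its rotation yields the undulation phase and signed phase velocity in
#' cycles/s; frames whose projection magnitude falls below 1 % of the
#' series median are masked in the phase outputs.
#'
#' @param series a [posture_series()]
#' @param basis an [eigenworm_basis()]
#' @param phase_smooth_s smoothing window for (a1, a2) before phase
#'   computation (s)
#' @return an object of class `mode_decomposition` with posture series
#'   `undulation` and `turning`, per-frame `undulation_amp`, `turning_amp`,
#'   `body_amp` (rad), `proj` (frames x 2), `phase` (rad) and
#'   `phase_velocity` (cycles/s)
#' @export
decompose <- function(series, basis, phase_smooth_s = 0.5) {
  stopifnot(inherits(series, "posture_series"),
            inherits(basis, "eigenworm_basis"))
  if (sum(series$valid) < 1) stop("no valid frames", call. = FALSE)
  X <- series$angles
  if (ncol(X) != nrow(basis$vectors))
    stop("dimension mismatch between series and basis", call. = FALSE)
  Xc <- sweep(X, 2, basis$means)
  U <- basis$vectors[, 1:2, drop = FALSE]
  proj <- Xc %*% U
  und <- sweep(proj %*% t(U), 2, basis$means, `+`)
  trn <- X - und
  bad <- !series$valid
  und[bad, ] <- NA_real_
  trn[bad, ] <- NA_real_
  proj[bad, ] <- NA_real_

  pv <- phase_velocity(proj, series$frame_rate, smooth_s = phase_smooth_s)

  structure(list(
    undulation = posture_series(und, series$frame_rate, valid = series$valid,
                                t0 = series$timestamps[1]),
    turning = posture_series(trn, series$frame_rate, valid = series$valid,
                             t0 = series$timestamps[1]),
    undulation_amp = apply(und, 1, amplitude),
    turning_amp = apply(trn, 1, amplitude),
    body_amp = apply(X * ifelse(series$valid, 1, NA), 1, amplitude),
    proj = proj,
    phase = attr(pv, "phase"),
    phase_velocity = as.numeric(pv),
    frame_rate = series$frame_rate,
    timestamps = series$timestamps
  ), class = "mode_decomposition")
}

#' Total bending amplitude of a posture frame
#'
#' The sum of absolute inter-segment angles; invalid (non-finite) frames
#' give `NA`.
#'
#' @param frame_angles numeric vector of 24 angles (rad)
#' @return amplitude (rad), `NA` for invalid frames
#' @export
amplitude <- function(frame_angles) {
  if (any(!is.finite(frame_angles))) return(NA_real_)
  sum(abs(frame_angles))
}

#' Undulation phase velocity from the (a1, a2) projection pair
#'
#' The projection pair is smoothed by a centered moving average, its phase
#' angle `atan2(a2, a1)` is unwrapped by smallest-angle increments, and the
#' per-frame signed rotation rate (central difference) is returned in
#' cycles/s. Positive values are counterclockwise rotation in the
#' (a1, a2) plane; for a given basis the dominant (forward-crawling) sign
#' is consistent within a recording, so reversals appear as sign flips.
#' Frames with projection magnitude below `mask_frac` of the series median
#' are masked.
#'
#' @param proj matrix (frames x 2) of projection amplitudes, or a
#'   `mode_decomposition`
#' @param frame_rate frames per second
#' @param smooth_s moving-average window (s)
#' @param mask_frac low-magnitude mask threshold as a fraction of the
#'   median magnitude
#' @return numeric vector of cycles/s, with attribute `phase` (unwrapped
#'   rad)
#' @export
phase_velocity <- function(proj, frame_rate, smooth_s = 0.5,
                           mask_frac = 0.01) {
  if (inherits(proj, "mode_decomposition")) proj <- proj$proj
  proj <- as.matrix(proj)
  stopifnot(ncol(proj) == 2, nrow(proj) >= 2)
  w <- max(1L, as.integer(round(smooth_s * frame_rate)))
  a1 <- moving_average(proj[, 1], w)
  a2 <- moving_average(proj[, 2], w)
  mag <- sqrt(a1^2 + a2^2)
  lowmag <- !is.finite(mag) | mag < mask_frac * stats::median(mag, na.rm = TRUE)
  ph <- atan2(a2, a1)
  ok <- is.finite(ph)
  if (any(ok)) ph[ok] <- unwrap_phase(ph[ok])
  n <- length(ph)
  vel <- rep(NA_real_, n)
  if (n >= 3)
    vel[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) * frame_rate / (2 * 2 * pi)
  vel[1] <- vel[2]
  vel[n] <- vel[n - 1]
  vel[lowmag] <- NA_real_
  structure(vel, phase = ph)
}

#' Normalized cross-correlation between two behavioral signals
#'
#' Computes the normalized cross-correlation over lags in
#' `[-max_lag, max_lag]` and reports the peak absolute correlation and its
#' lag. A peak at positive lag means `y` lags behind `x`. When `x` and `y`
#' are lists of per-track signals, the correlation is computed per track
#' and averaged across tracks; tracks shorter than `min_track_s` are
#' discarded.
#'
#' @param x,y numeric vectors, or lists of per-track numeric vectors
#' @param max_lag maximum lag (s)
#' @param frame_rate frames per second
#' @param min_track_s minimum track duration for inclusion (s), default 20
#' @return list with `lag` (s), `r` (mean correlation per lag), `peak_r`
#'   (signed correlation at the peak of |r|), `peak_lag` (s), `n_tracks`
#' @export
mode_crosscorrelation <- function(x, y, max_lag, frame_rate,
                                  min_track_s = 20) {
  if (!is.list(x)) { x <- list(x); y <- list(y) }
  stopifnot(length(x) == length(y))
  keep <- vapply(x, function(v) length(v) / frame_rate >= min_track_s,
                 logical(1))
  L <- as.integer(round(max_lag * frame_rate))
  keep <- keep & vapply(x, function(v)
    sum(is.finite(v)) >= 10 * L, logical(1))
  if (!any(keep)) stop("no track long enough for cross-correlation",
                       call. = FALSE)
  rmats <- mapply(function(xi, yi) {
    if (stats::sd(xi, na.rm = TRUE) == 0 || stats::sd(yi, na.rm = TRUE) == 0)
      stop("constant signal: correlation undefined", call. = FALSE)
    xcorr_lagged(xi, yi, max_lag, frame_rate)$r
  }, x[keep], y[keep], SIMPLIFY = TRUE)
  rmean <- rowMeans(as.matrix(rmats), na.rm = TRUE)
  lag <- seq(-L, L) / frame_rate
  ipk <- which.max(abs(rmean))
  list(lag = lag, r = rmean, peak_r = rmean[ipk], peak_lag = lag[ipk],
       n_tracks = sum(keep))
}

# Cumulative variance-fraction curve of the pooled PCA of a series group.
cumvar_curve <- function(series_list) {
  X <- collect_valid_angles(series_list)
  Xc <- sweep(X, 2, colMeans(X))
  lam <- pmax(eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE,
                    only.values = TRUE)$values, 0)
  cumsum(lam / sum(lam))
}

#' Upper-bound p-value of a permutation test
#'
#' With `n_exceed` null statistics at or above the observed one in `n_iter`
#' iterations, the reported bound is `max(n_exceed, 1) / n_iter`: a run
#' with zero exceedances cannot claim p = 0, only p <= 1/n_iter (e.g.
#' 10^-6 at a million iterations).
#'
#' @param n_exceed number of null statistics >= observed
#' @param n_iter number of iterations
#' @return the p-value upper bound
#' @export
p_upper_bound <- function(n_exceed, n_iter) max(n_exceed, 1) / n_iter

#' Resampling test for a difference between variance spectra
#'
#' The observed statistic is the summed absolute difference between the two
#' groups' cumulative variance-fraction curves (per-group PCA on the pooled
#' valid frames). The null distribution is built by shuffling the
#' series-level group labels (preserving group sizes) and recomputing the
#' statistic `n_iter` times. The reported p-value is an upper bound,
#' `max(#exceedances, 1) / n_iter`: a run in which no shuffled statistic
#' reaches the observed one reports `1/n_iter`.
#'
#' @param group_a,group_b lists of [posture_series()] (>= 2 series each)
#' @param n_iter number of shuffles (>= 100)
#' @param seed RNG seed for the shuffles
#' @return list with `statistic`, `p_upper_bound`, `n_exceed`, `n_iter`,
#'   and the two observed cumulative curves
#' @export
variance_resampling_test <- function(group_a, group_b, n_iter = 1000L,
                                     seed = 1L) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 series", call. = FALSE)
  if (n_iter < 100) stop("n_iter must be >= 100", call. = FALSE)
  stat_fun <- function(ga, gb) sum(abs(cumvar_curve(ga) - cumvar_curve(gb)))
  obs <- stat_fun(group_a, group_b)
  all_series <- c(group_a, group_b)
  na <- length(group_a)
  nn <- length(all_series)
  n_exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(nn, na)
      stat_fun(all_series[idx], all_series[-idx]) >= obs
    }, logical(1)))
  })
  list(statistic = obs,
       p_upper_bound = p_upper_bound(n_exceed, n_iter),
       n_exceed = n_exceed, n_iter = n_iter,
       cumvar_a = cumvar_curve(group_a), cumvar_b = cumvar_curve(group_b))
}
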
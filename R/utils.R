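# Internal numerical helpers shared across modules.

#' Wrap angles to (-pi, pi]
#' @param x numeric vector of angles (rad)
#' @return wrapped angles
#' @keywords internal
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Centered moving average with NA passthrough; window in frames (odd forced).
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L) return(x)
  n <- length(x)
  xf <- ifelse(is.finite(x), x, 0)
  cnt <- as.numeric(is.finite(x))
  cs <- c(0, cumsum(xf))
  cc <- c(0, cumsum(cnt))
  h <- window %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cc[hi + 1L] - cc[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Unwrap a phase series by smallest-angle per-step increments.
unwrap_phase <- function(phase) {
  d <- wrap_angle(diff(phase))
  c(phase[1], phase[1] + cumsum(d))
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Stop with the offending field named; used by parameter validators.
check_nonneg <- function(value, field) {
  if (length(value) != 1L || !is.finite(value) || value < 0)
    stop(sprintf("parameter '%s' must be a single finite value >= 0", field),
         call. = FALSE)
  invisible(value)
}

check_pos <- function(value, field) {
  if (length(value) != 1L || !is.finite(value) || value <= 0)
    stop(sprintf("parameter '%s' must be a single finite value > 0", field),
         call. = FALSE)
  invisible(value)
}

#' Normalized cross-correlation over a symmetric lag range
#'
#' Computes the Pearson correlation between `x` and `y` over integer lags in
#' `[-max_lag, max_lag]` seconds. The sign convention is: a peak at a
#' *positive* lag means `y` lags behind `x` by that amount, i.e.
#' `r(lag) = cor(x[t], y[t + lag/dt])`.
#'
#' Missing values are dropped pairwise per lag. For a list of per-track
#' signal pairs use [mode_crosscorrelation()].
#'
#' @param x,y numeric vectors on a common uniform time base
#' @param max_lag maximum lag (s)
#' @param frame_rate sampling rate (frames/s)
#' @return data.frame with columns `lag` (s) and `r`
#' @keywords internal
xcorr_lagged <- function(x, y, max_lag, frame_rate) {
  n <- length(x)
  stopifnot(length(y) == n)
  L <- as.integer(round(max_lag * frame_rate))
  if (L >= n - 2) stop("max_lag too long for the series", call. = FALSE)
  lags <- seq(-L, L)
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      xi <- x[seq_len(n - l)]
      yi <- y[seq_len(n - l) + l]
    } else {
      xi <- x[seq_len(n + l) - l]
      yi <- y[seq_len(n + l)]
    }
    ok <- is.finite(xi) & is.finite(yi)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(xi[ok]) == 0 || stats::sd(yi[ok]) == 0) return(NA_real_)
    stats::cor(xi[ok], yi[ok])
  }, numeric(1))
  data.frame(lag = lags / frame_rate, r = r)
}

# Shift a series by a (possibly fractional) delay in seconds using linear
# interpolation; head padded with the first finite value.
shift_series <- function(x, delay_s, frame_rate) {
  n <- length(x)
  t_idx <- seq_len(n) - delay_s * frame_rate
  out <- stats::approx(seq_len(n), x, xout = t_idx, rule = 2)$y
  out
}
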
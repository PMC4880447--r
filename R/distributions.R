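# Trial-level aggregation: fractional distributions, 2-D density maps
# with iso-mass boundaries, feature-vs-feature binned relations, and
# trial-mean time profiles.

#' Trial-averaged fractional distribution of a behavioral feature
#'
#' Per trial, values inside the interval are histogrammed and normalized
#' to fractions (summing to 1); the trial mean and SEM per bin are
#' returned.
#'
#' @param trials list of per-trial numeric series (or a single series)
#' @param frame_rate frames per second
#' @param interval `c(start, end)` time window (s)
#' @param bin_width histogram bin width (feature units)
#' @param range_lim optional `c(lo, hi)` fixed bin range; computed from
#'   the pooled data when omitted
#' @return data.frame with `bin_mid`, `mean_fraction`, `sem`, `n_trials`
#' @export
fractional_distribution <- function(trials, frame_rate, interval,
                                    bin_width, range_lim = NULL) {
  if (!is.list(trials)) trials <- list(trials)
  i0 <- as.integer(round(interval[1] * frame_rate)) + 1L
  i1 <- as.integer(round(interval[2] * frame_rate))
  vals <- lapply(trials, function(v)
    v[seq(max(1L, i0), min(length(v), i1))])
  vals <- lapply(vals, function(v) v[is.finite(v)])
  if (all(!lengths(vals))) stop("empty interval", call. = FALSE)
  pooled <- unlist(vals)
  if (is.null(range_lim)) range_lim <- range(pooled)
  edges <- seq(floor(range_lim[1] / bin_width) * bin_width,
               range_lim[2] + bin_width, by = bin_width)
  fracs <- vapply(vals, function(v) {
    if (!length(v)) return(rep(NA_real_, length(edges) - 1L))
    h <- hist(pmin(pmax(v, edges[1]), edges[length(edges)]), breaks = edges,
              plot = FALSE)$counts
    h / sum(h)
  }, numeric(length(edges) - 1L))
  fracs <- matrix(fracs, nrow = length(edges) - 1L)
  data.frame(bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
             mean_fraction = rowMeans(fracs, na.rm = TRUE),
             sem = apply(fracs, 1, sem),
             n_trials = rowSums(!is.na(fracs)))
}

#' 2-D density map with an iso-mass boundary
#'
#' Normalized 2-D histogram of two aligned series; the iso-mass boundary
#' is the set of bins, ranked by density, whose cumulative mass first
#' reaches `mass`. The fraction of a second dataset falling inside that
#' boundary measures overlap between conditions.
#'
#' @param x,y aligned numeric series
#' @param bin_widths `c(wx, wy)` bin widths
#' @param mass boundary mass level (default 0.99)
#' @param range_x,range_y optional fixed ranges
#' @return an object of class `density_map_2d`: `density` matrix (sums to
#'   1), `x_edges`, `y_edges`, `boundary` (logical matrix), `mass`
#' @export
density_map_2d <- function(x, y, bin_widths, mass = 0.99,
                           range_x = NULL, range_y = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(range_x)) range_x <- range(x)
  if (is.null(range_y)) range_y <- range(y)
  xe <- seq(floor(range_x[1] / bin_widths[1]) * bin_widths[1],
            range_x[2] + bin_widths[1], by = bin_widths[1])
  ye <- seq(floor(range_y[1] / bin_widths[2]) * bin_widths[2],
            range_y[2] + bin_widths[2], by = bin_widths[2])
  xi <- findInterval(x, xe, rightmost.closed = TRUE)
  yi <- findInterval(y, ye, rightmost.closed = TRUE)
  inb <- xi >= 1 & xi < length(xe) & yi >= 1 & yi < length(ye)
  h <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  tt <- table(factor(xi[inb], levels = seq_len(length(xe) - 1L)),
              factor(yi[inb], levels = seq_len(length(ye) - 1L)))
  h[] <- as.numeric(tt)
  dens <- h / sum(h)
  ord <- order(dens, decreasing = TRUE)
  cm <- cumsum(dens[ord])
  k <- which(cm >= mass)[1]
  boundary <- matrix(FALSE, nrow(dens), ncol(dens))
  boundary[ord[seq_len(k)]] <- TRUE
  structure(list(density = dens, x_edges = xe, y_edges = ye,
                 boundary = boundary, mass = mass),
            class = "density_map_2d")
}

#' Fraction of a dataset inside an iso-mass boundary
#' @param map a [density_map_2d()]
#' @param x,y aligned series of the second dataset
#' @return fraction in \[0, 1\]
#' @export
fraction_inside_boundary <- function(map, x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xi <- findInterval(x, map$x_edges, rightmost.closed = TRUE)
  yi <- findInterval(y, map$y_edges, rightmost.closed = TRUE)
  inb <- xi >= 1 & xi <= nrow(map$boundary) & yi >= 1 &
    yi <= ncol(map$boundary)
  inside <- logical(length(x))
  inside[inb] <- map$boundary[cbind(xi[inb], yi[inb])]
  mean(inside)
}

#' Binned feature-versus-feature relation
#'
#' Frames are pre-averaged in 0.5 s blocks, pooled, and the y feature is
#' summarized by median and interquartile range within equal-width x
#' bins; sparse bins (fewer than `min_count` blocks) are dropped.
#'
#' @param x,y aligned per-frame series (or lists of per-trial series,
#'   pooled after block averaging)
#' @param bin_width_x x bin width
#' @param frame_rate frames per second
#' @param block_s block length (s), default 0.5
#' @param min_count sparse-bin threshold (default 20)
#' @return data.frame with `bin_mid`, `median`, `q25`, `q75`, `n`
#' @export
binned_relation <- function(x, y, bin_width_x, frame_rate,
                            block_s = 0.5, min_count = 20) {
  if (!is.list(x)) { x <- list(x); y <- list(y) }
  per <- max(1L, as.integer(round(block_s * frame_rate)))
  bx <- by <- numeric(0)
  for (j in seq_along(x)) {
    n <- min(length(x[[j]]), length(y[[j]]))
    blk <- (seq_len(n) - 1L) %/% per
    bx <- c(bx, tapply(x[[j]][seq_len(n)], blk, mean, na.rm = TRUE))
    by <- c(by, tapply(y[[j]][seq_len(n)], blk, mean, na.rm = TRUE))
  }
  ok <- is.finite(bx) & is.finite(by)
  bx <- bx[ok]; by <- by[ok]
  edges <- seq(floor(min(bx) / bin_width_x) * bin_width_x,
               max(bx) + bin_width_x, by = bin_width_x)
  bin <- cut(bx, edges, right = FALSE, include.lowest = TRUE)
  out <- data.frame(
    bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
    median = as.numeric(tapply(by, bin, stats::median)),
    q25 = as.numeric(tapply(by, bin, stats::quantile, probs = 0.25)),
    q75 = as.numeric(tapply(by, bin, stats::quantile, probs = 0.75)),
    n = as.numeric(table(bin)))
  out[!is.na(out$median) & out$n >= min_count, , drop = FALSE]
}

#' Trial-mean time profile with SEM
#'
#' Frame-wise mean and SEM across trials (trials may differ in length;
#' per-frame n reflects availability), then averaged into display bins.
#'
#' @param trials list of per-trial numeric series on a common time base
#' @param frame_rate frames per second
#' @param bin display bin length (s), default 1
#' @return data.frame with `time_s`, `mean`, `sem`, `n`
#' @export
trial_mean_profile <- function(trials, frame_rate, bin = 1) {
  nmax <- max(lengths(trials))
  M <- vapply(trials, function(v) c(v, rep(NA_real_, nmax - length(v))),
              numeric(nmax))
  M <- matrix(M, nrow = nmax)
  mu <- rowMeans(M, na.rm = TRUE)
  se <- apply(M, 1, sem)
  nn <- rowSums(!is.na(M))
  mu[nn == 0] <- NA_real_
  per <- max(1L, as.integer(round(bin * frame_rate)))
  blk <- (seq_len(nmax) - 1L) %/% per
  data.frame(time_s = as.numeric(tapply((seq_len(nmax) - 1L) / frame_rate,
                                        blk, mean)),
             mean = as.numeric(tapply(mu, blk, mean, na.rm = TRUE)),
             sem = as.numeric(tapply(se, blk, mean, na.rm = TRUE)),
             n = as.numeric(tapply(nn, blk, min)))
}
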
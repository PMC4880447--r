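# Image -> skeleton -> angle extraction: cleaning/binarization,
# morphological thinning, midline tracing with branch trimming, 26-point
# resampling, head assignment and the 24 inter-segment angles.

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  rs <- seq_len(n) - dr
  cs <- seq_len(p) - dc
  rok <- rs >= 1 & rs <= n
  cok <- cs >= 1 & cs <= p
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Zhang-Suen morphological thinning of a binary matrix to a 1-px-wide,
# 8-connected skeleton. No installed package provides 2-D binary thinning,
# so it is implemented here; fully vectorized per sub-iteration.
zhang_suen_thin <- function(mask) {
  img <- mask != 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1)
        kill <- img & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        kill <- img & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(kill)) { img[kill] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Zhang-Suen can leave 2x2 foreground blocks; delete one pixel per block
# (the most-connected corner) so only genuine loops remain as cycles.
remove_square_blocks <- function(img) {
  repeat {
    blk <- img & shift_mat(img, 0, -1) & shift_mat(img, -1, 0) &
      shift_mat(img, -1, -1)
    idx <- which(blk, arr.ind = TRUE)
    if (!nrow(idx)) break
    nbcount <- shift_mat(img, -1, 0) + shift_mat(img, 1, 0) +
      shift_mat(img, 0, -1) + shift_mat(img, 0, 1) +
      shift_mat(img, -1, -1) + shift_mat(img, -1, 1) +
      shift_mat(img, 1, -1) + shift_mat(img, 1, 1)
    for (b in seq_len(nrow(idx))) {
      r <- idx[b, 1]; c <- idx[b, 2]
      corners <- rbind(c(r, c), c(r - 1, c), c(r, c - 1), c(r - 1, c - 1))
      if (!all(img[corners])) next          # already broken by earlier pick
      pick <- corners[which.max(nbcount[corners]), , drop = FALSE]
      img[pick] <- FALSE
    }
  }
  img
}

#' Clean and binarize a raw worm frame
#'
#' Thresholds a grayscale (or binary) frame, bridges small gaps by
#' morphological closing, fills holes, and keeps the image only if exactly
#' one foreground connected component survives; otherwise the frame is
#' flagged invalid.
#'
#' @param raw_image numeric matrix (rows = y, cols = x) or a `worm_image`
#' @param threshold gray-level threshold; pixels `> threshold` are
#'   foreground
#' @param dilate_px,erode_px radius (px) of the closing; both default 1
#' @param scale mm per pixel (required when `raw_image` is a bare matrix)
#' @param origin mm position of the lower-left pixel corner
#' @param min_component_px components smaller than this are discarded as
#'   specks before the single-component check
#' @return a `worm_image`; `valid = FALSE` when zero or more than one
#'   component survives
#' @export
clean_binarize <- function(raw_image, threshold = 0.5, dilate_px = 1,
                           erode_px = 1, scale = NULL, origin = c(0, 0),
                           min_component_px = 9) {
  if (inherits(raw_image, "worm_image")) {
    scale <- raw_image$scale
    origin <- raw_image$origin
    ts <- raw_image$timestamp
    m <- raw_image$pixels
  } else {
    if (is.null(scale)) stop("scale (mm/px) is required", call. = FALSE)
    ts <- 0
    m <- raw_image
  }
  if (length(m) == 0 || sum(m > threshold) == 0)
    stop("raw image is empty", call. = FALSE)
  mask <- (m > threshold) * 1
  if (dilate_px > 0 && erode_px > 0) {
    brush <- EBImage::makeBrush(2 * max(dilate_px, 1) + 1, shape = "disc")
    mask <- EBImage::erode(EBImage::dilate(mask, brush),
                           EBImage::makeBrush(2 * max(erode_px, 1) + 1,
                                              shape = "disc"))
  }
  pre_fill <- sum(mask > 0)
  mask <- EBImage::fillHull(mask)
  ## a large enclosed hole means the body closes on itself (deep omega
  ## coil): such frames cannot be skeletonized
  hole_frac <- (sum(mask > 0) - pre_fill) / sum(mask > 0)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_component_px)
  valid <- length(keep) == 1L && hole_frac <= 0.2
  pixels <- if (valid) (lab == keep) else (mask > 0)
  structure(list(pixels = unname(pixels * 1 > 0), scale = scale,
                 origin = origin, timestamp = ts, valid = valid),
            class = "worm_image")
}

# Build the skeleton-pixel graph (8-connectivity, diagonal shortcuts that
# duplicate an orthogonal 2-step path removed) and return the longest
# geodesic path between endpoints as pixel (row, col) coordinates.
# NULL when the skeleton is cyclic (coiled) or degenerate.
trace_midline <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  np <- nrow(px)
  if (np < 5) return(NULL)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(np)
  nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
              c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (j in seq_len(nrow(nb))) {
    r2 <- px[, 1] + nb[j, 1]
    c2 <- px[, 2] + nb[j, 2]
    ok <- r2 >= 1 & r2 <= nrow(skel) & c2 >= 1 & c2 <= ncol(skel)
    tid <- integer(np)
    tid[ok] <- id[cbind(r2[ok], c2[ok])]
    hit <- which(tid > seq_len(np))       # each edge once
    if (!length(hit)) next
    diag_edge <- all(nb[j, ] != 0)
    if (diag_edge) {
      # drop the diagonal when an orthogonal stepping stone connects the
      # same two pixels in two 4-connected steps
      s1 <- id[cbind(px[hit, 1], c2[hit])] > 0
      s2 <- id[cbind(r2[hit], px[hit, 2])] > 0
      hit <- hit[!(s1 | s2)]
      if (!length(hit)) next
    }
    from <- c(from, hit)
    to <- c(to, tid[hit])
    w <- c(w, rep(if (diag_edge) sqrt(2) else 1, length(hit)))
  }
  g <- igraph::make_graph(rbind(from, to), n = np, directed = FALSE)
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vmain <- which(comp$membership == main)
  gs <- igraph::induced_subgraph(g, vmain)
  if (igraph::ecount(gs) >= igraph::vcount(gs)) return(NULL)  # cycle: coil
  deg <- igraph::degree(gs)
  ends <- which(deg == 1)
  if (length(ends) < 2) return(NULL)
  dm <- igraph::distances(gs, v = ends, to = ends)
  dm[!is.finite(dm)] <- -1
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(gs, from = ends[ij[1]], to = ends[ij[2]],
                               output = "vpath")$vpath[[1]]
  px[vmain[as.integer(sp)], , drop = FALSE]
}

#' Extract the 26-point midline skeleton of a worm image
#'
#' Thins the binary silhouette to a 1-px midline, trims branches by taking
#' the longest end-to-end geodesic through the skeleton-pixel graph,
#' extends both ends to the body tips using the distance transform,
#' smooths the traced path with smoothing splines, and resamples it to 26
#' points equally spaced in arc length. Coiled shapes whose skeleton
#' contains a loop cannot be traced and give an invalid skeleton, as do
#' artificially short skeletons (`length < short_frac * ref_length_mm`
#' when a reference length is supplied).
#'
#' @param image a `worm_image` (see [clean_binarize()])
#' @param ref_length_mm running-median body length used for the
#'   short-skeleton rule; `NULL` skips the rule
#' @param short_frac short-skeleton threshold as a fraction of
#'   `ref_length_mm` (default 0.6)
#' @param spline_df degrees of freedom of the midline smoothing spline
#' @return an object of class `worm_skeleton`: `points` (26 x 2, mm; row 1
#'   is one body end, head assignment is done by [orient_head()]),
#'   `length_mm`, `valid`
#' @export
extract_skeleton <- function(image, ref_length_mm = NULL, short_frac = 0.6,
                             spline_df = 14) {
  invalid <- structure(list(points = matrix(NA_real_, 26, 2),
                            length_mm = NA_real_, valid = FALSE),
                       class = "worm_skeleton")
  if (!inherits(image, "worm_image") || !isTRUE(image$valid)) return(invalid)
  skel <- remove_square_blocks(zhang_suen_thin(image$pixels))
  path <- trace_midline(skel)
  if (is.null(path) || nrow(path) < 10) return(invalid)

  sc <- image$scale
  ## work in pixel units: x = col, y = row
  xy <- cbind(path[, 2], path[, 1])
  dmap <- EBImage::distmap(image$pixels * 1)
  bilerp <- function(m, x, y) {
    x <- pmin(pmax(x, 1), ncol(m)); y <- pmin(pmax(y, 1), nrow(m))
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, ncol(m)); y1 <- pmin(y0 + 1, nrow(m))
    fx <- x - x0; fy <- y - y0
    m[cbind(y0, x0)] * (1 - fx) * (1 - fy) + m[cbind(y0, x1)] * fx * (1 - fy) +
      m[cbind(y1, x0)] * (1 - fx) * fy + m[cbind(y1, x1)] * fx * fy
  }
  fg <- image$pixels * 1
  ## extend each end along the local tangent until leaving the body
  extend_end <- function(xy, at_start) {
    n <- nrow(xy)
    idx <- if (at_start) seq_len(min(9L, n)) else seq(n, max(1L, n - 8L))
    pts <- xy[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    dirv <- stats::prcomp(pts)$rotation[, 1]
    tip <- if (at_start) xy[1, ] else xy[n, ]
    if (sum((tip - ctr) * dirv) < 0) dirv <- -dirv
    steps <- seq(0.25, 25, by = 0.25)
    probe_x <- tip[1] + steps * dirv[1]
    probe_y <- tip[2] + steps * dirv[2]
    inside <- bilerp(fg, probe_x, probe_y) >= 0.5
    last <- if (all(inside)) length(steps) else (which(!inside)[1] - 1L)
    if (last < 1) return(xy)
    newpt <- c(tip[1] + steps[last] * dirv[1], tip[2] + steps[last] * dirv[2])
    if (at_start) rbind(newpt, xy) else rbind(xy, newpt)
  }
  xy <- extend_end(extend_end(xy, TRUE), FALSE)

  ## smooth against cumulative chord length
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  df <- min(spline_df, max(4, nrow(xy) %/% 3))
  fx <- stats::smooth.spline(s, xy[, 1], df = df)
  fy <- stats::smooth.spline(s, xy[, 2], df = df)
  sf <- seq(0, max(s), length.out = 400)
  fine <- cbind(stats::predict(fx, sf)$y, stats::predict(fy, sf)$y)

  ## recenter on the ridge of the distance transform: thinning and spline
  ## smoothing bias the trace off the true midline by up to a pixel
  tang <- rbind(fine[2, ] - fine[1, ], fine[3:400, ] - fine[1:398, ],
                fine[400, ] - fine[399, ])
  tlen <- sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2] / tlen, tang[, 1] / tlen)
  offs <- seq(-1.5, 1.5, by = 0.5)
  dvals <- vapply(offs, function(o)
    bilerp(dmap, fine[, 1] + o * nrm[, 1], fine[, 2] + o * nrm[, 2]),
    numeric(400))
  best <- offs[max.col(dvals, ties.method = "first")]
  ## parabolic sub-step refinement around the discrete maximum
  ib <- max.col(dvals, ties.method = "first")
  can <- ib > 1 & ib < length(offs)
  sub <- numeric(400)
  if (any(can)) {
    ic <- which(can)
    y0 <- dvals[cbind(ic, ib[ic] - 1L)]
    y1 <- dvals[cbind(ic, ib[ic])]
    y2 <- dvals[cbind(ic, ib[ic] + 1L)]
    den <- y0 - 2 * y1 + y2
    sub[ic] <- ifelse(abs(den) > 1e-12, 0.25 * (y0 - y2) / den, 0)
    sub[ic] <- pmin(pmax(sub[ic], -0.25), 0.25)
  }
  shift <- pmin(pmax(best + sub, -2), 2)
  fine <- fine + cbind(shift * nrm[, 1], shift * nrm[, 2])
  ## light arc-length smoothing of the recentered trace
  fine[, 1] <- moving_average(fine[, 1], 9)
  fine[, 2] <- moving_average(fine[, 2], 9)

  ## the medial axis continues through the tapered tips; follow its ridge
  ## from each end, recentering every step, until the silhouette boundary
  ridge_walk <- function(p, d) {
    out <- matrix(NA_real_, 80, 2)
    k <- 0L
    woff <- seq(-2, 2, by = 0.25)
    repeat {
      pn <- p + d
      nv <- c(-d[2], d[1])
      vals <- bilerp(dmap, pn[1] + woff * nv[1], pn[2] + woff * nv[2])
      pn <- pn + woff[which.max(vals)] * nv
      if (bilerp(fg, pn[1], pn[2]) < 0.5 || k >= 78L) break
      dn <- pn - p
      d <- dn / sqrt(sum(dn^2))
      k <- k + 1L
      out[k, ] <- pn
      p <- pn
    }
    ## finish with the exact boundary crossing along the last direction
    steps <- seq(0.25, 6, by = 0.25)
    inside <- bilerp(fg, p[1] + steps * d[1], p[2] + steps * d[2]) >= 0.5
    if (!all(inside) && which(!inside)[1] > 1) {
      k <- k + 1L
      out[k, ] <- p + steps[which(!inside)[1] - 1L] * d
    }
    out[seq_len(k), , drop = FALSE]
  }
  trim <- 12L
  core <- fine[(trim + 1):(400 - trim), , drop = FALSE]
  nc <- nrow(core)
  d_head <- core[1, ] - core[6, ]
  d_tail <- core[nc, ] - core[nc - 5, ]
  walk_head <- ridge_walk(core[1, ], d_head / sqrt(sum(d_head^2)))
  walk_tail <- ridge_walk(core[nc, ], d_tail / sqrt(sum(d_tail^2)))
  if (nrow(walk_head)) walk_head <- walk_head[nrow(walk_head):1, , drop = FALSE]
  fine <- rbind(walk_head, core, walk_tail)

  fine <- cbind(image$origin[1] + (fine[, 1] - 0.5) * sc,
                image$origin[2] + (fine[, 2] - 0.5) * sc)
  sa <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
  len <- max(sa)
  if (!is.null(ref_length_mm) && is.finite(ref_length_mm) &&
      len < short_frac * ref_length_mm) return(invalid)
  targets <- seq(0, len, length.out = 26)
  pts <- cbind(stats::approx(sa, fine[, 1], xout = targets)$y,
               stats::approx(sa, fine[, 2], xout = targets)$y)
  structure(list(points = pts, length_mm = len, valid = TRUE),
            class = "worm_skeleton")
}

#' @export
print.worm_skeleton <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<worm_skeleton> 26 points, length %.3f mm\n", x$length_mm))
  else cat("<worm_skeleton> invalid\n")
  invisible(x)
}

# Reverse a skeleton head<->tail.
flip_skeleton <- function(sk) {
  sk$points <- sk$points[26:1, , drop = FALSE]
  sk
}

#' Assign the head end across a skeleton sequence
#'
#' The head is chosen at the first valid frames by the movement direction
#' of the centroid track (the end pointing along the motion is the head),
#' then propagated frame-to-frame by endpoint proximity: the end closer to
#' the previous head stays the head. During frames flagged as omega turns
#' the proximity rule is suspended and the direction rule is used instead.
#'
#' @param skeletons list of `worm_skeleton`
#' @param centroid_track a [worm_track()] on the same frames
#' @param omega_flags optional logical per-frame flags
#' @return the skeleton list, flipped so row 1 of `points` is the head
#' @export
orient_head <- function(skeletons, centroid_track, omega_flags = NULL) {
  nf <- length(skeletons)
  valid <- vapply(skeletons, function(s) isTRUE(s$valid), logical(1))
  if (sum(valid) < 2) {
    warning("fewer than 2 valid frames; head assignment skipped")
    return(skeletons)
  }
  if (is.null(omega_flags)) omega_flags <- rep(FALSE, nf)
  fr <- centroid_track$frame_rate
  h <- max(2L, as.integer(round(fr)))          # ~1 s look-ahead
  motion_dir <- function(i) {
    j <- min(nrow(centroid_track$xy), i + h)
    v <- centroid_track$xy[j, ] - centroid_track$xy[i, ]
    if (sqrt(sum(v^2)) < 1e-9) c(NA, NA) else v / sqrt(sum(v^2))
  }
  direction_rule <- function(sk, i) {
    v <- motion_dir(i)
    if (any(!is.finite(v))) return(sk)
    body_dir <- sk$points[1, ] - sk$points[26, ]
    if (sum(body_dir * v) < 0) flip_skeleton(sk) else sk
  }
  first <- which(valid)[1]
  skeletons[[first]] <- direction_rule(skeletons[[first]], first)
  prev_head <- skeletons[[first]]$points[1, ]
  idx <- which(valid)
  for (i in idx[-1]) {
    sk <- skeletons[[i]]
    if (omega_flags[i]) {
      sk <- direction_rule(sk, i)
    } else {
      d_head <- sum((sk$points[1, ] - prev_head)^2)
      d_tail <- sum((sk$points[26, ] - prev_head)^2)
      if (d_tail < d_head) sk <- flip_skeleton(sk)
    }
    skeletons[[i]] <- sk
    prev_head <- sk$points[1, ]
  }
  skeletons
}

#' Inter-segment angles of a skeleton
#'
#' The 24 signed turns between consecutive segments of the 26-point
#' midline, head (#1) to tail (#24). The sign convention (which side is
#' positive) is set by the head assignment and is arbitrary per recording;
#' downstream statistics are sign-symmetric.
#'
#' @param skeleton a `worm_skeleton`
#' @return list with `angles` (24 rad) and `valid`
#' @export
angles_from_skeleton <- function(skeleton) {
  if (!isTRUE(skeleton$valid))
    return(list(angles = rep(NA_real_, 24), valid = FALSE))
  seg <- diff(skeleton$points)
  dirs <- atan2(seg[, 2], seg[, 1])
  list(angles = wrap_angle(diff(dirs)), valid = TRUE)
}

#' Full image-stack to posture-series extraction
#'
#' Runs [clean_binarize()], [extract_skeleton()] (with the running-median
#' short-skeleton rule), [orient_head()] and [angles_from_skeleton()] over
#' a frame sequence.
#'
#' @param images list of raw frames or `worm_image`s
#' @param centroid_track a [worm_track()] for head assignment
#' @param frame_rate frames per second of the stack
#' @param omega_flags optional per-frame omega flags for [orient_head()]
#' @param ... passed to [clean_binarize()]
#' @return a [posture_series()]
#' @export
extract_posture_series <- function(images, centroid_track, frame_rate,
                                   omega_flags = NULL, ...) {
  cleaned <- lapply(images, clean_binarize, ...)
  skels <- lapply(cleaned, extract_skeleton)
  lens <- vapply(skels, function(s) s$length_mm, numeric(1))
  med <- stats::median(lens, na.rm = TRUE)
  runmed_len <- if (sum(is.finite(lens)) >= 11) {
    filled <- lens
    filled[!is.finite(filled)] <- med
    as.numeric(zoo::rollmedian(zoo::zoo(filled), 11, fill = med))
  } else rep(med, length(lens))
  for (i in seq_along(skels))
    if (isTRUE(skels[[i]]$valid) && is.finite(runmed_len[i]) &&
        lens[i] < 0.6 * runmed_len[i])
      skels[[i]] <- structure(list(points = matrix(NA_real_, 26, 2),
                                   length_mm = NA_real_, valid = FALSE),
                              class = "worm_skeleton")
  skels <- orient_head(skels, centroid_track, omega_flags)
  frames <- lapply(skels, angles_from_skeleton)
  angles <- do.call(rbind, lapply(frames, `[[`, "angles"))
  valid <- vapply(frames, `[[`, logical(1), "valid")
  posture_series(angles, frame_rate, valid = valid)
}
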
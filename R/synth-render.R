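# Rendering of 2-D worm silhouettes from inter-segment angles: a filled
# polygon built from the 26-point midline, 25 fixed segment lengths and 26
# cross-sectional widths (50 quadrilaterals, triangular head/tail tips).

#' Fixed body-shape model used for rendering
#'
#' Segment lengths and cross-sectional widths of the rendered worm, scaled
#' to a 1 mm animal: 25 equal segments and a smooth width taper that is
#' widest (80 um by default) at 40 % of body length from the head and
#' vanishes at both tips, making the end pieces triangular.
#'
#' @param length_mm total body length (mm)
#' @param max_width_mm maximum body width (mm)
#' @return list with `seg_len` (25 lengths, mm) and `widths` (26 widths, mm)
#' @export
worm_body_model <- function(length_mm = 1, max_width_mm = 0.08) {
  s <- seq(0, 1, length.out = 26)
  # blunt head (sqrt rise to the 40 % maximum), pointed tail whose width
  # rises steeply enough from the tip that a rasterized silhouette loses
  # less than a pixel of body length
  w <- ifelse(s <= 0.4, sqrt(s / 0.4), ((1 - s) / 0.6)^0.6)
  w <- w * max_width_mm
  list(seg_len = rep(length_mm / 25, 25), widths = w)
}

# 26-point midline (mm) from 24 angles: direction of segment j+1 is the
# direction of segment j turned by angle j.
midline_from_angles <- function(angles, body = worm_body_model(),
                                orientation = 0, centroid = c(0, 0)) {
  stopifnot(length(angles) == 24)
  dirs <- orientation + cumsum(c(0, angles))   # 25 segment directions
  p <- cbind(cumsum(c(0, body$seg_len * cos(dirs))),
             cumsum(c(0, body$seg_len * sin(dirs))))
  sweep(p, 2, colMeans(p) - centroid, `-`)
}

#' Render a binary worm silhouette from a posture frame
#'
#' Builds the 26-point midline from the angles and fixed segment lengths,
#' offsets it by half the local cross-sectional width on each side, and
#' rasterizes the filled polygon onto a pixel grid.
#'
#' @param angles 24 finite inter-segment angles (rad), head to tail
#' @param scale pixel size (mm/pixel), > 0
#' @param orientation heading of the first body segment (rad)
#' @param centroid midline centroid position (mm, length-2)
#' @param body a [worm_body_model()]
#' @param pad_mm blank margin around the silhouette (mm)
#' @param timestamp frame time (s)
#' @return an object of class `worm_image`: binary `pixels` matrix (rows =
#'   y, cols = x), `scale` (mm/px), `origin` (mm position of the lower-left
#'   pixel corner), `timestamp`, `valid`
#' @export
render_worm <- function(angles, scale = 0.003, orientation = 0,
                        centroid = c(0, 0), body = worm_body_model(),
                        pad_mm = 0.06, timestamp = 0) {
  if (length(angles) != 24 || any(!is.finite(angles)))
    stop("render_worm needs 24 finite angles", call. = FALSE)
  check_pos(scale, "scale")
  p <- midline_from_angles(angles, body, orientation, centroid)
  seg <- diff(p)
  seg_dir <- atan2(seg[, 2], seg[, 1])
  pt_dir <- c(seg_dir[1],
              seg_dir[-25] + wrap_angle(diff(seg_dir)) / 2,
              seg_dir[25])
  nx <- -sin(pt_dir)
  ny <- cos(pt_dir)
  hw <- body$widths / 2
  left <- cbind(p[, 1] + hw * nx, p[, 2] + hw * ny)
  right <- cbind(p[, 1] - hw * nx, p[, 2] - hw * ny)
  poly <- rbind(left, right[26:1, ])

  x0 <- min(poly[, 1]) - pad_mm
  y0 <- min(poly[, 2]) - pad_mm
  ncol_px <- ceiling((max(poly[, 1]) + pad_mm - x0) / scale)
  nrow_px <- ceiling((max(poly[, 2]) + pad_mm - y0) / scale)
  xc <- x0 + (seq_len(ncol_px) - 0.5) * scale
  yc <- y0 + (seq_len(nrow_px) - 0.5) * scale
  gx <- rep(xc, each = nrow_px)
  gy <- rep(yc, times = ncol_px)
  inside <- pracma::inpolygon(gx, gy, poly[, 1], poly[, 2])
  pixels <- matrix(inside, nrow = nrow_px, ncol = ncol_px)
  structure(list(pixels = pixels, scale = scale, origin = c(x0, y0),
                 timestamp = timestamp, valid = TRUE),
            class = "worm_image")
}

#' @export
print.worm_image <- function(x, ...) {
  cat(sprintf("<worm_image> %d x %d px @ %g mm/px, %d foreground px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$scale, sum(x$pixels),
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}
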
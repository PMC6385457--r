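# Low-level raster helpers. Images are numeric arrays dim = c(width,
# height, 3), values in [0, 1], pixel (x, y) 0-based at img[x+1, y+1, ].
# This matches EBImage's storage order, so EBImage::Image(img,
# colormode = "Color") wraps an array without copying semantics changing.
#
# Shape helpers (idx_*) compute 1-based linear indices into one image
# plane; painting happens in the caller's loop so the image array stays
# local and R modifies it in place instead of copying per primitive.

new_canvas <- function(width, height, color = c(1, 1, 1)) {
  arr <- array(0, dim = c(width, height, 3L))
  arr[, , 1L] <- color[1L]
  arr[, , 2L] <- color[2L]
  arr[, , 3L] <- color[3L]
  arr
}

# Clip 0-based pixel coordinates and convert to linear plane indices.
idx_from_xy <- function(dm, xs, ys) {
  keep <- xs >= 0 & xs < dm[1L] & ys >= 0 & ys < dm[2L]
  xs[keep] + as.double(dm[1L]) * ys[keep] + 1
}

idx_disc <- function(dm, cx, cy, r) {
  xs <- floor(cx - r):ceiling(cx + r)
  ys <- floor(cy - r):ceiling(cy + r)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  idx_from_xy(dm, gx[keep], gy[keep])
}

idx_ring <- function(dm, cx, cy, r, thickness = 2) {
  xs <- floor(cx - r - thickness):ceiling(cx + r + thickness)
  ys <- floor(cy - r - thickness):ceiling(cy + r + thickness)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  d2 <- (gx - cx)^2 + (gy - cy)^2
  keep <- d2 <= r^2 & d2 >= (r - thickness)^2
  idx_from_xy(dm, gx[keep], gy[keep])
}

idx_rect <- function(dm, x0, y0, x1, y1) {
  xs <- floor(x0):ceiling(x1)
  ys <- floor(y0):ceiling(y1)
  idx_from_xy(dm, rep(xs, times = length(ys)), rep(ys, each = length(xs)))
}

idx_ellipse <- function(dm, cx, cy, rx, ry, theta = 0) {
  r <- max(rx, ry)
  xs <- floor(cx - r):ceiling(cx + r)
  ys <- floor(cy - r):ceiling(cy + r)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  dx <- gx - cx; dy <- gy - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / rx)^2 + (v / ry)^2 <= 1
  idx_from_xy(dm, gx[keep], gy[keep])
}

# Paint one flat color at plane indices, all three channels.
paint <- function(img, idx, color) {
  if (!length(idx)) return(img)
  plane <- as.double(dim(img)[1L]) * dim(img)[2L]
  img[idx] <- color[1L]
  img[idx + plane] <- color[2L]
  img[idx + 2 * plane] <- color[3L]
  img
}

# Single-primitive conveniences (each costs one array copy; fine for a
# handful of calls, use idx_* + paint loops for dense drawing).
draw_disc <- function(img, cx, cy, r, color)
  paint(img, idx_disc(dim(img), cx, cy, r), color)

draw_ring <- function(img, cx, cy, r, color, thickness = 2)
  paint(img, idx_ring(dim(img), cx, cy, r, thickness), color)

draw_rect <- function(img, x0, y0, x1, y1, color)
  paint(img, idx_rect(dim(img), x0, y0, x1, y1), color)

draw_ellipse <- function(img, cx, cy, rx, ry, color, theta = 0)
  paint(img, idx_ellipse(dim(img), cx, cy, rx, ry, theta), color)

# Luminance (Rec. 709) of an image array, as a width x height matrix.
luminance <- function(img) {
  0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear sampling of `img` at fractional 0-based coordinates (sx, sy).
# Points outside the image take `fill`. Returns an n x 3 matrix.
# Integer flat indexing and chunked evaluation keep this fast and
# memory-bounded on multi-megapixel photos.
bilinear_sample <- function(img, sx, sy, fill = c(1, 1, 1)) {
  w <- dim(img)[1L]; h <- dim(img)[2L]
  n <- length(sx)
  if (3 * as.double(w) * h >= .Machine$integer.max)
    stop("image too large for flat integer indexing", call. = FALSE)
  out <- matrix(rep(fill, each = n), nrow = n, ncol = 3L)
  chunk <- 2000000L
  for (lo in seq.int(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    cx <- sx[lo:hi]; cy <- sy[lo:hi]
    inside <- cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
    all_in <- all(inside)
    x <- if (all_in) cx else cx[inside]
    y <- if (all_in) cy else cy[inside]
    if (!length(x)) next
    x0 <- as.integer(x); y0 <- as.integer(y)     # floor: coords >= 0
    fx <- x - x0; fy <- y - y0
    x1 <- pmin.int(x0 + 1L, w - 1L); y1 <- pmin.int(y0 + 1L, h - 1L)
    r0 <- w * y0; r1 <- w * y1
    i00 <- x0 + r0 + 1L; i10 <- x1 + r0 + 1L
    i01 <- x0 + r1 + 1L; i11 <- x1 + r1 + 1L
    plane <- w * h
    for (ch in 1:3) {
      base <- (ch - 1L) * plane
      v <- img[base + i00] * ((1 - fx) * (1 - fy))
      v <- v + img[base + i10] * (fx * (1 - fy))
      v <- v + img[base + i01] * ((1 - fx) * fy)
      v <- v + img[base + i11] * (fx * fy)
      dest <- if (all_in) lo:hi else (lo:hi)[inside]
      out[dest + (ch - 1L) * n] <- v
    }
  }
  out
}
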
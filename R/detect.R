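# Card detection: locate the four fiducial corner dots, orient the card
# by their center colors, rigidly rotate + crop, validate geometry, then
# read the mean gray of each spot window and decode mark patterns.

# Geometric tolerances. "Within 5%" for the diagonal check means
# shorter/longer >= 0.95; the aspect check compares the cropped ratio to
# the configured ratio with 5% relative tolerance. Both correspond to an
# out-of-plane tilt of acos(0.95) = 18.19 degrees under orthographic
# foreshortening.
DIAG_RATIO_MIN <- 0.95
ASPECT_TOL     <- 0.05
MARK_THRESHOLD_DEFAULT <- 128   # mean gray (0-255) below which a spot is inked
MIN_DOT_AREA_PX  <- 80          # components smaller than this are color noise
MIN_DOT_DIAMETER_PX <- 60       # below this, decoding reliability degrades

# Classed conditions so the batch driver can map failures to CSV error
# codes without string matching.
sm_error <- function(code, message) {
  stop(structure(class = c("spotmark_error", "error", "condition"),
                 list(message = paste0(code, ": ", message),
                      call = NULL, code = code)))
}

sm_warn <- function(code, message) {
  warning(structure(class = c("spotmark_warning", "warning", "condition"),
                    list(message = paste0(code, ": ", message),
                         call = NULL, code = code)))
}

#' Percentile contrast stretch
#'
#' The brightness/contrast adjustment applied before color thresholding
#' and before spot reading: a linear stretch mapping the 0.5% and 99.5%
#' luminance percentiles to 0 and 1. Deterministic stand-in for an
#' interactive auto-contrast.
#'
#' @param img A `w x h x 3` array in `[0, 1]`.
#' @return The stretched array.
#' @export
stretch_contrast <- function(img) {
  lum <- luminance(img)
  # percentiles from a deterministic stride subsample on large images:
  # indistinguishable for contrast purposes, much cheaper than a full
  # sort of a multi-megapixel frame
  n <- length(lum)
  if (n > 500000L) lum <- lum[seq.int(1L, n, by = n %/% 400000L)]
  q <- stats::quantile(lum, c(0.005, 0.995), names = FALSE)
  if (q[2L] - q[1L] < 1e-6) return(img)
  clamp01((img - q[1L]) / (q[2L] - q[1L]))
}

# HSV box masks for the two fiducial palettes, wide enough that the
# rendered palette colors pass under +/-30% illumination scaling.
# Saturation/value prefilter first, hue only on the survivors: on a
# typical photo the dots are a small fraction of the frame.
color_mask <- function(img, palette = c("blue", "pink")) {
  palette <- match.arg(palette)
  w <- dim(img)[1L]; h <- dim(img)[2L]
  box <- if (palette == "blue") c(hmin = 0.52, hmax = 0.78,
                                  smin = 0.35, vmin = 0.15)
  else c(hmin = 0.83, hmax = 0.98, smin = 0.25, vmin = 0.25)
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  cand <- which(mx >= box["vmin"] & (mx - mn) >= box["smin"] * mx)
  keep <- matrix(FALSE, nrow = w, ncol = h)
  if (!length(cand)) return(keep)
  rr <- r[cand]; gg <- g[cand]; bb <- b[cand]
  dd <- (mx - mn)[cand]; mm <- mx[cand]
  hue <- numeric(length(cand))
  ir <- mm == rr
  ig <- !ir & mm == gg
  ib <- !ir & !ig
  hue[ir] <- (((gg[ir] - bb[ir]) / dd[ir]) %% 6) / 6
  hue[ig] <- ((bb[ig] - rr[ig]) / dd[ig] + 2) / 6
  hue[ib] <- ((rr[ib] - gg[ib]) / dd[ib] + 4) / 6
  keep[cand[hue >= box["hmin"] & hue <= box["hmax"]]] <- TRUE
  keep
}

#' Find the fiducial corner dots in a photograph
#'
#' Applies the palette color mask to a contrast-stretched copy of the
#' image, labels connected components, and keeps the four largest —
#' smaller colored noise is ignored. Fails with `CORNERS_NOT_FOUND` if
#' fewer than four plausible components exist; dots smaller than the
#' recommended 60 px diameter raise a `DOT_TOO_SMALL` warning but
#' processing continues.
#'
#' @param img A `w x h x 3` photo array in `[0, 1]`.
#' @param palette `"blue"` or `"pink"`.
#' @return A data.frame with one row per dot: `cx`, `cy` (0-based pixel
#'   centroids), `area`, `eqdiam`.
#' @export
find_corner_dots <- function(img, palette = "blue") {
  mask <- color_mask(stretch_contrast(img), palette)
  lab <- EBImage::bwlabel(EBImage::Image(mask + 0))
  labv <- as.integer(lab)
  areas <- tabulate(labv[labv > 0L])
  cand <- which(areas >= MIN_DOT_AREA_PX)
  if (length(cand) < 4L)
    sm_error("CORNERS_NOT_FOUND",
             sprintf("found %d candidate dot(s), need 4", length(cand)))
  top4 <- cand[order(areas[cand], decreasing = TRUE)][1:4]
  w <- dim(img)[1L]
  idx <- which(labv %in% top4)
  xs <- (idx - 1L) %% w
  ys <- (idx - 1L) %/% w
  grp <- match(labv[idx], top4)
  out <- data.frame(
    cx = as.vector(tapply(xs, grp, mean)),
    cy = as.vector(tapply(ys, grp, mean)),
    area = areas[top4])
  out$eqdiam <- 2 * sqrt(out$area / pi)
  # the center disc is punched out of the mask, so the annulus
  # equivalent diameter underestimates the true dot diameter by
  # sqrt(8/9); correct before comparing to the size guideline
  if (any(out$eqdiam / sqrt(8 / 9) < MIN_DOT_DIAMETER_PX))
    sm_warn("DOT_TOO_SMALL",
            "corner dot(s) below the recommended 60 px diameter")
  out
}

# Mean RGB over a disc; coords 0-based.
sample_disc_color <- function(img, cx, cy, r) {
  w <- dim(img)[1L]; h <- dim(img)[2L]
  xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  gx <- gx[keep]; gy <- gy[keep]
  vapply(1:3, function(ch) mean(img[cbind(gx + 1L, gy + 1L, ch)]), 1)
}

# Reference corner-center colors for classification (idealized, the
# nearest-neighbour rule tolerates the renderer's slightly desaturated
# inks and moderate illumination changes).
.center_refs <- rbind(red = c(1, 0, 0), green = c(0, 1, 0),
                      white = c(1, 1, 1), black = c(0, 0, 0))

classify_center_color <- function(rgb, tie_tol = 0.02) {
  d <- sqrt(rowSums(sweep(.center_refs, 2L, rgb)^2))
  o <- order(d)
  if (d[o[2L]] - d[o[1L]] < tie_tol) return(NA_character_)
  rownames(.center_refs)[o[1L]]
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Label the corner dots by center color and recover the card rotation
#'
#' Samples the small center disc of each dot, classifies it as one of
#' red/green/white/black, and computes the in-plane rotation from the
#' angles of the two diagonals (red-center to black-center, green-center
#' to white-center). The card convention places red top-left, green
#' top-right, white bottom-left, black bottom-right; the recovered
#' rotation is the angle the photograph must be rotated by so red ends
#' up top-left. No configuration is needed for this step.
#'
#' @param img The photo array.
#' @param dots Data.frame from [find_corner_dots()].
#' @return A list with `corners` (the dots data.frame with a `color`
#'   column, rows named by corner) and `rotation_deg`.
#' @export
identify_orientation <- function(img, dots) {
  cols <- character(4L)
  for (i in 1:4) {
    rgb <- sample_disc_color(img, dots$cx[i], dots$cy[i], dots$eqdiam[i] / 6)
    cols[i] <- classify_center_color(rgb)
  }
  if (anyNA(cols) || length(unique(cols)) != 4L)
    sm_error("CENTERS_UNRESOLVED",
             paste("corner center colors are not a permutation of",
                   "red/green/white/black:", paste(cols, collapse = ", ")))
  names(cols) <- NULL
  get <- function(col) as.numeric(dots[match(col, cols), c("cx", "cy")])
  red <- get("red"); black <- get("black")
  green <- get("green"); white <- get("white")
  # diagonal directions; in an upright card their circular mean is 90
  # degrees (red->black points down-right, green->white down-left)
  th1 <- atan2(black[2L] - red[2L], black[1L] - red[1L]) * 180 / pi
  th2 <- atan2(white[2L] - green[2L], white[1L] - green[1L]) * 180 / pi
  mean_dir <- th1 + ((th2 - th1) %% 360) / 2
  rotation <- wrap180(90 - mean_dir)
  corners <- dots[match(c("red", "green", "white", "black"), cols), ]
  corners$color <- c("red", "green", "white", "black")
  rownames(corners) <- c("top_left", "top_right", "bottom_left",
                         "bottom_right")
  list(corners = corners, rotation_deg = rotation)
}

# Rigid rotation of points about a center; angle in degrees, y-down
# coordinates (positive angle rotates screen-clockwise in math terms,
# consistently for points and image content).
rotate_points <- function(xy, angle_deg, center) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  sweep(sweep(xy, 2L, center) %*% t(R), 2L, center, `+`)
}

#' Rotate, crop and validate a located card
#'
#' Applies the three geometric validation checks in order and, between
#' the first and second, rigidly rotates the photograph (bilinear
#' interpolation, no perspective correction) so the red-centered dot is
#' top-left, then crops to the bounding box of the four corner-dot
#' centers:
#'
#' 1. `DIAGONAL_MISMATCH` — the two diagonals between opposing corner
#'    dots must be within 5% of each other (shorter/longer >= 0.95).
#' 2. `ASPECT_MISMATCH` — the cropped aspect ratio must be within 5% of
#'    the configured card ratio.
#' 3. `ORIENTATION_CHECK_FAILED` — the central portion of the top-left
#'    dot must be red.
#'
#' @param img The photo array.
#' @param oriented Result of [identify_orientation()].
#' @param layout The card's `spotcard_layout` (from its configuration
#'   file).
#' @return A `spotcard_detection`: labeled corner centers, rotation,
#'   the rectified crop, per-axis mm-per-px scales, `diag_ratio` and
#'   `aspect_error`.
#' @export
rectify_and_validate <- function(img, oriented, layout) {
  co <- oriented$corners
  d1 <- sqrt(sum((co["top_left", c("cx", "cy")] -
                    co["bottom_right", c("cx", "cy")])^2))
  d2 <- sqrt(sum((co["top_right", c("cx", "cy")] -
                    co["bottom_left", c("cx", "cy")])^2))
  diag_ratio <- min(d1, d2) / max(d1, d2)
  if (diag_ratio < DIAG_RATIO_MIN)
    sm_error("DIAGONAL_MISMATCH",
             sprintf("diagonal ratio %.4f < %.2f (card too tilted?)",
                     diag_ratio, DIAG_RATIO_MIN))

  pts <- as.matrix(co[, c("cx", "cy")])
  ctr <- colMeans(pts)
  ang <- oriented$rotation_deg
  rot <- rotate_points(pts, ang, ctr)
  x0 <- min(rot[, 1L]); x1 <- max(rot[, 1L])
  y0 <- min(rot[, 2L]); y1 <- max(rot[, 2L])
  span_x <- x1 - x0; span_y <- y1 - y0

  # cropped aspect measured from the mean opposite-edge lengths of the
  # dot-center rectangle: equals the bounding-box ratio for a flat card
  # but cancels (to first order) the near/far-edge magnification a real
  # camera adds under tilt, keeping the 5% tolerance aligned with the
  # orthographic cos(tilt) model
  edge <- function(a, b) sqrt(sum((pts[a, ] - pts[b, ])^2))
  wid <- (edge(1L, 2L) + edge(3L, 4L)) / 2   # TL-TR, BL-BR
  hei <- (edge(1L, 3L) + edge(2L, 4L)) / 2   # TL-BL, TR-BR
  aspect_obs <- wid / hei
  aspect_th <- layout$card_width_mm / layout$card_height_mm
  aspect_error <- abs(aspect_obs - aspect_th) / aspect_th
  if (aspect_error > ASPECT_TOL)
    sm_error("ASPECT_MISMATCH",
             sprintf("cropped aspect %.4f vs configured %.4f (error %.1f%%)",
                     aspect_obs, aspect_th, 100 * aspect_error))

  out_w <- as.integer(round(span_x)) + 1L
  out_h <- as.integer(round(span_y)) + 1L
  u <- rep(0:(out_w - 1L), times = out_h)
  v <- rep(0:(out_h - 1L), each = out_w)
  a <- -ang * pi / 180  # inverse map: output frame back to source
  sx <- (u + x0 - ctr[1L]) * cos(a) - (v + y0 - ctr[2L]) * sin(a) + ctr[1L]
  sy <- (u + x0 - ctr[1L]) * sin(a) + (v + y0 - ctr[2L]) * cos(a) + ctr[2L]
  samp <- bilinear_sample(img, sx, sy)
  rectified <- array(samp, dim = c(out_w, out_h, 3L))

  # check 3: the central portion of the top-left dot is red
  tl <- rot[rownames(co) == "top_left", ] - c(x0, y0)
  r_center <- co["top_left", "eqdiam"] / 6
  tl_col <- classify_center_color(
    sample_disc_color(rectified, tl[1L], tl[2L], r_center))
  if (is.na(tl_col) || tl_col != "red")
    sm_error("ORIENTATION_CHECK_FAILED",
             paste0("top-left dot center reads '",
                    if (is.na(tl_col)) "?" else tl_col, "', expected red"))

  structure(list(
    corner_centers = co,
    rotation_deg = ang,
    rectified = rectified,
    crop_span_px = c(x = span_x, y = span_y),
    mm_per_px = layout$card_width_mm / span_x,
    mm_per_px_y = layout$card_height_mm / span_y,
    diag_ratio = diag_ratio,
    aspect_error = aspect_error),
    class = "spotcard_detection")
}

#' @export
print.spotcard_detection <- function(x, ...) {
  cat("<spotcard_detection> rotation ", round(x$rotation_deg, 2),
      " deg, crop ", round(x$crop_span_px[1L]), " x ",
      round(x$crop_span_px[2L]), " px, ",
      signif(x$mm_per_px, 4), " mm/px, diag ratio ",
      round(x$diag_ratio, 4), ", aspect error ",
      round(100 * x$aspect_error, 2), "%\n", sep = "")
  invisible(x)
}

#' Read the mean gray value of one spot window
#'
#' Samples the central window covering 25% of the (scaled) spot width
#' and height — tolerant of small positioning discrepancies — and
#' returns its mean gray value on the 0-255 scale.
#'
#' @param gray A `w x h` luminance matrix of the rectified crop in
#'   `[0, 1]` (already contrast-stretched).
#' @param spot One row of `layout$spots` (template coordinates).
#' @param sx,sy Template-to-crop linear scales for x and y.
#' @return Mean gray in `[0, 255]`.
#' @export
read_spot <- function(gray, spot, sx, sy) {
  cx <- spot$x * sx; cy <- spot$y * sy
  hw <- spot$width * sx * 0.25 / 2
  hh <- spot$height * sy * 0.25 / 2
  xs <- round(cx - hw):round(cx + hw)
  ys <- round(cy - hh):round(cy + hh)
  if (min(xs) < 0 || min(ys) < 0 || max(xs) >= nrow(gray) ||
      max(ys) >= ncol(gray))
    sm_error("SPOT_OUT_OF_BOUNDS", "spot window falls outside the crop")
  mean(gray[xs + 1L, ys + 1L]) * 255
}

#' Read all spot windows of a rectified card
#'
#' @param detected A `spotcard_detection`.
#' @param layout The card layout.
#' @return Numeric vector of per-spot mean gray values (0-255), in
#'   `layout$spots` order.
#' @export
read_spots <- function(detected, layout) {
  gray <- luminance(stretch_contrast(detected$rectified))
  sx <- detected$crop_span_px["x"] / layout$card_width_px
  sy <- detected$crop_span_px["y"] / layout$card_height_px
  vapply(seq_len(nrow(layout$spots)), function(i)
    read_spot(gray, layout$spots[i, ], sx, sy), 1)
}

#' Decode spot readings into category values
#'
#' A spot is marked when its mean gray falls below `threshold`. Explicit
#' categories decode to the unique marked value; integer-range
#' categories decode row by row, most-significant first. A category (or
#' any digit row) with no mark decodes to `"MISSING"`, with more than
#' one mark to `"AMBIGUOUS"` — both are soft outcomes recorded per
#' category, never failures of the whole image.
#'
#' @param spot_means Per-spot mean gray values from [read_spots()].
#' @param layout The card layout.
#' @param threshold Marked/unmarked cutoff on mean gray (default 128).
#' @return A `spotcard_reading`: named `values`, raw `spot_means`, and
#'   a `status`.
#' @export
decode_reading <- function(spot_means, layout,
                           threshold = MARK_THRESHOLD_DEFAULT) {
  marked <- spot_means < threshold
  values <- character(length(layout$categories))
  names(values) <- vapply(layout$categories, `[[`, "", "name")
  for (ci in seq_along(layout$categories)) {
    cs <- layout$categories[[ci]]
    in_cat <- layout$spots$category_index == ci
    if (cs$mode == "explicit") {
      hit <- which(in_cat & marked)
      values[ci] <- if (length(hit) == 0L) "MISSING"
        else if (length(hit) > 1L) "AMBIGUOUS"
        else layout$spots$value_label[hit]
    } else {
      k <- category_rows(cs)
      digits <- integer(k)
      status <- "ok"
      for (r in 0:(k - 1L)) {
        hit <- which(in_cat & layout$spots$row_index == r & marked)
        if (length(hit) == 0L) { status <- "MISSING"; break }
        if (length(hit) > 1L) { status <- "AMBIGUOUS"; break }
        digits[r + 1L] <- as.integer(layout$spots$value_label[hit])
      }
      values[ci] <- if (status == "ok")
        as.character(decode_integer(digits)) else status
    }
  }
  structure(list(values = values, spot_means = spot_means, status = "ok"),
            class = "spotcard_reading")
}

#' @export
print.spotcard_reading <- function(x, ...) {
  cat("<spotcard_reading> ",
      paste(names(x$values), x$values, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Detect and decode the card in one photograph
#'
#' The full per-image pipeline: find the corner dots, orient by center
#' colors, rotate/crop/validate, read and decode the spots. Any
#' validation failure is returned as a machine-readable error code
#' rather than thrown, so batch processing can record it and continue.
#'
#' @param img A photo array (`w x h x 3`, values in `[0, 1]`) or a path
#'   to a JPEG/PNG/TIFF file.
#' @param layout The card's `spotcard_layout`.
#' @param palette Fiducial palette; defaults to the layout's.
#' @param threshold Marked/unmarked mean-gray cutoff.
#' @return A `spotcard_result` with elements `ok`, `error_code`,
#'   `error_message`, `detection`, `reading`.
#' @export
read_card <- function(img, layout, palette = layout$dot_palette,
                      threshold = MARK_THRESHOLD_DEFAULT) {
  if (is.character(img)) img <- load_photo(img)
  res <- list(ok = FALSE, error_code = "", error_message = "",
              detection = NULL, reading = NULL)
  class(res) <- "spotcard_result"
  out <- tryCatch({
    dots <- find_corner_dots(img, palette)
    oriented <- identify_orientation(img, dots)
    detected <- rectify_and_validate(img, oriented, layout)
    means <- read_spots(detected, layout)
    reading <- decode_reading(means, layout, threshold)
    res$ok <- TRUE
    res$detection <- detected
    res$reading <- reading
    res
  }, spotmark_error = function(e) {
    res$error_code <- e$code
    res$error_message <- conditionMessage(e)
    res
  })
  out
}

#' @export
print.spotcard_result <- function(x, ...) {
  if (x$ok) {
    cat("<spotcard_result> ok\n")
    print(x$reading)
  } else {
    cat("<spotcard_result> ERROR ", x$error_message, "\n", sep = "")
  }
  invisible(x)
}

#' Load a photograph as a pixel array
#'
#' Reads JPEG, PNG or TIFF into the package's `w x h x 3` array
#' convention.
#'
#' @param path Image file path.
#' @return A `w x h x 3` array in `[0, 1]`.
#' @export
load_photo <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                jpg = , jpeg = jpeg::readJPEG(path),
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image extension '.", ext, "'",
                     call. = FALSE))
  from_reader_array(arr)
}
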
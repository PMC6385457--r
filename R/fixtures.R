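# Synthetic ground-truth photographs. A rendered card is placed on a
# background under a pinhole (projective) camera model: in-plane
# rotation, out-of-plane tilt about a chosen axis, configurable render
# scale, optional noise / illumination gradient / distractors /
# occlusions, and optional injected EXIF. The ground truth travels with
# the image, so every downstream module can be tested without real
# photographs.

#' Specify a synthetic card photograph
#'
#' Captures everything needed to render one ground-truth fixture. With
#' the default camera distance of 10 card widths the small-tilt
#' foreshortening closely follows the orthographic cos(tilt) model;
#' `camera_distance_cards = Inf` gives exactly orthographic projection.
#'
#' @param layout A `spotcard_layout`.
#' @param marks Named mark set (category name -> value), or `NULL` for
#'   an unmarked card.
#' @param rotation_deg In-plane rotation of the card in the photo.
#' @param tilt_deg Out-of-plane tilt in degrees.
#' @param tilt_axis `"x"`, `"y"` or `"diagonal"` (the card's diagonal).
#' @param px_per_mm Render scale of the photo at the card plane. The
#'   default 8 px/mm puts the 10 mm corner dots at 80 px, above the
#'   60 px floor needed for reliable decoding.
#' @param background `"plain"` or `"textured"`.
#' @param distractor_px Diameter of an extraneous palette-colored disc
#'   placed in the background (0 = none).
#' @param occlude_corner `NULL`, or one of `"top_left"`, `"top_right"`,
#'   `"bottom_left"`, `"bottom_right"`: a leaf-green ellipse is drawn
#'   over that corner dot.
#' @param reflection_corner Like `occlude_corner`, but a saturated white
#'   patch emulating a specular reflection on a laminated card.
#' @param flower_radius_mm Radius of a bright synthetic flower disc
#'   drawn over the card's clearance (0 = none). A matt-black backing
#'   disc fills the clearance behind it.
#' @param noise_sigma Additive Gaussian pixel noise (0-1 scale).
#' @param illumination_gradient Multiplicative left-to-right ramp
#'   amplitude (0 = flat; 0.3 = +/-15% across the frame).
#' @param exif Optional list with any of `datetime`, `latitude`,
#'   `longitude`, `altitude` to embed when the fixture is written as
#'   JPEG.
#' @param camera_distance_cards Camera distance in card widths
#'   (`Inf` = orthographic).
#' @param seed Seed for the stochastic elements (noise, texture).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(layout, marks = NULL, rotation_deg = 0,
                         tilt_deg = 0, tilt_axis = c("x", "y", "diagonal"),
                         px_per_mm = 8, background = c("plain", "textured"),
                         distractor_px = 0, occlude_corner = NULL,
                         reflection_corner = NULL, flower_radius_mm = 0,
                         noise_sigma = 0, illumination_gradient = 0,
                         exif = NULL, camera_distance_cards = 10, seed = 0L) {
  tilt_axis <- match.arg(tilt_axis)
  background <- match.arg(background)
  structure(list(layout = layout, marks = marks,
                 rotation_deg = rotation_deg, tilt_deg = tilt_deg,
                 tilt_axis = tilt_axis, px_per_mm = px_per_mm,
                 background = background, distractor_px = distractor_px,
                 occlude_corner = occlude_corner,
                 reflection_corner = reflection_corner,
                 flower_radius_mm = flower_radius_mm,
                 noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 exif = exif, camera_distance_cards = camera_distance_cards,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Direct linear transform: exact homography through 4 correspondences.
solve_homography <- function(src, dst) {
  A <- matrix(0, 8L, 8L)
  b <- numeric(8L)
  for (i in 1:4) {
    x <- src[i, 1L]; y <- src[i, 2L]
    u <- dst[i, 1L]; v <- dst[i, 2L]
    A[2L * i - 1L, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2L * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2L * i - 1L] <- u
    b[2L * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3L, 3L, byrow = TRUE)
}

apply_homography <- function(H, x, y) {
  d <- H[3L, 1L] * x + H[3L, 2L] * y + H[3L, 3L]
  list(x = (H[1L, 1L] * x + H[1L, 2L] * y + H[1L, 3L]) / d,
       y = (H[2L, 1L] * x + H[2L, 2L] * y + H[2L, 3L]) / d)
}

# Rodrigues rotation of in-plane points (z = 0) about an in-plane axis.
tilt_points_3d <- function(x, y, axis_xy, tilt_rad) {
  a <- axis_xy / sqrt(sum(axis_xy^2))
  # component along the axis stays; the perpendicular one rotates out
  along <- x * a[1L] + y * a[2L]
  perp <- -x * a[2L] + y * a[1L]
  cbind(X = along * a[1L] - perp * cos(tilt_rad) * a[2L],
        Y = along * a[2L] + perp * cos(tilt_rad) * a[1L],
        Z = perp * sin(tilt_rad))
}

# Forward projection of card-image pixel coordinates to photo
# coordinates (before translation to the photo frame).
project_card_points <- function(spec, card_dim_px, tx, ty) {
  ppm_t <- spec$layout$px_per_mm
  cx <- (card_dim_px[1L] - 1) / 2; cy <- (card_dim_px[2L] - 1) / 2
  xm <- (tx - cx) / ppm_t
  ym <- (ty - cy) / ppm_t
  # tilt about the card's own axis first, then spin the tilted card in
  # the image plane
  axis <- switch(spec$tilt_axis,
                 x = c(1, 0), y = c(0, 1),
                 diagonal = c(spec$layout$card_width_mm,
                              spec$layout$card_height_mm))
  p3 <- tilt_points_3d(xm, ym, axis, spec$tilt_deg * pi / 180)
  th <- spec$rotation_deg * pi / 180
  X <- p3[, "X"] * cos(th) - p3[, "Y"] * sin(th)
  Y <- p3[, "X"] * sin(th) + p3[, "Y"] * cos(th)
  d <- spec$camera_distance_cards * spec$layout$card_width_mm
  s <- spec$px_per_mm
  if (is.finite(d)) {
    list(x = s * d * X / (d - p3[, "Z"]),
         y = s * d * Y / (d - p3[, "Z"]))
  } else {
    list(x = s * X, y = s * Y)
  }
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Render a synthetic card photograph with its ground truth
#'
#' Renders the card (with inked marks and optional synthetic flower),
#' maps it onto the background with the exact plane-to-plane homography
#' implied by the fixture's rotation/tilt/scale/camera model, then
#' applies distractors, occlusions, illumination and noise. Identical
#' specs render identical images.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `image` (photo array), `truth` (list with the
#'   expected per-category values, expected orthographic diagonal
#'   ratio `cos(tilt)`, flower geometry and the spec's parameters).
#' @export
render_fixture <- function(spec) {
  layout <- spec$layout
  card <- render_card(layout, marks = spec$marks)
  org <- attr(card, "card_origin_px")
  if (spec$flower_radius_mm > 0) {
    if (layout$flower_diameter_mm <= 0)
      stop("layout has no flower clearance to draw a flower in",
           call. = FALSE)
    fx <- org[1L] + layout$flower_centroid_x_px
    fy <- org[2L] + layout$flower_centroid_y_px
    ppm_t <- layout$px_per_mm
    card <- draw_disc(card, fx, fy,
                      (layout$flower_diameter_mm + CLEARANCE_PAD_MM) / 2 *
                        ppm_t, c(0.05, 0.05, 0.05))    # matt-black backing
    card <- draw_disc(card, fx, fy, spec$flower_radius_mm * ppm_t,
                      c(0.97, 0.95, 0.90))             # flower disc
  }
  cd <- dim(card)[1:2]

  # project the card image corners to size the photo
  crn <- project_card_points(spec, cd,
                             c(0, cd[1L] - 1, 0, cd[1L] - 1),
                             c(0, 0, cd[2L] - 1, cd[2L] - 1))
  border <- 40
  w <- ceiling(max(crn$x) - min(crn$x)) + 2 * border
  h <- ceiling(max(crn$y) - min(crn$y)) + 2 * border
  off_x <- border - min(crn$x)
  off_y <- border - min(crn$y)

  dst <- cbind(crn$x + off_x, crn$y + off_y)
  src <- cbind(c(0, cd[1L] - 1, 0, cd[1L] - 1),
               c(0, 0, cd[2L] - 1, cd[2L] - 1))
  H <- solve_homography(src, dst)
  Hinv <- solve(H)

  bg_col <- c(0.32, 0.42, 0.30)
  img <- with_seed(spec$seed, {
    img <- new_canvas(w, h, bg_col)
    if (spec$background == "textured") {
      # coarse mottle: low-resolution noise field, nearest upsampled
      gw <- ceiling(w / 16); gh <- ceiling(h / 16)
      field <- matrix(stats::rnorm(gw * gh, 0, 0.05), gw, gh)
      big <- field[pmin(gw, (0:(w - 1)) %/% 16 + 1),
                   pmin(gh, (0:(h - 1)) %/% 16 + 1)]
      for (ch in 1:3) img[, , ch] <- clamp01(img[, , ch] + big)
    }

    # inverse-map the quadrilateral covered by the card
    x0 <- max(0L, floor(min(dst[, 1L]))); x1 <- min(w - 1L, ceiling(max(dst[, 1L])))
    y0 <- max(0L, floor(min(dst[, 2L]))); y1 <- min(h - 1L, ceiling(max(dst[, 2L])))
    gx <- rep(x0:x1, times = y1 - y0 + 1L)
    gy <- rep(y0:y1, each = x1 - x0 + 1L)
    sc <- apply_homography(Hinv, gx, gy)
    in_card <- sc$x >= 0 & sc$x <= cd[1L] - 1 & sc$y >= 0 & sc$y <= cd[2L] - 1
    samp <- bilinear_sample(card, sc$x[in_card], sc$y[in_card])
    lin <- gx[in_card] + as.double(w) * gy[in_card] + 1
    plane <- as.double(w) * h
    for (ch in 1:3) img[lin + (ch - 1) * plane] <- samp[, ch]

    # distractor: an extraneous palette-colored object in the background
    if (spec$distractor_px > 0) {
      img <- draw_disc(img, border / 2, border / 2, spec$distractor_px / 2,
                       palette_rgb(layout$dot_palette))
    }
    corner_photo <- function(which) {
      p <- corner_positions_px(layout)[which, ]
      q <- project_card_points(spec, cd, org[1L] + p["x"], org[2L] + p["y"])
      c(q$x + off_x, q$y + off_y)
    }
    dot_px <- layout$dot_diameter_mm * spec$px_per_mm
    if (!is.null(spec$occlude_corner)) {
      q <- corner_photo(spec$occlude_corner)
      img <- draw_ellipse(img, q[1L], q[2L], dot_px * 0.9, dot_px * 0.6,
                          c(0.20, 0.45, 0.15), theta = 0.5)
    }
    if (!is.null(spec$reflection_corner)) {
      q <- corner_photo(spec$reflection_corner)
      img <- draw_disc(img, q[1L], q[2L], dot_px * 0.55, c(1, 1, 1))
    }
    if (spec$illumination_gradient > 0) {
      g <- spec$illumination_gradient
      ramp <- 1 - g / 2 + g * (0:(w - 1)) / max(w - 1, 1)
      for (ch in 1:3) img[, , ch] <- clamp01(img[, , ch] * ramp)
    }
    if (spec$noise_sigma > 0) {
      img <- clamp01(img + array(stats::rnorm(length(img), 0,
                                              spec$noise_sigma), dim(img)))
    }
    img
  })

  expected <- expected_values(layout, spec$marks)
  truth <- list(
    expected_values = expected,
    expected_diag_ratio = cos(spec$tilt_deg * pi / 180),
    rotation_deg = spec$rotation_deg,
    tilt_deg = spec$tilt_deg,
    tilt_axis = spec$tilt_axis,
    px_per_mm = spec$px_per_mm,
    flower_radius_mm = spec$flower_radius_mm,
    flower_area_mm2 = if (spec$flower_radius_mm > 0)
      pi * spec$flower_radius_mm^2 else NA_real_,
    flower_perimeter_mm = if (spec$flower_radius_mm > 0)
      2 * pi * spec$flower_radius_mm else NA_real_,
    exif = spec$exif,
    seed = spec$seed)
  list(image = img, truth = truth)
}

# Expected decoded value per category: marked categories decode to their
# value, unmarked ones to MISSING.
expected_values <- function(layout, marks) {
  vals <- vapply(layout$categories, function(cs) {
    if (!is.null(marks) && cs$name %in% names(marks)) {
      v <- marks[[cs$name]]
      if (cs$mode == "integer_range") as.character(as.integer(v))
      else as.character(v)
    } else "MISSING"
  }, "")
  names(vals) <- vapply(layout$categories, `[[`, "", "name")
  vals
}

#' Write a fixture to disk as a photograph plus ground-truth sidecar
#'
#' Saves `<stem>.jpg` (EXIF injected when the spec carries it) or
#' `<stem>.png`/`.tif`, and `<stem>.json` holding the ground truth.
#'
#' @param spec A [fixture_spec()].
#' @param stem Output path without extension.
#' @param format `"jpg"`, `"png"` or `"tif"`.
#' @param quality JPEG quality (0-1).
#' @return Invisibly, the rendered fixture (list `image`, `truth`).
#' @export
write_fixture <- function(spec, stem, format = c("jpg", "png", "tif"),
                          quality = 0.95) {
  format <- match.arg(format)
  fx <- render_fixture(spec)
  if (!dir.exists(dirname(stem)))
    dir.create(dirname(stem), recursive = TRUE)
  img_path <- paste0(stem, ".", format)
  switch(format,
         jpg = jpeg::writeJPEG(to_writer_array(fx$image), img_path,
                               quality = quality),
         png = png::writePNG(to_writer_array(fx$image), img_path),
         tif = tiff::writeTIFF(to_writer_array(fx$image), img_path,
                               reduce = TRUE))
  if (format == "jpg" && !is.null(spec$exif)) {
    e <- spec$exif
    inject_exif_jpeg(img_path, build_exif(
      datetime = e$datetime, latitude = e$latitude,
      longitude = e$longitude, altitude = e$altitude))
  }
  truth <- fx$truth
  truth$expected_values <- as.list(truth$expected_values)  # keep names
  jsonlite::write_json(truth, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(fx)
}

#' Sweep one fixture parameter and tabulate pipeline outcomes
#'
#' Renders one fixture per value of the swept parameter, runs the full
#' detection/decoding pipeline on each, and reports whether validation
#' passed and whether every category decoded to its ground-truth value.
#'
#' @param axis Name of the swept `fixture_spec` field: one of
#'   `"tilt_deg"`, `"rotation_deg"`, `"px_per_mm"`, `"noise_sigma"`.
#' @param values Numeric vector of parameter values.
#' @param base A [fixture_spec()] providing all other parameters.
#' @return A data.frame with one row per value: `value`, `ok`,
#'   `error_code`, `decoded_correct`, `diag_ratio`.
#' @export
sweep_fixture <- function(axis, values, base) {
  axis <- match.arg(axis, c("tilt_deg", "rotation_deg", "px_per_mm",
                            "noise_sigma"))
  rows <- lapply(values, function(v) {
    spec <- base
    spec[[axis]] <- v
    fx <- render_fixture(spec)
    res <- suppressWarnings(read_card(fx$image, spec$layout))
    correct <- res$ok &&
      identical(unname(res$reading$values[names(fx$truth$expected_values)]),
                unname(fx$truth$expected_values))
    data.frame(value = v, ok = res$ok,
               error_code = res$error_code,
               decoded_correct = correct,
               diag_ratio = if (res$ok) res$detection$diag_ratio else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
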
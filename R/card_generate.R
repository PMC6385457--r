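# Card geometry defaults. The template raster is laid out at 10 px/mm
# (254 dpi); all sizes below are in millimetres. card_width_px/height_px
# and every spot coordinate refer to the rectangle spanned by the four
# corner-dot CENTERS; the rendered image adds RENDER_MARGIN_MM of quiet
# zone around that rectangle so the dots are not clipped.
TEMPLATE_PX_PER_MM <- 10
SPOT_DIAMETER_MM   <- 5
SPOT_PITCH_MM      <- 7    # center-to-center, both axes
DOT_DIAMETER_MM    <- 10   # fiducial corner dots
CONTENT_MARGIN_MM  <- 8    # corner rectangle edge -> nearest spot center
GROUP_GAP_MM       <- 4    # vertical gap between category groups
LABEL_BLOCK_MM     <- 4    # height reserved for a category name line
CLEARANCE_PAD_MM   <- 6    # added to flower diameter for the clearance
RENDER_MARGIN_MM   <- 8    # quiet zone outside the corner-center rectangle
MAX_SPOTS_PER_ROW  <- 10L

INK_GRAY <- 20 / 255       # dry-wipe marker emulation
INK_AREA_FRACTION <- 0.8   # inked disc covers 80% of the spot area

palette_rgb <- function(palette) {
  switch(palette,
         blue = c(0.05, 0.15, 0.85),
         pink = c(0.95, 0.30, 0.65),
         stop("unknown palette '", palette, "'", call. = FALSE))
}

center_rgb <- function(color) {
  switch(color,
         red   = c(0.85, 0.08, 0.08),
         green = c(0.05, 0.65, 0.15),
         white = c(1, 1, 1),
         black = c(0.04, 0.04, 0.04),
         stop("unknown center color '", color, "'", call. = FALSE))
}

# Split a category into display rows of spot value labels.
category_display_rows <- function(cs) {
  if (cs$mode == "integer_range") {
    k <- category_rows(cs)
    lapply(seq_len(k), function(r) as.character(0:9))
  } else {
    split(cs$values,
          ceiling(seq_along(cs$values) / MAX_SPOTS_PER_ROW))
  }
}

#' Lay out a spot card
#'
#' Computes the full geometry of a card from its categories: spot
#' positions, physical size, flower clearance and fiducial corner-dot
#' convention. The layout is deterministic — the same input always
#' yields the same geometry.
#'
#' When `flower_diameter_mm > 0` a circular clearance of that diameter
#' (plus a fixed pad) is reserved at the top center of the card, kept
#' free of spots; the slit for the flower stem is cut from the top edge
#' down to its center, and the flower centroid recorded in the
#' configuration file is the clearance center. Category groups stack
#' below it. With `flower_diameter_mm = 0` ("no flower") the groups
#' simply stack from the top.
#'
#' @param categories A list of [spot_category()] objects (at least one).
#' @param flower_diameter_mm Approximate flower diameter in mm; presets
#'   run 20-100 mm, `0` means a card with no flower clearance. Other
#'   values are accepted with a warning.
#' @param palette Fiducial dot color, `"blue"` (default) or `"pink"`
#'   (for photographing blue samples).
#' @return A validated `spotcard_layout`.
#' @export
#' @examples
#' layout_card(list(spot_category("Variety", values = c("A", "B", "C", "D")),
#'                  spot_category("Plant", range_max = 99)),
#'             flower_diameter_mm = 20)
layout_card <- function(categories, flower_diameter_mm = 0,
                        palette = c("blue", "pink")) {
  palette <- match.arg(palette)
  if (inherits(categories, "spot_category")) categories <- list(categories)
  if (!length(categories)) stop("need at least one category", call. = FALSE)
  if (!all(vapply(categories, inherits, TRUE, "spot_category")))
    stop("`categories` must be a list of spot_category objects", call. = FALSE)
  if (length(categories) > 9L)
    warning("more than ~9 categories makes a physically large card")
  if (flower_diameter_mm < 0) stop("flower_diameter_mm must be >= 0",
                                   call. = FALSE)
  if (flower_diameter_mm > 0 &&
      (flower_diameter_mm < 20 || flower_diameter_mm > 100))
    warning("flower diameter ", flower_diameter_mm,
            " mm is outside the 20-100 mm presets")

  ppm <- TEMPLATE_PX_PER_MM
  rows_per_cat <- lapply(categories, category_display_rows)
  row_width_mm <- function(n) (n - 1L) * SPOT_PITCH_MM + SPOT_DIAMETER_MM
  group_width_mm <- vapply(rows_per_cat, function(rows)
    max(vapply(rows, function(r) row_width_mm(length(r)), 1)), 1)
  clearance_mm <- if (flower_diameter_mm > 0)
    flower_diameter_mm + CLEARANCE_PAD_MM else 0
  content_w_mm <- max(group_width_mm, clearance_mm)
  card_w_mm <- content_w_mm + 2 * CONTENT_MARGIN_MM

  y_mm <- CONTENT_MARGIN_MM
  flower_cy_mm <- 0
  if (clearance_mm > 0) {
    flower_cy_mm <- y_mm + clearance_mm / 2
    y_mm <- y_mm + clearance_mm + GROUP_GAP_MM
  }
  spot_rows <- list()
  for (ci in seq_along(categories)) {
    cs <- categories[[ci]]
    rows <- rows_per_cat[[ci]]
    y_mm <- y_mm + LABEL_BLOCK_MM
    for (ri in seq_along(rows)) {
      labels <- rows[[ri]]
      rw <- row_width_mm(length(labels))
      x0 <- (card_w_mm - rw) / 2 + SPOT_DIAMETER_MM / 2
      cy <- y_mm + SPOT_DIAMETER_MM / 2
      spot_rows[[length(spot_rows) + 1L]] <- data.frame(
        x = (x0 + (seq_along(labels) - 1L) * SPOT_PITCH_MM) * ppm,
        y = cy * ppm,
        width = SPOT_DIAMETER_MM * ppm,
        height = SPOT_DIAMETER_MM * ppm,
        category_index = ci,
        row_index = if (cs$mode == "integer_range") ri - 1L else 0L,
        value_label = labels,
        stringsAsFactors = FALSE)
      y_mm <- y_mm + SPOT_PITCH_MM
    }
    y_mm <- y_mm - (SPOT_PITCH_MM - SPOT_DIAMETER_MM) + GROUP_GAP_MM
  }
  card_h_mm <- y_mm - GROUP_GAP_MM + CONTENT_MARGIN_MM

  layout <- structure(list(
    categories = categories,
    spots = do.call(rbind, spot_rows),
    flower_diameter_mm = flower_diameter_mm,
    card_width_px = card_w_mm * ppm,
    card_height_px = card_h_mm * ppm,
    card_width_mm = card_w_mm,
    card_height_mm = card_h_mm,
    flower_centroid_x_px = card_w_mm * ppm / 2,
    flower_centroid_y_px = flower_cy_mm * ppm,
    dot_palette = palette,
    corner_center_colors = corner_center_map(),
    dot_diameter_mm = DOT_DIAMETER_MM,
    px_per_mm = ppm),
    class = "spotcard_layout")
  validate_layout(layout)
  layout
}

#' Encode an integer as marked digits of an integer-range category
#'
#' Returns which digit spot must be inked in each row to record `n`:
#' one digit per row, most-significant row first, with leading zeros
#' marked explicitly (so an entirely unmarked row always signals a
#' reading problem, never a legitimate short number).
#'
#' @param n Integer in `0..range_max`.
#' @param spec An integer-range [spot_category()].
#' @return A data.frame with columns `row_index` (0 = most significant)
#'   and `digit`.
#' @export
#' @examples
#' encode_integer(532, spot_category("Plant", range_max = 999))
encode_integer <- function(n, spec) {
  if (spec$mode != "integer_range")
    stop("category '", spec$name, "' is not an integer range", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 0L || n > spec$range_max)
    stop("value ", n, " outside range 0-", spec$range_max, call. = FALSE)
  k <- category_rows(spec)
  digits <- (n %/% 10L^((k - 1L):0L)) %% 10L
  data.frame(row_index = 0:(k - 1L), digit = digits)
}

#' Decode marked digits back to the integer they encode
#'
#' Inverse of [encode_integer()]: digits are concatenated
#' most-significant row first.
#'
#' @param digits Integer vector of digits ordered by row (row 0 first).
#' @return The encoded integer.
#' @export
decode_integer <- function(digits) {
  sum(digits * 10L^((length(digits) - 1L):0L))
}

# Resolve a named mark set (category name -> value) to spot row indices
# in layout$spots. Range categories take integers (or digit strings).
spots_for_marks <- function(layout, marks) {
  if (!length(marks)) return(integer(0))
  cat_names <- vapply(layout$categories, `[[`, "", "name")
  idx <- integer(0)
  for (nm in names(marks)) {
    ci <- match(nm, cat_names)
    if (is.na(ci)) stop("no category named '", nm, "' on this card",
                        call. = FALSE)
    cs <- layout$categories[[ci]]
    sp_cat <- which(layout$spots$category_index == ci)
    if (cs$mode == "explicit") {
      hit <- sp_cat[layout$spots$value_label[sp_cat] == as.character(marks[[nm]])]
      if (!length(hit)) stop("category '", nm, "' has no value '",
                             marks[[nm]], "'", call. = FALSE)
      idx <- c(idx, hit)
    } else {
      enc <- encode_integer(as.integer(marks[[nm]]), cs)
      for (r in seq_len(nrow(enc))) {
        hit <- sp_cat[layout$spots$row_index[sp_cat] == enc$row_index[r] &
                        layout$spots$value_label[sp_cat] ==
                          as.character(enc$digit[r])]
        idx <- c(idx, hit)
      }
    }
  }
  sort(idx)
}

#' Render a card layout to a raster image
#'
#' Draws the printable card: unfilled spot outlines with their value
#' labels, category captions, the slit indicator line (flower cards
#' only) and the four fiducial corner dots, each with its small
#' orientation-color center disc. The image spans the corner-dot-center
#' rectangle plus a fixed quiet-zone margin on every side; the margin in
#' pixels is stored in the `"card_origin_px"` attribute.
#'
#' @param layout A `spotcard_layout`.
#' @param marks Optional named mark set (category name -> value label or
#'   integer) inked onto the card, as a field user would with a dry-wipe
#'   marker.
#' @return A `width x height x 3` array in `[0, 1]` with attribute
#'   `card_origin_px` giving the (x, y) image coordinate of the
#'   top-left corner-dot center.
#' @export
render_card <- function(layout, marks = NULL) {
  validate_layout(layout)
  ppm <- layout$px_per_mm
  m <- RENDER_MARGIN_MM * ppm
  w <- as.integer(round(layout$card_width_px + 2 * m))
  h <- as.integer(round(layout$card_height_px + 2 * m))
  dm <- c(w, h)
  black <- c(0, 0, 0)

  # accumulate (indices, color) pairs, then paint in one local loop so
  # the array is modified in place rather than copied per primitive
  ops <- list()
  add <- function(idx, color)
    ops[[length(ops) + 1L]] <<- list(idx = idx, color = color)

  # slit indicator: top edge of the image down to the clearance center
  if (layout$flower_diameter_mm > 0) {
    cx <- m + layout$flower_centroid_x_px
    add(idx_rect(dm, cx - 1, 0, cx + 1, m + layout$flower_centroid_y_px),
        black)
    # faint clearance outline as a positioning guide
    add(idx_ring(dm, cx, m + layout$flower_centroid_y_px,
                 (layout$flower_diameter_mm + CLEARANCE_PAD_MM) / 2 * ppm,
                 thickness = 1), c(0.8, 0.8, 0.8))
  }

  sp <- layout$spots
  for (i in seq_len(nrow(sp))) {
    cx <- m + sp$x[i]; cy <- m + sp$y[i]
    add(idx_ring(dm, cx, cy, sp$width[i] / 2, thickness = 2), black)
    add(idx_text_centered(dm, sp$value_label[i], cx, cy, scale = 2L), black)
  }
  # category captions above each group
  for (ci in seq_along(layout$categories)) {
    sp_cat <- sp[sp$category_index == ci, ]
    top <- min(sp_cat$y - sp_cat$height / 2)
    add(idx_text_centered(dm, layout$categories[[ci]]$name,
                          m + mean(range(sp_cat$x)),
                          m + top - LABEL_BLOCK_MM / 2 * ppm, scale = 3L),
        black)
  }
  if (!is.null(marks)) {
    r_ink <- SPOT_DIAMETER_MM / 2 * ppm * sqrt(INK_AREA_FRACTION)
    ink <- rep(INK_GRAY, 3)
    for (i in spots_for_marks(layout, marks))
      add(idx_disc(dm, m + sp$x[i], m + sp$y[i], r_ink), ink)
  }

  # fiducial corner dots last, so nothing overprints them
  dotc <- palette_rgb(layout$dot_palette)
  r_dot <- layout$dot_diameter_mm / 2 * ppm
  corners <- corner_positions_px(layout)
  for (corner in rownames(corners)) {
    cx <- m + corners[corner, "x"]; cy <- m + corners[corner, "y"]
    add(idx_disc(dm, cx, cy, r_dot), dotc)
    add(idx_disc(dm, cx, cy, r_dot / 3),
        center_rgb(layout$corner_center_colors[[corner]]))
  }

  img <- new_canvas(w, h)
  plane <- as.double(w) * h
  for (op in ops) {
    img[op$idx] <- op$color[1L]
    img[op$idx + plane] <- op$color[2L]
    img[op$idx + 2 * plane] <- op$color[3L]
  }
  attr(img, "card_origin_px") <- c(m, m)
  img
}

# Corner-dot centers in card-frame pixels (0-based).
corner_positions_px <- function(layout) {
  w <- layout$card_width_px; h <- layout$card_height_px
  m <- matrix(c(0, 0, w, 0, 0, h, w, h), ncol = 2, byrow = TRUE,
              dimnames = list(c("top_left", "top_right",
                                "bottom_left", "bottom_right"),
                              c("x", "y")))
  m
}

#' Write a rendered card to disk
#'
#' Saves the card raster as TIFF and/or PNG (by file extension) with the
#' template resolution recorded in the image metadata, plus the matching
#' configuration file when `config` is `TRUE`.
#'
#' @param layout A `spotcard_layout`.
#' @param path Output image path ending in `.tif`, `.tiff` or `.png`.
#' @param config Write `<stem>.spotcard.cfg` next to the image?
#' @return Invisibly, the paths written.
#' @export
save_card <- function(layout, path, config = TRUE) {
  img <- render_card(layout)
  ext <- tolower(tools::file_ext(path))
  dpi <- layout$px_per_mm * 25.4
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(to_writer_array(img), path, reduce = TRUE)
  else if (ext == "png")
    png::writePNG(to_writer_array(img), path, dpi = dpi)
  else stop("unsupported card image extension '.", ext, "'", call. = FALSE)
  paths <- path
  if (config) {
    cfg <- paste0(sub("\\.[^.]+$", "", path), ".spotcard.cfg")
    write_config(layout, cfg)
    paths <- c(paths, cfg)
  }
  invisible(paths)
}

# jpeg/png/tiff writers expect height x width x channel arrays; our
# in-memory order is width x height x channel (EBImage convention).
to_writer_array <- function(img) aperm(img, c(2L, 1L, 3L))
from_reader_array <- function(arr) {
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3L] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  aperm(arr, c(2L, 1L, 3L))
}
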
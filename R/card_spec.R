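#' Category specification for a spot card
#'
#' A category is one set of mutually exclusive spots on the card. It is
#' either *explicit* — a short list of labelled values, one spot each —
#' or an *integer range* `0..(10^k - 1)`, laid out as `k` rows of ten
#' digit spots (most-significant row first) so that any integer in the
#' range can be recorded by marking one digit per row.
#'
#' @param name Category name shown above the spot group. Must be
#'   non-empty.
#' @param values Character vector of value labels (explicit mode).
#'   Supply exactly one of `values` / `range_max`.
#' @param range_max Upper end of an integer range; must be of the form
#'   `10^k - 1` (9, 99, 999, ...).
#' @return An object of class `spot_category`.
#' @export
#' @examples
#' spot_category("Variety", values = c("A", "B", "C", "D"))
#' spot_category("Plant", range_max = 99)
spot_category <- function(name, values = NULL, range_max = NULL) {
  name <- trimws(name)
  if (!nzchar(name)) stop("category name must be non-empty", call. = FALSE)
  if (is.null(values) == is.null(range_max))
    stop("supply exactly one of `values` or `range_max`", call. = FALSE)
  if (!is.null(values)) {
    values <- trimws(as.character(values))
    if (length(values) < 2L)
      stop("category '", name,
           "': a single value is not a markable choice (need >= 2)",
           call. = FALSE)
    if (any(!nzchar(values)))
      stop("category '", name, "': empty value label", call. = FALSE)
    if (anyDuplicated(values))
      stop("category '", name, "': duplicate value labels", call. = FALSE)
    if (length(values) > 15L)
      warning("category '", name, "' has ", length(values),
              " values; cards get physically large beyond ~15")
    out <- list(name = name, mode = "explicit", values = values,
                range_max = NA_integer_)
  } else {
    range_max <- as.integer(range_max)
    k <- nchar(as.character(range_max))
    if (range_max < 9L || range_max != 10L^k - 1L)
      stop("category '", name, "': range must run 0-", paste(rep("9", max(k, 1L)), collapse = ""),
           " style (0 to all nines), got max ", range_max, call. = FALSE)
    out <- list(name = name, mode = "integer_range",
                values = as.character(0:9), range_max = range_max)
  }
  structure(out, class = "spot_category")
}

#' Number of digit rows of a category (1 for explicit mode)
#' @param spec A `spot_category`.
#' @return Integer row count.
#' @export
category_rows <- function(spec) {
  if (spec$mode == "integer_range") nchar(as.character(spec$range_max)) else 1L
}

#' Parse user text into a category specification
#'
#' Interprets the value string the way the card-creation dialog does:
#' a string like `"0-99"` (zero to all nines) becomes an integer-range
#' category; anything else is split on commas into an explicit value
#' list, with labels whitespace-trimmed.
#'
#' @param name Category name.
#' @param value_string Comma-separated labels, or a `0-9...9` range.
#' @return A `spot_category`.
#' @export
#' @examples
#' parse_category_input("Variety", "A, B, C, D")
#' parse_category_input("Plant", "0-99")
parse_category_input <- function(name, value_string) {
  if (!nzchar(trimws(value_string)))
    stop("empty value string for category '", name, "'", call. = FALSE)
  s <- trimws(value_string)
  # en-dash tolerated: ranges are often typed as 0–99
  if (grepl("^[0-9]+\\s*[-–]\\s*[0-9]+$", s)) {
    ends <- strsplit(s, "\\s*[-–]\\s*")[[1]]
    if (ends[1L] != "0" || !grepl("^9+$", ends[2L]))
      stop("range for '", name, "' must start at 0 and end in all 9s (e.g. 0-999), got '",
           s, "'", call. = FALSE)
    return(spot_category(name, range_max = as.integer(ends[2L])))
  }
  spot_category(name, values = strsplit(s, ",")[[1]])
}

#' @export
print.spot_category <- function(x, ...) {
  if (x$mode == "explicit")
    cat("<spot_category> ", x$name, ": ", paste(x$values, collapse = ", "),
        "\n", sep = "")
  else
    cat("<spot_category> ", x$name, ": integers 0-", x$range_max, " (",
        category_rows(x), " digit rows)\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Card layout object

#' @export
print.spotcard_layout <- function(x, ...) {
  cat("<spotcard_layout> ", length(x$categories), " categories, ",
      nrow(x$spots), " spots, ",
      round(x$card_width_mm, 1), " x ", round(x$card_height_mm, 1),
      " mm (corner-dot centers)\n", sep = "")
  for (cs in x$categories) print(cs)
  if (x$flower_diameter_mm > 0)
    cat("flower clearance: ", x$flower_diameter_mm, " mm diameter at (",
        round(x$flower_centroid_x_px), ", ", round(x$flower_centroid_y_px),
        ") px\n", sep = "")
  else cat("no flower clearance\n")
  invisible(x)
}

# The four corner-dot center colors fix the card's orientation. The
# assignment is a package convention shared by the renderer and the
# detector: red = top-left, green = top-right, white = bottom-left,
# black = bottom-right.
corner_center_map <- function() {
  c(top_left = "red", top_right = "green",
    bottom_left = "white", bottom_right = "black")
}

#' Validate a card layout
#'
#' Re-checks every structural invariant of a layout: the flower centroid
#' sits at half the card width, pixel and millimetre aspect ratios agree,
#' spots lie strictly inside the corner-dot-center rectangle and do not
#' overlap, and the corner center colors are pairwise distinct.
#'
#' @param layout A `spotcard_layout`.
#' @return The layout, invisibly; errors describe the first violation.
#' @export
validate_layout <- function(layout) {
  need <- c("categories", "spots", "flower_diameter_mm", "card_width_px",
            "card_height_px", "card_width_mm", "card_height_mm",
            "flower_centroid_x_px", "flower_centroid_y_px", "dot_palette",
            "corner_center_colors", "dot_diameter_mm", "px_per_mm")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (abs(layout$flower_centroid_x_px - layout$card_width_px / 2) > 1e-6)
    stop("flower centroid X must be half the card width", call. = FALSE)
  ar_px <- layout$card_width_px / layout$card_height_px
  ar_mm <- layout$card_width_mm / layout$card_height_mm
  if (abs(ar_px - ar_mm) > 1e-6 * ar_mm)
    stop("pixel and mm aspect ratios disagree", call. = FALSE)
  if (!identical(sort(unname(layout$corner_center_colors)),
                 c("black", "green", "red", "white")))
    stop("corner center colors must be a permutation of red/green/white/black",
         call. = FALSE)
  if (!layout$dot_palette %in% c("blue", "pink"))
    stop("dot_palette must be 'blue' or 'pink'", call. = FALSE)
  sp <- layout$spots
  if (nrow(sp)) {
    inside <- sp$x - sp$width / 2 > 0 & sp$x + sp$width / 2 < layout$card_width_px &
      sp$y - sp$height / 2 > 0 & sp$y + sp$height / 2 < layout$card_height_px
    if (!all(inside))
      stop("spot(s) outside the corner-dot rectangle: ",
           paste(which(!inside), collapse = ", "), call. = FALSE)
    if (nrow(sp) > 1L) {
      for (i in seq_len(nrow(sp) - 1L)) {
        j <- (i + 1L):nrow(sp)
        ox <- abs(sp$x[j] - sp$x[i]) < (sp$width[j] + sp$width[i]) / 2
        oy <- abs(sp$y[j] - sp$y[i]) < (sp$height[j] + sp$height[i]) / 2
        if (any(ox & oy))
          stop("overlapping spots: ", i, " and ", j[which(ox & oy)[1L]],
               call. = FALSE)
      }
    }
  }
  invisible(layout)
}

# ---------------------------------------------------------------------------
# Configuration file: versioned key = value text, lists comma-separated.
# One card design <-> one file; the file carries everything the detector
# needs, so a printed card plus its .spotcard.cfg is self-contained.

CONFIG_FORMAT_VERSION <- 1L
NO_FLOWER_SENTINEL <- "no flower"

fmt_num <- function(x) format(x, digits = 15L, scientific = FALSE, trim = TRUE)

#' Write a card configuration file
#'
#' Serializes a validated layout to the plain-text `key = value` dialect
#' (format version 1). The file is loss-free:
#' [read_config()] returns an identical layout.
#'
#' @param layout A valid `spotcard_layout`.
#' @param path Output path; conventionally ends in `.spotcard.cfg`.
#' @return `path`, invisibly.
#' @export
write_config <- function(layout, path) {
  validate_layout(layout)
  ln <- character(0)
  add <- function(key, value) ln[[length(ln) + 1L]] <<- paste0(key, " = ", value)
  add("spotcard_format_version", CONFIG_FORMAT_VERSION)
  add("card_width_px", fmt_num(layout$card_width_px))
  add("card_height_px", fmt_num(layout$card_height_px))
  add("card_width_mm", fmt_num(layout$card_width_mm))
  add("card_height_mm", fmt_num(layout$card_height_mm))
  add("px_per_mm", fmt_num(layout$px_per_mm))
  add("dot_palette", layout$dot_palette)
  add("dot_diameter_mm", fmt_num(layout$dot_diameter_mm))
  add("flower_diameter_mm",
      if (layout$flower_diameter_mm == 0) NO_FLOWER_SENTINEL
      else fmt_num(layout$flower_diameter_mm))
  add("flower_centroid_x_px", fmt_num(layout$flower_centroid_x_px))
  add("flower_centroid_y_px", fmt_num(layout$flower_centroid_y_px))
  for (corner in names(layout$corner_center_colors))
    add(paste0("corner_center.", corner), layout$corner_center_colors[[corner]])
  add("n_categories", length(layout$categories))
  for (i in seq_along(layout$categories)) {
    cs <- layout$categories[[i]]
    add(paste0("category.", i, ".name"), cs$name)
    add(paste0("category.", i, ".mode"), cs$mode)
    if (cs$mode == "explicit")
      add(paste0("category.", i, ".values"), paste(cs$values, collapse = ","))
    else
      add(paste0("category.", i, ".range_max"), cs$range_max)
  }
  sp <- layout$spots
  add("n_spots", nrow(sp))
  for (i in seq_len(nrow(sp)))
    add(paste0("spot.", i),
        paste(fmt_num(sp$x[i]), fmt_num(sp$y[i]), fmt_num(sp$width[i]),
              fmt_num(sp$height[i]), sp$category_index[i], sp$row_index[i],
              sp$value_label[i], sep = ","))
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}

cfg_get <- function(kv, key, path) {
  if (!key %in% names(kv))
    stop("configuration file '", path, "' is missing key '", key, "'",
         call. = FALSE)
  kv[[key]]
}

#' Read a card configuration file
#'
#' Parses the `key = value` file written by [write_config()] and
#' re-validates every layout invariant, so a hand-edited or truncated
#' file is rejected with a message naming the offending key.
#'
#' @param path Path to a `.spotcard.cfg` file.
#' @return A `spotcard_layout`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path,
                               call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")]
  m <- regmatches(raw, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", raw))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed line in '", path, "': ", raw[bad][1L],
                     call. = FALSE)
  kv <- stats::setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
  ver <- cfg_get(kv, "spotcard_format_version", path)
  if (ver != as.character(CONFIG_FORMAT_VERSION))
    stop("unsupported configuration format version '", ver, "'",
         call. = FALSE)
  num <- function(key) as.numeric(cfg_get(kv, key, path))
  fl_raw <- cfg_get(kv, "flower_diameter_mm", path)
  flower <- if (identical(fl_raw, NO_FLOWER_SENTINEL)) 0 else as.numeric(fl_raw)
  ncat <- as.integer(cfg_get(kv, "n_categories", path))
  categories <- vector("list", ncat)
  for (i in seq_len(ncat)) {
    mode <- cfg_get(kv, paste0("category.", i, ".mode"), path)
    nm <- cfg_get(kv, paste0("category.", i, ".name"), path)
    categories[[i]] <- if (mode == "explicit")
      spot_category(nm, values = strsplit(
        cfg_get(kv, paste0("category.", i, ".values"), path), ",")[[1]])
    else
      spot_category(nm, range_max = as.integer(
        cfg_get(kv, paste0("category.", i, ".range_max"), path)))
  }
  nsp <- as.integer(cfg_get(kv, "n_spots", path))
  rows <- vector("list", nsp)
  for (i in seq_len(nsp)) {
    f <- strsplit(cfg_get(kv, paste0("spot.", i), path), ",")[[1]]
    if (length(f) != 7L)
      stop("malformed spot record 'spot.", i, "' in '", path, "'",
           call. = FALSE)
    rows[[i]] <- data.frame(
      x = as.numeric(f[1L]), y = as.numeric(f[2L]),
      width = as.numeric(f[3L]), height = as.numeric(f[4L]),
      category_index = as.integer(f[5L]), row_index = as.integer(f[6L]),
      value_label = f[7L], stringsAsFactors = FALSE)
  }
  corners <- c(
    top_left = cfg_get(kv, "corner_center.top_left", path),
    top_right = cfg_get(kv, "corner_center.top_right", path),
    bottom_left = cfg_get(kv, "corner_center.bottom_left", path),
    bottom_right = cfg_get(kv, "corner_center.bottom_right", path))
  layout <- structure(list(
    categories = categories,
    spots = if (nsp) do.call(rbind, rows) else empty_spots(),
    flower_diameter_mm = flower,
    card_width_px = num("card_width_px"),
    card_height_px = num("card_height_px"),
    card_width_mm = num("card_width_mm"),
    card_height_mm = num("card_height_mm"),
    flower_centroid_x_px = num("flower_centroid_x_px"),
    flower_centroid_y_px = num("flower_centroid_y_px"),
    dot_palette = cfg_get(kv, "dot_palette", path),
    corner_center_colors = corners,
    dot_diameter_mm = num("dot_diameter_mm"),
    px_per_mm = num("px_per_mm")),
    class = "spotcard_layout")
  validate_layout(layout)
  layout
}

empty_spots <- function() {
  data.frame(x = numeric(0), y = numeric(0), width = numeric(0),
             height = numeric(0), category_index = integer(0),
             row_index = integer(0), value_label = character(0),
             stringsAsFactors = FALSE)
}
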
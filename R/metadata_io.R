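# Batch results: one CSV row per photograph, in lexicographic filename
# order, with per-image soft error handling — a failed image records its
# error code and the batch moves on.

#' Assemble one results row
#'
#' @param filename Image file name (no directory).
#' @param exif List from [extract_exif()].
#' @param layout Card layout (fixes the category columns).
#' @param reading A `spotcard_reading`, or `NULL` on failure.
#' @param measurement Named vector `c(area_mm2, perimeter_mm)`, or `NULL`.
#' @param error_code Machine-readable error code, `""` when ok.
#' @return A one-row data.frame; missing values are empty strings.
#' @export
record_row <- function(filename, exif, layout, reading = NULL,
                       measurement = NULL, error_code = "") {
  blank_if_na <- function(x, fmt) {
    if (is.null(x) || length(x) == 0L || is.na(x)) "" else sprintf(fmt, x)
  }
  cat_names <- vapply(layout$categories, `[[`, "", "name")
  vals <- stats::setNames(rep("", length(cat_names)), cat_names)
  if (!is.null(reading)) vals[names(reading$values)] <- reading$values
  row <- data.frame(
    filename = filename,
    datetime = if (is.null(exif) || is.na(exif$datetime)) "" else exif$datetime,
    latitude = blank_if_na(if (is.null(exif)) NA else exif$latitude, "%.6f"),
    longitude = blank_if_na(if (is.null(exif)) NA else exif$longitude, "%.6f"),
    altitude = blank_if_na(if (is.null(exif)) NA else exif$altitude, "%.1f"),
    stringsAsFactors = FALSE)
  for (nm in cat_names) row[[nm]] <- unname(vals[[nm]])
  row$area_mm2 <- blank_if_na(
    if (is.null(measurement)) NA else measurement[["area_mm2"]], "%.4f")
  row$perimeter_mm <- blank_if_na(
    if (is.null(measurement)) NA else measurement[["perimeter_mm"]], "%.4f")
  row$error <- error_code
  row
}

#' Write the batch results CSV
#'
#' RFC 4180 CSV (UTF-8, LF line endings, fields quoted where needed)
#' with the fixed column order: `filename`, `datetime`, `latitude`,
#' `longitude`, `altitude`, one column per category in card order,
#' `area_mm2`, `perimeter_mm`, `error`. Zero rows produce a header-only
#' file.
#'
#' @param rows A data.frame of [record_row()]s (possibly 0-row).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  quote_field <- function(x) {
    needs <- grepl('[",\n\r]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  writeLines(paste(quote_field(names(rows)), collapse = ","), con,
             sep = "\n", useBytes = TRUE)
  for (i in seq_len(nrow(rows))) {
    fields <- vapply(rows[i, ], as.character, "")
    writeLines(paste(quote_field(fields), collapse = ","), con,
               sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Process a directory of photographs against one card design
#'
#' The batch driver: reads the card configuration, walks the image
#' directory in lexicographic order, and for each photograph extracts
#' EXIF metadata, runs detection/decoding, optionally measures the
#' flower, and appends a results row. A failure on any single image
#' (unreadable file, validation error, missing flower) is recorded in
#' that image's `error` column — or as MISSING/AMBIGUOUS category cells
#' — and processing continues; the row count always equals the image
#' count.
#'
#' @param config_path Path to the card's `.spotcard.cfg`.
#' @param image_dir Directory of JPEG/PNG/TIFF photographs.
#' @param out_csv Results CSV path.
#' @param palette Fiducial palette override; default from the config.
#' @param threshold Marked/unmarked mean-gray cutoff (0-255).
#' @param measure_flower Measure flower area/perimeter on cards with a
#'   flower clearance?
#' @param save_crops Directory for confirmation images
#'   (`<stem>_flower.png`, `<stem>_floodfill.png`), or `NULL`.
#' @param quiet Suppress the progress/summary messages?
#' @return Invisibly, a list: `rows` (the results data.frame), `n_ok`,
#'   `n_error`, `error_counts`, `csv`.
#' @export
run_batch <- function(config_path, image_dir, out_csv,
                      palette = NULL, threshold = MARK_THRESHOLD_DEFAULT,
                      measure_flower = TRUE, save_crops = NULL,
                      quiet = FALSE) {
  layout <- read_config(config_path)
  if (is.null(palette)) palette <- layout$dot_palette
  if (!dir.exists(image_dir))
    stop("image directory not found: ", image_dir, call. = FALSE)
  files <- list.files(image_dir,
                      pattern = "\\.(jpg|jpeg|png|tif|tiff)$",
                      ignore.case = TRUE)
  files <- sort(files, method = "radix")
  if (!length(files) && !quiet)
    warning("no images found in ", image_dir)
  if (!is.null(save_crops) && !dir.exists(save_crops))
    dir.create(save_crops, recursive = TRUE)

  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    path <- file.path(image_dir, f)
    exif <- tryCatch(extract_exif(path), error = function(e) NULL)
    row <- tryCatch({
      img <- load_photo(path)
      res <- suppressWarnings(read_card(img, layout, palette = palette,
                                        threshold = threshold))
      meas <- NULL
      err <- res$error_code
      if (res$ok && measure_flower && layout$flower_diameter_mm > 0) {
        meas <- tryCatch({
          seg <- segment_flower(res$detection, layout)
          if (!is.null(save_crops)) {
            stem <- tools::file_path_sans_ext(f)
            png::writePNG(to_writer_array(seg$flower_crop),
                          file.path(save_crops,
                                    paste0(stem, "_flower.png")))
            png::writePNG(to_writer_array(seg$floodfill_crop),
                          file.path(save_crops,
                                    paste0(stem, "_floodfill.png")))
          }
          measure_region(seg$mask, compute_scale(res$detection, layout))
        }, spotmark_error = function(e) {
          # flower not found: record the code, keep the decoded values
          err <<- e$code
          NULL
        })
      }
      record_row(f, exif, layout,
                 reading = res$reading, measurement = meas,
                 error_code = err)
    }, error = function(e) {
      record_row(f, exif, layout, error_code = "READ_ERROR")
    })
    rows[[i]] <- row
  }
  rows_df <- if (length(rows)) do.call(rbind, rows)
  else record_row("x", NULL, layout)[0, ]
  write_results(rows_df, out_csv)

  errs <- rows_df$error[nzchar(rows_df$error)]
  summary <- list(rows = rows_df,
                  n_ok = sum(!nzchar(rows_df$error)),
                  n_error = length(errs),
                  error_counts = if (length(errs)) table(errs) else table(character(0)),
                  csv = out_csv)
  if (!quiet) {
    message(sprintf("processed %d image(s): %d ok, %d with errors -> %s",
                    nrow(rows_df), summary$n_ok, summary$n_error, out_csv))
    if (length(errs))
      message(paste(sprintf("  %s: %d", names(summary$error_counts),
                            summary$error_counts), collapse = "\n"))
  }
  invisible(summary)
}
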
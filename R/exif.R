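# Minimal EXIF 2.3 codec. The reader walks the TIFF-structured metadata
# (either a JPEG APP1 "Exif" segment or the IFDs of a TIFF file itself)
# for the handful of tags the results table needs: DateTimeOriginal /
# DateTime, GPSLatitude(+Ref), GPSLongitude(+Ref), GPSAltitude(+Ref).
# The writer builds such a block so the fixture renderer can inject
# known metadata into synthetic test JPEGs. Both ends support big- and
# little-endian byte order.

TAG_DATETIME       <- 0x0132L
TAG_EXIF_IFD       <- 0x8769L
TAG_GPS_IFD        <- 0x8825L
TAG_DATETIME_ORIG  <- 0x9003L
GPS_LAT_REF <- 0x0001L; GPS_LAT <- 0x0002L
GPS_LON_REF <- 0x0003L; GPS_LON <- 0x0004L
GPS_ALT_REF <- 0x0005L; GPS_ALT <- 0x0006L
EXIF_HEADER <- as.raw(c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00))  # "Exif\0\0"

# --- binary helpers (1-based offsets into a raw vector) --------------------

rd_uint <- function(bytes, offset, size, big_endian) {
  b <- as.integer(bytes[offset:(offset + size - 1L)])
  if (!big_endian) b <- rev(b)
  sum(b * 256^((size - 1L):0))
}

wr_uint <- function(x, size) {
  # little-endian; the writer always emits "II" order
  as.raw((x %/% 256^(0:(size - 1L))) %% 256)
}

# --- reading ---------------------------------------------------------------

# Returns the raw TIFF block holding the metadata, or NULL.
exif_tiff_block <- function(bytes) {
  if (length(bytes) < 8L) return(NULL)
  if (bytes[1L] == as.raw(0xFF) && bytes[2L] == as.raw(0xD8)) {
    # JPEG: scan segments for APP1/Exif until the scan data starts
    p <- 3L
    while (p + 3L <= length(bytes)) {
      if (bytes[p] != as.raw(0xFF)) break
      marker <- as.integer(bytes[p + 1L])
      if (marker == 0xDA || marker == 0xD9) break
      len <- rd_uint(bytes, p + 2L, 2L, TRUE)
      if (marker == 0xE1 && len >= 8L &&
          identical(bytes[(p + 4L):(p + 9L)], EXIF_HEADER))
        return(bytes[(p + 10L):(p + 1L + len)])
      p <- p + 2L + len
    }
    return(NULL)
  }
  two <- rawToChar(bytes[1:2])
  if (two %in% c("II", "MM")) return(bytes)   # TIFF file
  NULL
}

ifd_entries <- function(tiff, offset, big_endian) {
  if (offset + 1L > length(tiff)) return(list())
  n <- rd_uint(tiff, offset + 1L, 2L, big_endian)
  if (n > 200L) return(list())   # malformed guard
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e <- offset + 3L + (i - 1L) * 12L
    if (e + 11L > length(tiff)) break
    out[[i]] <- list(tag = rd_uint(tiff, e, 2L, big_endian),
                     type = rd_uint(tiff, e + 2L, 2L, big_endian),
                     count = rd_uint(tiff, e + 4L, 4L, big_endian),
                     voff = e + 8L)
  }
  out[!vapply(out, is.null, TRUE)]
}

type_size <- function(type) c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L,
                              4L, 8L)[type]

entry_value <- function(tiff, entry, big_endian) {
  sz <- type_size(entry$type) * entry$count
  off <- if (sz <= 4L) entry$voff
  else rd_uint(tiff, entry$voff, 4L, big_endian) + 1L
  if (off + sz - 1L > length(tiff)) return(NULL)
  if (entry$type == 2L) {            # ASCII: bytes before the first NUL
    v <- tiff[off:(off + sz - 1L)]
    nul <- which(v == as.raw(0))
    end <- if (length(nul)) nul[1L] - 1L else length(v)
    return(rawToChar(v[seq_len(end)]))
  }
  if (entry$type %in% c(5L, 10L)) {  # (S)RATIONAL pairs
    vapply(seq_len(entry$count), function(k) {
      num <- rd_uint(tiff, off + (k - 1L) * 8L, 4L, big_endian)
      den <- rd_uint(tiff, off + (k - 1L) * 8L + 4L, 4L, big_endian)
      if (entry$type == 10L && num >= 2^31) num <- num - 2^32
      if (den == 0) return(NA_real_)
      num / den
    }, 1)
  } else {                           # integer types
    sz1 <- type_size(entry$type)
    vapply(seq_len(entry$count), function(k)
      rd_uint(tiff, off + (k - 1L) * sz1, sz1, big_endian), 1)
  }
}

find_tag <- function(entries, tag) {
  for (e in entries) if (e$tag == tag) return(e)
  NULL
}

#' Convert degree/minute/second GPS readings to signed decimal degrees
#'
#' @param dms Numeric vector `c(degrees, minutes, seconds)` as stored in
#'   EXIF rationals.
#' @param ref Hemisphere reference, one of `"N"`, `"S"`, `"E"`, `"W"`.
#' @return Signed decimal degrees.
#' @export
dms_to_decimal <- function(dms, ref) {
  dec <- dms[1L] + dms[2L] / 60 + dms[3L] / 3600
  if (toupper(ref) %in% c("S", "W")) dec <- -dec
  dec
}

#' Convert signed decimal degrees to EXIF degree/minute/second form
#'
#' @param dec Signed decimal degrees.
#' @return List with `dms = c(deg, min, sec)` (seconds carry 1/10000
#'   precision, i.e. well below 1e-6 degrees) and the hemisphere `ref`
#'   character for the given `axis`.
#' @param axis `"lat"` or `"lon"`, selecting N/S or E/W references.
#' @export
decimal_to_dms <- function(dec, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  ref <- if (dec < 0) (if (axis == "lat") "S" else "W")
  else (if (axis == "lat") "N" else "E")
  a <- abs(dec)
  d <- floor(a)
  m <- floor((a - d) * 60)
  s <- round((a - d - m / 60) * 3600 * 10000) / 10000
  if (s >= 60) { s <- s - 60; m <- m + 1 }
  if (m >= 60) { m <- m - 60; d <- d + 1 }
  list(dms = c(d, m, s), ref = ref)
}

#' Extract date/time and GPS position from an image file
#'
#' Reads `DateTimeOriginal` (falling back to `DateTime`) as ISO-8601
#' local time, and the GPS latitude/longitude/altitude converted to
#' signed decimal degrees / metres using their reference tags. Absent
#' metadata yields `NA` fields, never an error — files without EXIF
#' (e.g. PNG) simply produce blanks downstream.
#'
#' @param path Image file path (JPEG, TIFF, or anything else — non-EXIF
#'   formats return all-`NA`).
#' @return List with `datetime` (character), `latitude`, `longitude`
#'   (decimal degrees), `altitude` (metres); `NA` where absent.
#' @export
extract_exif <- function(path) {
  blank <- list(datetime = NA_character_, latitude = NA_real_,
                longitude = NA_real_, altitude = NA_real_)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.info(path)$size)
  tiff <- exif_tiff_block(bytes)
  if (is.null(tiff)) return(blank)
  be <- rawToChar(tiff[1:2]) == "MM"
  ifd0_off <- rd_uint(tiff, 5L, 4L, be)
  ifd0 <- ifd_entries(tiff, ifd0_off, be)
  out <- blank

  dt <- NULL
  exif_ptr <- find_tag(ifd0, TAG_EXIF_IFD)
  if (!is.null(exif_ptr)) {
    sub <- ifd_entries(tiff, entry_value(tiff, exif_ptr, be), be)
    e <- find_tag(sub, TAG_DATETIME_ORIG)
    if (!is.null(e)) dt <- entry_value(tiff, e, be)
  }
  if (is.null(dt)) {
    e <- find_tag(ifd0, TAG_DATETIME)
    if (!is.null(e)) dt <- entry_value(tiff, e, be)
  }
  if (!is.null(dt) && nzchar(dt)) {
    iso <- sub("^(\\d{4}):(\\d{2}):(\\d{2}) ", "\\1-\\2-\\3T", dt)
    out$datetime <- iso
  }

  gps_ptr <- find_tag(ifd0, TAG_GPS_IFD)
  if (!is.null(gps_ptr)) {
    gps <- ifd_entries(tiff, entry_value(tiff, gps_ptr, be), be)
    lat <- find_tag(gps, GPS_LAT); latr <- find_tag(gps, GPS_LAT_REF)
    lon <- find_tag(gps, GPS_LON); lonr <- find_tag(gps, GPS_LON_REF)
    if (!is.null(lat) && !is.null(latr))
      out$latitude <- dms_to_decimal(entry_value(tiff, lat, be),
                                     entry_value(tiff, latr, be))
    if (!is.null(lon) && !is.null(lonr))
      out$longitude <- dms_to_decimal(entry_value(tiff, lon, be),
                                      entry_value(tiff, lonr, be))
    alt <- find_tag(gps, GPS_ALT)
    if (!is.null(alt)) {
      a <- entry_value(tiff, alt, be)
      altr <- find_tag(gps, GPS_ALT_REF)
      if (!is.null(altr) && isTRUE(entry_value(tiff, altr, be) == 1)) a <- -a
      out$altitude <- a
    }
  }
  out
}

# --- writing ---------------------------------------------------------------

rational_raw <- function(num, den) c(wr_uint(num, 4L), wr_uint(den, 4L))

# entries: list of list(tag, type, count, value = raw vector).
# Returns the serialized IFD (entries sorted by tag, values > 4 bytes
# stored after the entry table) for placement at `offset` in the block.
build_ifd <- function(entries, offset) {
  entries <- entries[order(vapply(entries, `[[`, 1, "tag"))]
  n <- length(entries)
  table_len <- 2L + 12L * n + 4L
  voff <- offset + table_len
  tab <- wr_uint(n, 2L)
  blob <- raw(0)
  for (e in entries) {
    tab <- c(tab, wr_uint(e$tag, 2L), wr_uint(e$type, 2L),
             wr_uint(e$count, 4L))
    v <- e$value
    if (length(v) <= 4L) {
      tab <- c(tab, v, raw(4L - length(v)))
    } else {
      tab <- c(tab, wr_uint(voff, 4L))
      if (length(v) %% 2L) v <- c(v, raw(1L))
      blob <- c(blob, v)
      voff <- voff + length(v)
    }
  }
  c(tab, wr_uint(0L, 4L), blob)
}

ifd_size <- function(entries) {
  vals <- vapply(entries, function(e) {
    l <- length(e$value)
    if (l <= 4L) 0L else l + l %% 2L
  }, 1L)
  2L + 12L * length(entries) + 4L + sum(vals)
}

ascii_entry <- function(tag, text) {
  v <- c(charToRaw(text), as.raw(0))
  list(tag = tag, type = 2L, count = length(v), value = v)
}

#' Build an EXIF APP1 payload
#'
#' Assembles a little-endian TIFF metadata block (IFD0 + Exif IFD + GPS
#' IFD) carrying the given capture time and GPS position, in the form
#' used by [inject_exif_jpeg()]. Mainly for generating synthetic test
#' images with known metadata.
#'
#' @param datetime ISO-8601 or EXIF-style local time, or `NULL`.
#' @param latitude,longitude Signed decimal degrees, or `NULL`.
#' @param altitude Metres (negative = below sea level), or `NULL`.
#' @return Raw vector: the TIFF block (without the `Exif\0\0` header).
#' @export
build_exif <- function(datetime = NULL, latitude = NULL, longitude = NULL,
                       altitude = NULL) {
  ifd0 <- list()
  exif_ifd <- list()
  gps_ifd <- list()
  if (!is.null(datetime)) {
    ex <- gsub("T", " ", datetime)
    ex <- gsub("(\\d{4})-(\\d{2})-(\\d{2})", "\\1:\\2:\\3", ex)
    ifd0[[length(ifd0) + 1L]] <- ascii_entry(TAG_DATETIME, ex)
    exif_ifd[[1L]] <- ascii_entry(TAG_DATETIME_ORIG, ex)
  }
  gps_coord <- function(ref_tag, tag, value, axis) {
    conv <- decimal_to_dms(value, axis)
    s_num <- round(conv$dms[3L] * 10000)
    list(
      list(tag = ref_tag, type = 2L, count = 2L,
           value = c(charToRaw(conv$ref), as.raw(0))),
      list(tag = tag, type = 5L, count = 3L,
           value = c(rational_raw(conv$dms[1L], 1L),
                     rational_raw(conv$dms[2L], 1L),
                     rational_raw(s_num, 10000L))))
  }
  if (!is.null(latitude))
    gps_ifd <- c(gps_ifd, gps_coord(GPS_LAT_REF, GPS_LAT, latitude, "lat"))
  if (!is.null(longitude))
    gps_ifd <- c(gps_ifd, gps_coord(GPS_LON_REF, GPS_LON, longitude, "lon"))
  if (!is.null(altitude)) {
    gps_ifd <- c(gps_ifd, list(
      list(tag = GPS_ALT_REF, type = 1L, count = 1L,
           value = as.raw(as.integer(altitude < 0))),
      list(tag = GPS_ALT, type = 5L, count = 1L,
           value = rational_raw(round(abs(altitude) * 100), 100L))))
  }
  ifd0_off <- 8L
  # pointers depend only on sizes, which are known before the offsets
  exif_off <- if (length(exif_ifd)) NA else NULL
  gps_off <- if (length(gps_ifd)) NA else NULL
  n_ptrs <- length(ifd0)
  with_ptrs <- ifd0
  if (!is.null(exif_off))
    with_ptrs[[length(with_ptrs) + 1L]] <-
      list(tag = TAG_EXIF_IFD, type = 4L, count = 1L, value = wr_uint(0L, 4L))
  if (!is.null(gps_off))
    with_ptrs[[length(with_ptrs) + 1L]] <-
      list(tag = TAG_GPS_IFD, type = 4L, count = 1L, value = wr_uint(0L, 4L))
  sz0 <- ifd_size(with_ptrs)
  cur <- ifd0_off + sz0
  if (!is.null(exif_off)) { exif_off <- cur; cur <- cur + ifd_size(exif_ifd) }
  if (!is.null(gps_off)) gps_off <- cur
  final0 <- ifd0
  if (!is.null(exif_off))
    final0[[length(final0) + 1L]] <-
      list(tag = TAG_EXIF_IFD, type = 4L, count = 1L,
           value = wr_uint(exif_off, 4L))
  if (!is.null(gps_off))
    final0[[length(final0) + 1L]] <-
      list(tag = TAG_GPS_IFD, type = 4L, count = 1L,
           value = wr_uint(gps_off, 4L))
  out <- c(charToRaw("II"), wr_uint(42L, 2L), wr_uint(ifd0_off, 4L),
           build_ifd(final0, ifd0_off))
  if (!is.null(exif_off)) out <- c(out, build_ifd(exif_ifd, exif_off))
  if (!is.null(gps_off)) out <- c(out, build_ifd(gps_ifd, gps_off))
  out
}

#' Insert an EXIF block into a JPEG file
#'
#' Splices an APP1/Exif segment directly after the JPEG start-of-image
#' marker. Existing APP1 segments are left untouched (the injected one
#' comes first, so it wins for readers that take the first match).
#'
#' @param path JPEG file to modify in place.
#' @param tiff_block Raw TIFF metadata block from [build_exif()].
#' @return `path`, invisibly.
#' @export
inject_exif_jpeg <- function(path, tiff_block) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 2L || bytes[1L] != as.raw(0xFF) ||
      bytes[2L] != as.raw(0xD8))
    stop("not a JPEG file: ", path, call. = FALSE)
  payload <- c(EXIF_HEADER, tiff_block)
  seg <- c(as.raw(c(0xFF, 0xE1)),
           rev(wr_uint(length(payload) + 2L, 2L)),  # big-endian length
           payload)
  writeBin(c(bytes[1:2], seg, bytes[3:length(bytes)]), path)
  invisible(path)
}
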
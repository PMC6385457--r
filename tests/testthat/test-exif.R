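test_that("DMS to decimal conversion applies hemisphere signs", {
  expect_equal(dms_to_decimal(c(52, 12, 18), "N"), 52.205)
  expect_equal(dms_to_decimal(c(0, 7, 30), "E"), 0.125)
  expect_equal(dms_to_decimal(c(52, 12, 18), "S"), -52.205)
  expect_equal(dms_to_decimal(c(0, 7, 30), "W"), -0.125)
})

test_that("decimal degrees survive the DMS rational round trip to 1e-6", {
  set.seed(11)
  lats <- stats::runif(50, -90, 90)
  lons <- stats::runif(50, -180, 180)
  for (v in lats) {
    conv <- decimal_to_dms(v, "lat")
    expect_equal(dms_to_decimal(conv$dms, conv$ref), v, tolerance = 1e-6)
  }
  for (v in lons) {
    conv <- decimal_to_dms(v, "lon")
    expect_equal(dms_to_decimal(conv$dms, conv$ref), v, tolerance = 1e-6)
  }
})

test_that("written EXIF blocks read back field for field", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "meta.jpg")
  jpeg::writeJPEG(array(0.5, c(8, 8, 3)), path)
  inject_exif_jpeg(path, build_exif(
    datetime = "2019-02-22T10:30:00",
    latitude = dms_to_decimal(c(52, 12, 18), "N"),
    longitude = dms_to_decimal(c(0, 7, 30), "E"),
    altitude = 21))
  got <- extract_exif(path)
  expect_equal(got$datetime, "2019-02-22T10:30:00")
  expect_equal(got$latitude, 52.205, tolerance = 1e-6)
  expect_equal(got$longitude, 0.125, tolerance = 1e-6)
  expect_equal(got$altitude, 21, tolerance = 0.01)

  # southern/western hemisphere and below-sea-level altitude
  path2 <- file.path(dir, "meta2.jpg")
  jpeg::writeJPEG(array(0.5, c(8, 8, 3)), path2)
  inject_exif_jpeg(path2, build_exif(latitude = -33.8568,
                                     longitude = -151.2153,
                                     altitude = -12.5))
  got2 <- extract_exif(path2)
  expect_equal(got2$latitude, -33.8568, tolerance = 1e-6)
  expect_equal(got2$longitude, -151.2153, tolerance = 1e-6)
  expect_equal(got2$altitude, -12.5, tolerance = 0.01)
  expect_true(is.na(got2$datetime))
})

test_that("images without EXIF give blank metadata, never an error", {
  dir <- withr::local_tempdir()
  png_path <- file.path(dir, "plain.png")
  png::writePNG(array(0.5, c(8, 8, 3)), png_path)
  got <- extract_exif(png_path)
  expect_true(is.na(got$datetime))
  expect_true(is.na(got$latitude))
  expect_true(is.na(got$longitude))
  expect_true(is.na(got$altitude))

  jpg_path <- file.path(dir, "plain.jpg")
  jpeg::writeJPEG(array(0.5, c(8, 8, 3)), jpg_path)
  expect_true(is.na(extract_exif(jpg_path)$datetime))

  tif_path <- file.path(dir, "plain.tif")
  tiff::writeTIFF(array(0.5, c(8, 8, 3)), tif_path)
  expect_true(is.na(extract_exif(tif_path)$datetime))
})

test_that("fixture-written JPEGs carry their requested metadata", {
  lay <- tiny_layout()
  dir <- withr::local_tempdir()
  write_fixture(fixture_spec(lay, list(Set = "A"),
                             exif = list(datetime = "2020-06-01T09:15:30",
                                         latitude = 52.2053,
                                         longitude = 0.1218,
                                         altitude = 6)),
                file.path(dir, "fx"))
  got <- extract_exif(file.path(dir, "fx.jpg"))
  expect_equal(got$datetime, "2020-06-01T09:15:30")
  expect_equal(got$latitude, 52.2053, tolerance = 1e-6)
  expect_equal(got$longitude, 0.1218, tolerance = 1e-6)
})
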
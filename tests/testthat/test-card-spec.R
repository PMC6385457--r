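test_that("category input parsing handles lists, ranges and bad input", {
  v <- parse_category_input("Variety", "A, B, C, D")
  expect_s3_class(v, "spot_category")
  expect_equal(v$mode, "explicit")
  expect_equal(v$values, c("A", "B", "C", "D"))

  p <- parse_category_input("Plant", "0-99")
  expect_equal(p$mode, "integer_range")
  expect_equal(p$range_max, 99L)
  expect_equal(category_rows(p), 2L)

  expect_error(parse_category_input("X", "7"), "single value")
  expect_error(parse_category_input("X", ""), "empty")
  expect_error(parse_category_input("X", "1-99"), "start at 0")
  expect_error(parse_category_input("X", "0-50"), "all 9s")
  expect_error(parse_category_input("X", "A, A, B"), "duplicate")
  expect_error(parse_category_input("X", "A, , B"), "empty value")
  expect_error(parse_category_input("", "A, B"), "non-empty")
})

test_that("integer ranges expand to 10k spots in k most-significant-first rows", {
  for (k in 1:3) {
    cs <- spot_category("N", range_max = 10^k - 1)
    lay <- layout_card(list(cs))
    expect_equal(nrow(lay$spots), 10L * k)
    expect_equal(sort(unique(lay$spots$row_index)), 0:(k - 1L))
    # row 0 is the most significant: it sits highest on the card
    ys <- tapply(lay$spots$y, lay$spots$row_index, unique)
    expect_true(all(diff(ys) > 0))
  }
})

test_that("the three-category example card has 4 + 3 + 20 = 27 spots", {
  lay <- fig1_layout()
  expect_equal(nrow(lay$spots), 27L)
  expect_length(lay$categories, 3L)
})

test_that("configuration round-trip is the identity on randomized layouts", {
  set.seed(101)
  for (i in 1:6) {
    lay <- suppressWarnings(random_layout())
    path <- withr::local_tempfile(fileext = ".spotcard.cfg")
    write_config(lay, path)
    back <- read_config(path)
    expect_equal(back, lay, tolerance = 1e-12)
  }
})

test_that("flowerless cards are serialized with a 'no flower' sentinel", {
  lay <- layout_card(fig1_categories(), flower_diameter_mm = 0)
  path <- withr::local_tempfile(fileext = ".spotcard.cfg")
  write_config(lay, path)
  expect_true(any(grepl("flower_diameter_mm = no flower",
                        readLines(path), fixed = TRUE)))
  expect_equal(read_config(path)$flower_diameter_mm, 0)
})

test_that("tampered and truncated configuration files are rejected", {
  lay <- fig1_layout()
  path <- withr::local_tempfile(fileext = ".spotcard.cfg")
  write_config(lay, path)

  lines <- readLines(path)
  bad <- sub("^flower_centroid_x_px = .*",
             "flower_centroid_x_px = 1", lines)
  writeLines(bad, path)
  expect_error(read_config(path), "half the card width")

  writeLines(lines[1:5], path)
  expect_error(read_config(path), "missing key")

  writeLines(sub("spotcard_format_version = 1",
                 "spotcard_format_version = 99", lines), path)
  expect_error(read_config(path), "version")
})

test_that("layout validation rejects overlapping and out-of-bounds spots", {
  lay <- fig1_layout()
  broken <- lay
  broken$spots$x[2L] <- broken$spots$x[1L] + 0.1
  broken$spots$y[2L] <- broken$spots$y[1L]
  expect_error(validate_layout(broken), "overlap")
  broken2 <- lay
  broken2$spots$x[1L] <- -5
  expect_error(validate_layout(broken2), "outside")
})
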
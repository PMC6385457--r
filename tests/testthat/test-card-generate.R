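test_that("integer marking encodes one digit per row, leading zeros included", {
  p999 <- spot_category("Plant", range_max = 999)
  enc <- encode_integer(532, p999)
  expect_equal(enc$row_index, 0:2)
  expect_equal(enc$digit, c(5, 3, 2))

  p99 <- spot_category("Plant", range_max = 99)
  expect_equal(encode_integer(0, p99)$digit, c(0, 0))
  expect_equal(encode_integer(7, p99)$digit, c(0, 7))

  expect_error(encode_integer(1000, p999), "outside range")
  expect_error(encode_integer(-1, p99), "outside range")
})

test_that("decoding marked digits inverts encoding over a full range", {
  p99 <- spot_category("Plant", range_max = 99)
  for (n in 0:99)
    expect_equal(decode_integer(encode_integer(n, p99)$digit), n)
})

test_that("card layout is deterministic and keeps spots out of the clearance", {
  a <- fig1_layout()
  b <- fig1_layout()
  expect_identical(a, b)

  # no spot center may fall inside the clearance circle
  r_clear <- (a$flower_diameter_mm + 6) / 2 * a$px_per_mm
  d <- sqrt((a$spots$x - a$flower_centroid_x_px)^2 +
              (a$spots$y - a$flower_centroid_y_px)^2)
  expect_true(all(d > r_clear + a$spots$width / 2))

  # adding a category leaves existing spot positions untouched when the
  # card width does not change, and never pushes them into the clearance
  more <- layout_card(c(fig1_categories(),
                        list(spot_category("Rep", values = c("1", "2")))),
                      flower_diameter_mm = 20)
  d2 <- sqrt((more$spots$x - more$flower_centroid_x_px)^2 +
               (more$spots$y - more$flower_centroid_y_px)^2)
  expect_true(all(d2 > r_clear + more$spots$width / 2))
  expect_equal(nrow(more$spots), 29L)
})

test_that("flowerless cards stack groups with no clearance or slit anchor", {
  lay <- layout_card(fig1_categories(), flower_diameter_mm = 0)
  expect_equal(lay$flower_centroid_y_px, 0)
  expect_lt(lay$card_height_mm, fig1_layout()$card_height_mm)
})

test_that("rendering places palette dots with distinct center colors at the corners", {
  for (pal in c("blue", "pink")) {
    lay <- layout_card(fig1_categories(), flower_diameter_mm = 20,
                       palette = pal)
    img <- render_card(lay)
    m <- attr(img, "card_origin_px")
    expect_equal(dim(img)[1:2],
                 c(lay$card_width_px + 2 * m[1L],
                   lay$card_height_px + 2 * m[2L]))
    # dot body color just outside the center disc
    probe <- img[m[1L] + 1L + round(lay$dot_diameter_mm * lay$px_per_mm / 4),
                 m[2L] + 1L, ]
    hsv <- grDevices::rgb2hsv(matrix(probe, 3L))
    if (pal == "blue") expect_true(hsv[1L] > 0.5 && hsv[1L] < 0.8)
    else expect_true(hsv[1L] > 0.8)
    # center pixels: red TL, green TR, white BL, black BR
    ctr <- function(cx, cy) img[round(cx) + 1L, round(cy) + 1L, ]
    tl <- ctr(m[1L], m[2L])
    tr <- ctr(m[1L] + lay$card_width_px, m[2L])
    bl <- ctr(m[1L], m[2L] + lay$card_height_px)
    br <- ctr(m[1L] + lay$card_width_px, m[2L] + lay$card_height_px)
    expect_gt(tl[1L], 2 * max(tl[2L], tl[3L]))       # red-dominant
    expect_gt(tr[2L], 2 * max(tr[1L], tr[3L]))       # green-dominant
    expect_true(all(bl > 0.9))                        # white
    expect_true(all(br < 0.1))                        # black
  }
})

test_that("rendered cards are byte-identical across calls", {
  lay <- tiny_layout()
  expect_identical(render_card(lay, marks = list(Set = "A")),
                   render_card(lay, marks = list(Set = "A")))
})

test_that("marking a value inks the right spot darkly", {
  lay <- tiny_layout()
  img <- render_card(lay, marks = list(Set = "B"))
  m <- attr(img, "card_origin_px")
  sp <- lay$spots
  # probe below the printed value label but inside the spot: blank
  # spots are paper there, inked ones are covered by the mark disc
  dy <- round(sp$width[1L] * 0.34)
  a_px <- img[round(m[1L] + sp$x[sp$value_label == "A"]) + 1L,
              round(m[2L] + sp$y[sp$value_label == "A"]) + 1L + dy, ]
  b_px <- img[round(m[1L] + sp$x[sp$value_label == "B"]) + 1L,
              round(m[2L] + sp$y[sp$value_label == "B"]) + 1L + dy, ]
  expect_true(all(b_px < 0.2))
  expect_true(all(a_px > 0.8))
})

test_that("saved cards write both image and configuration file", {
  lay <- tiny_layout()
  dir <- withr::local_tempdir()
  paths <- save_card(lay, file.path(dir, "card.tif"))
  expect_true(all(file.exists(paths)))
  expect_equal(read_config(file.path(dir, "card.spotcard.cfg")), lay,
               tolerance = 1e-12)
  img <- load_photo(file.path(dir, "card.tif"))
  expect_equal(dim(img)[1:2], dim(render_card(lay))[1:2])
})
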
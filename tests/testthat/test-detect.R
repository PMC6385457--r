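# Detection tests run on synthetic photographs with known ground truth.

test_that("small colored specks are ignored by the largest-four rule", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- cached("fx_frontal",
               render_fixture(fixture_spec(lay, fig1_marks())))
  img <- fx$image
  # a ~10 px blue speck in the background
  img <- spotmark:::draw_disc(img, 15, 15, 5, c(0.05, 0.15, 0.85))
  dots <- find_corner_dots(img, "blue")
  expect_equal(nrow(dots), 4L)
  expect_true(all(dots$eqdiam > 60))
  # none of the four centroids is near the speck
  expect_true(all(sqrt((dots$cx - 15)^2 + (dots$cy - 15)^2) > 50))
})

test_that("an occluded corner dot stops the image with CORNERS_NOT_FOUND", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- render_fixture(fixture_spec(lay, fig1_marks(),
                                    occlude_corner = "top_left"))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_false(res$ok)
  expect_equal(res$error_code, "CORNERS_NOT_FOUND")
})

test_that("decoding is invariant to 0/90/180/270 degree card rotation", {
  lay <- cached("lay_fig1", fig1_layout())
  for (rot in c(0, 90, 180, 270)) {
    fx <- render_fixture(fixture_spec(lay, fig1_marks(),
                                      rotation_deg = rot))
    res <- suppressWarnings(read_card(fx$image, lay))
    expect_true(res$ok)
    expect_equal(unname(res$reading$values), c("B", "2", "37"))
    expect_equal(spotmark:::wrap180(res$detection$rotation_deg + rot), 0,
                 tolerance = 0.5)
  }
})

test_that("detector diagonal ratio matches cos(tilt) on orthographic renders", {
  lay <- cached("lay_fig1", fig1_layout())
  for (tilt in c(5, 10, 15)) {
    fx <- render_fixture(fixture_spec(lay, fig1_marks(), tilt_deg = tilt,
                                      tilt_axis = "diagonal",
                                      camera_distance_cards = Inf))
    res <- suppressWarnings(read_card(fx$image, lay))
    expect_true(res$ok)
    expect_equal(res$detection$diag_ratio, cos(tilt * pi / 180),
                 tolerance = 0.005)
  }
})

test_that("excessive tilt about a card axis fails the aspect check", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- render_fixture(fixture_spec(lay, fig1_marks(), tilt_deg = 25,
                                    tilt_axis = "x"))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_false(res$ok)
  expect_equal(res$error_code, "ASPECT_MISMATCH")
})

test_that("spot windows read near 0 on ink and near 255 on paper", {
  gray <- matrix(1, 200, 200)
  gray[81:120, 81:120] <- 20 / 255
  spot_dark <- data.frame(x = 100, y = 100, width = 50, height = 50)
  spot_blank <- data.frame(x = 30, y = 30, width = 50, height = 50)
  expect_lt(read_spot(gray, spot_dark, 1, 1), 30)
  expect_gt(read_spot(gray, spot_blank, 1, 1), 240)
  spot_out <- data.frame(x = 2, y = 2, width = 50, height = 50)
  expect_error(read_spot(gray, spot_out, 1, 1),
               class = "spotmark_error")
})

test_that("decoding flags unmarked and doubly-marked categories per category", {
  lay <- fig1_layout()
  n <- nrow(lay$spots)
  blank <- rep(255, n)

  r <- decode_reading(blank, lay)
  expect_equal(unname(r$values),
               c("MISSING", "MISSING", "MISSING"))
  expect_equal(r$status, "ok")

  means <- blank
  means[lay$spots$category_index == 1 &
          lay$spots$value_label %in% c("A", "C")] <- 10
  means[lay$spots$category_index == 2 & lay$spots$value_label == "3"] <- 10
  means[lay$spots$category_index == 3 & lay$spots$row_index == 0 &
          lay$spots$value_label == "4"] <- 10
  means[lay$spots$category_index == 3 & lay$spots$row_index == 1 &
          lay$spots$value_label == "2"] <- 10
  r <- decode_reading(means, lay)
  expect_equal(unname(r$values), c("AMBIGUOUS", "3", "42"))

  # an unmarked digit row makes the whole integer MISSING
  means2 <- blank
  means2[lay$spots$category_index == 3 & lay$spots$row_index == 1 &
           lay$spots$value_label == "9"] <- 10
  expect_equal(unname(decode_reading(means2, lay)$values)[3L], "MISSING")
})

test_that("duplicate center colors are reported as unresolved", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- cached("fx_frontal",
               render_fixture(fixture_spec(lay, fig1_marks())))
  img <- fx$image
  dots <- find_corner_dots(img, "blue")
  # paint every center red
  for (i in 1:4)
    img <- spotmark:::draw_disc(img, dots$cx[i], dots$cy[i],
                                dots$eqdiam[i] / 5, c(0.9, 0.05, 0.05))
  expect_error(identify_orientation(img, find_corner_dots(img, "blue")),
               class = "spotmark_error")
})

test_that("pink-palette cards are detected like blue ones", {
  lay <- layout_card(fig1_categories(), flower_diameter_mm = 20,
                     palette = "pink")
  fx <- render_fixture(fixture_spec(lay, fig1_marks(), rotation_deg = 45))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_true(res$ok)
  expect_equal(unname(res$reading$values), c("B", "2", "37"))
})
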
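test_that("area is exact pixel counting times the scale product", {
  sq <- matrix(FALSE, 140, 140)
  sq[21:120, 21:120] <- TRUE
  m <- measure_region(sq, 0.1)
  expect_equal(unname(m["area_mm2"]), 100)                # exact
  expect_equal(unname(m["perimeter_mm"]), 40, tolerance = 0.02)
})

test_that("random blob areas equal the brute-force pixel count", {
  set.seed(7)
  for (r in c(8, 15, 23)) {
    blob <- disc_mask(r)
    s <- 0.05 * r
    m <- measure_region(blob, s)
    expect_equal(unname(m["area_mm2"]), sum(blob) * s^2)
  }
})

test_that("disc area and perimeter match closed forms within tolerance", {
  for (r_px in c(50, 100, 200)) {
    blob <- disc_mask(r_px)
    m <- measure_region(blob, 0.1)
    r_mm <- r_px * 0.1
    expect_equal(unname(m["area_mm2"]), pi * r_mm^2, tolerance = 0.03)
    expect_equal(unname(m["perimeter_mm"]), 2 * pi * r_mm, tolerance = 0.05)
  }
})

test_that("area is conserved exactly under quarter-turn rotations of the mask", {
  blob <- disc_mask(17)
  blob[10:12, 20:40] <- TRUE  # asymmetric appendage
  base <- measure_region(blob, 0.1)
  rot90 <- t(blob)[ncol(blob):1, ]
  expect_equal(measure_region(rot90, 0.1)["area_mm2"], base["area_mm2"])
})

test_that("scale factors derive from the card's physical size", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- cached("fx_scale10",
               render_fixture(fixture_spec(lay, fig1_marks(),
                                           px_per_mm = 10)))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_true(res$ok)
  sc <- compute_scale(res$detection, lay)
  expect_equal(sc$x, 0.1, tolerance = 0.01)
  expect_equal(sc$geom, 0.1, tolerance = 0.01)
})

test_that("synthetic disc flowers measure close to their analytic size", {
  for (r in c(10, 20)) {
    lay <- suppressWarnings(
      layout_card(fig1_categories(), flower_diameter_mm = 2 * r))
    fx <- render_fixture(fixture_spec(lay, fig1_marks(),
                                      flower_radius_mm = r))
    res <- suppressWarnings(read_card(fx$image, lay))
    expect_true(res$ok)
    seg <- segment_flower(res$detection, lay)
    m <- measure_region(seg$mask, compute_scale(res$detection, lay))
    expect_equal(unname(m["area_mm2"]), pi * r^2, tolerance = 0.03)
    expect_equal(unname(m["perimeter_mm"]), 2 * pi * r, tolerance = 0.05)
  }
})

test_that("measurements are stable under a 2x change of render scale", {
  lay <- cached("lay_fig1", fig1_layout())
  res <- lapply(c(8, 16), function(ppm) {
    fx <- render_fixture(fixture_spec(lay, fig1_marks(),
                                      flower_radius_mm = 10,
                                      px_per_mm = ppm))
    r <- suppressWarnings(read_card(fx$image, lay))
    seg <- segment_flower(r$detection, lay)
    measure_region(seg$mask, compute_scale(r$detection, lay))
  })
  expect_equal(res[[1L]][["area_mm2"]], res[[2L]][["area_mm2"]],
               tolerance = 0.02)
  expect_equal(res[[1L]][["perimeter_mm"]], res[[2L]][["perimeter_mm"]],
               tolerance = 0.02)
})

test_that("a card without a flower yields FLOWER_NOT_FOUND, not a fake area", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- cached("fx_frontal",
               render_fixture(fixture_spec(lay, fig1_marks())))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_error(segment_flower(res$detection, lay),
               class = "spotmark_error")
})
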
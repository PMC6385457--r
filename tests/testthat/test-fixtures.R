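test_that("clean frontal renders decode exactly to the ground truth", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- cached("fx_frontal",
               render_fixture(fixture_spec(lay, fig1_marks())))
  expect_equal(unname(fx$truth$expected_values), c("B", "2", "37"))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_true(res$ok)
  expect_equal(res$reading$values, fx$truth$expected_values)
})

test_that("a blank card decodes every category MISSING with ok status", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- render_fixture(fixture_spec(lay, marks = NULL))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_true(res$ok)
  expect_equal(unname(res$reading$values),
               rep("MISSING", 3L))
})

test_that("fixture rendering is reproducible for identical specs", {
  lay <- tiny_layout()
  spec <- fixture_spec(lay, list(Set = "B"), rotation_deg = 33,
                       tilt_deg = 7, background = "textured",
                       noise_sigma = 0.02, seed = 5L)
  expect_identical(render_fixture(spec)$image, render_fixture(spec)$image)
  # and differs for a different seed
  spec2 <- spec; spec2$seed <- 6L
  expect_false(identical(render_fixture(spec)$image,
                         render_fixture(spec2)$image))
})

test_that("an 18-degree diagonal tilt sits at the documented ratio boundary", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- render_fixture(fixture_spec(lay, fig1_marks(), tilt_deg = 18,
                                    tilt_axis = "diagonal",
                                    camera_distance_cards = Inf))
  expect_equal(fx$truth$expected_diag_ratio, cos(18 * pi / 180))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_true(res$ok)
  expect_equal(res$detection$diag_ratio, 0.951, tolerance = 0.005)
})

test_that("written fixtures carry a readable ground-truth sidecar", {
  lay <- tiny_layout()
  dir <- withr::local_tempdir()
  write_fixture(fixture_spec(lay, list(Set = "A"), tilt_deg = 4),
                file.path(dir, "fx"))
  expect_true(file.exists(file.path(dir, "fx.jpg")))
  truth <- jsonlite::read_json(file.path(dir, "fx.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$expected_values[["Set"]], "A")
  expect_equal(truth$tilt_deg, 4)
})

test_that("noise and illumination gradients within spec do not break decoding", {
  lay <- cached("lay_fig1", fig1_layout())
  fx <- render_fixture(fixture_spec(lay, fig1_marks(), rotation_deg = 75,
                                    tilt_deg = 8, background = "textured",
                                    noise_sigma = 0.03,
                                    illumination_gradient = 0.3,
                                    seed = 3L))
  res <- suppressWarnings(read_card(fx$image, lay))
  expect_true(res$ok)
  expect_equal(res$reading$values, fx$truth$expected_values)
})

test_that("fixture presets render through the command-line helper", {
  lay <- tiny_layout()
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "card.spotcard.cfg")
  write_config(lay, cfg)
  stems <- write_fixture_preset(cfg, preset = "failure_modes",
                                out_dir = file.path(dir, "fx"), seed = 1L)
  expect_length(stems, 4L)
  expect_true(all(file.exists(paste0(stems, ".jpg"))))
  expect_true(all(file.exists(paste0(stems, ".json"))))
})
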
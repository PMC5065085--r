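test_that("generation is byte-deterministic given the seed", {
  sp <- fixture_spec("UVVIS", form = "DIF", seed = 42)
  a <- generate_fixture(sp, id = "000000001")
  b <- generate_fixture(sp, id = "000000001")
  expect_identical(a$text, b$text)
  c <- generate_fixture(fixture_spec("UVVIS", form = "DIF", seed = 43),
                        id = "000000001")
  expect_false(identical(a$text, c$text))
})

test_that("a noiseless single peak is maximal at the nearest grid point", {
  sp <- fixture_spec("UVVIS", n_peaks = 1, noise_sd = 0, seed = 13)
  fx <- generate_fixture(sp)
  pts <- fx$record$data$points
  # the generator drew one center; the y maximum must sit on the grid
  # point nearest that center, reproducible from the same seed
  center <- specdx:::.with_seed(13, stats::runif(1, 200, 800))
  dx <- abs(pts$x[2] - pts$x[1])
  # quantization can tie the two grid points flanking the center, so the
  # maximum must sit within one grid step of it
  expect_lte(abs(pts$x[which.max(pts$y)] - center), dx)
})

test_that("generated files validate and carry the requested geometry", {
  for (tech in c("UVVIS", "IR", "MS")) {
    sp <- fixture_spec(tech, seed = 4)
    fx <- generate_fixture(sp)
    expect_true(fx$record$report$is_valid, info = tech)
    expect_identical(length(fx$record$data$raw_y),
                     as.integer(sp$n_points), info = tech)
  }
  # IR grids run high-to-low: strictly decreasing X
  ir <- generate_fixture(fixture_spec("IR", seed = 4))
  expect_true(all(diff(ir$record$data$points$x) < 0))
  # MS writes a PEAKTABLE whatever form was requested
  ms <- generate_fixture(fixture_spec("MS", form = "DIFDUP", seed = 4))
  expect_identical(ms$record$data$table_form, "PEAKTABLE")
  expect_match(ms$text, "##PEAKTABLE=", fixed = TRUE)
})

test_that("fixture specs reject impossible geometries", {
  expect_error(fixture_spec("UVVIS", x_range = c(5, 5)), "interval")
  expect_error(fixture_spec("UVVIS", n_points = 1), "n_points")
  expect_error(fixture_spec("IR", noise_sd = -1), "non-negative")
  expect_error(fixture_spec("MS", yfactor = 0), "positive")
})

test_that("each corruption mode produces its promised report entry", {
  fx <- generate_fixture(fixture_spec("UVVIS", form = "DIFDUP", seed = 8))

  ct <- corrupt_fixture(fx$text, "DROP_LDR", seed = 1)
  expect_false(identical(ct, fx$text))
  rec <- jdx_parse(ct)
  expect_false(rec$report$is_valid)
  expect_identical(sum(grepl("required label .* is missing",
                             rec$report$errors$message)), 1L)

  ct <- corrupt_fixture(fx$text, "BAD_CHAR", seed = 1)
  rec <- jdx_parse(ct)
  expect_true(any(grepl("invalid character|lacks a leading X",
                        rec$report$errors$message)))

  ct <- corrupt_fixture(fx$text, "TRUNCATE_TABLE", seed = 1)
  rec <- jdx_parse(ct)
  expect_true(any(grepl("point\\(s\\) decoded", rec$report$errors$message)))
  expect_lt(length(rec$data$raw_y), fx$spec$n_points)

  ct <- corrupt_fixture(fx$text, "BAD_YCHECK", seed = 1)
  rec <- jdx_parse(ct)
  expect_true(any(grepl("Y-check mismatch", rec$report$errors$message)))

  # BAD_YCHECK needs DIF-mode continuation lines to exist
  ms <- generate_fixture(fixture_spec("MS", seed = 8))
  expect_error(corrupt_fixture(ms$text, "BAD_YCHECK", seed = 1),
               "DIF-mode")
})
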
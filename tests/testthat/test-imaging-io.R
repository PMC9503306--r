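test_that("scan geometry validates fields and derives pixel sizes", {
  g <- scan_geometry(6, 6, 500, 500)
  expect_equal(pixel_width_um(g), 12)
  expect_equal(pixel_height_um(g), 12)
  expect_equal(pixel_area_um2(g), 144)
  g2 <- scan_geometry(3, 6, 300, 500)
  expect_equal(pixel_width_um(g2), 10)
  expect_equal(pixel_area_um2(g2), 10 * 12)
  expect_error(scan_geometry(0, 6, 500, 500), "positive")
  expect_error(scan_geometry(6, 6, 1, 500), ">= 2")
})

test_that("en-face images round-trip losslessly through TIFF and PNG at both depths", {
  withr::local_seed(42)
  for (depth in c(8L, 16L)) {
    maxval <- 2^depth - 1
    g <- scan_geometry(6, 6, 13, 11)
    px <- matrix(sample(0:maxval, 11 * 13, replace = TRUE), 11, 13)
    img <- enface_image(px, depth, g, "flow")
    path <- withr::local_tempfile(fileext = ".tif")
    write_enface(img, path)
    back <- read_enface(path, g, "flow")
    expect_identical(back$pixels, px)
    expect_identical(back$bit_depth, depth)
    expect_equal(pixel_area_um2(back$geometry), pixel_area_um2(g))
    if (depth == 8L) {
      p2 <- withr::local_tempfile(fileext = ".png")
      write_enface(img, p2)
      expect_identical(read_enface(p2, g, "flow")$pixels, px)
    }
  }
})

test_that("read_enface rejects missing files, geometry mismatches and RGB input", {
  g <- scan_geometry(6, 6, 4, 4)
  expect_error(read_enface("no/such/file.tif", g), "cannot read")
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), path)
  expect_error(read_enface(path, scan_geometry(6, 6, 512, 4)),
               "geometry declares")
  rgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(4, 4, 3)), rgb)
  expect_error(read_enface(rgb, g), "single-channel")
  # degenerate all-zero 16-bit image reads back as all zero
  zpath <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 4, 4), zpath, bits.per.sample = 16L)
  z <- read_enface(zpath, g)
  expect_equal(range(z$pixels), c(0, 0))
  expect_identical(z$bit_depth, 16L)
})

test_that("masks serialize as 0/255 with deficit black and round-trip losslessly", {
  g <- scan_geometry(6, 6, 4, 4)
  all_def <- binary_mask(matrix(TRUE, 4, 4), g)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(all_def, path)
  expect_true(all(png::readPNG(path) == 0))

  checker <- binary_mask(outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0), g)
  for (ext in c(".png", ".tif")) {
    p <- withr::local_tempfile(fileext = ext)
    write_mask(checker, p)
    back <- read_mask(p, g, radius_px = 4L)
    expect_identical(back$pixels, checker$pixels)
    expect_identical(back$radius_px, 4L)
    # write -> read -> write is byte-identical (idempotent encoding)
    p2 <- withr::local_tempfile(fileext = ext)
    write_mask(back, p2)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("report CSV has the documented schema and parses numbers back exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fd_report(list(), path)
  empty <- read_fd_report(path)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("eye_id", "group", "radius_px", "fd_percent",
                        "fd_count", "fd_mean_size_um2", "fd_total_area_mm2"))

  g <- scan_geometry()
  reps <- list(
    fd_report(48.96, 100L, 50, 17.6256, 4L, g, eye_id = "e1", group = "1b"),
    fd_report(41.2, 80L, 40, 14.832, 8L, g, eye_id = "e1", group = "1b"),
    fd_report(30.1, 10L, 20, 10.836, 4L, g, eye_id = "e2", group = "2"),
    fd_report(31.5, 12L, 22, 11.34, 8L, g, eye_id = "e2", group = "2"))
  write_fd_report(reps, path, params = list(sigma_px = 2, radii = c(4, 8)))
  back <- read_fd_report(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$fd_percent[1], 48.96)
  expect_equal(back$eye_id, c("e1", "e1", "e2", "e2"))
  # parameter header is logged as comment lines
  expect_true(any(grepl("^# sigma_px", readLines(path))))
})

test_that("fd_report enforces its internal consistency invariants", {
  expect_error(fd_report(120, 1L, 1, 1), "0, 100")
  expect_error(fd_report(10, 0L, 0, 5), "if and only if")
  r <- fd_report(0, 0L, 0, 0)
  expect_equal(r$fd_count, 0L)
})
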
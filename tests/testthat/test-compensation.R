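test_that("inversion reflects intensities about full scale and is an involution", {
  g <- scan_geometry(6, 6, 5, 5)
  px <- matrix(c(0, 100, 255, rep(7, 22)), 5, 5)
  img <- enface_image(px, 8L, g, "structure")
  inv <- invert_image(img)
  expect_equal(inv$pixels[1, 1], 255)
  expect_equal(inv$pixels[2, 1], 155)
  expect_equal(inv$pixels[3, 1], 0)
  withr::local_seed(1)
  img16 <- rand_image(9, 7, maxval = 65535)
  expect_identical(invert_image(invert_image(img16))$pixels, img16$pixels)
})

test_that("gaussian smoothing normalizes its kernel and matches a direct convolution oracle", {
  g <- scan_geometry(6, 6, 7, 7)
  const <- enface_image(matrix(123, 7, 7), 8L, g, "flow")
  expect_identical(gaussian_smooth(const, 3)$pixels, const$pixels)

  withr::local_seed(2)
  img <- rand_image(7, 7)
  expect_identical(gaussian_smooth(img, 0)$pixels, img$pixels)
  expect_error(gaussian_smooth(img, -1), "nonnegative")

  impulse <- matrix(0, 7, 7); impulse[4, 4] <- 255
  sm <- gaussian_smooth(enface_image(impulse, 8L, g, "flow"), 1)
  for (ij in list(c(4, 4), c(3, 4), c(2, 5), c(1, 1))) {
    expect_equal(sm$pixels[ij[1], ij[2]],
                 floor(oracle_gauss_at(impulse, ij[1], ij[2], 1) + 0.5))
  }
  # oracle check on a dense random image too, away from the impulse case
  sm2 <- gaussian_smooth(img, 1.5)
  for (ij in list(c(1, 1), c(4, 3), c(7, 7), c(2, 6))) {
    expect_equal(sm2$pixels[ij[1], ij[2]],
                 floor(oracle_gauss_at(img$pixels, ij[1], ij[2], 1.5) + 0.5))
  }
})

test_that("compensation handles degenerate structure images as multiplication dictates", {
  g <- scan_geometry(6, 6, 8, 8)
  withr::local_seed(3)
  flow <- rand_image(8, 8)
  # uniformly bright structure -> inverse is 0 everywhere -> zero product
  bright <- enface_image(matrix(255, 8, 8), 8L, g, "structure")
  out <- compensate(flow, bright)
  expect_true(all(out$pixels == 0))
  expect_identical(out$channel, "compensated")
  # constant structure -> positive scalar multiple of flow: rank order kept
  px <- matrix(100:163, 8, 8)
  flow2 <- enface_image(px, 8L, g, "flow")
  const <- enface_image(matrix(40, 8, 8), 8L, g, "structure")
  out2 <- compensate(flow2, const)
  expect_identical(order(out2$pixels), order(px))
  expect_true(all(diff(out2$pixels[order(px)]) > 0))
})

test_that("compensation validates geometry and is deterministic", {
  withr::local_seed(4)
  flow <- rand_image(8, 8)
  other <- rand_image(8, 9)
  expect_error(compensate(flow, other), "geometry")
  structure_img <- rand_image(8, 8)
  structure_img$channel <- "structure"
  a <- compensate(flow, structure_img)
  b <- compensate(flow, structure_img)
  expect_identical(a$pixels, b$pixels)
})

test_that("full-range rescale removes any positive scaling of the processed structure multiplier", {
  withr::local_seed(5)
  flow <- rand_image(12, 12)
  mult <- matrix(runif(144, 10, 200), 12, 12)
  rescale01 <- function(m) (m - min(m)) / (max(m) - min(m)) * 255
  a <- floor(rescale01(flow$pixels * mult) + 0.5)
  b <- floor(rescale01(flow$pixels * (3.7 * mult)) + 0.5)
  expect_identical(a, b)
})

test_that("compensation flattens a synthetic shadow band on the flow slab", {
  spec <- synthetic_spec(geometry = scan_geometry(6, 6, 200, 200),
                         target_fd_fraction = 0, noise_sd = 1, seed = 6,
                         shadow_bands = list(c(80, 120, 0.5)))
  pair <- generate_pair(spec)
  comp <- compensate(pair$flow, pair$structure)
  inside <- 90:110          # rows well inside the band (past the penumbra)
  outside <- c(10:60, 150:190)
  ratio <- function(px) mean(px[inside, ]) / mean(px[outside, ])
  r_raw <- ratio(pair$flow$pixels)
  r_comp <- ratio(comp$pixels)
  expect_lt(abs(r_comp - 1), abs(r_raw - 1))
  expect_lt(abs(r_raw - 0.5), 0.05)   # the band really attenuates ~2x
  expect_lt(abs(r_comp - 1), 0.05)    # and compensation restores it
})
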
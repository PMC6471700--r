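test_that("normalization and cropping behave per contract", {
  img <- matrix(c(10, 12, 15, 20), 2, 2)
  expect_equal(normalize_image(img), (img - 10) / 10)
  already <- matrix(seq(0, 1, length.out = 12), 3, 4)
  expect_equal(normalize_image(already), already, tolerance = 1e-12)
  expect_error(normalize_image(matrix(3, 2, 2)), "constant")

  ramp <- outer(1:50, 1:60)
  expect_equal(crop_field(ramp, c(1, 1, 50, 60)), ramp, ignore_attr = TRUE)
  top <- crop_field(ramp, c(1, 1, 30, 30))
  expect_equal(unclass(top), ramp[1:30, 1:30], ignore_attr = TRUE)
  expect_identical(attr(top, "crop_window"), c(1L, 1L, 30L, 30L))
  expect_error(crop_field(ramp, c(-1, 1, 10, 10)), "out of bounds")
  expect_error(crop_field(ramp, c(30, 40, 30, 30)), "out of bounds")
})

test_that("self-registration is a fixed point of the optimizer", {
  ph <- small_phantom(noise_sd = 0)
  w <- normalize_image(render_white_still(ph, 1))
  for (tr in c("translation", "rigid")) {
    reg <- register_images(w, w, reg_config(transform = tr))
    expect_lt(max(abs(reg$transform$params)), 0.1)
    expect_lt(reg$metric_value, 1e-6)
    expect_equal(sum(reg$overlay), sum(w), tolerance = 0.02)
  }
})

test_that("planted translations up to 10 px are recovered within half a pixel", {
  ph <- tissue_phantom(noise_sd = 0)
  w <- normalize_image(render_white_still(ph, 1))
  for (sh in list(c(5, -3), c(10, 7), c(-10, 4))) {
    mv <- shift_image(w, sh[1], sh[2])
    reg <- register_images(mv, w, reg_config(transform = "translation"))
    expect_lt(max(abs(reg$transform$params - sh)), 0.5)
    expect_true(reg$iterations <= 300)
  }
})

test_that("fiducial centroids coincide within one pixel after registration", {
  ph <- tissue_phantom(noise_sd = 1)
  w <- normalize_image(render_white_still(ph, 1))
  mv <- shift_image(normalize_image(render_white_still(ph, 2)), 6, -4)
  reg <- register_images(mv, w, reg_config(transform = "translation"))
  expect_lt(max(abs(bright_centroid(reg$overlay) - bright_centroid(w))), 1)
})

test_that("the homogeneous transform matrix reproduces the coordinate mapping", {
  p <- c(0.1, 3, -2)   # theta, t_row, t_col
  center <- c(10, 12)
  M <- nirdr:::transform_matrix(p, "rigid", center)
  tc <- nirdr:::transform_coords(p, "rigid", 4, 7, center)
  expect_equal(as.vector(M %*% c(4, 7, 1))[1:2], c(tc$r, tc$c))
})

test_that("the mutual-information metric also recovers an alignment", {
  ph <- small_phantom(noise_sd = 0)
  w <- normalize_image(render_white_still(ph, 1))
  mv <- shift_image(w, 3, 2)
  reg <- register_images(mv, w, reg_config(transform = "translation", metric = "mi"))
  expect_lt(max(abs(reg$transform$params - c(3, 2))), 1)
})

test_that("degenerate registration inputs are rejected", {
  img <- matrix(runif(100), 10, 10)
  expect_error(register_images(matrix(1, 10, 10), img), "nonconstant")
  expect_error(register_images(img, matrix(0, 10, 10)), "nonconstant")
})
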
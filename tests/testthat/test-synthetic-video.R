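test_that("rendering is bit-reproducible for a fixed seed", {
  cfg <- small_config()
  ph <- small_phantom(noise_sd = 3)
  v1 <- render_video(cfg, ph, "REST", seed = 7)
  v2 <- render_video(cfg, ph, "REST", seed = 7)
  expect_identical(v1$frames, v2$frames)
  v3 <- render_video(cfg, ph, "REST", seed = 8)
  expect_false(identical(v1$frames, v3$frames))

  st <- render_occlusion_study(cfg, ph, seed = 5)
  st2 <- render_occlusion_study(cfg, ph, seed = 5)
  expect_identical(st$occlusion$frames, st2$occlusion$frames)
  expect_identical(st$white, st2$white)
})

test_that("frame labels contain exactly three complete cycles of the four-state sequence", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  in_cycle <- vid$cycle_index >= 1 & vid$cycle_index <= cfg$n_cycles
  compressed <- rle(vid$frame_labels[in_cycle])$values
  expect_identical(compressed, rep(cfg$source_sequence, 3L))
})

test_that("with no subsurface and no noise every NIR frame has rank at most r_surf + 1", {
  cfg <- small_config()
  ph <- tissue_phantom(frame_shape = c(60L, 80L), noise_sd = 0,
                       subsurface_map = matrix(0, 60, 80))
  vid <- render_video(cfg, ph, "REST", seed = 1, quantize = FALSE)
  nir <- which(vid$frame_labels %in% c("NIR690", "NIR800", "NIR840"))
  for (f in nir[c(1, 25, 49)]) {
    sv <- svd(vid$frames[, , f], nu = 0, nv = 0)$d
    expect_lte(sum(sv > 1e-8 * sv[1]), ph$r_surf + 1L)
  }
})

test_that("the noiseless red-channel trace is piecewise constant with 4 x cycles + flash plateaus", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  prof <- intensity_profile(vid)
  vals <- prof$values
  nondark <- vals > 0.1 * max(vals)
  runs <- rle(round(vals[nondark], 10))
  expect_equal(length(runs$values), 4L * cfg$n_cycles + 1L)
})

test_that("planted occlusion factors order the tissue means and white light is brightest", {
  cfg <- small_config()
  ph <- small_phantom(noise_sd = 1)
  st <- render_occlusion_study(cfg, ph, seed = 3)
  tissue_mean <- function(video) {
    f <- which(video$frame_labels == "NIR690")
    mean(video$frames[, , f])
  }
  m <- vapply(st[c("rest", "occlusion", "release")], tissue_mean, 0)
  expect_lt(m[["occlusion"]], m[["rest"]])
  expect_gt(m[["release"]], m[["occlusion"]])

  prof <- intensity_profile(st$rest)
  lab <- segment_profile(prof, cfg)
  white_level <- max(lab$level_centers)
  expect_true(all(lab$level_centers[-which.max(lab$level_centers)] < white_level))
})

test_that("ill-posed configurations and mismatched phantoms are rejected", {
  expect_error(render_video(acq_config(frame_rate_hz = 4, multiplex_hz = 2.5,
                                       frame_shape = c(10L, 10L))),
               "at least 2")
  cfg <- small_config()
  expect_error(render_video(cfg, tissue_phantom(frame_shape = c(30L, 40L))),
               "does not match")
})

test_that("phantom construction enforces its invariants", {
  ph <- small_phantom()
  sv <- svd(ph$surface_map, nu = 0, nv = 0)$d
  expect_lte(sum(sv > 1e-8 * sv[1]), ph$r_surf)
  expect_error(tissue_phantom(frame_shape = c(20L, 20L),
                              occlusion_delta = list(NIR690 = c(1, -0.5, 1))),
               "strictly positive")
  expect_error(tissue_phantom(frame_shape = c(20L, 20L), noise_sd = -1),
               "nonnegative")
  # a high-rank user surface map is rejected
  set.seed(1)
  expect_error(tissue_phantom(frame_shape = c(20L, 20L),
                              surface_map = matrix(runif(400), 20, 20)),
               "rank")
})
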
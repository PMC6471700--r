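test_that("intensity profile is the mean red value per frame", {
  frames <- array(0, dim = c(4, 5, 3))
  frames[, , 1] <- 100
  frames[, , 2] <- 0
  frames[, , 3] <- 30.5
  prof <- intensity_profile(frames, frame_rate_hz = 60, single_channel = TRUE)
  expect_equal(prof$values, c(100, 0, 30.5))

  rgb <- array(0, dim = c(4, 5, 3, 2))
  rgb[, , 1, 1] <- 7; rgb[, , 2, 1] <- 99   # green must be ignored
  prof2 <- intensity_profile(rgb)
  expect_equal(prof2$values, c(7, 0))

  expect_error(intensity_profile(array(0, dim = c(4, 5, 0)), single_channel = TRUE))
  expect_error(intensity_profile(frames), "single_channel")
})

test_that("noiseless profile matches the ground-truth labels on segment interiors", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  prof <- intensity_profile(vid)
  lab <- segment_profile(prof, cfg)
  segs <- lab$segments
  in_cycles <- segs[!is.na(segs$cycle) & segs$cycle <= lab$n_cycles_detected, ]
  for (i in seq_len(nrow(in_cycles))) {
    truth <- unique(vid$frame_labels[in_cycles$int_start[i]:in_cycles$int_end[i]])
    expect_identical(truth, in_cycles$state[i])
  }
})

test_that("segmentation finds 3 cycles and 4 distinguishable source states", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  lab <- segment_profile(intensity_profile(vid), cfg)
  expect_equal(lab$n_cycles_detected, 3L)
  nondark <- lab$level_centers >= 0.1 * max(lab$level_centers)
  expect_equal(sum(nondark), 4L)
  # per cycle: one WHITE followed by the three NIR states in multiplex order
  for (cy in 1:3) {
    states <- lab$segments$state[!is.na(lab$segments$cycle) & lab$segments$cycle == cy]
    expect_identical(states, c("WHITE", "NIR690", "NIR800", "NIR840"))
  }
})

test_that("a video truncated mid-cycle yields fewer cycles with a warning", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  # cut inside the second cycle's second NIR dwell
  segs <- segment_profile(intensity_profile(vid), cfg)$segments
  cut <- segs$start[!is.na(segs$cycle) & segs$cycle == 2 & segs$state == "NIR800"] + 3L
  tr <- vid
  tr$frames <- vid$frames[, , 1:cut, drop = FALSE]
  expect_warning(lab <- segment_profile(intensity_profile(tr), cfg), "truncated")
  expect_equal(lab$n_cycles_detected, 1L)
})

test_that("indistinct profiles are rejected with the level count found", {
  prof <- structure(list(values = rep(c(10, 200), each = 50), frame_rate_hz = 60),
                    class = "intensity_profile")
  expect_error(segment_profile(prof), "distinguishable source-intensity levels")
})

test_that("switching frequency is recovered from the median inter-switch gap", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  expect_equal(estimate_switching_frequency(intensity_profile(vid)), 2.5)

  # plateaus switching every 30 frames at 60 fps: 2 Hz
  prof <- structure(list(values = rep(rep(c(50, 100, 150, 200), each = 30), 3),
                         frame_rate_hz = 60),
                    class = "intensity_profile")
  expect_equal(estimate_switching_frequency(prof), 2)

  const <- structure(list(values = rep(5, 100), frame_rate_hz = 60),
                     class = "intensity_profile")
  expect_error(estimate_switching_frequency(const), "constant profile")
})

test_that("switching frequency survives sensor noise up to sd 5", {
  cfg <- small_config()
  for (s in 1:3) {
    vid <- render_video(cfg, small_phantom(noise_sd = 5), "REST", seed = s)
    est <- estimate_switching_frequency(intensity_profile(vid))
    expect_equal(est, 2.5, tolerance = 1 / dwell_frames(cfg))
  }
})

test_that("extracted wavelength images reproduce the quantized phantom exactly", {
  cfg <- small_config()
  ph <- small_phantom()
  vid <- render_video(cfg, ph, "OCCLUSION", seed = 1)
  lab <- segment_profile(intensity_profile(vid), cfg)
  imgs <- extract_wavelength_images(vid, lab, cycle = 2)
  expect_named(imgs, c("NIR690", "NIR800", "NIR840"))
  for (st in names(imgs)) {
    oracle <- round(pmin(pmax(
      ph$wavelength_gain[[st]] * ph$occlusion_delta[[st]][["OCCLUSION"]] *
        (ph$surface_map + ph$subsurface_map) + ph$fiducial_map, 0), 255))
    expect_equal(unclass(imgs[[st]]), oracle, ignore_attr = TRUE)
  }
})

test_that("frame combination rules agree on identical frames and cycles are permutation-safe", {
  cfg <- small_config()
  vid <- render_video(cfg, small_phantom(), "REST", seed = 1)
  lab <- segment_profile(intensity_profile(vid), cfg)
  for (pick in c("mean", "first", "median")) {
    img <- extract_wavelength_images(vid, lab, 1, frame_pick = pick)$NIR690
    expect_equal(unclass(img),
                 unclass(extract_wavelength_images(vid, lab, 1)$NIR690),
                 ignore_attr = TRUE)
  }
  # requesting cycles in any order gives identical per-cycle images
  a2 <- extract_wavelength_images(vid, lab, 2)
  a1 <- extract_wavelength_images(vid, lab, 1)
  b2 <- extract_wavelength_images(vid, lab, 2)
  expect_identical(a2, b2)
  expect_equal(unclass(a1$NIR690), unclass(b2$NIR690),
               ignore_attr = TRUE)               # noiseless: cycles equal

  expect_error(extract_wavelength_images(vid, lab, 4), "cycle 4")
})
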
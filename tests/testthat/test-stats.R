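test_that("box sampling honours count, size, disjointness and determinism", {
  s <- sample_boxes(c(1, 1, 300, 300), seed = 1)
  expect_equal(nrow(s$boxes), 17L)
  expect_equal(s$box_size, 30L)
  # pairwise disjoint and inside the roi
  for (i in seq_len(nrow(s$boxes))) {
    expect_gte(s$boxes$row0[i], 1); expect_lte(s$boxes$row0[i] + 29, 300)
    for (j in seq_len(i - 1)) {
      expect_true(abs(s$boxes$row0[i] - s$boxes$row0[j]) >= 30 ||
                    abs(s$boxes$col0[i] - s$boxes$col0[j]) >= 30)
    }
  }
  expect_identical(sample_boxes(c(1, 1, 300, 300), seed = 1), s)
  expect_false(identical(sample_boxes(c(1, 1, 300, 300), seed = 2)$boxes, s$boxes))

  s1 <- sample_boxes(c(5, 9, 40, 40), n_boxes = 1)
  expect_equal(nrow(s1$boxes), 1L)
  expect_error(sample_boxes(c(1, 1, 40, 40)), "at most 1 non-overlapping")
})

test_that("time-stamp summaries compute per-box means, grand mean and sample sd", {
  img <- matrix(7, 100, 100)
  s <- sample_boxes(c(1, 1, 100, 100), n_boxes = 3, seed = 2)
  su <- summarize_timestamp(img, s, timestamp = "REST")
  expect_equal(su$per_box_means, rep(7, 3))
  expect_equal(su$mean, 7)
  expect_equal(su$sd, 0)

  # two hand-placed boxes with means 4 and 6: mean 5, sd sqrt(2)
  img2 <- matrix(0, 60, 30)
  img2[1:30, ] <- 4
  img2[31:60, ] <- 6
  hand <- structure(list(boxes = data.frame(row0 = c(1L, 31L), col0 = c(1L, 1L)),
                         box_size = 30L, roi = c(1L, 1L, 60L, 30L), seed = 0L),
                    class = "box_sampling")
  su2 <- summarize_timestamp(img2, hand)
  expect_equal(su2$mean, 5)
  expect_equal(su2$sd, sqrt(2))

  oob <- structure(list(boxes = data.frame(row0 = 50L, col0 = 1L),
                        box_size = 30L, roi = c(1L, 1L, 60L, 30L), seed = 0L),
                   class = "box_sampling")
  expect_error(summarize_timestamp(img2, oob), "outside")
})

test_that("the hypothesis counter counts exactly the two physiological comparisons", {
  x <- rep(3, 17)
  expect_warning(expect_warning(expect_warning(
    h0 <- hypothesis_counter(x, x, x), "zero variance"), "zero variance"),
    "zero variance")   # one warning per degenerate comparison
  expect_equal(h0$H, 0L)
  expect_equal(c(h0$p_rest_vs_occ, h0$p_occ_vs_relax, h0$p_rest_vs_relax), c(1, 1, 1))

  set.seed(21)
  occ <- rnorm(17, 10, 1)
  rest <- occ + 5 + rnorm(17, 0, 0.3)    # sd of differences > 0
  relax <- occ + 5 + rnorm(17, 0, 0.3)
  h2 <- hypothesis_counter(rest, occ, relax)
  expect_equal(h2$H, 2L)
  # independently coded paired t: t = dbar / (s_d / sqrt(n)), df = 16
  d <- rest - occ
  t_oracle <- mean(d) / (sd(d) / sqrt(17))
  expect_equal(h2$t_rest_vs_occ, t_oracle, tolerance = 1e-12)
  expect_equal(h2$p_rest_vs_occ, 2 * pt(-abs(t_oracle), df = 16), tolerance = 1e-12)

  # an effect only in rest vs occlusion gives H = 1
  set.seed(22)
  noise <- rnorm(17, 0, 0.5)
  h1 <- hypothesis_counter(occ + 5 + noise, occ, occ + rnorm(17, 0, 0.4))
  expect_equal(h1$H, 1L)

  expect_error(hypothesis_counter(1:5, 1:5, 1:4), "differ in length")
})

test_that("hypothesis counter matches the closed-form paired-t oracle on random data", {
  set.seed(33)
  for (i in 1:200) {
    r <- rnorm(17, 10, 2); o <- rnorm(17, 10, 2); x <- rnorm(17, 10, 2)
    h <- hypothesis_counter(r, o, x)
    for (pair in list(list(r, o, h$t_rest_vs_occ, h$p_rest_vs_occ),
                      list(o, x, h$t_occ_vs_relax, h$p_occ_vs_relax),
                      list(r, x, h$t_rest_vs_relax, h$p_rest_vs_relax))) {
      d <- pair[[1]] - pair[[2]]
      t0 <- mean(d) / (sd(d) / sqrt(17))
      expect_equal(pair[[3]], t0, tolerance = 1e-10)
      expect_equal(pair[[4]], 2 * pt(-abs(t0), 16), tolerance = 1e-10)
    }
    expect_equal(h$H, (h$p_rest_vs_occ < 0.05) + (h$p_occ_vs_relax < 0.05))
  }
})

test_that("H is invariant under a common affine rescaling of all three summaries", {
  set.seed(44)
  r <- rnorm(17, 12, 1); o <- rnorm(17, 10, 1); x <- rnorm(17, 11, 1)
  h <- hypothesis_counter(r, o, x)
  hs <- hypothesis_counter(3.7 * r + 2, 3.7 * o + 2, 3.7 * x + 2)
  expect_equal(hs$H, h$H)
  expect_equal(hs$p_rest_vs_occ, h$p_rest_vs_occ, tolerance = 1e-9)
  expect_equal(hs$p_occ_vs_relax, h$p_occ_vs_relax, tolerance = 1e-9)
})

test_that("run_study produces the full band-by-repetition grid reproducibly", {
  cfg <- acq_config()
  ph <- tissue_phantom()
  st <- list(rest = render_wavelength_image(cfg, ph, "NIR690", "REST", seed = 11),
             occlusion = render_wavelength_image(cfg, ph, "NIR690", "OCCLUSION", seed = 12),
             release = render_wavelength_image(cfg, ph, "NIR690", "RELEASE", seed = 13),
             white = render_white_still(ph, 14))
  res <- run_study(st, ev_bands = c("1:15", "2:15", "3:15", "4:15", "5:15"),
                   repetitions = 4, base_seed = 9, register = FALSE)
  expect_s3_class(res, "occlusion_study_result")
  expect_equal(nrow(res$cells), 20L)
  expect_true(all(res$cells$H %in% 0:2))
  expect_true(all(table(res$cells$band) == 4))

  res2 <- run_study(st, ev_bands = c("1:15", "2:15", "3:15", "4:15", "5:15"),
                    repetitions = 4, base_seed = 9, register = FALSE)
  expect_identical(res$cells, res2$cells)

  s <- summary(res)
  expect_equal(nrow(s$by_band), 5L)
  expect_error(run_study(st[c("rest", "white")]), "missing")
})

test_that("expected H does not decrease as the planted occlusion effect grows", {
  cfg <- acq_config()
  mean_h <- vapply(c(1.0, 0.92, 0.8), function(occ_factor) {
    deltas <- null_deltas()
    deltas$NIR690 <- c(REST = 1, OCCLUSION = occ_factor, RELEASE = 1 / occ_factor)
    ph <- tissue_phantom(r_surf = 3, occlusion_delta = deltas)
    mean(vapply(1:8, function(s) measure_h_once(cfg, ph, 5000 + s), 0L))
  }, 0)
  expect_true(all(diff(mean_h) >= -0.25))   # non-decreasing within Monte-Carlo error
  expect_gt(mean_h[3], mean_h[1])
})
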
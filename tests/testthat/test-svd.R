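test_that("decomposition satisfies the factorization invariants", {
  d <- svd_decompose(diag(c(3, 1)))
  expect_equal(d$d, c(3, 1))

  u <- seq_len(6); v <- seq_len(5)
  d1 <- svd_decompose(outer(u, v))
  expect_lt(d1$d[2], 1e-10 * d1$d[1])

  set.seed(4)
  x <- matrix(rnorm(2000), 50, 40)
  d2 <- svd_decompose(x)
  rec <- d2$u %*% (d2$d * t(d2$v))
  expect_lt(norm(rec - x, "F") / norm(x, "F"), 1e-10)
  expect_lt(max(abs(crossprod(d2$u) - diag(40))), 1e-8)
  expect_lt(max(abs(crossprod(d2$v) - diag(40))), 1e-8)
  expect_true(all(diff(d2$d) <= 1e-12))

  expect_error(svd_decompose(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(svd_decompose(matrix(1:3, 3, 1)), "at least 2 x 2")
})

test_that("sign convention makes the decomposition deterministic", {
  set.seed(9)
  x <- matrix(rnorm(300), 20, 15)
  d <- svd_decompose(x)
  for (k in seq_along(d$d))
    expect_gte(d$u[which.max(abs(d$u[, k])), k], 0)
  expect_identical(svd_decompose(x), d)
})

test_that("band reconstruction equals the explicit rank-1 summation", {
  set.seed(11)
  for (i in 1:20) {
    x <- matrix(rnorm(300), 20, 15)
    d <- svd_decompose(x)
    band <- ev_band(sample(1:5, 1), sample(10:15, 1))
    oracle <- matrix(0, 20, 15)
    for (k in band$lo:band$hi)
      oracle <- oracle + d$d[k] * d$u[, k] %*% t(d$v[, k])
    expect_lt(norm(reconstruct_band(d, band) - oracle, "F") /
                max(norm(oracle, "F"), 1e-300), 1e-10)
  }
})

test_that("bands are additive, the full band is the identity, and the rank-1 residual is Eckart-Young", {
  set.seed(12)
  x <- matrix(rnorm(300), 20, 15) + 5
  d <- svd_decompose(x)
  expect_lt(norm(reconstruct_band(d, ev_band(1, 15)) - x, "F") / norm(x, "F"), 1e-10)
  sum_parts <- reconstruct_band(d, ev_band(1, 2)) + reconstruct_band(d, ev_band(3, 15))
  expect_equal(sum_parts, reconstruct_band(d, ev_band(1, 15)))

  r1 <- reconstruct_band(d, ev_band(1, 1))
  expect_equal(norm(x - r1, "F"), sqrt(sum(d$d[-1]^2)), tolerance = 1e-10)
})

test_that("the singular-value spectrum accessor behaves at the edges", {
  d <- svd_decompose(diag(c(5, 4, 3)))
  expect_equal(ev_spectrum(d, 1), 5)
  expect_equal(ev_spectrum(d, 3), c(5, 4, 3))
  expect_error(ev_spectrum(d, 4), "\\[1, 3\\]")
  expect_error(ev_spectrum(d, 0))
  z <- svd_decompose(matrix(0, 4, 4))
  expect_equal(ev_spectrum(z, 4), rep(0, 4))
})

test_that("band parsing accepts the lo:hi notation and rejects invalid bands", {
  b <- ev_band("4:15")
  expect_equal(c(b$lo, b$hi), c(4L, 15L))
  expect_equal(format(ev_band(1, 15)), "1:15")
  expect_error(ev_band("15:4"), "lo <= hi")
  expect_error(ev_band(0, 5))
  d <- svd_decompose(diag(c(2, 1)))
  expect_error(reconstruct_band(d, "1:15"), "exceeds")
  expect_error(reconstruct_series(d, hi = 15), "exceeds")
})

test_that("sequential reconstructions expose the subsurface after surface removal", {
  ph <- tissue_phantom(fiducial = NULL)
  cfg <- acq_config()
  img <- render_wavelength_image(cfg, ph, "NIR690", "REST", seed = 3)
  d <- svd_decompose(img)
  series <- reconstruct_series(d, hi = 15, lo_range = 1:8)
  expect_length(series, 8)
  expect_named(series, sprintf("%d:15", 1:8))
  cors <- vapply(series, function(r) cor(as.vector(r), as.vector(ph$subsurface_map)), 0)
  expect_gt(cors[["3:15"]], cors[["1:15"]])
  # the surface pair carries the bulk of the plotted spectrum
  expect_gt(sum(d$d[1:2]) / sum(d$d[1:15]), 0.9)
})
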
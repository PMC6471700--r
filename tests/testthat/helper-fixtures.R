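# Small, fast fixtures: a 60 x 80 sensor with a short start delay keeps unit
# tests quick; the acceptance tests use the full default acquisition.

small_config <- function(start_delay_s = 0.5, ...) {
  acq_config(frame_shape = c(60L, 80L), start_delay_s = start_delay_s, ...)
}

small_phantom <- function(noise_sd = 0, ...) {
  tissue_phantom(frame_shape = c(60L, 80L), noise_sd = noise_sd, ...)
}

# Shift an image by whole pixels, zero-filling: out[r, c] = img[r - dr, c - dc].
shift_image <- function(img, dr, dc) {
  out <- matrix(0, nrow(img), ncol(img))
  rs <- seq_len(nrow(img)); cs <- seq_len(ncol(img))
  ok_r <- rs - dr >= 1 & rs - dr <= nrow(img)
  ok_c <- cs - dc >= 1 & cs - dc <= ncol(img)
  out[rs[ok_r], cs[ok_c]] <- img[rs[ok_r] - dr, cs[ok_c] - dc]
  out
}

# Intensity-weighted centroid of the brightest pixels (marker detection).
bright_centroid <- function(img, q = 0.999) {
  th <- stats::quantile(img, q)
  idx <- which(img >= th, arr.ind = TRUE)
  w <- img[idx]
  c(sum(idx[, 1] * w) / sum(w), sum(idx[, 2] * w) / sum(w))
}

# Occlusion factors all 1: a phantom with no planted physiological change.
null_deltas <- function() {
  list(NIR690 = c(REST = 1, OCCLUSION = 1, RELEASE = 1),
       NIR800 = c(REST = 1, OCCLUSION = 1, RELEASE = 1),
       NIR840 = c(REST = 1, OCCLUSION = 1, RELEASE = 1))
}

# One end-to-end repetition of the occlusion measurement on freshly rendered
# wavelength images (fresh sensor noise and fresh boxes per call).
measure_h_once <- function(config, phantom, seed, band = "4:15") {
  st <- list(
    rest      = render_wavelength_image(config, phantom, "NIR690", "REST",
                                        seed = nirdr:::derive_seed(seed, 1L)),
    occlusion = render_wavelength_image(config, phantom, "NIR690", "OCCLUSION",
                                        seed = nirdr:::derive_seed(seed, 2L)),
    release   = render_wavelength_image(config, phantom, "NIR690", "RELEASE",
                                        seed = nirdr:::derive_seed(seed, 3L)),
    white     = render_white_still(phantom, nirdr:::derive_seed(seed, 4L)))
  run_study(st, ev_bands = band, repetitions = 1L, base_seed = seed,
            register = FALSE)$cells$H
}
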
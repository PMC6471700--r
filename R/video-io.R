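#' Write a video as a directory of numbered PNG frames
#'
#' The on-disk video container: 8-bit RGB PNG frames `frame_000001.png`, ...
#' (the red channel carries the signal; green and blue hold an attenuated
#' copy, as a stand-in for the broadband response of a colour sensor), plus a
#' `truth.json` sidecar with the ground-truth labels, configuration, and
#' phantom scalars for test oracles.
#'
#' @param video An `nir_video`.
#' @param dir Output directory (created if needed).
#' @param rgb_leak Fraction of the red signal copied into green/blue.
#' @return `dir`, invisibly.
#' @export
write_video_frames <- function(video, dir, rgb_leak = 0.15) {
  stopifnot(inherits(video, "nir_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(video$frames)
  for (f in seq_len(d[3])) {
    red <- video$frames[, , f] / 255
    rgb <- array(0, dim = c(d[1], d[2], 3))
    rgb[, , 1] <- red
    rgb[, , 2] <- rgb_leak * red
    rgb[, , 3] <- rgb_leak * red
    png::writePNG(rgb, file.path(dir, sprintf("frame_%06d.png", f)))
  }
  ph <- video$truth
  sidecar <- list(
    frame_rate_hz = video$frame_rate_hz,
    frame_labels = video$frame_labels,
    cycle_index = video$cycle_index,
    timestamp = video$timestamp,
    rng_seed = video$rng_seed,
    config = unclass(video$config),
    phantom = list(r_surf = ph$r_surf, noise_sd = ph$noise_sd,
                   wavelength_gain = as.list(ph$wavelength_gain),
                   occlusion_delta = ph$occlusion_delta,
                   frame_shape = ph$frame_shape))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a PNG-frame video directory
#'
#' Reads the numbered PNG frames of a directory written by
#' [write_video_frames()] (or any directory of equally sized PNG frames),
#' extracting the red channel. The `truth.json` sidecar, when present,
#' restores the frame labels and acquisition configuration.
#'
#' @param dir Directory of `*.png` frames.
#' @return An `nir_video` (with `truth = NULL`; the sidecar ground truth, if
#'   any, is attached as the `sidecar` element).
#' @export
read_video_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stopf("no PNG frames found in %s", dir)
  first <- png::readPNG(files[1])
  d <- dim(first)
  frames <- array(0, dim = c(d[1], d[2], length(files)))
  for (f in seq_along(files)) {
    img <- png::readPNG(files[f])
    frames[, , f] <- if (length(dim(img)) == 3) img[, , 1] else img
  }
  frames <- frames * 255
  sidecar <- NULL
  sc_path <- file.path(dir, "truth.json")
  if (file.exists(sc_path)) sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  cfg <- NULL
  if (!is.null(sidecar$config)) {
    sc <- sidecar$config
    cfg <- acq_config(sc$frame_rate_hz, sc$multiplex_hz, sc$source_sequence,
                      sc$n_cycles, sc$start_delay_s, sc$frame_shape,
                      sc$terminal_flash)
  }
  structure(
    list(frames = frames,
         frame_labels = sidecar$frame_labels,
         cycle_index = sidecar$cycle_index,
         frame_rate_hz = sidecar$frame_rate_hz %||% NA_real_,
         config = cfg,
         truth = NULL,
         sidecar = sidecar,
         timestamp = sidecar$timestamp %||% NA_character_,
         rng_seed = sidecar$rng_seed %||% NA_integer_,
         channels = "red"),
    class = "nir_video")
}

#' Write an image to disk
#'
#' 16-bit TIFF (default; preserves sub-count precision of averaged or
#' reconstructed images after min-max scaling) or 8-bit PNG. Negative pixels
#' of band reconstructions are clipped here, at export only.
#'
#' @param image Numeric matrix.
#' @param path Output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- unclass(as.matrix(image))
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else stopf("unsupported image extension '%s'", ext)
  invisible(path)
}

#' Read an image written by [write_image()]
#' @param path `.png` or `.tif`/`.tiff` file.
#' @return Numeric matrix in `[0, 1]` (red channel of RGB files).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write an intensity profile as CSV
#' @param profile An [intensity_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  utils::write.csv(data.frame(frame = seq_along(profile$values),
                              mean_red_intensity = profile$values),
                   path, row.names = FALSE)
  invisible(path)
}
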
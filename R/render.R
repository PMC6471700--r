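#' Render a synthetic multiplexed-LED acquisition video
#'
#' Simulates the camera output for one imaging time stamp of an occlusion
#' study. For a frame in which source state `s` is active, the red channel is
#'
#' `gain[s] * delta[timestamp, s] * (surface + subsurface) + fiducial + noise`
#'
#' where `delta` is 1 for white light. Delay frames (before the source starts)
#' are dark (noise only). Noise is additive Gaussian, clipped to the 8-bit
#' range, with quantization to integer counts applied last. Frames are stored
#' red-channel-only (the channel carrying the NIR signal); the video is
#' declared single-channel for downstream processing, and RGB is materialised
#' only when writing PNG frames to disk.
#'
#' @param config An [acq_config()].
#' @param phantom A [tissue_phantom()] with matching `frame_shape`.
#' @param timestamp One of `"REST"`, `"OCCLUSION"`, `"RELEASE"`.
#' @param seed Integer seed; renders are bit-reproducible per seed.
#' @param quantize Quantize frames to integer 8-bit counts (default `TRUE`).
#'   Disable to inspect the algebraic structure of the forward model (e.g.
#'   frame rank) unperturbed by rounding.
#'
#' @return An object of class `nir_video`: list with `frames` (rows x cols x
#'   n_frames array, red channel, 0-255), `frame_labels`, `cycle_index`,
#'   `frame_rate_hz`, `config`, `truth` (the phantom), `timestamp`,
#'   `rng_seed`, `channels = "red"`.
#' @export
#' @examples
#' cfg <- acq_config(frame_shape = c(40L, 60L), start_delay_s = 0.5)
#' ph  <- tissue_phantom(frame_shape = c(40L, 60L), noise_sd = 0)
#' vid <- render_video(cfg, ph, "REST", seed = 1)
#' table(vid$frame_labels)
render_video <- function(config, phantom, timestamp = c("REST", "OCCLUSION", "RELEASE"),
                         seed = 1L, quantize = TRUE) {
  timestamp <- match.arg(timestamp)
  validate_acq_config(config)
  validate_tissue_phantom(phantom)
  if (!identical(as.integer(phantom$frame_shape), as.integer(config$frame_shape)))
    stopf("phantom frame_shape does not match config frame_shape")

  sched <- frame_schedule(config)
  n_frames <- nrow(sched)
  shp <- config$frame_shape
  base <- state_images(phantom, timestamp)   # named list incl. DELAY

  frames <- array(0, dim = c(shp[1], shp[2], n_frames))
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      img <- base[[sched$label[f]]]
      if (phantom$noise_sd > 0)
        img <- img + matrix(stats::rnorm(shp[1] * shp[2], 0, phantom$noise_sd),
                            shp[1], shp[2])
      frames[, , f] <- if (quantize) quantize8(img) else clip255(img)
    }
  })

  structure(
    list(frames = frames,
         frame_labels = sched$label,
         cycle_index = sched$cycle,
         frame_rate_hz = config$frame_rate_hz,
         config = config,
         truth = phantom,
         timestamp = timestamp,
         rng_seed = as.integer(seed),
         channels = "red"),
    class = "nir_video")
}

# Noiseless red-channel image for each source state at a time stamp,
# pre-quantization. DELAY frames are dark.
state_images <- function(phantom, timestamp) {
  tissue <- phantom$surface_map + phantom$subsurface_map
  out <- list(DELAY = matrix(0, phantom$frame_shape[1], phantom$frame_shape[2]))
  for (st in c("WHITE", "NIR690", "NIR800", "NIR840")) {
    delta <- if (st == "WHITE") 1 else phantom$occlusion_delta[[st]][[timestamp]]
    out[[st]] <- phantom$wavelength_gain[[st]] * delta * tissue + phantom$fiducial_map
  }
  out
}

#' Render a full occlusion study (rest / occlusion / release + white still)
#'
#' Renders three acquisitions sharing one phantom geometry, differing only in
#' the occlusion factors and the noise draws, plus the white-light anatomical
#' still used as the coregistration target. This reproduces the occlusion
#' protocol: image at rest, after 45 s of cuff occlusion, and within seconds
#' of cuff release.
#'
#' @inheritParams render_video
#' @return An object of class `occlusion_study`: list with elements `rest`,
#'   `occlusion`, `release` (each an `nir_video`) and `white` (matrix, the
#'   white-light still).
#' @export
render_occlusion_study <- function(config, phantom, seed = 1L, quantize = TRUE) {
  out <- list(
    rest      = render_video(config, phantom, "REST",      derive_seed(seed, 11L), quantize),
    occlusion = render_video(config, phantom, "OCCLUSION", derive_seed(seed, 12L), quantize),
    release   = render_video(config, phantom, "RELEASE",   derive_seed(seed, 13L), quantize),
    white     = render_white_still(phantom, derive_seed(seed, 14L), quantize)
  )
  structure(out, class = "occlusion_study")
}

#' Render the white-light anatomical still
#'
#' Surface + subsurface + fiducial at unit gain (no NIR scaling, no occlusion
#' factor), with the phantom's sensor noise.
#'
#' @inheritParams render_video
#' @return Matrix of red-channel counts.
#' @export
render_white_still <- function(phantom, seed = 1L, quantize = TRUE) {
  shp <- phantom$frame_shape
  img <- phantom$surface_map + phantom$subsurface_map + phantom$fiducial_map
  if (phantom$noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(shp[1] * shp[2], 0, phantom$noise_sd),
                                        shp[1], shp[2]))
  img <- if (quantize) quantize8(img) else clip255(img)
  wavelength_image(img, state = "WHITE", cycle = NA_integer_, timestamp = "REST")
}

#' Render one demultiplexed wavelength image directly
#'
#' Shortcut for simulation studies: renders the frames of a single source
#' dwell and combines their interior (guard-trimmed) frames exactly as the
#' demultiplexer would, skipping the full video. Statistically identical to
#' rendering a video and extracting the dwell.
#'
#' @inheritParams render_video
#' @param state Source state to render (default `"NIR690"`).
#' @param guard Fraction of frames trimmed from each end of the dwell before
#'   averaging (default 0.2, as in demultiplexing).
#' @param frame_pick `"mean"`, `"median"` or `"first"` combination rule.
#' @return A `wavelength_image` (matrix with state/cycle/timestamp attributes).
#' @export
render_wavelength_image <- function(config, phantom, state = "NIR690",
                                    timestamp = c("REST", "OCCLUSION", "RELEASE"),
                                    seed = 1L, guard = 0.2,
                                    frame_pick = c("mean", "first", "median"),
                                    quantize = TRUE) {
  timestamp <- match.arg(timestamp)
  frame_pick <- match.arg(frame_pick)
  validate_tissue_phantom(phantom)
  shp <- phantom$frame_shape
  dwell <- dwell_frames(config)
  base <- state_images(phantom, timestamp)[[state]]
  keep <- interior_indices(1L, dwell, guard)
  npx <- shp[1] * shp[2]
  stack <- array(rep(as.vector(base), dwell), dim = c(shp[1], shp[2], dwell))
  if (phantom$noise_sd > 0)
    stack <- stack + with_seed(seed, array(stats::rnorm(npx * dwell, 0, phantom$noise_sd),
                                           dim = dim(stack)))
  stack <- if (quantize) quantize8(stack) else clip255(stack)
  px <- combine_frames(stack[, , keep, drop = FALSE], frame_pick)
  wavelength_image(px, state = state, cycle = 1L, timestamp = timestamp)
}

#' @export
print.nir_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("NIR acquisition video: %d frames of %d x %d (red channel), %g fps\n",
              d[3], d[1], d[2], x$frame_rate_hz))
  cat(sprintf("  time stamp %s, seed %d, %d cycles of %s\n",
              x$timestamp, x$rng_seed, x$config$n_cycles,
              paste(x$config$source_sequence, collapse = "/")))
  invisible(x)
}

#' @export
print.occlusion_study <- function(x, ...) {
  cat("Occlusion study: rest / occlusion / release acquisitions + white-light still\n")
  for (ts in c("rest", "occlusion", "release"))
    cat(sprintf("  %-9s: %d frames, seed %d\n", ts,
                dim(x[[ts]]$frames)[3], x[[ts]]$rng_seed))
  invisible(x)
}
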
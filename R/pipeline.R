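#' Pipeline configuration
#'
#' One human-readable configuration object binding all stage parameters:
#' acquisition protocol, registration settings, eigen bands, and the
#' box-statistics protocol. Serializes to JSON and round-trips exactly.
#'
#' @param acquisition An [acq_config()].
#' @param registration A [reg_config()].
#' @param ev_bands Character vector of `"lo:hi"` bands to analyse.
#' @param n_boxes,box_size,alpha,repetitions Statistics protocol.
#' @param wavelength NIR state analysed.
#' @param cycle Cycle extracted from each video.
#' @param seed Base seed; all stage substreams derive from it.
#' @param phantom_args Optional named list of [tissue_phantom()] arguments
#'   used by the simulate verb.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = acq_config(),
                            registration = reg_config(),
                            ev_bands = c("1:15", "2:15", "3:15", "4:15", "5:15"),
                            n_boxes = 17L, box_size = 30L, alpha = 0.05,
                            repetitions = 4L,
                            wavelength = "NIR690", cycle = 1L,
                            seed = 1L, phantom_args = list()) {
  validate_acq_config(acquisition)
  stopifnot(inherits(registration, "reg_config"))
  lapply(ev_bands, ev_band)   # validate
  structure(list(acquisition = acquisition, registration = registration,
                 ev_bands = ev_bands,
                 stats = list(n_boxes = as.integer(n_boxes),
                              box_size = as.integer(box_size),
                              alpha = alpha, repetitions = as.integer(repetitions)),
                 wavelength = wavelength, cycle = as.integer(cycle),
                 seed = as.integer(seed), phantom_args = phantom_args),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(config_to_list(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

config_to_list <- function(config) {
  list(acquisition = unclass(config$acquisition),
       registration = unclass(config$registration),
       ev_bands = as.list(config$ev_bands),
       stats = config$stats,
       wavelength = config$wavelength, cycle = config$cycle,
       seed = config$seed, phantom_args = config$phantom_args)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- x$acquisition
  pipeline_config(
    acquisition = acq_config(a$frame_rate_hz, a$multiplex_hz, a$source_sequence,
                             a$n_cycles, a$start_delay_s, a$frame_shape,
                             a$terminal_flash),
    registration = reg_config(x$registration$initial_step, x$registration$iterations,
                              x$registration$transform, x$registration$metric,
                              x$registration$min_step),
    ev_bands = unlist(x$ev_bands),
    n_boxes = x$stats$n_boxes, box_size = x$stats$box_size,
    alpha = x$stats$alpha, repetitions = x$stats$repetitions,
    wavelength = x$wavelength, cycle = x$cycle, seed = x$seed,
    phantom_args = as.list(x$phantom_args))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Data extraction -> noise removal -> coregistration -> quantification, on
#' the three time-stamp acquisitions, writing all declared outputs and a
#' provenance manifest. Idempotent: running twice with the same configuration
#' and inputs produces identical files.
#'
#' @param config A [pipeline_config()].
#' @param inputs Named list: `rest`, `occlusion`, `release` (each an
#'   `nir_video` or a PNG-frame directory path) and `white` (matrix or image
#'   path).
#' @param out_dir Output directory, created if needed. Writes: per-time-stamp
#'   intensity-profile CSVs and demultiplexed wavelength TIFFs, the singular
#'   value spectrum CSV, the H table CSV (bands x repetitions), the
#'   per-band mean/sd CSV, per-band overlay PNGs, and `manifest.json`.
#' @return The [run_study()] result, invisibly, with the manifest attached
#'   as attribute `"manifest"`.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (ts in c("rest", "occlusion", "release"))
    if (is.null(inputs[[ts]]))
      stopf("missing input for time stamp '%s'", ts)
  if (is.null(inputs$white)) stopf("missing input 'white' (white-light image)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  videos <- lapply(c(rest = "rest", occlusion = "occlusion", release = "release"),
                   function(ts) {
    x <- inputs[[ts]]
    if (is.character(x)) {
      with_stage_context(sprintf("read (%s: %s)", ts, x), read_video_frames(x))
    } else x
  })
  white <- inputs$white
  if (is.character(white))
    white <- with_stage_context(sprintf("read (white: %s)", white),
                                read_image(white) * 255)

  # stage: extraction
  images <- list()
  for (ts in names(videos)) {
    dm <- with_stage_context(sprintf("demux (%s)", ts),
                             demux_video(videos[[ts]], config$acquisition,
                                         cycle = config$cycle))
    write_profile_csv(dm$profile, file.path(out_dir, sprintf("profile_%s.csv", ts)))
    for (st in names(dm$images))
      write_image(dm$images[[st]],
                  file.path(out_dir, sprintf("%s_%s_cycle%d.tif", st, ts, config$cycle)))
    images[[ts]] <- dm$images[[config$wavelength]]
    if (is.null(images[[ts]]))
      stopf("[demux (%s)] wavelength %s not recovered", ts, config$wavelength)
  }

  # stage: noise removal diagnostics (singular value spectrum at rest)
  d_rest <- svd_decompose(images$rest)
  n_sv <- min(15L, length(d_rest$d))
  utils::write.csv(data.frame(component = seq_len(n_sv),
                              singular_value = ev_spectrum(d_rest, n_sv)),
                   file.path(out_dir, "singular_values_rest.csv"), row.names = FALSE)

  # stages: reconstruction, coregistration, quantification
  res <- run_study(list(rest = images$rest, occlusion = images$occlusion,
                        release = images$release, white = white),
                   ev_bands = config$ev_bands,
                   repetitions = config$stats$repetitions,
                   base_seed = config$seed,
                   wavelength = config$wavelength,
                   alpha = config$stats$alpha,
                   n_boxes = config$stats$n_boxes,
                   box_size = config$stats$box_size,
                   registration = config$registration)

  utils::write.csv(res$cells[, c("band", "repetition", "H",
                                 "p_rest_vs_occ", "p_occ_vs_relax", "p_rest_vs_relax")],
                   file.path(out_dir, "hypothesis_table.csv"), row.names = FALSE)
  utils::write.csv(res$cells[, c("band", "repetition",
                                 "mean_rest", "sd_rest", "mean_occlusion",
                                 "sd_occlusion", "mean_release", "sd_release")],
                   file.path(out_dir, "reflectance_means.csv"), row.names = FALSE)
  # pseudo-colour overlay per band (release vs rest difference shown as PNG)
  whiten <- normalize_image(white)
  for (b in config$ev_bands) {
    rec <- normalize_image(reconstruct_band(svd_decompose(images$rest), ev_band(b)))
    ov <- register_images(rec, whiten, config$registration)$overlay
    write_image(ov, file.path(out_dir, sprintf("overlay_rest_%s.png", gsub(":", "-", b))))
  }

  manifest <- list(
    package = "nirdr",
    package_version = as.character(utils::packageVersion("nirdr")),
    config_hash = config_hash(config),
    seed = config$seed,
    wavelength = config$wavelength,
    ev_bands = config$ev_bands,
    inputs = vapply(inputs, function(x) if (is.character(x)) x else "<in-memory>", ""),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(res, "manifest") <- manifest
  invisible(res)
}
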
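#' Per-frame red-channel intensity profile
#'
#' The demultiplexing primitive: the mean of the red channel of each frame,
#' plotted across frames. Because the LEDs are multiplexed in time and the
#' four source states reflect at distinct intensities, the profile is a
#' staircase of plateaus from which dwells and cycles are segmented.
#'
#' @param video An `nir_video`, a `rows x cols x 3 x frames` RGB array, or a
#'   `rows x cols x frames` single-channel array (requires
#'   `single_channel = TRUE`).
#' @param frame_rate_hz Frame rate; taken from the video object if present.
#' @param single_channel Declare a 3-D array as single-channel (red) data.
#' @return An object of class `intensity_profile`: list with `values` (one
#'   mean per frame, 0-255) and `frame_rate_hz`.
#' @export
intensity_profile <- function(video, frame_rate_hz = NULL, single_channel = FALSE) {
  if (inherits(video, "nir_video")) {
    frames <- video$frames
    frame_rate_hz <- frame_rate_hz %||% video$frame_rate_hz
    single_channel <- TRUE          # declared: red channel only is stored
  } else {
    frames <- video
  }
  if (is.null(frames) || length(frames) == 0) stopf("empty video")
  nd <- length(dim(frames))
  if (nd == 4) {
    if (dim(frames)[3] < 3) stopf("RGB video must have >= 3 channels")
    frames <- frames[, , 1, , drop = TRUE]   # red channel
    if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1L)
  } else if (nd == 3) {
    if (!single_channel)
      stopf("3-D frame array is not RGB; pass single_channel = TRUE if the red channel is stored directly")
  } else stopf("video must be a 3-D or 4-D frame array")
  vals <- apply(frames, 3, mean)
  structure(list(values = as.numeric(vals),
                 frame_rate_hz = frame_rate_hz %||% NA_real_),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile: %d frames, %s fps, range [%.1f, %.1f] counts\n",
              length(x$values),
              if (is.na(x$frame_rate_hz)) "?" else format(x$frame_rate_hz),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "frame", ylab = "mean red-channel intensity (counts)", ...)
  invisible(x)
}

# ---- optimal 1-D k-class partition (multi-level Otsu / Fisher breaks) -------
# Dynamic programme minimising total within-class sum of squares of the sorted
# values; returns the class means and value thresholds separating classes.
fisher_partition <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  k <- min(k, length(unique(xs)))
  if (k <= 1)
    return(list(centers = mean(xs), thresholds = numeric(0)))
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  ssq_to <- function(i, j) {   # vectorised over i, fixed j
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- pmax(cs2[-1] - cs[-1]^2 / seq_len(n), 0)
  for (cl in 2:k) {
    for (j in cl:n) {
      m <- cl:j                      # class cl covers xs[m..j]
      v <- D[cl - 1, m - 1] + ssq_to(m, j)
      best <- which.min(v)
      D[cl, j] <- v[best]
      B[cl, j] <- m[best]
    }
  }
  # backtrack class boundaries over sorted values
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (cl in k:2) {
    m <- B[cl, j]
    bounds[cl] <- m - 1L
    j <- m - 1L
  }
  bounds[1] <- 0L
  centers <- vapply(seq_len(k), function(cl)
    mean(xs[(bounds[cl] + 1):bounds[cl + 1]]), 0)
  thresholds <- vapply(seq_len(k - 1), function(cl)
    (xs[bounds[cl + 1]] + xs[bounds[cl + 1] + 1]) / 2, 0)
  list(centers = centers, thresholds = thresholds)
}

# Classify profile values into intensity levels: k-class optimal partition,
# then merge classes whose centers are indistinguishable. Returns integer
# class per frame (1 = dimmest) and the class centers.
classify_levels <- function(values, k = 5, merge_frac = 0.05) {
  fp <- fisher_partition(values, k)
  cls <- findInterval(values, fp$thresholds) + 1L
  centers <- vapply(seq_along(fp$centers), function(c0) mean(values[cls == c0]), 0)
  # merge adjacent classes closer than merge_frac of the dynamic range
  tol <- merge_frac * max(diff(range(values)), 1e-12)
  keep_map <- seq_along(centers)
  for (c0 in seq_along(centers)[-1]) {
    if (!is.na(centers[c0]) && !is.na(centers[c0 - 1]) &&
        abs(centers[c0] - centers[c0 - 1]) < tol)
      keep_map[keep_map == c0] <- keep_map[c0 - 1]
  }
  cls <- keep_map[cls]
  lev <- sort(unique(cls))
  cls <- match(cls, lev)
  centers <- vapply(seq_along(lev), function(c0) mean(values[cls == c0]), 0)
  list(class = cls, centers = centers)
}

interior_indices <- function(start, end, guard = 0.2) {
  n <- end - start + 1L
  drop <- floor(n * guard)
  if (2 * drop >= n) drop <- max(0L, (n - 1L) %/% 2L)
  seq.int(start + drop, end - drop)
}

combine_frames <- function(stack, frame_pick = "mean") {
  d <- dim(stack)
  switch(frame_pick,
         mean   = matrix(rowMeans(matrix(stack, nrow = d[1] * d[2])), d[1], d[2]),
         median = apply(stack, c(1, 2), stats::median),
         first  = stack[, , 1],
         stopf("unknown frame_pick '%s'", frame_pick))
}

#' Demultiplexed single-wavelength image
#'
#' Constructor for the red-channel diffuse-reflectance image of one source
#' state, one cycle, one time stamp.
#'
#' @param pixels Numeric matrix.
#' @param state Source state (e.g. `"NIR690"`).
#' @param cycle Cycle index.
#' @param timestamp Time stamp label.
#' @return A `wavelength_image`: the matrix with metadata attributes.
#' @export
wavelength_image <- function(pixels, state = NA_character_, cycle = NA_integer_,
                             timestamp = NA_character_) {
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels))) stopf("wavelength image contains non-finite pixels")
  structure(pixels, class = c("wavelength_image", class(pixels)),
            state = state, cycle = cycle, timestamp = timestamp)
}

#' @export
print.wavelength_image <- function(x, ...) {
  cat(sprintf("Wavelength image %s (cycle %s, %s): %d x %d, range [%.2f, %.2f]\n",
              attr(x, "state"), format(attr(x, "cycle")), attr(x, "timestamp"),
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Segment an intensity profile into source dwells and cycles
#'
#' Detects the intensity plateaus of the multiplexed acquisition by optimal
#' multi-level thresholding of the profile (up to 5 classes: dark + four
#' source states) followed by run-length segmentation. The brightest plateau
#' class is the white-light flash; a cycle starts at each white flash and is
#' complete once the expected number of NIR dwells follows it. A trailing
#' white flash with no NIR dwells after it is the acquisition-complete
#' indicator, not a cycle. Segment interiors are shrunk by a guard margin to
#' exclude source-transition frames from downstream averaging.
#'
#' @param profile An [intensity_profile()].
#' @param config Optional [acq_config()]; supplies the number of NIR states
#'   per cycle and their wavelength identities (which cannot be inferred from
#'   intensity alone). Without it, NIR dwells are named `NIR_A/B/C` in order
#'   of appearance.
#' @param guard Fraction of each dwell trimmed from both ends for the segment
#'   interior (default 0.2).
#' @param dark_frac Classes with center below this fraction of the brightest
#'   center are dark (default 0.1).
#' @return An object of class `segment_labeling`: list with `segments` (data
#'   frame: `start`, `end` inclusive, `state`, `cycle`, `int_start`,
#'   `int_end`), `n_cycles_detected`, and `level_centers`.
#' @export
segment_profile <- function(profile, config = NULL, guard = 0.2, dark_frac = 0.1) {
  stopifnot(inherits(profile, "intensity_profile"))
  v <- profile$values
  n_nir <- if (is.null(config)) 3L else length(nir_states(config))
  cl <- classify_levels(v, k = 2L + n_nir)
  centers <- cl$centers
  is_dark <- centers < dark_frac * max(centers)
  n_levels <- sum(!is_dark)
  if (n_levels < n_nir + 1L)
    stopf("only %d distinguishable source-intensity levels found (need %d)",
          n_levels, n_nir + 1L)
  white_class <- which.max(centers)

  r <- rle(cl$class)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, class = r$values)

  segs <- list()
  cycle <- 0L
  pending_nir <- 0L       # NIR dwells seen in the currently open cycle
  open <- FALSE
  incomplete <- 0L
  for (i in seq_len(nrow(runs))) {
    k <- runs$class[i]
    if (is_dark[k]) {
      if (open && pending_nir < n_nir) { incomplete <- incomplete + 1L; open <- FALSE }
      state <- "DARK"; cyc <- NA_integer_
    } else if (k == white_class) {
      if (open && pending_nir < n_nir) incomplete <- incomplete + 1L
      cycle <- cycle + 1L
      open <- TRUE
      pending_nir <- 0L
      state <- "WHITE"; cyc <- cycle
    } else {
      pending_nir <- pending_nir + 1L
      state <- paste0("NIR_", LETTERS[min(pending_nir, 26L)])
      cyc <- if (open) cycle else NA_integer_
    }
    it <- interior_indices(runs$start[i], runs$end[i], guard)
    segs[[i]] <- data.frame(start = runs$start[i], end = runs$end[i],
                            state = state, cycle = cyc,
                            int_start = it[1], int_end = it[length(it)],
                            stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, segs)

  # complete cycles: a WHITE followed by n_nir NIR dwells
  complete <- integer(0)
  for (cy in seq_len(cycle)) {
    nir_cy <- segs$state[!is.na(segs$cycle) & segs$cycle == cy & grepl("^NIR", segs$state)]
    if (length(nir_cy) == n_nir) complete <- c(complete, cy)
  }
  n_detected <- length(complete)
  # warn on truncated (incomplete, non-terminal) cycles
  n_trunc <- 0L
  for (cy in setdiff(seq_len(cycle), complete)) {
    nir_cy <- sum(!is.na(segs$cycle) & segs$cycle == cy & grepl("^NIR", segs$state))
    if (nir_cy > 0L) n_trunc <- n_trunc + 1L
  }
  if (n_trunc > 0L)
    warnf("%d truncated cycle(s) discarded; %d complete cycle(s) detected",
          n_trunc, n_detected)

  # renumber: complete cycles 1..n; terminal flash keeps a cycle number past n
  remap <- rep(NA_integer_, cycle)
  remap[complete] <- seq_len(n_detected)
  terminal <- setdiff(seq_len(cycle), complete)
  remap[terminal] <- n_detected + seq_along(terminal)
  segs$cycle <- ifelse(is.na(segs$cycle), NA_integer_, remap[segs$cycle])

  # map NIR dwell order to wavelength identities from the configuration
  if (!is.null(config)) {
    nirs <- nir_states(config)
    ord <- match(segs$state, paste0("NIR_", LETTERS[seq_len(n_nir)]))
    segs$state <- ifelse(!is.na(ord) & !is.na(segs$cycle) &
                           segs$cycle <= n_detected, nirs[ord], segs$state)
  }

  structure(list(segments = segs,
                 n_cycles_detected = n_detected,
                 level_centers = centers),
            class = "segment_labeling")
}

#' @export
print.segment_labeling <- function(x, ...) {
  cat(sprintf("Segment labeling: %d segments, %d complete cycle(s)\n",
              nrow(x$segments), x$n_cycles_detected))
  cat(sprintf("  intensity levels at %s counts\n",
              paste(sprintf("%.1f", x$level_centers), collapse = ", ")))
  print(utils::head(x$segments, 12))
  if (nrow(x$segments) > 12) cat(sprintf("  ... %d more\n", nrow(x$segments) - 12))
  invisible(x)
}

#' Estimate the source switching frequency
#'
#' The multiplexing rate recovered from the profile: switch frames are the
#' boundaries between intensity plateaus, and the frequency is the frame rate
#' divided by the median inter-switch frame gap.
#'
#' @param profile An [intensity_profile()] with a known frame rate.
#' @return Estimated switching frequency in Hz.
#' @export
#' @examples
#' # plateaus switching every 24 frames at 60 fps estimate as 2.5 Hz
estimate_switching_frequency <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (is.na(profile$frame_rate_hz)) stopf("profile has no frame rate")
  v <- profile$values
  if (diff(range(v)) < 1e-9) stopf("constant profile: no source switches detected")
  cl <- classify_levels(v)
  switches <- which(diff(cl$class) != 0) + 1L   # frame where a new dwell starts
  if (length(switches) < 2) stopf("fewer than 2 source switches detected")
  gaps <- diff(switches)
  profile$frame_rate_hz / stats::median(gaps)
}

#' Extract per-wavelength diffuse-reflectance images for one cycle
#'
#' For each NIR dwell of the requested cycle, combines the red channels of
#' the dwell's interior (guard-trimmed) frames into one image. The default
#' combination is the arithmetic mean (lowest-variance single-image summary);
#' `"first"` reproduces a single-frame reading, `"median"` is robust to
#' outlier frames.
#'
#' @param video An `nir_video` or a `rows x cols x frames` red-channel array.
#' @param labeling A [segment_profile()] result.
#' @param cycle Cycle index to extract (1-based).
#' @param frame_pick `"mean"`, `"first"` or `"median"`.
#' @return Named list of [wavelength_image()]s, one per NIR state, in
#'   within-cycle order.
#' @export
extract_wavelength_images <- function(video, labeling, cycle = 1L,
                                      frame_pick = c("mean", "first", "median")) {
  frame_pick <- match.arg(frame_pick)
  stopifnot(inherits(labeling, "segment_labeling"))
  frames <- if (inherits(video, "nir_video")) video$frames else video
  timestamp <- if (inherits(video, "nir_video")) video$timestamp else NA_character_
  if (cycle < 1 || cycle > labeling$n_cycles_detected)
    stopf("cycle %d not available: %d complete cycle(s) detected",
          cycle, labeling$n_cycles_detected)
  segs <- labeling$segments
  nir <- segs[!is.na(segs$cycle) & segs$cycle == cycle & segs$state != "WHITE" &
                segs$state != "DARK", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(nir))) {
    if (nir$int_end[i] < nir$int_start[i])
      stopf("segment %s of cycle %d has no interior frames", nir$state[i], cycle)
    stack <- frames[, , nir$int_start[i]:nir$int_end[i], drop = FALSE]
    out[[nir$state[i]]] <- wavelength_image(combine_frames(stack, frame_pick),
                                            state = nir$state[i],
                                            cycle = as.integer(cycle),
                                            timestamp = timestamp)
  }
  out
}

#' One-call demultiplexing of a video into wavelength images
#'
#' Convenience wrapper: profile, segmentation, extraction.
#'
#' @inheritParams extract_wavelength_images
#' @param config Optional [acq_config()] used for wavelength identity.
#' @return List with `profile`, `labeling`, and `images` (per-wavelength list).
#' @export
demux_video <- function(video, config = NULL, cycle = 1L,
                        frame_pick = c("mean", "first", "median")) {
  frame_pick <- match.arg(frame_pick)
  if (is.null(config) && inherits(video, "nir_video")) config <- video$config
  prof <- intensity_profile(video)
  lab <- segment_profile(prof, config)
  list(profile = prof, labeling = lab,
       images = extract_wavelength_images(video, lab, cycle, frame_pick))
}
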
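#' Acquisition configuration
#'
#' Describes the timed multiplexed-LED acquisition protocol: a camera records
#' continuously at `frame_rate_hz` while the source unit switches between a
#' white-light LED and three NIR LEDs (690, 800, 840 nm) at `multiplex_hz`.
#' Each cycle is preceded by the white-light flash (used downstream to delimit
#' cycles), the four-state cycle repeats `n_cycles` times, and an optional
#' terminal white flash marks the end of acquisition. A start delay models the
#' operator switching on the source after the camera is already rolling.
#'
#' @param frame_rate_hz Camera frame rate in Hz (nominal 60).
#' @param multiplex_hz Source switching rate in Hz (nominal 2.5): every
#'   `1/multiplex_hz` seconds the active LED changes, so one source dwell
#'   spans `frame_rate_hz / multiplex_hz` frames.
#' @param source_sequence Character vector of source states per cycle, a
#'   permutation of `"WHITE", "NIR690", "NIR800", "NIR840"` starting with the
#'   white flash.
#' @param n_cycles Number of repeats of the source cycle (nominal 3).
#' @param start_delay_s Dark delay before the source starts, in seconds
#'   (nominal 5).
#' @param frame_shape Integer `(rows, cols)` of a frame.
#' @param terminal_flash Logical; whether a final white flash follows the last
#'   cycle (the acquisition-complete indicator).
#'
#' @return An object of class `acq_config`.
#' @export
#' @examples
#' cfg <- acq_config()
#' dwell_frames(cfg)   # 24 frames per source state at 60 fps / 2.5 Hz
acq_config <- function(frame_rate_hz = 60,
                       multiplex_hz = 2.5,
                       source_sequence = c("WHITE", "NIR690", "NIR800", "NIR840"),
                       n_cycles = 3,
                       start_delay_s = 5,
                       frame_shape = c(270L, 480L),
                       terminal_flash = TRUE) {
  cfg <- structure(
    list(frame_rate_hz = frame_rate_hz,
         multiplex_hz = multiplex_hz,
         source_sequence = source_sequence,
         n_cycles = as.integer(n_cycles),
         start_delay_s = start_delay_s,
         frame_shape = as.integer(frame_shape),
         terminal_flash = isTRUE(terminal_flash)),
    class = "acq_config")
  validate_acq_config(cfg)
}

validate_acq_config <- function(cfg) {
  stopifnot(inherits(cfg, "acq_config"))
  if (!is.numeric(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0)
    stopf("frame_rate_hz must be a positive number")
  if (!is.numeric(cfg$multiplex_hz) || cfg$multiplex_hz <= 0)
    stopf("multiplex_hz must be a positive number")
  if (cfg$multiplex_hz >= cfg$frame_rate_hz)
    stopf("multiplex_hz (%g) must be below frame_rate_hz (%g)",
          cfg$multiplex_hz, cfg$frame_rate_hz)
  states <- sort(cfg$source_sequence)
  if (!identical(states, sort(c("WHITE", "NIR690", "NIR800", "NIR840"))))
    stopf("source_sequence must contain WHITE, NIR690, NIR800, NIR840 exactly once each")
  if (!is_count(cfg$n_cycles)) stopf("n_cycles must be a positive integer")
  if (!is.numeric(cfg$start_delay_s) || cfg$start_delay_s < 0)
    stopf("start_delay_s must be nonnegative")
  if (length(cfg$frame_shape) != 2 || any(cfg$frame_shape < 1))
    stopf("frame_shape must be two positive integers (rows, cols)")
  if (cfg$frame_rate_hz / cfg$multiplex_hz < 2)
    stopf("frames per source dwell = frame_rate_hz/multiplex_hz = %.2f; at least 2 are required for demultiplexing",
          cfg$frame_rate_hz / cfg$multiplex_hz)
  cfg
}

#' Frames per source dwell
#'
#' Number of video frames captured while one LED state is active,
#' `round(frame_rate_hz / multiplex_hz)`.
#'
#' @param cfg An [acq_config()].
#' @return Integer frame count.
#' @export
dwell_frames <- function(cfg) {
  as.integer(round(cfg$frame_rate_hz / cfg$multiplex_hz))
}

#' NIR states of a configuration, in multiplexing order
#' @param cfg An [acq_config()].
#' @return Character vector of the three NIR source states.
#' @export
nir_states <- function(cfg) {
  cfg$source_sequence[cfg$source_sequence != "WHITE"]
}

# Expected per-frame labels and cycle indices for a configuration.
# Labels: "DELAY" during the start delay, a source state during dwells;
# the terminal flash is labelled WHITE with cycle_index n_cycles + 1.
frame_schedule <- function(cfg) {
  dwell <- dwell_frames(cfg)
  delay <- as.integer(round(cfg$start_delay_s * cfg$frame_rate_hz))
  labels <- rep("DELAY", delay)
  cycles <- rep(0L, delay)
  for (cy in seq_len(cfg$n_cycles)) {
    labels <- c(labels, rep(cfg$source_sequence, each = dwell))
    cycles <- c(cycles, rep(cy, 4L * dwell))
  }
  if (cfg$terminal_flash) {
    labels <- c(labels, rep("WHITE", dwell))
    cycles <- c(cycles, rep(cfg$n_cycles + 1L, dwell))
  }
  data.frame(label = labels, cycle = cycles, stringsAsFactors = FALSE)
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Acquisition configuration\n")
  cat(sprintf("  frame rate    : %g fps\n", x$frame_rate_hz))
  cat(sprintf("  multiplexing  : %g Hz (%d frames per dwell)\n",
              x$multiplex_hz, dwell_frames(x)))
  cat(sprintf("  cycle         : %s, repeated %d times\n",
              paste(x$source_sequence, collapse = " -> "), x$n_cycles))
  cat(sprintf("  start delay   : %g s; terminal flash: %s\n",
              x$start_delay_s, x$terminal_flash))
  cat(sprintf("  frame shape   : %d x %d\n", x$frame_shape[1], x$frame_shape[2]))
  invisible(x)
}
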
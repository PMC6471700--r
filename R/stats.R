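#' Sample non-overlapping pixel boxes within a region of interest
#'
#' Draws `n_boxes` square boxes of `box_size` pixels uniformly at random
#' inside the ROI, rejecting overlaps, deterministically per seed. The same
#' box set is reused across the three time stamps of a study; the analysis
#' repetitions redraw boxes within the same ROI.
#'
#' @param roi Integer `(row0, col0, rows, cols)`: the region of interest in
#'   image coordinates (1-based origin and extent).
#' @param n_boxes Number of boxes (default 17).
#' @param box_size Box side length in pixels (default 30).
#' @param seed Integer seed.
#' @param max_tries Per-box rejection attempts before the placement is
#'   restarted from scratch.
#' @param max_restarts Full restarts before giving up.
#' @return An object of class `box_sampling`: list with `boxes` (data frame
#'   of absolute `row0`, `col0`), `box_size`, `roi`, `seed`.
#' @export
#' @examples
#' s <- sample_boxes(c(1, 1, 300, 300), seed = 1)
#' nrow(s$boxes)
sample_boxes <- function(roi, n_boxes = 17L, box_size = 30L, seed = 1L,
                         max_tries = 200L, max_restarts = 100L) {
  roi <- as.integer(roi)
  if (length(roi) != 4) stopf("roi must be (row0, col0, rows, cols)")
  rows <- roi[3]; cols <- roi[4]
  capacity <- (rows %/% box_size) * (cols %/% box_size)
  if (capacity < n_boxes)
    stopf("roi of %d x %d can host at most %d non-overlapping %d x %d boxes; %d requested",
          rows, cols, capacity, box_size, box_size, n_boxes)
  max_r <- rows - box_size; max_c <- cols - box_size
  placed_r <- integer(0); placed_c <- integer(0)
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      placed_r <- integer(0); placed_c <- integer(0)
      while (length(placed_r) < n_boxes) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          r <- sample.int(max_r + 1L, 1L) - 1L
          c <- sample.int(max_c + 1L, 1L) - 1L
          if (!any(abs(placed_r - r) < box_size & abs(placed_c - c) < box_size)) {
            placed_r <- c(placed_r, r)
            placed_c <- c(placed_c, c)
            placed <- TRUE
            break
          }
        }
        if (!placed) break      # jammed: restart placement from scratch
      }
      if (length(placed_r) == n_boxes) break
    }
    if (length(placed_r) < n_boxes)
      stopf("could not place %d non-overlapping boxes in the roi after %d restarts (capacity %d)",
            n_boxes, max_restarts, capacity)
  })
  structure(list(boxes = data.frame(row0 = roi[1] + placed_r,
                                    col0 = roi[2] + placed_c),
                 box_size = as.integer(box_size), roi = roi,
                 seed = as.integer(seed)),
            class = "box_sampling")
}

#' @export
print.box_sampling <- function(x, ...) {
  cat(sprintf("Box sampling: %d boxes of %d x %d px in roi [%s], seed %d\n",
              nrow(x$boxes), x$box_size, x$box_size,
              paste(x$roi, collapse = ", "), x$seed))
  invisible(x)
}

#' Box-mean summary of one time stamp's image
#'
#' Per-box mean diffuse reflectance, plus their grand mean and sample
#' standard deviation — the error-bar summary of the occlusion analysis.
#'
#' @param image Numeric matrix (typically the normalized, coregistered band
#'   reconstruction).
#' @param sampling A [sample_boxes()] result.
#' @param timestamp Optional time stamp label carried on the result.
#' @return An object of class `timestamp_summary`: list with `per_box_means`,
#'   `mean`, `sd`, `timestamp`.
#' @export
summarize_timestamp <- function(image, sampling, timestamp = NULL) {
  stopifnot(inherits(sampling, "box_sampling"))
  bs <- sampling$box_size
  b <- sampling$boxes
  if (any(b$row0 < 1 | b$col0 < 1 |
          b$row0 + bs - 1 > nrow(image) | b$col0 + bs - 1 > ncol(image)))
    stopf("a sampling box lies outside the %d x %d image", nrow(image), ncol(image))
  means <- vapply(seq_len(nrow(b)), function(i)
    mean(image[b$row0[i]:(b$row0[i] + bs - 1), b$col0[i]:(b$col0[i] + bs - 1)]), 0)
  timestamp <- timestamp %||% attr(image, "timestamp") %||% NA_character_
  structure(list(per_box_means = means, mean = mean(means),
                 sd = stats::sd(means), timestamp = timestamp),
            class = "timestamp_summary")
}

#' @export
print.timestamp_summary <- function(x, ...) {
  cat(sprintf("Time stamp %s: mean %.4f, sd %.4f over %d box means\n",
              x$timestamp, x$mean, x$sd, length(x$per_box_means)))
  invisible(x)
}

paired_t <- function(a, b) {
  d <- a - b
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1e-300)) {
    warnf("zero variance of paired differences; p set to %s",
          if (mean(d) != 0) "0" else "1")
    return(if (mean(d) != 0) list(t = Inf * sign(mean(d)), p = 0)
           else list(t = 0, p = 1))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Hypothesis counter for the occlusion comparisons
#'
#' Two-sided paired t-tests on the per-box means for the two physiological
#' comparisons — rest vs. occlusion and occlusion vs. release — with the
#' counter `H` equal to the number of significant comparisons at level
#' `alpha`: `H = 0` no significant difference, `H = 1` one of the two,
#' `H = 2` both. The rest-vs-release p-value is computed and reported but
#' never counted. Pairing unit is the box (the box set is shared across time
#' stamps), so with 17 boxes the tests have 16 degrees of freedom.
#'
#' @param rest,occ,relax [summarize_timestamp()] results (or plain numeric
#'   vectors of per-box means) for the three time stamps.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply a Bonferroni correction across the two counted
#'   comparisons (default `FALSE`, matching the uncorrected protocol).
#' @return An object of class `hypothesis_result`: list with `H`, the three
#'   p-values (`p_rest_vs_occ`, `p_occ_vs_relax`, `p_rest_vs_relax`), the
#'   corresponding t statistics, and `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' occ <- rnorm(17, 10, 1)
#' hypothesis_counter(occ + 5, occ, occ + 5)$H   # both comparisons significant
hypothesis_counter <- function(rest, occ, relax, alpha = 0.05, bonferroni = FALSE) {
  vecs <- lapply(list(rest = rest, occ = occ, relax = relax), function(x) {
    if (inherits(x, "timestamp_summary")) x$per_box_means else as.numeric(x)
  })
  n <- lengths(vecs)
  if (length(unique(n)) != 1)
    stopf("per-box mean vectors differ in length (%s); boxes must be paired",
          paste(n, collapse = ", "))
  a <- if (bonferroni) alpha / 2 else alpha
  t_ro <- paired_t(vecs$rest, vecs$occ)
  t_or <- paired_t(vecs$occ, vecs$relax)
  t_rr <- paired_t(vecs$rest, vecs$relax)
  structure(list(H = as.integer((t_ro$p < a) + (t_or$p < a)),
                 p_rest_vs_occ = t_ro$p, p_occ_vs_relax = t_or$p,
                 p_rest_vs_relax = t_rr$p,
                 t_rest_vs_occ = t_ro$t, t_occ_vs_relax = t_or$t,
                 t_rest_vs_relax = t_rr$t,
                 alpha = alpha),
            class = "hypothesis_result")
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat(sprintf("H = %d (alpha = %g)\n", x$H, x$alpha))
  cat(sprintf("  rest vs occlusion   p = %.4g %s\n", x$p_rest_vs_occ,
              if (x$p_rest_vs_occ < x$alpha) "*" else ""))
  cat(sprintf("  occlusion vs release p = %.4g %s\n", x$p_occ_vs_relax,
              if (x$p_occ_vs_relax < x$alpha) "*" else ""))
  cat(sprintf("  rest vs release      p = %.4g (reported, not counted)\n",
              x$p_rest_vs_relax))
  invisible(x)
}
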
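#' Singular value decomposition of a diffuse-reflectance image
#'
#' Decomposes the image matrix `X` (M x N) as `X = U S V'` with the singular
#' values (the "eigen values" of the imaging vocabulary; the diagonal of `S`)
#' in descending order. The leading components carry the bright specular
#' surface structure; later components carry the smooth subsurface signal.
#' Signs are fixed deterministically: the largest-magnitude entry of each
#' left singular vector is made positive (the right vector flipped
#' accordingly), so decompositions agree across numerical backends.
#'
#' @param image Finite numeric matrix (e.g. a [wavelength_image()]), minimum
#'   dimension at least 2.
#' @return An object of class `dr_svd`: list with `u`, `d` (singular values,
#'   descending), `v`, `shape`.
#' @export
#' @examples
#' d <- svd_decompose(diag(c(3, 1)))
#' d$d
svd_decompose <- function(image) {
  if (!is.matrix(image)) image <- as.matrix(image)
  if (any(!is.finite(image))) stopf("image contains non-finite pixels")
  if (min(dim(image)) < 2) stopf("image must be at least 2 x 2")
  s <- svd(image)
  for (k in seq_along(s$d)) {
    j <- which.max(abs(s$u[, k]))
    if (s$u[j, k] < 0) {
      s$u[, k] <- -s$u[, k]
      s$v[, k] <- -s$v[, k]
    }
  }
  structure(list(u = s$u, d = s$d, v = s$v, shape = dim(image)),
            class = "dr_svd")
}

#' @export
print.dr_svd <- function(x, ...) {
  cat(sprintf("SVD of a %d x %d image: %d singular values\n",
              x$shape[1], x$shape[2], length(x$d)))
  n <- min(8, length(x$d))
  cat(sprintf("  leading: %s\n", paste(sprintf("%.3g", x$d[seq_len(n)]), collapse = ", ")))
  frac <- sum(x$d[seq_len(min(2, length(x$d)))]) / max(sum(x$d), 1e-300)
  cat(sprintf("  first two components carry %.1f%% of the singular-value sum\n",
              100 * frac))
  invisible(x)
}

#' First n singular values ("eigen value" spectrum)
#'
#' @param d A [svd_decompose()] result.
#' @param n How many leading singular values to return (default 15, beyond
#'   which the spectrum of these images is essentially zero).
#' @return Numeric vector, descending.
#' @export
ev_spectrum <- function(d, n = 15L) {
  stopifnot(inherits(d, "dr_svd"))
  if (!is_count(n) || n > length(d$d))
    stopf("n must be an integer in [1, %d]", length(d$d))
  d$d[seq_len(n)]
}

#' Eigen-band specification
#'
#' The retained component range of a band reconstruction, written `"lo:hi"`:
#' `"4:15"` retains singular components 4 through 15, i.e. removes the three
#' leading (surface-dominated) components. Indices are 1-based.
#'
#' @param lo Either the lower 1-based index, or a string `"lo:hi"`.
#' @param hi Upper 1-based index (ignored when `lo` is a string).
#' @return An object of class `ev_band` with fields `lo`, `hi`.
#' @export
#' @examples
#' ev_band("4:15")
#' ev_band(1, 15)
ev_band <- function(lo, hi = NULL) {
  if (is.character(lo)) {
    parts <- strsplit(lo, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stopf("band string must look like 'lo:hi'")
    hi <- as.integer(parts[2]); lo <- as.integer(parts[1])
  }
  if (is.null(hi)) stopf("hi is required")
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (is.na(lo) || is.na(hi) || lo < 1 || hi < lo)
    stopf("need 1 <= lo <= hi")
  structure(list(lo = lo, hi = hi), class = "ev_band")
}

#' @export
format.ev_band <- function(x, ...) sprintf("%d:%d", x$lo, x$hi)

#' @export
print.ev_band <- function(x, ...) {
  cat(sprintf("Eigen band %s (retain components %d..%d)\n", format(x), x$lo, x$hi))
  invisible(x)
}

as_ev_band <- function(x) {
  if (inherits(x, "ev_band")) x else ev_band(x)
}

check_band <- function(d, band) {
  band <- as_ev_band(band)
  if (band$hi > length(d$d))
    stopf("band %s exceeds the available %d components", format(band), length(d$d))
  band
}

#' Reconstruct an image from an eigen band
#'
#' Returns the truncated expansion `sum_{k=lo..hi} u_k d_k v_k'`. Removing
#' the leading components (`lo > 1`) strips the surface-dominated structure;
#' the reconstruction is linear in the retained rank-1 terms, so disjoint
#' bands add exactly and the full band reproduces the input. Small negative
#' pixels can occur and are preserved (clipping happens only at export).
#'
#' @param d A [svd_decompose()] result.
#' @param band An [ev_band()] or `"lo:hi"` string.
#' @return Numeric matrix of the same shape as the input image.
#' @export
#' @examples
#' x <- outer(1:5, 1:4) + 1
#' d <- svd_decompose(x)
#' max(abs(reconstruct_band(d, ev_band(1, 4)) - x))  # full band: identity
reconstruct_band <- function(d, band) {
  stopifnot(inherits(d, "dr_svd"))
  band <- check_band(d, band)
  ks <- band$lo:band$hi
  d$u[, ks, drop = FALSE] %*% (d$d[ks] * t(d$v[, ks, drop = FALSE]))
}

#' Sequential band reconstructions with one more leading component removed
#'
#' Produces the reconstruction series `lo:hi` for `lo` in `lo_range`,
#' mirroring the exploratory procedure of removing one more leading component
#' at each step to expose the subsurface signal.
#'
#' @param d A [svd_decompose()] result.
#' @param hi Upper retained component (default 15).
#' @param lo_range Lower indices to sweep (default `1:8`).
#' @return Named list of images, names `"lo:hi"`.
#' @export
reconstruct_series <- function(d, hi = 15L, lo_range = 1:8) {
  stopifnot(inherits(d, "dr_svd"))
  if (hi > length(d$d))
    stopf("hi = %d exceeds the available %d components", hi, length(d$d))
  out <- lapply(lo_range, function(lo) reconstruct_band(d, ev_band(lo, hi)))
  names(out) <- sprintf("%d:%d", lo_range, hi)
  out
}
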
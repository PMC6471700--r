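#' Min-max normalize an image to [0, 1]
#'
#' @param image Finite numeric matrix with `max > min`.
#' @return Matrix rescaled to `[0, 1]`.
#' @export
normalize_image <- function(image) {
  if (any(!is.finite(image))) stopf("image contains non-finite pixels")
  rng <- range(image)
  if (diff(rng) <= 0) stopf("constant image cannot be normalized")
  (image - rng[1]) / diff(rng)
}

#' Crop an image to a rectangular field of interest
#'
#' @param image Numeric matrix.
#' @param window Integer `(row0, col0, rows, cols)`: 1-based origin and
#'   extent of the window.
#' @return The cropped matrix, with the window recorded in the
#'   `"crop_window"` attribute for provenance.
#' @export
crop_field <- function(image, window) {
  window <- as.integer(window)
  if (length(window) != 4) stopf("window must be (row0, col0, rows, cols)")
  r0 <- window[1]; c0 <- window[2]; nr <- window[3]; nc <- window[4]
  if (r0 < 1 || c0 < 1 || nr < 1 || nc < 1 ||
      r0 + nr - 1 > nrow(image) || c0 + nc - 1 > ncol(image))
    stopf("crop window [%d,%d,%d,%d] out of bounds for a %d x %d image",
          r0, c0, nr, nc, nrow(image), ncol(image))
  out <- image[r0:(r0 + nr - 1), c0:(c0 + nc - 1), drop = FALSE]
  attr(out, "crop_window") <- window
  out
}

#' Registration configuration
#'
#' Parameters of the intensity-based registration optimizer: regular-step
#' gradient descent over a spatial transform, matching the standard
#' parameterisation (initial step size 0.02, 300 iterations).
#'
#' Parameters are optimised on a scaled axis system so one optimizer step is
#' commensurate across translation (unit: a quarter of the larger image
#' dimension, in pixels) and rotation (unit: 0.5 rad); `initial_step` is the
#' step length on that scaled system.
#'
#' @param initial_step Initial step length (default 0.02).
#' @param iterations Maximum iterations (default 300).
#' @param transform `"rigid"` (default), `"translation"`, or `"affine"`.
#' @param metric `"meansq"` (default; mean squared intensity difference) or
#'   `"mi"` (negative joint-histogram mutual information, for multimodal
#'   NIR-to-white-light pairs).
#' @param min_step Step length at which the search is declared converged.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(initial_step = 0.02, iterations = 300L,
                       transform = c("rigid", "translation", "affine"),
                       metric = c("meansq", "mi"),
                       min_step = 1e-5) {
  transform <- match.arg(transform)
  metric <- match.arg(metric)
  if (initial_step <= 0) stopf("initial_step must be positive")
  if (!is_count(iterations)) stopf("iterations must be a positive integer")
  structure(list(initial_step = initial_step, iterations = as.integer(iterations),
                 transform = transform, metric = metric, min_step = min_step),
            class = "reg_config")
}

# Map fixed-grid pixel centres through the transform into moving-image
# coordinates. Params by model: translation (tr, tc); rigid (theta, tr, tc);
# affine (a11, a12, a21, a22, tr, tc) as offsets from the identity.
transform_coords <- function(params, model, rr, cc, center) {
  u <- rr - center[1]; w <- cc - center[2]
  if (model == "translation") {
    list(r = rr + params[1], c = cc + params[2])
  } else if (model == "rigid") {
    th <- params[1]
    list(r = center[1] + cos(th) * u - sin(th) * w + params[2],
         c = center[2] + sin(th) * u + cos(th) * w + params[3])
  } else {
    list(r = center[1] + (1 + params[1]) * u + params[2] * w + params[5],
         c = center[2] + params[3] * u + (1 + params[4]) * w + params[6])
  }
}

n_params <- function(model) switch(model, translation = 2L, rigid = 3L, affine = 6L)

param_scales <- function(model, dims) {
  t_unit <- max(dims) / 4
  switch(model,
         translation = c(t_unit, t_unit),
         rigid = c(0.5, t_unit, t_unit),
         affine = c(0.25, 0.25, 0.25, 0.25, t_unit, t_unit))
}

# Bilinear sampling of img at (rm, cm); NA outside the field.
resample_bilinear <- function(img, rm, cm) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rm); c0 <- floor(cm)
  fr <- rm - r0; fc <- cm - c0
  out <- rep(NA_real_, length(rm))
  i <- which(r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc)
  if (length(i)) {
    base <- (c0[i] - 1) * nr + r0[i]
    v00 <- img[base]; v10 <- img[base + 1]
    v01 <- img[base + nr]; v11 <- img[base + nr + 1]
    out[i] <- v00 * (1 - fr[i]) * (1 - fc[i]) + v10 * fr[i] * (1 - fc[i]) +
      v01 * (1 - fr[i]) * fc[i] + v11 * fr[i] * fc[i]
  }
  out
}

metric_value <- function(sampled, fixed_vals, metric) {
  ok <- !is.na(sampled)
  if (sum(ok) < max(16, 0.05 * length(fixed_vals))) return(Inf)
  a <- sampled[ok]; b <- fixed_vals[ok]
  if (metric == "meansq") return(mean((a - b)^2))
  # negative mutual information on a 32-bin joint histogram
  nb <- 32L
  ab <- cut(a, breaks = seq(min(a), max(a), length.out = nb + 1), include.lowest = TRUE)
  bb <- cut(b, breaks = seq(min(b), max(b), length.out = nb + 1), include.lowest = TRUE)
  jt <- table(ab, bb) / length(a)
  pa <- rowSums(jt); pb <- colSums(jt)
  nz <- jt > 0
  -sum(jt[nz] * log(jt[nz] / outer(pa, pb)[nz]))
}

#' Register a moving image onto a fixed (white-light) image
#'
#' Intensity-based registration by regular-step gradient descent: at each
#' iteration the numeric gradient of the similarity metric with respect to
#' the (scaled) transform parameters is evaluated, a unit step of the current
#' length is taken downhill, and the step length is halved whenever it fails
#' to improve the metric. The search stops at `iterations` or when the step
#' length falls below `min_step`. Deterministic for fixed inputs.
#'
#' @param moving Numeric matrix to be aligned (e.g. a band reconstruction).
#' @param fixed Numeric matrix target (e.g. the white-light still).
#' @param config A [reg_config()].
#' @param crop_window Optional field-of-interest window recorded on the
#'   result (provenance only).
#' @return An object of class `coregistration`: list with `overlay` (moving
#'   resampled into fixed coordinates, out-of-field pixels 0), `mask`
#'   (logical matrix of in-field pixels), `transform` (list: `model`,
#'   `params`, `matrix` mapping fixed to moving homogeneous (row, col)
#'   coordinates), `metric`, `metric_value`, `iterations`, `converged`,
#'   `crop_window`.
#' @export
#' @examples
#' img <- outer(sin(seq(0, 3, length.out = 40)), cos(seq(0, 4, length.out = 50)))
#' reg <- register_images(img, img, reg_config(transform = "translation"))
#' reg$transform$params   # identity recovered
register_images <- function(moving, fixed, config = reg_config(),
                            crop_window = NULL) {
  stopifnot(inherits(config, "reg_config"))
  moving <- unclass(as.matrix(moving)); fixed <- unclass(as.matrix(fixed))
  if (diff(range(moving)) <= 0 || diff(range(fixed)) <= 0)
    stopf("both images must be nonconstant")
  dims <- dim(fixed)
  center <- (dims + 1) / 2
  grid <- expand.grid(r = seq_len(dims[1]), c = seq_len(dims[2]))
  rr <- grid$r; cc <- grid$c
  fixed_vals <- as.vector(fixed)
  scales <- param_scales(config$transform, dims)

  eval_metric <- function(q, it = NA_integer_) {
    p <- q * scales
    tc <- transform_coords(p, config$transform, rr, cc, center)
    m <- metric_value(resample_bilinear(moving, tc$r, tc$c), fixed_vals, config$metric)
    if (is.nan(m)) stopf("registration metric became non-finite at iteration %d", it)
    m
  }

  np <- n_params(config$transform)
  q <- rep(0, np)
  m <- eval_metric(q)
  step <- config$initial_step
  it <- 0L
  converged <- FALSE
  while (it < config$iterations) {
    it <- it + 1L
    # finite-difference scale tied to the current step length: coarse probes
    # early (insensitive to sub-pixel interpolation artifacts), fine late
    h <- max(1e-4, step / 2)
    g <- vapply(seq_len(np), function(j) {
      e <- rep(0, np); e[j] <- h
      (eval_metric(q + e, it) - eval_metric(q - e, it)) / (2 * h)
    }, 0)
    if (any(!is.finite(g))) stopf("registration gradient non-finite at iteration %d", it)
    ng <- sqrt(sum(g^2))
    if (ng < 1e-12) { converged <- TRUE; break }
    cand <- q - step * g / ng
    mc <- eval_metric(cand, it)
    if (is.infinite(mc) && is.infinite(m))
      stopf("registration diverged (no image overlap) at iteration %d", it)
    if (mc < m) {
      q <- cand; m <- mc
    } else {
      step <- step / 2
      if (step < config$min_step) { converged <- TRUE; break }
    }
  }

  p <- q * scales
  tc <- transform_coords(p, config$transform, rr, cc, center)
  sampled <- resample_bilinear(moving, tc$r, tc$c)
  mask <- matrix(!is.na(sampled), dims[1], dims[2])
  overlay <- matrix(ifelse(is.na(sampled), 0, sampled), dims[1], dims[2])

  structure(list(overlay = overlay, mask = mask,
                 transform = list(model = config$transform,
                                  params = named_params(p, config$transform),
                                  matrix = transform_matrix(p, config$transform, center)),
                 metric = config$metric, metric_value = m,
                 iterations = it, converged = converged,
                 crop_window = crop_window),
            class = "coregistration")
}

#' Apply an estimated transform to another image
#'
#' Resamples `image` into fixed coordinates using a transform estimated by
#' [register_images()] — the standard way to carry an alignment estimated on
#' an anatomically informative image over to derived maps (e.g. band
#' reconstructions) of the same acquisition.
#'
#' @param image Numeric matrix in moving-image coordinates.
#' @param transform The `transform` element of a [register_images()] result.
#' @param dims Output (fixed-image) dimensions; defaults to `dim(image)`.
#' @return Matrix in fixed coordinates, out-of-field pixels 0, with the
#'   in-field mask in attribute `"mask"`.
#' @export
apply_transform <- function(image, transform, dims = dim(image)) {
  grid <- expand.grid(r = seq_len(dims[1]), c = seq_len(dims[2]))
  center <- (dims + 1) / 2
  tc <- transform_coords(transform$params, transform$model, grid$r, grid$c, center)
  sampled <- resample_bilinear(unclass(as.matrix(image)), tc$r, tc$c)
  out <- matrix(ifelse(is.na(sampled), 0, sampled), dims[1], dims[2])
  attr(out, "mask") <- matrix(!is.na(sampled), dims[1], dims[2])
  out
}

named_params <- function(p, model) {
  names(p) <- switch(model,
                     translation = c("t_row", "t_col"),
                     rigid = c("theta", "t_row", "t_col"),
                     affine = c("a11", "a12", "a21", "a22", "t_row", "t_col"))
  p
}

# Homogeneous 3x3 matrix mapping fixed (row, col, 1) to moving coordinates.
transform_matrix <- function(p, model, center) {
  A <- switch(model,
              translation = diag(2),
              rigid = {
                th <- p[1]
                matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
              },
              affine = matrix(c(1 + p[1], p[3], p[2], 1 + p[4]), 2, 2))
  t_off <- switch(model, translation = p, rigid = p[2:3], affine = p[5:6])
  shift <- center - A %*% center + t_off
  rbind(cbind(A, shift), c(0, 0, 1))
}

#' @export
print.coregistration <- function(x, ...) {
  cat(sprintf("Coregistration (%s transform, %s metric)\n", x$transform$model, x$metric))
  cat(sprintf("  params : %s\n",
              paste(sprintf("%s = %.4f", names(x$transform$params), x$transform$params),
                    collapse = ", ")))
  cat(sprintf("  metric value %.6g after %d iterations (%s)\n",
              x$metric_value, x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}
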
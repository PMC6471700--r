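#' Tissue phantom for the acquisition simulator
#'
#' A phenomenological forward model of the imaged scene, with the two layers
#' the SVD denoiser is meant to separate planted explicitly:
#'
#' * a bright, low-rank *surface* layer (specular reflection / illumination
#'   structure), built as a sum of `r_surf` rank-1 outer products of smooth
#'   profiles so that its matrix rank is exactly controlled;
#' * a spatially smooth *subsurface* absorption pattern (the physiological
#'   signal), a perfusion-like field of compact bumps tiling the lower-right
#'   tissue quadrant sampled by the analysis region of interest;
#' * a separable (rank-1) Gaussian-profile fiducial marker disk, placed in
#'   the surface glare's row band so most of its energy is absorbed into the
#'   leading singular components (its imprint fades as the leading eigen
#'   values are removed, like a physical marker's);
#' * per-source-state reflectance gains, with white light the brightest; and
#' * multiplicative occlusion factors per NIR state and time stamp, encoding
#'   the venous-occlusion response: at 690 nm (deoxy-hemoglobin sensitive)
#'   reflectance drops under occlusion and overshoots on release.
#'
#' All intensities are on the camera's 8-bit scale (0-255 counts).
#'
#' @param frame_shape Integer `(rows, cols)`; must match the acquisition
#'   configuration used for rendering.
#' @param r_surf Rank of the surface layer (default 2).
#' @param surface_amplitude Peak surface intensity in counts (default 245).
#' @param subsurface_amplitude Peak subsurface intensity in counts (default 25;
#'   with the default sensor noise of 2 counts this is a signal-to-noise ratio
#'   of 12.5).
#' @param surface_map,subsurface_map Optional user-supplied maps overriding the
#'   built-in constructions; matrices of shape `frame_shape`.
#' @param wavelength_gain Named numeric: baseline reflectance scale per source
#'   state. White light must be the brightest so cycle delimiting by flash
#'   detection is possible.
#' @param occlusion_delta Named list (per NIR state) of length-3 numeric
#'   vectors `(REST, OCCLUSION, RELEASE)` of strictly positive multiplicative
#'   reflectance factors.
#' @param fiducial List with `center` (row, col), `radius` (pixels) and
#'   `intensity` (counts) of the marker, or `NULL` for no marker.
#' @param noise_sd Additive Gaussian sensor noise standard deviation in counts
#'   (default 2).
#'
#' @return An object of class `tissue_phantom` with components `surface_map`,
#'   `subsurface_map`, `fiducial_map`, `wavelength_gain`, `occlusion_delta`,
#'   `noise_sd`, `r_surf`, `frame_shape`, `fiducial`.
#' @export
#' @examples
#' ph <- tissue_phantom(frame_shape = c(60L, 80L))
#' range(ph$surface_map)
tissue_phantom <- function(frame_shape = c(270L, 480L),
                           r_surf = 2,
                           surface_amplitude = 245,
                           subsurface_amplitude = 25,
                           surface_map = NULL,
                           subsurface_map = NULL,
                           wavelength_gain = c(WHITE = 1.0, NIR690 = 0.82,
                                               NIR800 = 0.60, NIR840 = 0.42),
                           occlusion_delta = list(
                             NIR690 = c(REST = 1.0, OCCLUSION = 0.8, RELEASE = 1.1),
                             NIR800 = c(REST = 1.0, OCCLUSION = 0.93, RELEASE = 1.05),
                             NIR840 = c(REST = 1.0, OCCLUSION = 0.95, RELEASE = 1.03)),
                           fiducial = list(center = NULL, radius = 4, intensity = 60),
                           noise_sd = 2) {
  frame_shape <- as.integer(frame_shape)
  if (is.null(surface_map))
    surface_map <- build_surface_map(frame_shape, r_surf, surface_amplitude)
  if (is.null(subsurface_map))
    subsurface_map <- build_subsurface_map(frame_shape, subsurface_amplitude)
  fid_map <- matrix(0, frame_shape[1], frame_shape[2])
  if (!is.null(fiducial)) {
    if (is.null(fiducial$center))
      fiducial$center <- c(round(frame_shape[1] * 0.2), round(frame_shape[2] * 0.88))
    fid_map <- build_fiducial_map(frame_shape, fiducial$center,
                                  fiducial$radius, fiducial$intensity)
  }
  ph <- structure(
    list(surface_map = surface_map,
         subsurface_map = subsurface_map,
         fiducial_map = fid_map,
         fiducial = fiducial,
         wavelength_gain = wavelength_gain,
         occlusion_delta = occlusion_delta,
         noise_sd = noise_sd,
         r_surf = as.integer(r_surf),
         frame_shape = frame_shape),
    class = "tissue_phantom")
  validate_tissue_phantom(ph)
}

validate_tissue_phantom <- function(ph) {
  stopifnot(inherits(ph, "tissue_phantom"))
  shp <- ph$frame_shape
  for (nm in c("surface_map", "subsurface_map", "fiducial_map"))
    if (!identical(dim(ph[[nm]]), as.integer(shp)))
      stopf("%s shape does not match frame_shape", nm)
  if (!all(c("WHITE", "NIR690", "NIR800", "NIR840") %in% names(ph$wavelength_gain)))
    stopf("wavelength_gain must name all four source states")
  for (st in names(ph$occlusion_delta)) {
    d <- ph$occlusion_delta[[st]]
    if (length(d) != 3 || any(d <= 0))
      stopf("occlusion_delta[[%s]] must be 3 strictly positive factors", st)
  }
  if (ph$noise_sd < 0) stopf("noise_sd must be nonnegative")
  # numerical rank of the surface layer must not exceed r_surf
  sv <- svd(ph$surface_map, nu = 0, nv = 0)$d
  if (sv[1] > 0 && sum(sv > 1e-8 * sv[1]) > ph$r_surf)
    stopf("surface_map numerical rank exceeds r_surf = %d", ph$r_surf)
  ph
}

# Smooth 1-D Gaussian bump on 1..n, used to compose separable map components.
gauss_profile <- function(n, center_frac, width_frac) {
  i <- seq_len(n)
  exp(-((i - center_frac * n)^2) / (2 * (width_frac * n)^2))
}

# Rank-r_surf surface: sum of outer products of smooth Gaussian spot profiles
# (specular glare patches) with distinct centres along the upper-left
# diagonal, scaled so the peak equals `amplitude`. The spots are comparable in
# magnitude and mutually near-orthogonal, so the layer's r_surf singular
# values all dominate the subsurface spectrum — the property the eigen-band
# denoiser relies on. Generic positions keep the numerical rank exactly
# r_surf.
build_surface_map <- function(shape, r_surf, amplitude) {
  if (r_surf > 4) stopf("built-in surface construction supports r_surf <= 4")
  # glare spots confined to the upper-left of the frame, clear of the
  # subsurface tissue quadrant; positions generic so rank is exactly r_surf
  spots <- list(c(0.20, 0.17, 1.00, 0.150, 0.085),
                c(0.40, 0.36, 0.95, 0.143, 0.081),
                c(0.05, 0.42, 1.00, 0.035, 0.080),
                c(0.47, 0.08, 0.65, 0.060, 0.045))
  m <- matrix(0, shape[1], shape[2])
  for (k in seq_len(r_surf)) {
    s <- spots[[k]]
    m <- m + s[3] * outer(gauss_profile(shape[1], s[1], s[4]),
                          gauss_profile(shape[2], s[2], s[5]))
  }
  m * (amplitude / max(m))
}

# Smooth subsurface absorption pattern: a perfusion-like field of compact
# bumps tiling the lower-right tissue quadrant (where the analysis ROI
# lives), built from four separable terms whose row bands and multi-bump
# column profiles are spatially separated from the surface glare in both
# image axes, so the subsurface singular components stay distinguishable
# from the surface span. Peak scaled to `amplitude`.
build_subsurface_map <- function(shape, amplitude) {
  bump_comb <- function(n, centers, width) {
    out <- 0
    for (cc in centers) out <- out + gauss_profile(n, cc, width)
    out
  }
  rowc <- function(from) bump_comb(shape[1], seq(from, 0.94, by = 0.12), 0.022)
  colc <- function(from) bump_comb(shape[2], seq(from, 0.92, by = 0.06), 0.015)
  m <- outer(rowc(0.52), colc(0.50)) +
    0.9 * outer(rowc(0.58), colc(0.53)) +
    0.8 * outer(rowc(0.55), colc(0.56)) +
    0.7 * outer(rowc(0.61), colc(0.59))
  # smooth proximal-distal amplitude gradient: the perfusion response is
  # strongest near the wrist edge of the field and tapers across the limb
  grad_r <- 1 - 0.45 * pmax(0, (seq_len(shape[1]) / shape[1] - 0.5)) / 0.45
  grad_c <- 1 - 0.55 * pmax(0, (seq_len(shape[2]) / shape[2] - 0.45)) / 0.5
  m <- m * outer(pmax(grad_r, 0.3), pmax(grad_c, 0.3))
  m * (amplitude / max(m))
}

# Separable Gaussian-profile marker "disk": rank 1 by construction so the
# rendered frame rank stays at r_surf + 1 when the subsurface layer is absent.
build_fiducial_map <- function(shape, center, radius, intensity) {
  sr <- exp(-((seq_len(shape[1]) - center[1])^2) / (2 * (radius / 1.5)^2))
  sc <- exp(-((seq_len(shape[2]) - center[2])^2) / (2 * (radius / 1.5)^2))
  intensity * outer(sr, sc)
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("Tissue phantom\n")
  cat(sprintf("  frame shape      : %d x %d\n", x$frame_shape[1], x$frame_shape[2]))
  cat(sprintf("  surface layer    : rank %d, peak %.1f counts\n",
              x$r_surf, max(x$surface_map)))
  cat(sprintf("  subsurface layer : peak %.1f counts\n", max(x$subsurface_map)))
  cat(sprintf("  fiducial         : %s\n",
              if (max(x$fiducial_map) > 0) sprintf("peak %.1f counts", max(x$fiducial_map)) else "none"))
  cat(sprintf("  sensor noise sd  : %.2f counts\n", x$noise_sd))
  d <- x$occlusion_delta$NIR690
  cat(sprintf("  690 nm occlusion : rest %.2f, occlusion %.2f, release %.2f\n",
              d[1], d[2], d[3]))
  invisible(x)
}
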
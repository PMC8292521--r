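#' SPECT acquisition geometry
#'
#' Describes a rotating-camera acquisition: number of views over an arc,
#' per-view orbit radius (body-contouring orbits give one radius per
#' view), time per view, and the photopeak and scatter energy windows.
#' Defaults mirror a clinical pediatric DMSA protocol: 120 views over
#' 360 degrees, 8 s per view, a 15\% photopeak window at 140 keV
#' (129.5-150.5 keV) and a 108-129 keV scatter window.
#'
#' @param n_views Number of projection views (> 0).
#' @param arc Total arc in degrees.
#' @param orbit_radius Orbit radius in cm: a scalar, a vector of length
#'   \code{n_views}, or \code{NULL} to derive a body-contouring orbit from
#'   the phantom at simulation time.
#' @param seconds_per_view Acquisition duration per view (s).
#' @param photopeak_window,scatter_window keV intervals \code{c(lo, hi)};
#'   must not overlap.
#' @param orbit_margin Clearance (cm) added to the body half-width when a
#'   contouring orbit is derived.
#' @return Object of class \code{"acquisition_geometry"} with fields as
#'   above plus \code{angles} (degrees; view 1 at 0 = anterior,
#'   counterclockwise).
#' @export
acquisition_geometry <- function(n_views = 120, arc = 360,
                                 orbit_radius = NULL, seconds_per_view = 8,
                                 photopeak_window = c(129.5, 150.5),
                                 scatter_window = c(108, 129),
                                 orbit_margin = 2) {
  stopifnot(n_views > 0, arc > 0, seconds_per_view > 0)
  if (max(scatter_window) > min(photopeak_window) &&
      max(photopeak_window) > min(scatter_window))
    stop("photopeak and scatter windows must not overlap")
  if (!is.null(orbit_radius)) {
    if (length(orbit_radius) == 1) orbit_radius <- rep(orbit_radius, n_views)
    if (length(orbit_radius) != n_views)
      stop("orbit_radius must be scalar or length n_views")
    if (any(orbit_radius <= 0)) stop("orbit radii must be positive")
  }
  angles <- seq(0, arc, length.out = n_views + 1)[seq_len(n_views)]
  structure(list(n_views = n_views, arc = arc, angles = angles,
                 orbit_radius = orbit_radius,
                 seconds_per_view = seconds_per_view,
                 photopeak_window = photopeak_window,
                 scatter_window = scatter_window,
                 orbit_margin = orbit_margin),
            class = "acquisition_geometry")
}

#' Distance-dependent collimator-detector response
#'
#' Gaussian response whose width grows with distance to the collimator
#' face: \code{sigma(d) = sqrt(sigma0^2 + (slope d)^2)} (cm). Defaults are
#' representative of a low-energy ultra-high-resolution parallel-hole
#' collimator. \code{collimator_response(0, 0)} disables the blur.
#'
#' @param sigma0 Intrinsic blur at the collimator face (cm, >= 0).
#' @param slope Blur growth per cm of source-to-collimator distance (>= 0).
#' @return Object of class \code{"collimator_response"}.
#' @export
collimator_response <- function(sigma0 = 0.2, slope = 0.02) {
  stopifnot(sigma0 >= 0, slope >= 0)
  structure(list(sigma0 = sigma0, slope = slope),
            class = "collimator_response")
}

#' @rdname collimator_response
#' @param response A \code{"collimator_response"}.
#' @param d Distance(s) to the collimator face in cm.
#' @return \code{response_sigma} returns sigma(d) in cm.
#' @export
response_sigma <- function(response, d) {
  sqrt(response$sigma0^2 + (response$slope * d)^2)
}

# per-view body-contouring orbit: smallest detector distance clearing the
# body mask at every view angle, plus a safety margin
body_contour_orbit <- function(phantom, geometry) {
  n <- dim(phantom$activity)[1]
  v <- phantom$voxel_size
  idx <- which(apply(phantom$body_mask, c(1, 2), any), arr.ind = TRUE)
  px <- (idx[, 1] - (n + 1) / 2) * v
  py <- (idx[, 2] - (n + 1) / 2) * v
  vapply(geometry$angles, function(ang) {
    th <- ang * pi / 180
    # y-coordinate in the detector frame (volume rotated by -ang)
    max(-sin(th) * px + cos(th) * py) + geometry$orbit_margin
  }, numeric(1))
}

# resolve a geometry against a phantom: fill orbit radii if absent and
# check they clear the body at every view
resolve_geometry <- function(geometry, phantom) {
  if (is.null(geometry$orbit_radius)) {
    geometry$orbit_radius <- body_contour_orbit(phantom, geometry)
  } else {
    need <- body_contour_orbit(phantom, geometry) - geometry$orbit_margin
    if (any(geometry$orbit_radius < need - 1e-9))
      stop("orbit radius smaller than body half-width at some view")
  }
  geometry
}
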
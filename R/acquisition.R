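# per-view wide in-plane blur used for the phenomenological scatter model
.scatter_blur <- function(views_arr, sigma_vox) {
  nu <- dim(views_arr)[1]; nv <- dim(views_arr)[2]
  Ku <- .blur_kernel(nu, sigma_vox); Kv <- .blur_kernel(nv, sigma_vox)
  out <- views_arr
  for (k in seq_len(dim(views_arr)[3])) {
    W <- views_arr[, , k]
    if (!is.null(Ku)) W <- Ku %*% W
    if (!is.null(Kv)) W <- W %*% t(Kv)
    out[, , k] <- W
  }
  out
}

#' Simulate a SPECT acquisition of a digital phantom
#'
#' Forward-projects the physically decayed phantom activity through the
#' attenuating body with the distance-dependent collimator response,
#' scales to expected counts with the system sensitivity and the per-view
#' duration, adds a phenomenological scatter component, and (optionally)
#' draws Poisson counts. The scatter model is a broad in-plane blur of the
#' primary projections: a fraction \code{photopeak_scatter_fraction}
#' contaminates the photopeak window and a fraction
#' \code{scatter_window_fraction} (blurred more strongly) forms the
#' scatter-window data used for body-contour attenuation mapping. It is
#' deliberately phenomenological, not photon transport: it exists to
#' exercise the scatter-window and scatter-compensation procedures.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param geometry An [acquisition_geometry()]; a body-contouring orbit is
#'   derived from the phantom when \code{orbit_radius} is \code{NULL}.
#' @param sensitivity A [sensitivity_from_flask()] factor, or a number in
#'   counts per minute per MBq (CPM/MBq).
#' @param time_post_injection Imaging time in hours (>= 0).
#' @param noise \code{TRUE} for Poisson counts, \code{FALSE} for expected
#'   values.
#' @param seed RNG seed used when \code{noise = TRUE}.
#' @param response A [collimator_response()].
#' @param T_phys Physical half-life (h).
#' @param photopeak_scatter_fraction Scatter-to-primary fraction in the
#'   photopeak window.
#' @param scatter_window_fraction Scatter-window amplitude relative to the
#'   primary projections.
#' @param scatter_blur_sigma In-plane scatter blur (cm).
#' @return Object of class \code{"projection_set"}: \code{counts} (list
#'   with arrays \code{photopeak}, \code{scatter}, each
#'   \code{[n_u, n_v, n_views]}), \code{expected} (noise-free expectations
#'   incl. \code{scatter_in_photopeak}, the matched scatter estimate for
#'   reconstruction), \code{geometry} (with resolved orbit), \code{voxel_size},
#'   \code{time_post_injection}, \code{sensitivity_cpm_per_mbq},
#'   \code{T_phys}.
#' @export
simulate_acquisition <- function(phantom, geometry = acquisition_geometry(),
                                 sensitivity = 5005,
                                 time_post_injection = 3, noise = TRUE,
                                 seed = NULL,
                                 response = collimator_response(),
                                 T_phys = 6.0,
                                 photopeak_scatter_fraction = 0.2,
                                 scatter_window_fraction = 0.5,
                                 scatter_blur_sigma = 3) {
  if (time_post_injection < 0) stop("negative time post-injection")
  geometry <- resolve_geometry(geometry, phantom)
  cps <- sensitivity_cps(sensitivity)
  act <- phantom$activity * decay_factor(time_post_injection, T_phys)
  prim <- forward_project(act, phantom$mu, geometry, response,
                          phantom$voxel_size)
  prim_counts <- prim * cps * geometry$seconds_per_view
  sb <- phantom$voxel_size
  scat_base <- .scatter_blur(prim_counts, scatter_blur_sigma / sb)
  pp_scatter <- photopeak_scatter_fraction * scat_base
  pp_expected <- prim_counts + pp_scatter
  sw_expected <- scatter_window_fraction *
    .scatter_blur(scat_base, scatter_blur_sigma / sb)
  counts <- if (noise) {
    with_seed(seed, list(
      photopeak = array(rpois(length(pp_expected), pp_expected),
                        dim(pp_expected)),
      scatter = array(rpois(length(sw_expected), sw_expected),
                      dim(sw_expected))))
  } else {
    list(photopeak = pp_expected, scatter = sw_expected)
  }
  structure(list(counts = counts,
                 expected = list(photopeak = pp_expected,
                                 scatter = sw_expected,
                                 primary = prim_counts,
                                 scatter_in_photopeak = pp_scatter),
                 geometry = geometry, voxel_size = phantom$voxel_size,
                 time_post_injection = time_post_injection,
                 sensitivity_cpm_per_mbq = 60 * cps,
                 T_phys = T_phys, noise = noise),
            class = "projection_set")
}

#' @method print projection_set
#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts$photopeak)
  cat(sprintf(
    "Projection set: %d views of %dx%d bins, %g s/view, t = %g h, %s\n",
    d[3], d[1], d[2], x$geometry$seconds_per_view, x$time_post_injection,
    if (x$noise) "Poisson noise" else "noise-free"))
  invisible(x)
}

#' Dual-window scatter estimate
#'
#' Clinical-style scatter estimate for the photopeak window formed by
#' scaling the scatter-window counts by a factor \code{k}, as an
#' alternative to the matched (simulation-truth) estimate.
#'
#' @param projections A \code{"projection_set"}.
#' @param k Scaling factor applied to the scatter-window counts.
#' @return Array shaped like the photopeak counts.
#' @export
dual_window_scatter <- function(projections, k = 0.4) {
  k * projections$counts$scatter
}
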
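#' Simulate an anterior/posterior planar pair
#'
#' Projects the decayed phantom at the anterior (0 degrees) and posterior
#' (180 degrees) views with attenuation and collimator response, scales to
#' expected counts, adds the phenomenological scatter component, and
#' optionally draws Poisson counts. Both views share geometry; detector
#' bins coincide with the voxel grid.
#'
#' @inheritParams simulate_acquisition
#' @param duration Acquisition duration per view in seconds.
#' @param detector_distance Distance from volume centre to each detector
#'   face (cm); default clears the phantom body with a 2 cm margin.
#' @return Object of class \code{"planar_image"}: \code{counts} and
#'   \code{scatter} (each a list with \code{anterior}/\code{posterior}
#'   matrices), \code{expected}, \code{duration}, \code{time_post_injection},
#'   \code{voxel_size}.
#' @export
simulate_planar <- function(phantom, sensitivity = 5005,
                            time_post_injection = 3, duration = 300,
                            noise = TRUE, seed = NULL,
                            response = collimator_response(),
                            detector_distance = NULL, T_phys = 6.0,
                            photopeak_scatter_fraction = 0.2,
                            scatter_window_fraction = 0.5,
                            scatter_blur_sigma = 3) {
  if (time_post_injection < 0) stop("negative time post-injection")
  geom <- acquisition_geometry(n_views = 2, arc = 360,
                               orbit_radius = detector_distance,
                               seconds_per_view = duration)
  geom$angles <- c(0, 180)
  geom <- resolve_geometry(geom, phantom)
  cps <- sensitivity_cps(sensitivity)
  act <- phantom$activity * decay_factor(time_post_injection, T_phys)
  prim <- forward_project(act, phantom$mu, geom, response,
                          phantom$voxel_size)
  prim_counts <- prim * cps * duration
  scat_base <- .scatter_blur(prim_counts,
                             scatter_blur_sigma / phantom$voxel_size)
  pp <- prim_counts + photopeak_scatter_fraction * scat_base
  sw <- scatter_window_fraction *
    .scatter_blur(scat_base, scatter_blur_sigma / phantom$voxel_size)
  draw <- function(arr) {
    if (!noise) return(arr)
    array(rpois(length(arr), arr), dim(arr))
  }
  drawn <- with_seed(seed, list(pp = draw(pp), sw = draw(sw)))
  structure(list(
    counts = list(anterior = drawn$pp[, , 1], posterior = drawn$pp[, , 2]),
    scatter = list(anterior = drawn$sw[, , 1], posterior = drawn$sw[, , 2]),
    expected = list(anterior = pp[, , 1], posterior = pp[, , 2]),
    duration = duration, time_post_injection = time_post_injection,
    voxel_size = phantom$voxel_size, T_phys = T_phys,
    sensitivity_cpm_per_mbq = 60 * cps),
    class = "planar_image")
}

#' Planar kidney and background ROIs from a phantom
#'
#' Projects the kidney masks geometrically at the anterior and posterior
#' view angles to form per-view kidney ROIs (dilated to catch blur
#' spill-over), and a background ROI inside the projected body but away
#' from the kidneys.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param dilate Dilation radius in pixels applied to the kidney ROI.
#' @param margin Dilation radius separating background from kidneys.
#' @return List with \code{kidney} and \code{background}, each a list of
#'   logical matrices \code{anterior}/\code{posterior}.
#' @export
planar_roi_from_phantom <- function(phantom, dilate = 2, margin = 6) {
  geom <- acquisition_geometry(n_views = 2, arc = 360, orbit_radius = 30,
                               seconds_per_view = 1)
  geom$angles <- c(0, 180)
  kmask <- (phantom$left_kidney_mask | phantom$right_kidney_mask) * 1
  kp <- forward_project(kmask, NULL, geom, collimator_response(0, 0),
                        phantom$voxel_size)
  bp <- forward_project(phantom$body_mask * 1, NULL, geom,
                        collimator_response(0, 0), phantom$voxel_size)
  brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  roi <- function(view) {
    k <- kp[, , view] > 1e-9
    kd <- EBImage::dilate(matrix(as.numeric(k), nrow(k)), brush(dilate)) > 0
    kb <- EBImage::dilate(matrix(as.numeric(k), nrow(k)), brush(margin)) > 0
    body <- bp[, , view] > 1e-9
    list(kidney = kd & body, background = body & !kb)
  }
  a <- roi(1); p <- roi(2)
  list(kidney = list(anterior = a$kidney, posterior = p$kidney),
       background = list(anterior = a$background, posterior = p$background))
}

#' Scatter-, background- and attenuation-corrected planar kidney count rate
#'
#' Per view, subtracts a dual-window scatter estimate
#' (\code{scatter_k} x scatter-window ROI counts) and the local background
#' (background ROI mean per pixel x kidney ROI area) from the kidney ROI
#' counts; combines the anterior and posterior views by the conjugate-view
#' geometric mean, for which the depth-dependent attenuation factors
#' \eqn{e^{-\mu d} e^{-\mu (L - d)}} reduce to \eqn{e^{-\mu L / 2}}
#' independent of source depth; corrects by \eqn{e^{+\mu L / 2}}; and
#' divides by the acquisition duration. Negative corrected counts are
#' floored at zero with a warning.
#'
#' @param planar A [simulate_planar()] image.
#' @param rois ROIs from [planar_roi_from_phantom()] (or the same shape).
#' @param body_thickness Body thickness L along the view axis (cm).
#' @param mu Soft-tissue attenuation coefficient (cm^-1).
#' @param scatter_k Dual-window scatter scaling factor (default 0.5).
#' @return Corrected count rate (counts/s), attenuation-corrected to the
#'   unattenuated equivalent.
#' @export
corrected_kidney_counts <- function(planar, rois, body_thickness,
                                    mu = 0.15, scatter_k = 0.5) {
  stopifnot(inherits(planar, "planar_image"))
  one_view <- function(view) {
    k <- rois$kidney[[view]]; b <- rois$background[[view]]
    if (!any(b)) stop("background ROI is empty")
    if (any(k & b)) stop("kidney and background ROIs must be disjoint")
    counts <- sum(planar$counts[[view]][k])
    scat <- sum(planar$scatter[[view]][k])
    bg <- mean(planar$counts[[view]][b]) * sum(k)
    net <- counts - scatter_k * scat - bg
    if (net < 0) {
      warning("negative corrected counts floored at 0 (", view, " view)")
      net <- 0
    }
    net / planar$duration
  }
  ra <- one_view("anterior")
  rp <- one_view("posterior")
  sqrt(ra * rp) * exp(mu * body_thickness / 2)
}

#' Hybrid SPECT-anchored planar calibration
#'
#' Converts corrected planar count rates into absolute activity using the
#' SPECT kidney activity measured in the same imaging session: the factor
#' is \code{spect_activity / planar_rate} at the shared (anchor) time
#' point, and applying it to the planar rate at another time point yields
#' that time point's absolute kidney activity.
#'
#' @param planar_rate_at_anchor Corrected planar count rate (counts/s) at
#'   the anchor time (> 0).
#' @param spect_activity_at_anchor SPECT kidney activity (MBq) at the
#'   anchor time (> 0).
#' @param anchor_time Anchor time post-injection (h).
#' @return Object of class \code{"hybrid_calibration"} with \code{factor}
#'   (MBq per count/s) and \code{anchor_time}.
#' @export
hybrid_calibrate <- function(planar_rate_at_anchor,
                             spect_activity_at_anchor, anchor_time = NA) {
  if (!is.numeric(planar_rate_at_anchor) || planar_rate_at_anchor <= 0)
    stop("planar rate must be positive")
  if (!is.numeric(spect_activity_at_anchor) || spect_activity_at_anchor <= 0)
    stop("SPECT activity must be positive")
  structure(list(factor = spect_activity_at_anchor / planar_rate_at_anchor,
                 anchor_time = anchor_time),
            class = "hybrid_calibration")
}

#' @rdname hybrid_calibrate
#' @param calibration A \code{"hybrid_calibration"}.
#' @param planar_rate Corrected planar count rate at any time point.
#' @return \code{apply_calibration} returns activity in MBq.
#' @export
apply_calibration <- function(calibration, planar_rate) {
  stopifnot(inherits(calibration, "hybrid_calibration"))
  calibration$factor * planar_rate
}
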
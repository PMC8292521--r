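#' Attenuation map container
#'
#' Binary-fill attenuation map: voxels are either 0 (outside the body
#' contour) or \code{mu_soft} (inside), matching the uniform soft-tissue
#' body model used for attenuation compensation.
#'
#' @param mu_grid 3-D array of attenuation coefficients (cm^-1).
#' @param provenance \code{"true"} (taken from the phantom) or
#'   \code{"scatter_window_derived"}.
#' @param mu_soft The fill value used (cm^-1).
#' @return Object of class \code{"mu_map"}.
#' @export
mu_map <- function(mu_grid, provenance = c("true", "scatter_window_derived"),
                   mu_soft = 0.15) {
  provenance <- match.arg(provenance)
  vals <- unique(as.numeric(mu_grid))
  if (!all(vapply(vals, function(v)
    isTRUE(all.equal(v, 0)) || isTRUE(all.equal(v, mu_soft)), logical(1))))
    stop("mu_grid must be binary-fill: values 0 or mu_soft only")
  structure(list(mu_grid = mu_grid, provenance = provenance,
                 mu_soft = mu_soft), class = "mu_map")
}

#' True attenuation map of a phantom
#'
#' @param phantom A [make_phantom()] phantom.
#' @return A [mu_map()] with provenance \code{"true"}.
#' @export
true_mu_map <- function(phantom) {
  mu_map(phantom$mu, "true", phantom$mu_soft)
}

# convex camera-orbit envelope: in-plane voxels whose detector-frame
# y-coordinate stays inside the orbit radius at every view
.orbit_envelope <- function(n, voxel_size, geometry) {
  c0 <- (n + 1) / 2
  px <- rep((seq_len(n) - c0) * voxel_size, times = n)
  py <- rep((seq_len(n) - c0) * voxel_size, each = n)
  inside <- rep(TRUE, n * n)
  for (v in seq_len(geometry$n_views)) {
    th <- geometry$angles[v] * pi / 180
    inside <- inside & (-sin(th) * px + cos(th) * py <=
                          geometry$orbit_radius[v])
  }
  matrix(inside, n, n)
}

#' Derive an attenuation map from scatter-window projections
#'
#' Reconstructs the scatter-window data with OS-EM using an initial
#' uniform attenuation map filling the camera-orbit envelope, averages
#' the reconstruction axially over the slice range spanning the kidneys,
#' thresholds the collapsed slice to a body contour (fraction of its
#' maximum), fills interior holes, keeps the largest connected region,
#' sets the interior to \code{mu_soft} and replicates the contour axially
#' across the kidney slice range. This mirrors CT-free clinical practice,
#' where the scattered-photon image supplies the body outline.
#'
#' @param projections A \code{"projection_set"} with scatter-window data.
#' @param kidney_slice_range Integer range of axial slices spanning the
#'   kidneys.
#' @param mu_soft Soft-tissue attenuation coefficient (cm^-1).
#' @param threshold_fraction Body-contour threshold as a fraction of the
#'   collapsed slice's maximum (default 0.20).
#' @param n_iterations,n_subsets OS-EM settings for the scatter-window
#'   reconstruction (contour definition needs only a coarse image).
#' @return A [mu_map()] with provenance \code{"scatter_window_derived"}.
#' @export
attenuation_map_from_scatter_window <- function(projections,
                                                kidney_slice_range,
                                                mu_soft = 0.15,
                                                threshold_fraction = 0.20,
                                                n_iterations = 2,
                                                n_subsets = 10) {
  stopifnot(inherits(projections, "projection_set"))
  sc <- projections$counts$scatter
  if (is.null(sc) || all(sc == 0)) stop("no scatter-window data present")
  nu <- dim(sc)[1]; nv <- dim(sc)[2]
  geom <- projections$geometry
  env <- .orbit_envelope(nu, projections$voxel_size, geom)
  mu0 <- array(mu_soft * as.numeric(env), c(nu, nu, nv))
  rec <- .osem_core(sc, geom, mu0, collimator_response(0, 0),
                    projections$voxel_size, scale = 1,
                    n_iterations = n_iterations, n_subsets = n_subsets)
  sl <- apply(rec[, , kidney_slice_range, drop = FALSE], c(1, 2), mean)
  thr <- threshold_fraction * max(sl)
  bw <- sl >= thr
  if (!any(bw))
    stop(sprintf("empty body contour at threshold %.3g", thr))
  bw <- EBImage::fillHull(matrix(as.numeric(bw), nu, nu))
  lab <- EBImage::bwlabel(bw)
  keep <- as.integer(names(which.max(table(lab[lab > 0]))))
  contour <- lab == keep
  mu_grid <- array(0, c(nu, nu, nv))
  for (z in kidney_slice_range)
    mu_grid[, , z] <- mu_soft * contour
  out <- mu_map(mu_grid, "scatter_window_derived", mu_soft)
  out$contour <- contour
  out$kidney_slice_range <- kidney_slice_range
  out
}
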
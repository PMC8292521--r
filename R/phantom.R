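#' Digital two-kidney activity/attenuation phantom
#'
#' Builds a voxelised soft-tissue body (ellipsoid) containing two kidney
#' ellipsoids, with a chosen fraction of the injected activity distributed
#' uniformly over the kidney voxels and the remainder spread uniformly
#' through the rest of the body as background. The attenuation grid is the
#' uniform-body model: \code{mu_soft} inside the body contour, 0 outside.
#' Nearby organs (liver, spleen) are deliberately not modelled - their
#' uptake is treated as part of the background.
#'
#' Geometry convention: isotropic voxels; array indices \code{[x, y, z]};
#' the axial direction is z; kidneys are displaced along x by
#' \code{+/- kidney_separation / 2} and posteriorly along y by
#' \code{kidney_offset_y}.
#'
#' @param grid_shape Integer vector of 3 voxel counts; the in-plane grid
#'   must be square (\code{nx == ny}).
#' @param voxel_size Isotropic voxel size in cm.
#' @param body_axes Semi-axes (cm) of the body ellipsoid, \code{c(x, y, z)}.
#' @param kidney_axes Semi-axes (cm) of each kidney ellipsoid.
#' @param kidney_separation Centre-to-centre kidney distance along x (cm).
#' @param kidney_offset_y Posterior displacement of kidney centres (cm).
#' @param kidney_fraction_of_A0 Fraction of injected activity in the two
#'   kidneys combined, in \[0, 1\].
#' @param A0 Injected activity in MBq.
#' @param mu_soft Soft-tissue linear attenuation coefficient at 140 keV,
#'   cm^-1 (default 0.15).
#' @return Object of class \code{"digital_phantom"}: \code{activity} (MBq
#'   per voxel), \code{mu} (cm^-1), \code{voxel_size},
#'   \code{left_kidney_mask}, \code{right_kidney_mask}, \code{body_mask},
#'   \code{A0}, \code{injection_time} (0 h), \code{mu_soft}.
#' @examples
#' ph <- make_phantom(grid_shape = c(32, 32, 32), voxel_size = 1)
#' sum(ph$activity[ph$left_kidney_mask | ph$right_kidney_mask])  # 30 MBq
#' @export
make_phantom <- function(grid_shape = c(64, 64, 64), voxel_size = 0.5,
                         body_axes = c(10, 8, 12),
                         kidney_axes = c(1.8, 1.8, 3.6),
                         kidney_separation = 7, kidney_offset_y = -2,
                         kidney_fraction_of_A0 = 0.3, A0 = 100,
                         mu_soft = 0.15) {
  stopifnot(length(grid_shape) == 3, voxel_size > 0, A0 >= 0)
  if (grid_shape[1] != grid_shape[2])
    stop("in-plane grid must be square (nx == ny)")
  if (kidney_fraction_of_A0 < 0 || kidney_fraction_of_A0 > 1)
    stop("kidney_fraction_of_A0 must be in [0, 1]")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (seq_len(nx) - (nx + 1) / 2) * voxel_size
  cy <- (seq_len(ny) - (ny + 1) / 2) * voxel_size
  cz <- (seq_len(nz) - (nz + 1) / 2) * voxel_size
  X <- array(rep(cx, times = ny * nz), grid_shape)
  Y <- array(rep(rep(cy, each = nx), times = nz), grid_shape)
  Z <- array(rep(cz, each = nx * ny), grid_shape)
  inside_ellipsoid <- function(center, axes)
    ((X - center[1]) / axes[1])^2 + ((Y - center[2]) / axes[2])^2 +
    ((Z - center[3]) / axes[3])^2 <= 1
  body <- inside_ellipsoid(c(0, 0, 0), body_axes)
  kl <- inside_ellipsoid(c(-kidney_separation / 2, kidney_offset_y, 0),
                         kidney_axes)
  kr <- inside_ellipsoid(c(+kidney_separation / 2, kidney_offset_y, 0),
                         kidney_axes)
  if (!any(body)) stop("body ellipsoid does not intersect the grid")
  if (!any(kl) || !any(kr)) stop("kidney ellipsoids do not intersect the grid")
  if (any(kl & kr)) stop("kidney ellipsoids overlap")
  if (any((kl | kr) & !body))
    stop("geometry overflow: kidney voxels fall outside the body ellipsoid")
  act <- array(0, grid_shape)
  nk <- sum(kl) + sum(kr)
  if (kidney_fraction_of_A0 > 0)
    act[kl | kr] <- kidney_fraction_of_A0 * A0 / nk
  bg <- body & !(kl | kr)
  act[bg] <- (1 - kidney_fraction_of_A0) * A0 / sum(bg)
  mu <- array(0, grid_shape)
  mu[body] <- mu_soft
  structure(list(activity = act, mu = mu, voxel_size = voxel_size,
                 left_kidney_mask = kl, right_kidney_mask = kr,
                 body_mask = body, A0 = A0, injection_time = 0,
                 mu_soft = mu_soft),
            class = "digital_phantom")
}

#' @method print digital_phantom
#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Digital phantom %dx%dx%d, voxel %.2g cm\n", d[1], d[2], d[3],
              x$voxel_size))
  kf <- sum(x$activity[x$left_kidney_mask | x$right_kidney_mask]) / x$A0
  cat(sprintf("  A0 = %g MBq, kidney fraction = %.3f, mu_soft = %g cm^-1\n",
              x$A0, kf, x$mu_soft))
  invisible(x)
}

#' True kidney activity of a phantom at a given time
#'
#' Total activity in both kidney masks after physical decay to time
#' \code{t} - the simulation ground truth against which reconstructed
#' activities are compared.
#'
#' @param phantom A \code{"digital_phantom"}.
#' @param t Time post-injection (h).
#' @param T_phys Physical half-life (h).
#' @return Activity in MBq.
#' @export
phantom_kidney_activity <- function(phantom, t = 0, T_phys = 6.0) {
  k <- phantom$left_kidney_mask | phantom$right_kidney_mask
  sum(phantom$activity[k]) * decay_factor(t, T_phys)
}
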
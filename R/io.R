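# NIfTI + YAML persistence for phantoms and projection sets.
#
# Volumes are written as NIfTI with the voxel size in the header; scalar
# metadata and geometry travel in a YAML sidecar next to the volumes.
# Coordinate convention (also recorded in the sidecar): array indices
# [x, y, z], axial slices along z, view angle 0 = anterior, rotation
# counterclockwise.

.write_nifti <- function(arr, path, voxel_size) {
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# read a NIfTI volume as a plain base array (strip image attributes)
.read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a digital phantom as NIfTI volumes plus a YAML sidecar
#'
#' Writes \code{<prefix>_activity.nii.gz}, \code{<prefix>_mu.nii.gz},
#' \code{<prefix>_masks.nii.gz} (0 background, 1 body, 2 left kidney,
#' 3 right kidney) and \code{<prefix>.yaml}.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param prefix Output path prefix.
#' @return \code{read_phantom} returns a \code{"digital_phantom"}.
#' @export
write_phantom <- function(phantom, prefix) {
  v <- phantom$voxel_size
  .write_nifti(phantom$activity, paste0(prefix, "_activity.nii.gz"), v)
  .write_nifti(phantom$mu, paste0(prefix, "_mu.nii.gz"), v)
  masks <- array(0L, dim(phantom$activity))
  masks[phantom$body_mask] <- 1L
  masks[phantom$left_kidney_mask] <- 2L
  masks[phantom$right_kidney_mask] <- 3L
  .write_nifti(masks, paste0(prefix, "_masks.nii.gz"), v)
  yaml::write_yaml(list(voxel_size_cm = v, A0_MBq = phantom$A0,
                        injection_time_h = phantom$injection_time,
                        mu_soft_cm1 = phantom$mu_soft,
                        convention = "xyz voxels, z axial, view 0 anterior, CCW"),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  act <- .read_nifti_array(paste0(prefix, "_activity.nii.gz"))
  mu <- .read_nifti_array(paste0(prefix, "_mu.nii.gz"))
  masks <- .read_nifti_array(paste0(prefix, "_masks.nii.gz"))
  structure(list(activity = act, mu = mu,
                 voxel_size = meta$voxel_size_cm,
                 left_kidney_mask = masks == 2,
                 right_kidney_mask = masks == 3,
                 body_mask = masks >= 1,
                 A0 = meta$A0_MBq, injection_time = meta$injection_time_h,
                 mu_soft = meta$mu_soft_cm1),
            class = "digital_phantom")
}

#' Write / read a projection set as NIfTI stacks plus a YAML sidecar
#'
#' Photopeak and scatter count stacks are written as 3-D NIfTI volumes
#' (\code{u} x \code{v} x view); angles, orbit radii, windows, timing and
#' sensitivity go in \code{<prefix>.yaml}.
#'
#' @param projections A \code{"projection_set"}.
#' @param prefix Output path prefix.
#' @return \code{read_projections} returns a \code{"projection_set"}
#'   (without stored noise-free expectations).
#' @export
write_projections <- function(projections, prefix) {
  v <- projections$voxel_size
  .write_nifti(projections$counts$photopeak,
               paste0(prefix, "_photopeak.nii.gz"), v)
  .write_nifti(projections$counts$scatter,
               paste0(prefix, "_scatter.nii.gz"), v)
  g <- projections$geometry
  yaml::write_yaml(list(
    n_views = g$n_views, arc_deg = g$arc, angles_deg = g$angles,
    orbit_radius_cm = g$orbit_radius,
    seconds_per_view = g$seconds_per_view,
    photopeak_window_kev = g$photopeak_window,
    scatter_window_kev = g$scatter_window,
    voxel_size_cm = v,
    time_post_injection_h = projections$time_post_injection,
    sensitivity_cpm_per_mbq = projections$sensitivity_cpm_per_mbq,
    T_phys_h = projections$T_phys,
    convention = "u along rotated x, v axial, view 0 anterior, CCW"),
    paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_projections
#' @export
read_projections <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  geom <- acquisition_geometry(
    n_views = meta$n_views, arc = meta$arc_deg,
    orbit_radius = as.numeric(meta$orbit_radius_cm),
    seconds_per_view = meta$seconds_per_view,
    photopeak_window = as.numeric(meta$photopeak_window_kev),
    scatter_window = as.numeric(meta$scatter_window_kev))
  geom$angles <- as.numeric(meta$angles_deg)
  structure(list(
    counts = list(
      photopeak = .read_nifti_array(paste0(prefix, "_photopeak.nii.gz")),
      scatter = .read_nifti_array(paste0(prefix, "_scatter.nii.gz"))),
    expected = NULL, geometry = geom, voxel_size = meta$voxel_size_cm,
    time_post_injection = meta$time_post_injection_h,
    sensitivity_cpm_per_mbq = meta$sensitivity_cpm_per_mbq,
    T_phys = meta$T_phys_h, noise = NA),
    class = "projection_set")
}
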
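# Rotation-based forward/adjoint projector with attenuation and
# distance-dependent collimator response.
#
# For each view the volume is rotated so the detector sits at +y in the
# rotated frame; attenuation is accumulated voxel-by-voxel along +y with
# the half-voxel-offset convention (path from the voxel centre to the
# detector); each constant-distance plane is blurred with the Gaussian
# collimator response for its distance to the detector and accumulated
# into the projection. Every step is a fixed linear operator applied via
# (sparse) matrices, so the back projector is the exact matrix adjoint:
# transposed blur, identical attenuation weights, transposed rotation.
#
# The in-plane rotation operator is built source-driven ("splatting"):
# each source voxel distributes its full content over the four target
# neighbours with bilinear weights, so rotation conserves total activity
# exactly for sources that remain inside the grid, and projections of a
# phantom inside the field of view conserve counts when attenuation and
# blur are off. Blur kernels are column-normalised for the same reason.

.dmsapk_cache <- new.env(parent = emptyenv())

# sparse in-plane rotation operator (n^2 x n^2), rotating CCW by theta_deg
# about the grid centre; exact permutation at quarter turns
.inplane_rotation <- function(n, theta_deg) {
  key <- sprintf("rot:%d:%.6f", n, theta_deg %% 360)
  hit <- .dmsapk_cache[[key]]
  if (!is.null(hit)) return(hit)
  th <- (theta_deg %% 360) * pi / 180
  c0 <- (n + 1) / 2
  src <- seq_len(n * n)
  xs <- ((src - 1) %% n) + 1
  ys <- ((src - 1) %/% n) + 1
  dx <- xs - c0; dy <- ys - c0
  tx <- c0 + cos(th) * dx - sin(th) * dy
  ty <- c0 + sin(th) * dx + cos(th) * dy
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  tx <- snap(tx); ty <- snap(ty)
  x0 <- floor(tx); y0 <- floor(ty)
  fx <- tx - x0; fy <- ty - y0
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (corner in 1:4) {
    cxo <- c(0, 1, 0, 1)[corner]; cyo <- c(0, 0, 1, 1)[corner]
    xt <- x0 + cxo; yt <- y0 + cyo
    w <- (if (cxo == 0) 1 - fx else fx) * (if (cyo == 0) 1 - fy else fy)
    ok <- xt >= 1 & xt <= n & yt >= 1 & yt <= n & w > 0
    ii <- c(ii, xt[ok] + n * (yt[ok] - 1))
    jj <- c(jj, src[ok])
    ww <- c(ww, w[ok])
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n * n, n * n))
  .dmsapk_cache[[key]] <- M
  M
}

# dense 1-D Gaussian blur kernel matrix (n x n), columns normalised to 1;
# sigma in voxel units. sigma ~ 0 returns the identity.
.blur_kernel <- function(n, sigma_vox) {
  if (sigma_vox < 1e-4) return(NULL)   # NULL means identity
  key <- sprintf("blur:%d:%.4f", n, sigma_vox)
  hit <- .dmsapk_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma_vox^2))
  K <- sweep(K, 2, colSums(K), "/")
  .dmsapk_cache[[key]] <- K
  K
}

# upper accumulation matrix for the half-voxel attenuation convention:
# row j holds 0.5 at j and 1 at j' > j, so (T %*% mu_column) is the
# attenuating path length (in voxels) from voxel centre j to the detector
.atten_accum <- function(n) {
  key <- sprintf("accum:%d", n)
  hit <- .dmsapk_cache[[key]]
  if (!is.null(hit)) return(hit)
  T <- matrix(0, n, n)
  T[upper.tri(T)] <- 1
  diag(T) <- 0.5
  .dmsapk_cache[[key]] <- T
  T
}

# attenuation factors for a rotated mu array (detector at +y)
.atten_factors <- function(mu_rot, voxel_size) {
  dd <- dim(mu_rot)
  Tm <- .atten_accum(dd[2])
  m <- matrix(aperm(mu_rot, c(2, 1, 3)), dd[2], dd[1] * dd[3])
  pl <- Tm %*% m
  aperm(array(exp(-voxel_size * pl), c(dd[2], dd[1], dd[3])), c(2, 1, 3))
}

# Depth planes grouped by (quantised) blur width. Within a group the blur
# kernel is identical, and by linearity the planes of a group can be
# summed before blurring (forward) or blurred once and broadcast
# (adjoint), which cuts the number of kernel multiplications several-fold.
# Quantisation step: 0.1 voxel in sigma.
.view_plane_groups <- function(n_u, n_v, ny, voxel_size, radius, response) {
  yw <- (seq_len(ny) - (ny + 1) / 2) * voxel_size
  s <- round(response_sigma(response, pmax(radius - yw, 0)) / voxel_size, 1)
  lapply(split(seq_len(ny), s), function(planes) {
    sv <- s[planes[1]]
    list(planes = planes, Ku = .blur_kernel(n_u, sv), Kv = .blur_kernel(n_v, sv))
  })
}

#' Forward projection of an activity volume
#'
#' Projects an activity volume (MBq per voxel) into per-view detector
#' images of attenuated, blurred ray sums (units MBq): multiply by the
#' system sensitivity (counts/s/MBq) and the view duration to obtain
#' expected counts. Detector bins coincide with the in-plane voxel grid
#' (u along rotated x, v along z), bin size = voxel size.
#'
#' @param activity 3-D array, MBq per voxel (\code{nx == ny}).
#' @param mu 3-D attenuation array (cm^-1) of the same shape, or
#'   \code{NULL} for no attenuation.
#' @param geometry An [acquisition_geometry()] with resolved orbit radii.
#' @param response A [collimator_response()].
#' @param voxel_size Voxel size in cm.
#' @param views Optional integer subset of views to project.
#' @return Array \code{[n_u, n_v, length(views)]} of projections.
#' @export
forward_project <- function(activity, mu = NULL, geometry,
                            response = collimator_response(0, 0),
                            voxel_size, views = NULL) {
  dd <- dim(activity)
  if (dd[1] != dd[2]) stop("in-plane grid must be square")
  if (!is.null(mu) && !identical(dim(mu), dd))
    stop("activity and mu grids have mismatched shapes")
  if (is.null(geometry$orbit_radius))
    stop("geometry has no orbit radii; call resolve_geometry() first")
  if (is.null(views)) views <- seq_len(geometry$n_views)
  nx <- dd[1]; ny <- dd[2]; nz <- dd[3]
  act_mat <- matrix(activity, nx * ny, nz)
  mu_mat <- if (!is.null(mu)) matrix(mu, nx * ny, nz)
  out <- array(0, c(nx, nz, length(views)))
  for (k in seq_along(views)) {
    v <- views[k]
    R <- .inplane_rotation(nx, -geometry$angles[v])
    a_arr <- array(as.matrix(R %*% act_mat), c(nx, ny, nz))
    if (!is.null(mu)) {
      m_arr <- array(as.matrix(R %*% mu_mat), c(nx, ny, nz))
      a_arr <- a_arr * .atten_factors(m_arr, voxel_size)
    }
    groups <- .view_plane_groups(nx, nz, ny, voxel_size,
                                 geometry$orbit_radius[v], response)
    proj <- matrix(0, nx, nz)
    for (grp in groups) {
      W <- if (length(grp$planes) == 1) a_arr[, grp$planes, ]
           else colSums(aperm(a_arr[, grp$planes, , drop = FALSE], c(2, 1, 3)))
      dim(W) <- c(nx, nz)
      if (!is.null(grp$Ku)) W <- grp$Ku %*% W
      if (!is.null(grp$Kv)) W <- W %*% t(grp$Kv)
      proj <- proj + W
    }
    out[, , k] <- proj
  }
  out
}

#' Back projection (exact adjoint of the forward projector)
#'
#' Applies the transpose of every linear step of [forward_project()]
#' (transposed blur kernels, identical attenuation weights, transposed
#' rotation), so the inner-product identity
#' \code{sum(P(x) * y) == sum(x * Pt(y))} holds to machine precision.
#'
#' @param projections Array \code{[n_u, n_v, length(views)]}.
#' @inheritParams forward_project
#' @return 3-D volume array.
#' @export
back_project <- function(projections, mu = NULL, geometry,
                         response = collimator_response(0, 0),
                         voxel_size, views = NULL) {
  if (is.null(views)) views <- seq_len(geometry$n_views)
  nu <- dim(projections)[1]; nv <- dim(projections)[2]
  nx <- nu; ny <- nu; nz <- nv
  if (!is.null(mu) && !identical(dim(mu), c(nx, ny, nz)))
    stop("mu grid shape inconsistent with projections")
  mu_mat <- if (!is.null(mu)) matrix(mu, nx * ny, nz)
  acc <- matrix(0, nx * ny, nz)
  for (k in seq_along(views)) {
    v <- views[k]
    R <- .inplane_rotation(nx, -geometry$angles[v])
    att <- if (!is.null(mu)) {
      m_arr <- array(as.matrix(R %*% mu_mat), c(nx, ny, nz))
      .atten_factors(m_arr, voxel_size)
    }
    groups <- .view_plane_groups(nx, nz, ny, voxel_size,
                                 geometry$orbit_radius[v], response)
    P <- projections[, , k]
    vol_rot <- array(0, c(nx, ny, nz))
    for (grp in groups) {
      W <- P
      if (!is.null(grp$Ku)) W <- t(grp$Ku) %*% W
      if (!is.null(grp$Kv)) W <- W %*% grp$Kv
      for (j in grp$planes) vol_rot[, j, ] <- W
    }
    if (!is.null(att)) vol_rot <- vol_rot * att
    acc <- acc + as.matrix(Matrix::crossprod(R, matrix(vol_rot, nx * ny, nz)))
  }
  array(acc, c(nx, ny, nz))
}
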
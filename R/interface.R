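# Sub-voxel interface reconstruction shared by the Laplace solver and the
# surface extractor.
#
# A binary segmentation locates a smooth anatomical interface only to within
# half a voxel; on axis-aligned stretches the voxel faces are systematically
# offset from the true surface by up to spacing/2. We recover sub-voxel
# position by fitting, at every boundary voxel, a moving-least-squares
# quadric patch through the midpoints of nearby label-change faces. The
# transverse window must span several staircase runs of the rasterization
# (runs have half-length ~ sqrt(2 * R * h) for surface curvature radius R),
# hence the fairly wide default of 6 mm.

#' @noRd
interface_reconstruct <- function(inside_mask, outside_mask, spacing, origin,
                                  sigma_t = 8 * max(spacing),
                                  sigma_n = 2.5 * max(spacing)) {
  d <- dim(inside_mask)
  cloud <- cpp_face_cloud(as.vector(inside_mask), as.vector(outside_mask),
                          as.integer(d), spacing, origin)
  centers_mask <- inside_mask & neighbor_any(outside_mask)
  center_idx <- which(centers_mask)
  if (length(center_idx) == 0L || nrow(cloud) == 0L) {
    return(list(ok = FALSE))
  }
  centers <- voxel_coords(center_idx, d, spacing, origin)

  # outward normals from the signed distance of the outside region
  phi <- signed_distance(outside_mask, spacing)  # negative inside 'outside'
  grad <- array_gradient(phi, spacing)
  normals <- -cbind(grad$x[center_idx], grad$y[center_idx], grad$z[center_idx])
  fit <- cpp_quadric_fit(cloud, centers, normals, sigma_t, sigma_n)

  center_grid <- integer(prod(d))
  center_grid[center_idx] <- seq_along(center_idx)

  list(ok = TRUE, fit = fit, centers = centers, normals = normals,
       center_idx = center_idx, center_grid = center_grid,
       dim = d, spacing = spacing, origin = origin)
}

# Crossing fraction theta in (0, 1] of the reconstructed interface along
# axis arms. `arm_center_idx`: linear voxel index of the inside (wall-side)
# voxel; `axis` 1:3; `dir` +1/-1.
#' @noRd
interface_theta <- function(rec, arm_center_idx, axis, dir,
                            min_theta = 0.05) {
  n <- length(arm_center_idx)
  if (!rec$ok || n == 0L) return(rep(0.5, n))
  fi <- rec$center_grid[arm_center_idx]
  stopifnot(all(fi > 0L))
  dmat <- matrix(0, n, 3)
  dmat[cbind(seq_len(n), axis)] <- dir
  len <- rep(rec$spacing[axis], n)
  cpp_arm_theta(rec$centers, rec$normals, rec$fit, fi, dmat, len, min_theta)
}

# Signed offsets (mm) from the reconstructed interface at given voxels
# (positive beyond the interface, on the outside). NA where no fit applies.
#' @noRd
interface_phi_at <- function(rec, voxel_idx, window = 3L) {
  cpp_band_phi(rec$center_grid, as.integer(rec$dim), rec$spacing, rec$origin,
               as.integer(voxel_idx), rec$centers, rec$normals, rec$fit,
               as.integer(window))
}

# Physical coordinates (mm) of linear voxel indices.
#' @noRd
voxel_coords <- function(idx, d, spacing, origin) {
  idx0 <- idx - 1L
  ix <- idx0 %% d[1]
  iy <- (idx0 %/% d[1]) %% d[2]
  iz <- idx0 %/% (d[1] * d[2])
  cbind(origin[1] + ix * spacing[1],
        origin[2] + iy * spacing[2],
        origin[3] + iz * spacing[3])
}

# Central-difference gradient with replicated edges, per-axis spacing.
#' @noRd
array_gradient <- function(a, spacing) {
  d <- dim(a)
  pad <- function(axis, shift) {
    # index vectors shifted by +-1 with edge replication
    i <- pmin(pmax(seq_len(d[axis]) + shift, 1L), d[axis])
    i
  }
  gx <- (a[pad(1, 1), , , drop = FALSE] - a[pad(1, -1), , , drop = FALSE]) /
    (2 * spacing[1])
  gy <- (a[, pad(2, 1), , drop = FALSE] - a[, pad(2, -1), , drop = FALSE]) /
    (2 * spacing[2])
  gz <- (a[, , pad(3, 1), drop = FALSE] - a[, , pad(3, -1), drop = FALSE]) /
    (2 * spacing[3])
  # halve one-sided differences at the edges (replication doubles the step)
  gx[1, , ] <- gx[1, , ] * 2; gx[d[1], , ] <- gx[d[1], , ] * 2
  gy[, 1, ] <- gy[, 1, ] * 2; gy[, d[2], ] <- gy[, d[2], ] * 2
  gz[, , 1] <- gz[, , 1] * 2; gz[, , d[3]] <- gz[, , d[3]] * 2
  list(x = gx, y = gy, z = gz)
}
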
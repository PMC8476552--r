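# Through-plane resampling: thick-slice downsampling (emulating 2D
# acquisitions) and shape-based upsampling of anisotropic segmentations back
# to isotropic resolution. In-plane resolution is never altered.

#' Resampling parameters
#'
#' @param fraction scar occupancy fraction (relative to wall occupancy)
#'   above which a downsampled wall voxel is labelled scar; in (0, 1].
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(fraction = 0.5) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  structure(list(fraction = fraction), class = "resample_spec")
}

#' Downsample a volume through-plane
#'
#' Partitions the through-plane extent into slabs of the target thickness
#' (slab k covers physical range `[k*T, (k+1)*T)` from the volume start;
#' thin slices contribute by their center position). Image intensities
#' become the slab mean. Labels are assigned by occupancy: the slab fraction
#' of background, blood and wall (myocardium + scar) compete and the largest
#' wins (ties resolved wall > blood > background); a winning wall voxel is
#' labelled scar when the scar fraction within the wall occupancy reaches
#' `spec$fraction`.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param target_thickness new through-plane spacing (mm), at least the
#'   current one.
#' @param spec a [resample_spec()].
#' @return A volume of the same type.
#' @export
downsample_throughplane <- function(vol, target_thickness,
                                    spec = resample_spec()) {
  stopifnot(inherits(vol, "volume"))
  dz <- vol$spacing[3]
  if (!is.finite(target_thickness) || target_thickness < dz - 1e-9)
    stop("target thickness (", target_thickness,
         " mm) must be at least the current through-plane spacing (",
         dz, " mm)")
  if (abs(target_thickness - dz) < 1e-9) return(vol)
  d <- dim(vol$data)
  zc <- axis_coords(vol, 3)
  start <- zc[1] - dz / 2
  slab <- floor((zc - start) / target_thickness)
  slab <- pmin(slab, max(slab))  # guard the last center against rounding
  nslab <- max(slab) + 1L
  new_z <- start + (seq_len(nslab) - 0.5) * target_thickness
  newdim <- c(d[1], d[2], nslab)
  spacing <- c(vol$spacing[1:2], target_thickness)
  origin <- c(vol$origin[1:2], new_z[1])

  if (inherits(vol, "label_volume")) {
    counts <- function(code) {
      m <- vol$data == code
      out <- array(0, newdim)
      for (k in seq_len(nslab)) {
        sel <- which(slab == k - 1L)
        out[, , k] <- rowSums(array(m[, , sel, drop = FALSE],
                                    c(d[1] * d[2], length(sel))))
      }
      out
    }
    n_bg <- counts(0L); n_bl <- counts(1L)
    n_my <- counts(2L); n_sc <- counts(3L)
    n_wall <- n_my + n_sc
    # winner among background / blood / wall, ties to the later (wall)
    lab <- array(0L, newdim)
    lab[n_bl >= n_bg & n_bl > n_wall] <- 1L
    lab[n_wall >= n_bg & n_wall >= n_bl & n_wall > 0] <- 2L
    scar_sel <- lab == 2L & n_sc >= spec$fraction * n_wall & n_sc > 0
    lab[scar_sel] <- 3L
    label_volume(lab, spacing, origin)
  } else {
    out <- array(0, newdim)
    for (k in seq_len(nslab)) {
      sel <- which(slab == k - 1L)
      out[, , k] <- rowMeans(array(vol$data[, , sel, drop = FALSE],
                                   c(d[1] * d[2], length(sel))))
    }
    image_volume(out, spacing, origin)
  }
}

#' Upsample a thick-slice segmentation to isotropic resolution
#'
#' Shape-based (topology-friendly) interpolation: each label's binary mask
#' is converted to a per-slice in-plane signed distance map (mm), distances
#' are interpolated linearly along the through-plane axis to the target
#' spacing, and each output voxel takes the label of the most interior
#' (most negative) interpolated distance, with background where all
#' distances are non-negative. The scar-within-wall nesting is enforced by
#' interpolating the wall (myocardium + scar) and the scar hierarchically.
#' The output grid covers the full physical slab extent (interpolation is
#' clamped beyond the outermost slice centers).
#'
#' @param seg a [label_volume()] thick-slice stack (at least 2 slices).
#' @param target_spacing new through-plane spacing (mm), smaller than the
#'   current one (equal returns the input).
#' @return A [label_volume()] with through-plane spacing `target_spacing`.
#' @export
upsample_topologic <- function(seg, target_spacing) {
  stopifnot(inherits(seg, "label_volume"))
  dz <- seg$spacing[3]
  if (abs(target_spacing - dz) < 1e-9) return(seg)
  if (target_spacing > dz)
    stop("target spacing must not exceed the current through-plane spacing")
  d <- dim(seg$data)
  if (d[3] < 2L) stop("upsampling requires at least 2 slices")
  if (!any(seg$data != 0L)) stop("empty segmentation")

  masks <- list(blood = seg$data == 1L,
                wall = seg$data >= 2L,
                scar = seg$data == 3L)
  sd_stack <- lapply(masks, slice_signed_distance, spacing = seg$spacing)

  zc <- axis_coords(seg, 3)
  t <- target_spacing
  z_start <- zc[1] - (dz - t) / 2
  z_end <- zc[d[3]] + (dz - t) / 2
  nz_new <- floor((z_end - z_start) / t + 1e-9) + 1L
  z_new <- z_start + (seq_len(nz_new) - 1L) * t

  # clamped linear interpolation weights along z
  pos <- (z_new - zc[1]) / dz
  k0 <- pmin(pmax(floor(pos), 0), d[3] - 2L)
  w1 <- pmin(pmax(pos - k0, 0), 1)
  interp <- function(stack) {
    out <- array(0, c(d[1], d[2], nz_new))
    for (j in seq_len(nz_new)) {
      out[, , j] <- (1 - w1[j]) * stack[, , k0[j] + 1L] +
        w1[j] * stack[, , k0[j] + 2L]
    }
    out
  }
  phi_bl <- interp(sd_stack$blood)
  phi_wa <- interp(sd_stack$wall)
  phi_sc <- interp(sd_stack$scar)

  lab <- array(0L, c(d[1], d[2], nz_new))
  wall_win <- phi_wa < 0 & phi_wa <= phi_bl
  blood_win <- phi_bl < 0 & !wall_win
  lab[blood_win] <- 1L
  lab[wall_win] <- 2L
  lab[wall_win & phi_sc < 0] <- 3L
  label_volume(lab, c(seg$spacing[1:2], t),
               c(seg$origin[1:2], z_new[1]))
}

# Per-slice in-plane signed distance (mm): negative inside the mask.
# Empty and full slices get a constant +/- cap so interpolation stays
# well behaved where a structure appears or vanishes between slices.
slice_signed_distance <- function(mask, spacing) {
  d <- dim(mask)
  cap <- sqrt(sum((d[1:2] * spacing[1:2])^2))
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    m <- mask[, , k]
    n_in <- sum(m)
    if (n_in == 0L) {
      out[, , k] <- cap
    } else if (n_in == length(m)) {
      out[, , k] <- -cap
    } else {
      m3 <- array(m, c(d[1], d[2], 1L))
      din <- cpp_edt(as.vector(m3), c(d[1], d[2], 1L),
                     c(spacing[1:2], 1))
      dout <- cpp_edt(as.vector(!m3), c(d[1], d[2], 1L),
                      c(spacing[1:2], 1))
      out[, , k] <- matrix(din - dout, d[1], d[2])
    }
  }
  out
}

#' Correct in-plane acquisition shifts of a thick-slice stack
#'
#' Each slice is rigidly translated in-plane by an integer number of voxels.
#' With a reference epicardial mesh (for example extracted from a 3D
#' acquisition of the same anatomy), each slice's epicardial contour
#' centroid is moved onto the centroid of the mesh section at that slice
#' position. Without a reference, successive slices are aligned by
#' wall-centroid continuity (the first slice is left in place, so a common
#' shift of all slices is not corrected: only relative alignment is
#' defined). Slices with no wall are passed through unshifted with a
#' message.
#'
#' @param seg2d a [label_volume()] thick-slice stack.
#' @param reference optional [surface_mesh()] of the epicardium.
#' @return The shifted [label_volume()]; the applied per-slice shifts (in
#'   voxels) are attached as attribute `"shifts"`.
#' @export
correct_slice_shifts <- function(seg2d, reference = NULL) {
  stopifnot(inherits(seg2d, "label_volume"))
  d <- dim(seg2d$data)
  zc <- axis_coords(seg2d, 3)
  xc <- axis_coords(seg2d, 1)
  yc <- axis_coords(seg2d, 2)
  out <- seg2d$data
  shifts <- matrix(0L, d[3], 2)

  epi_centroid <- function(slice) {
    # centroid of wall voxels that touch background within the slice
    wall <- slice >= 2L
    if (!any(wall)) return(c(NA_real_, NA_real_))
    bg <- slice == 0L
    nb <- matrix(FALSE, d[1], d[2])
    nb[-d[1], ] <- nb[-d[1], ] | bg[-1, ]
    nb[-1, ] <- nb[-1, ] | bg[-d[1], ]
    nb[, -d[2]] <- nb[, -d[2]] | bg[, -1]
    nb[, -1] <- nb[, -1] | bg[, -d[2]]
    ring <- wall & nb
    if (!any(ring)) ring <- wall
    ij <- which(ring, arr.ind = TRUE)
    c(mean(xc[ij[, 1]]), mean(yc[ij[, 2]]))
  }
  wall_centroid <- function(slice) {
    wall <- slice >= 2L
    if (!any(wall)) return(c(NA_real_, NA_real_))
    ij <- which(wall, arr.ind = TRUE)
    c(mean(xc[ij[, 1]]), mean(yc[ij[, 2]]))
  }
  shift_slice <- function(slice, sh) {
    if (all(sh == 0L)) return(slice)
    new <- matrix(0L, d[1], d[2])
    src_i <- seq_len(d[1]) - sh[1]
    src_j <- seq_len(d[2]) - sh[2]
    ok_i <- src_i >= 1L & src_i <= d[1]
    ok_j <- src_j >= 1L & src_j <= d[2]
    new[ok_i, ok_j] <- slice[src_i[ok_i], src_j[ok_j]]
    new
  }

  prev_cent <- NULL
  for (k in seq_len(d[3])) {
    slice <- out[, , k]
    if (!any(slice >= 2L)) {
      message("slice ", k, " has no wall; passed through unshifted")
      next
    }
    if (!is.null(reference)) {
      target <- mesh_section_centroid(reference, zc[k])
      if (any(is.na(target))) next
      cur <- epi_centroid(slice)
      sh <- round((target - cur) / seg2d$spacing[1:2])
    } else {
      cur <- wall_centroid(slice)
      if (is.null(prev_cent)) {
        prev_cent <- cur
        next
      }
      sh <- round((prev_cent - cur) / seg2d$spacing[1:2])
    }
    sh <- as.integer(sh)
    out[, , k] <- shift_slice(slice, sh)
    shifts[k, ] <- sh
    if (is.null(reference))
      prev_cent <- wall_centroid(out[, , k])
  }
  res <- label_volume(out, seg2d$spacing, seg2d$origin)
  attr(res, "shifts") <- shifts
  res
}
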
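# Full-width-half-maximum scar segmentation inside the myocardial wall.
#
# The reference maximum signal intensity is computed after through-plane
# slab averaging (~8 mm window) so that high-resolution isotropic
# acquisitions are not penalized by single-voxel noise relative to
# thick-slice 2D acquisitions; raw voxel intensities are then thresholded
# at fixed fractions of that maximum (0.45 scar, 0.67 dense core).

#' Scar signal-intensity criteria
#'
#' @param cutoff primary scar cutoff as a fraction of the maximum signal
#'   intensity (default 0.45).
#' @param dense_cutoff dense-core cutoff (default 0.67); intensities in
#'   `[cutoff, dense_cutoff)` of the maximum are heterogeneous (border
#'   zone) scar.
#' @param slab_mm through-plane extent (mm) of the averaging window used
#'   for the maximum (default 8).
#' @param slab_voxels optional explicit through-plane window size in
#'   voxels, overriding `slab_mm` (e.g. 12 neighbours at 0.75 mm
#'   reconstruction).
#' @return An object of class `scar_criteria`.
#' @export
scar_criteria <- function(cutoff = 0.45, dense_cutoff = 0.67, slab_mm = 8,
                          slab_voxels = NULL) {
  if (!(cutoff > 0 && cutoff < dense_cutoff && dense_cutoff <= 1))
    stop("need 0 < cutoff < dense_cutoff <= 1")
  if (!is.finite(slab_mm) || slab_mm <= 0)
    stop("slab_mm must be positive")
  structure(list(cutoff = cutoff, dense_cutoff = dense_cutoff,
                 slab_mm = slab_mm, slab_voxels = slab_voxels),
            class = "scar_criteria")
}

#' Slab-averaged maximum signal intensity over the wall
#'
#' Replaces each wall voxel's intensity by the mean over a through-plane
#' window of the criteria's slab extent (truncated at the volume edges,
#' so apical/basal slabs average over the available voxels only) and
#' returns the maximum of the averaged values over the wall mask.
#'
#' @param img an [image_volume()].
#' @param wall logical array (wall mask) on the image grid, or a
#'   [label_volume()] from which the wall (labels 2, 3) is taken.
#' @param criteria a [scar_criteria()].
#' @return The maximum slab-averaged signal intensity (scalar).
#' @export
slab_averaged_max <- function(img, wall, criteria = scar_criteria()) {
  stopifnot(inherits(img, "image_volume"))
  if (inherits(wall, "label_volume")) {
    stopifnot_same_grid(img, wall)
    wall <- wall_mask(wall)
  }
  if (!any(wall)) stop("empty wall mask")
  k <- slab_window_voxels(criteria, img$spacing[3])
  avg <- running_mean_z(img$data, k)
  max(avg[wall])
}

slab_window_voxels <- function(criteria, dz) {
  if (!is.null(criteria$slab_voxels)) return(max(1L, as.integer(criteria$slab_voxels)))
  if (criteria$slab_mm < dz) return(1L)
  max(1L, round(criteria$slab_mm / dz))
}

# Truncated running mean along axis 3 with window of k voxels
# (centered; k even uses floor(k/2) below, k - 1 - floor(k/2) above... the
# window spans voxel i + [-floor((k-1)/2), ceiling((k-1)/2)]).
running_mean_z <- function(a, k) {
  if (k <= 1L) return(a)
  d <- dim(a)
  lo <- floor((k - 1) / 2)
  hi <- k - 1L - lo
  # cumulative sums along z with a leading zero slab
  cs <- array(0, c(d[1], d[2], d[3] + 1L))
  cs[, , -1] <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  i <- seq_len(d[3])
  from <- pmax(i - lo, 1L)
  to <- pmin(i + hi, d[3])
  out <- array(0, d)
  for (z in i) {
    out[, , z] <- (cs[, , to[z] + 1L] - cs[, , from[z]]) /
      (to[z] - from[z] + 1L)
  }
  out
}

#' Segment scar by the FWHM criterion
#'
#' Wall voxels whose raw intensity reaches `cutoff` times the slab-averaged
#' maximum become scar (label 3); remaining wall stays myocardium (label 2);
#' other labels are untouched. The double criterion additionally splits the
#' scar into heterogeneous (`[cutoff, dense_cutoff)` of the maximum) and
#' dense (`>= dense_cutoff`) components, returned as logical masks.
#'
#' @param img an [image_volume()].
#' @param seg a [label_volume()] on the same grid (its wall defines where
#'   scar may occur; pre-existing scar labels count as wall).
#' @param criteria a [scar_criteria()].
#' @return A list of class `scar_segmentation`: `seg` (relabelled
#'   [label_volume()]), `dense` and `heterogeneous` (logical masks),
#'   `max_si`, `threshold`, `dense_threshold`.
#' @export
segment_scar <- function(img, seg, criteria = scar_criteria()) {
  stopifnot(inherits(img, "image_volume"), inherits(seg, "label_volume"))
  stopifnot_same_grid(img, seg)
  wall <- wall_mask(seg)
  max_si <- slab_averaged_max(img, wall, criteria)
  thr <- criteria$cutoff * max_si
  thr_dense <- criteria$dense_cutoff * max_si
  scar <- wall & img$data >= thr
  dense <- wall & img$data >= thr_dense
  lab <- seg$data
  lab[wall] <- 2L
  lab[scar] <- 3L
  structure(list(
    seg = label_volume(lab, seg$spacing, seg$origin),
    dense = dense,
    heterogeneous = scar & !dense,
    max_si = max_si, threshold = thr, dense_threshold = thr_dense,
    criteria = criteria
  ), class = "scar_segmentation")
}

#' @export
print.scar_segmentation <- function(x, ...) {
  v <- scar_volumes(x$seg, x$dense)
  cat(sprintf(
    "<scar_segmentation> max SI %.4g; thresholds %.4g / %.4g\n",
    x$max_si, x$threshold, x$dense_threshold))
  print(v)
  invisible(x)
}

#' Scar and wall volumes (cm^3)
#'
#' @param seg a [label_volume()] containing scar labels.
#' @param dense_mask optional logical mask of dense scar (subset of scar);
#'   when omitted all scar counts as heterogeneous.
#' @return An object of class `scar_volumes`: total, heterogeneous, dense,
#'   wall and healthy myocardial volumes in cm^3 (total = heterogeneous +
#'   dense; wall = healthy + total).
#' @export
scar_volumes <- function(seg, dense_mask = NULL) {
  stopifnot(inherits(seg, "label_volume"))
  vv <- voxel_volume_mm3(seg) / 1000  # cm^3 per voxel
  scar <- seg$data == 3L
  wall <- wall_mask(seg)
  n_dense <- if (is.null(dense_mask)) 0L else sum(dense_mask & scar)
  total <- sum(scar) * vv
  dense <- n_dense * vv
  structure(list(
    total = total,
    heterogeneous = total - dense,
    dense = dense,
    wall = sum(wall) * vv,
    healthy = (sum(wall) - sum(scar)) * vv
  ), class = "scar_volumes")
}

#' @export
print.scar_volumes <- function(x, ...) {
  cat(sprintf(
    paste0("  wall %.2f cm^3 = healthy %.2f + scar %.2f",
           " (heterogeneous %.2f + dense %.2f)\n"),
    x$wall, x$healthy, x$total, x$heterogeneous, x$dense))
  invisible(x)
}
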
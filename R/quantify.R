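# Scar quantification on the transmurality map: areas below transmurality
# thresholds and scar volume by wall-depth layer.

#' Epicardial scar area below transmurality thresholds
#'
#' For each threshold tau, sums the areas of epicardial triangles whose
#' vertices majority-satisfy "scar present (TsM > 0) and TsM < tau".
#' Requiring scar presence keeps scar-free regions out of the areas (a
#' region with TsM = 0 is not a scar area however small its transmurality);
#' set `require_scar = FALSE` for the pure sub-threshold area. Triangles
#' with any invalid vertex are excluded.
#'
#' @param map a [transmurality_map()].
#' @param epi_mesh the epicardial [surface_mesh()] the map was computed on.
#' @param thresholds transmurality thresholds (default 0.1, 0.2, ..., 1.0).
#' @param require_scar logical; require TsM > 0 (default `TRUE`).
#' @return A data.frame with columns `threshold` and `area_cm2`
#'   (monotone non-decreasing in the threshold).
#' @export
scar_area_at_thresholds <- function(map, epi_mesh,
                                    thresholds = seq(0.1, 1, by = 0.1),
                                    require_scar = TRUE) {
  stopifnot(inherits(map, "transmurality_map"),
            inherits(epi_mesh, "surface_mesh"))
  if (length(thresholds) == 0L)
    stop("empty threshold list")
  if (nrow(epi_mesh$vertices) != nrow(map))
    stop("map and mesh do not share vertices")
  f <- epi_mesh$faces
  areas <- triangle_areas(epi_mesh)
  v_ok <- map$valid
  t_ok <- v_ok[f[, 1]] & v_ok[f[, 2]] & v_ok[f[, 3]]
  tsm <- map$tsm
  out <- vapply(thresholds, function(tau) {
    cond <- tsm < tau
    if (require_scar) cond <- cond & tsm > 0
    nsat <- (cond[f[, 1]] + cond[f[, 2]] + cond[f[, 3]])
    sum(areas[t_ok & nsat >= 2]) / 100
  }, numeric(1))
  data.frame(threshold = thresholds, area_cm2 = out)
}

#' Scar volume by wall-depth layer
#'
#' Assigns every scar voxel to a wall-depth bin by its potential value.
#' Default boundaries 0.33, 0.67 and 0.97 of the wall depth give an
#' endocardial, midwall, epicardial and subepicardial-rim layer; bin
#' volumes sum exactly to the total scar volume.
#'
#' @param seg a [label_volume()] containing scar (label 3).
#' @param field the [solve_laplace()] potential on the same grid.
#' @param boundaries increasing depth boundaries in (0, 1).
#' @param scar_mask optional logical mask restricting which scar voxels are
#'   counted (e.g. scar within a low-transmurality region).
#' @return A data.frame of class `layer_partition` with columns `layer`,
#'   `from`, `to`, `volume_cm3`, `fraction`.
#' @export
layer_partition <- function(seg, field, boundaries = c(0.33, 0.67, 0.97),
                            scar_mask = NULL) {
  stopifnot(inherits(seg, "label_volume"),
            inherits(field, "potential_field"))
  scar <- seg$data == 3L
  if (!is.null(scar_mask)) scar <- scar & scar_mask
  sv <- field$s[scar]
  if (any(is.na(sv)))
    stop("scar voxel outside the solved wall (field does not cover scar)")
  brks <- c(0, boundaries, 1 + 1e-9)
  layer_names <- c("endocardial", "midwall", "epicardial", "rim")
  if (length(boundaries) != 3L)
    layer_names <- paste0("layer", seq_len(length(brks) - 1L))
  bin <- findInterval(sv, brks, rightmost.closed = TRUE)
  vv <- voxel_volume_mm3(seg) / 1000
  counts <- tabulate(bin, nbins = length(brks) - 1L)
  vols <- counts * vv
  total <- sum(vols)
  res <- data.frame(
    layer = layer_names,
    from = brks[-length(brks)],
    to = pmin(brks[-1], 1),
    volume_cm3 = vols,
    fraction = if (total > 0) vols / total else rep(0, length(vols))
  )
  class(res) <- c("layer_partition", "data.frame")
  res
}
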
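# Boundary classification of the myocardial wall: where the Dirichlet
# conditions of the wall-depth potential attach.

#' Classify wall boundary voxels
#'
#' Partitions the boundary of the myocardial wall (labels 2 and 3) into the
#' endocardial set (face-adjacent to blood pool), the epicardial set
#' (face-adjacent to background) and the basal-cut set (wall voxels on the
#' topmost occupied through-plane slice that touch neither). Voxels adjacent
#' to both blood and background are classified endocardial (precedence
#' endo > epi), which keeps the zero-potential surface connected in
#' single-voxel-thick walls; a message reports how many such voxels occur.
#'
#' @param seg a [label_volume()].
#' @return An object of class `boundary_classification` with integer linear
#'   voxel indices `endo_voxels`, `epi_voxels`, `cut_voxels`, and logical
#'   arrays `endo`, `epi`, `cut` on the segmentation grid.
#' @export
classify_boundaries <- function(seg) {
  stopifnot(inherits(seg, "label_volume"))
  wall <- wall_mask(seg)
  if (!any(wall))
    stop("empty wall: no voxels with label 2 or 3")
  blood <- seg$data == 1L
  bg <- seg$data == 0L

  near_blood <- neighbor_any(blood)
  near_bg <- neighbor_any(bg)
  endo <- wall & near_blood
  epi <- wall & near_bg & !endo
  if (!any(endo))
    stop("no endocardial boundary: wall has no face adjacency to blood pool")
  if (!any(epi))
    stop("no epicardial boundary: wall has no face adjacency to background")
  both <- sum(wall & near_blood & near_bg)
  if (both > 0)
    message(both, " wall voxel(s) adjacent to both blood and background; ",
            "classified endocardial (precedence endo > epi)")

  d <- dim(seg$data)
  occupied <- apply(wall, 3, any)
  top <- max(which(occupied))
  cut <- array(FALSE, d)
  cut[, , top] <- wall[, , top] & !endo[, , top] & !epi[, , top]

  structure(list(
    endo_voxels = which(endo),
    epi_voxels = which(epi),
    cut_voxels = which(cut),
    endo = endo, epi = epi, cut = cut,
    dim = d
  ), class = "boundary_classification")
}

#' @export
print.boundary_classification <- function(x, ...) {
  cat(sprintf(
    "<boundary_classification> endo: %d, epi: %d, basal cut: %d voxels\n",
    length(x$endo_voxels), length(x$epi_voxels), length(x$cut_voxels)))
  invisible(x)
}
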
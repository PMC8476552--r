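# Domain containers: scalar image volumes and categorical label volumes on a
# regular anisotropic grid. Convention: array axis 3 is the through-plane
# (long-axis) direction; voxel centers sit at origin + (index - 1) * spacing,
# all physical quantities in millimetres.

LABEL_CODES <- c(background = 0L, blood = 1L, myocardium = 2L, scar = 3L)

#' Construct a scalar image volume
#'
#' @param data 3D numeric array of signal intensities (arbitrary units).
#' @param spacing numeric length-3, voxel size in mm per axis (positive).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (any(!is.finite(data)))
    stop("image data must be finite (no NA/NaN/Inf)")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = c("image_volume", "volume"))
}

#' Construct a categorical label volume
#'
#' Label codes: 0 background, 1 blood pool, 2 myocardium, 3 scar. Scar voxels
#' are part of the wall: geometric operations treat wall = labels in \{2, 3\}.
#'
#' @param labels 3D integer array with values in \{0, 1, 2, 3\}.
#' @param spacing,origin see [image_volume()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (any(dim(labels) < 2L))
    stop("volume must have at least 2 voxels per axis")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), LABEL_CODES)
  if (length(bad))
    stop("invalid label code(s): ", paste(bad, collapse = ", "),
         " (allowed: 0 background, 1 blood, 2 myocardium, 3 scar)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  structure(list(data = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = c("label_volume", "volume"))
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "label_volume")) {
    tb <- table(factor(x$data, levels = LABEL_CODES,
                       labels = names(LABEL_CODES)))
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

vol_dim <- function(vol) dim(vol$data)

voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' Physical coordinates of voxel centers along one axis
#' @noRd
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("volumes are not on the same grid (dim/spacing/origin mismatch)")
}

wall_mask <- function(seg) seg$data == 2L | seg$data == 3L

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file. Spacing is taken from the header (mm);
#' data are kept in stored voxel order, with array axis 3 interpreted as the
#' through-plane direction (inputs are assumed short-axis aligned). Label
#' volumes are checked to contain only the codes \{0, 1, 2, 3\} and are
#' preserved exactly.
#'
#' @param path file path to a NIfTI-1 volume.
#' @param kind `"image"` for scalar intensities, `"label"` for segmentations.
#' @return An [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, kind = c("image", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(as.numeric(pd[1:3]))
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error")) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1, drop = TRUE]
  dim3 <- dim(arr)
  arr <- array(as.vector(arr), dim = dim3)
  if (kind == "label") {
    v <- as.vector(arr)
    if (any(v != round(v)))
      stop("label file contains non-integer values: ", path)
    label_volume(array(as.integer(round(v)), dim3), spacing, origin)
  } else {
    image_volume(arr, spacing, origin)
  }
}

#' Write a volume to NIfTI-1
#'
#' Label volumes are written as 16-bit integers so codes round-trip exactly;
#' image volumes as 32-bit float.
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  dt <- if (inherits(vol, "label_volume")) "int16" else "float"
  affine <- diag(c(vol$spacing, 1))
  affine[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write the label-scheme JSON sidecar
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_label_scheme <- function(path) {
  jsonlite::write_json(as.list(LABEL_CODES), path, auto_unbox = TRUE)
  invisible(path)
}

# Linear-index neighbour shifts for 6-connectivity on dims d.
# Returns a list per axis with strides and index bound helpers.
grid_strides <- function(d) c(1L, d[1], d[1] * d[2])

# Logical array of voxels having at least one face neighbour in `mask`.
neighbor_any <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[-1, , ]    <- out[-1, , ]    | mask[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, -1, ]    <- out[, -1, ]    | mask[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out[, , -1]    <- out[, , -1]    | mask[, , -d[3]]
  out
}

# Connected components (6-connectivity) of a logical array, frontier BFS.
# Returns integer array (0 outside mask).
conn_comp <- function(mask) {
  d <- dim(mask)
  strides <- grid_strides(d)
  n <- prod(d)
  comp <- integer(n)
  maskv <- as.vector(mask)
  remaining <- which(maskv)
  lab <- 0L
  # index coordinates for boundary tests
  ix <- ((seq_len(n) - 1L) %% d[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% (d[1] * d[2])) + 1L
  while (length(remaining)) {
    lab <- lab + 1L
    frontier <- remaining[1]
    comp[frontier] <- lab
    while (length(frontier)) {
      nb <- c(
        frontier[ix[frontier] < d[1]] + strides[1],
        frontier[ix[frontier] > 1L] - strides[1],
        frontier[iy[frontier] < d[2]] + strides[2],
        frontier[iy[frontier] > 1L] - strides[2],
        frontier[iz[frontier] < d[3]] + strides[3],
        frontier[iz[frontier] > 1L] - strides[3]
      )
      nb <- unique(nb[maskv[nb] & comp[nb] == 0L])
      comp[nb] <- lab
      frontier <- nb
    }
    remaining <- remaining[comp[remaining] == 0L]
  }
  array(comp, d)
}

# Euclidean distance transform: distance (mm) from every voxel to the
# nearest TRUE voxel of `mask` on the grid of `vol`-like spacing.
edt_mm <- function(mask, spacing) {
  d <- dim(mask)
  array(cpp_edt(as.vector(mask), as.integer(d), as.numeric(spacing)), d)
}

# Signed distance: negative inside mask, zero crossing at voxel faces.
signed_distance <- function(mask, spacing) {
  edt_mm(mask, spacing) - edt_mm(!mask, spacing)
}
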
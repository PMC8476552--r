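# Triangulated surfaces: extraction from label volumes, areas, PLY I/O.

#' Construct a surface mesh
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param vertex_values optional numeric per-vertex scalar.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_values = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices out of range")
  if (!is.null(vertex_values) && length(vertex_values) != nrow(vertices))
    stop("vertex_values must have one value per vertex")
  structure(list(vertices = vertices, faces = faces,
                 vertex_values = vertex_values),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.2f cm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x) / 100))
  invisible(x)
}

#' Total triangle area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh))
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Extract the endocardial or epicardial surface
#'
#' Triangulates the requested wall surface by marching cubes on a signed
#' distance field of the binary mask (blood pool for the endocardium,
#' blood + wall for the epicardium). With `subvoxel = TRUE` (default) the
#' distance field near the boundary is replaced by a moving-least-squares
#' reconstruction of the interface from the label-change face midpoints,
#' which places vertices on the underlying smooth surface rather than on the
#' voxel staircase. The mesh is open wherever the mask touches the grid
#' boundary (the basal cut).
#'
#' @param seg a [label_volume()].
#' @param which `"endo"` or `"epi"`.
#' @param subvoxel logical; apply sub-voxel interface reconstruction.
#' @return A [surface_mesh()] with vertices in mm.
#' @export
extract_surface <- function(seg, which = c("epi", "endo"), subvoxel = TRUE) {
  which <- match.arg(which)
  stopifnot(inherits(seg, "label_volume"))
  mask <- if (which == "endo") seg$data == 1L else seg$data >= 1L
  if (!any(mask))
    stop("empty mask: no ", which, " surface to extract")
  phi <- surface_sdf(mask, seg$spacing, seg$origin, subvoxel = subvoxel)
  mc <- cpp_marching_cubes(as.vector(phi), as.integer(dim(mask)),
                           seg$spacing, seg$origin, 0)
  surface_mesh(mc$vertices, mc$faces)
}

# Signed distance field whose zero level is the (sub-voxel reconstructed)
# surface of `mask`; negative inside.
surface_sdf <- function(mask, spacing, origin, subvoxel = TRUE) {
  phi <- signed_distance(mask, spacing)
  if (!subvoxel) return(phi)
  rec <- interface_reconstruct(mask, !mask, spacing, origin)
  if (!isTRUE(rec$ok)) return(phi)
  band <- which(abs(phi) <= 1.5 * max(spacing))
  val <- interface_phi_at(rec, band)
  keep <- !is.na(val)
  phi[band[keep]] <- val[keep]
  phi
}

#' Write a mesh to ASCII PLY
#'
#' The optional per-vertex scalar is stored as a named float property.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param value_name property name for `vertex_values` (default `"tsm"`).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, value_name = "tsm") {
  v <- mesh$vertices
  f <- mesh$faces
  has_val <- !is.null(mesh$vertex_values)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ply", "format ascii 1.0",
    "comment scartrans surface mesh",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    if (has_val) sprintf("property float %s", value_name),
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  writeLines(hdr, con)
  if (nrow(v)) {
    vm <- if (has_val) cbind(v, mesh$vertex_values) else v
    writeLines(apply(format(vm, trim = TRUE, digits = 9), 1,
                     paste, collapse = " "), con)
  }
  if (nrow(f))
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path file path.
#' @return A [surface_mesh()]; a fourth vertex property, if present, is
#'   returned as `vertex_values`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", hdr, value = TRUE)))
  vprops <- grep("^property float ", hdr, value = TRUE)
  vlines <- lines[end + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(vlines, " +"))),
               nrow = nv, byrow = TRUE)
  vals <- if (length(vprops) > 3L) vm[, 4] else NULL
  flines <- lines[end + nv + seq_len(nf)]
  fm <- matrix(as.integer(unlist(strsplit(flines, " +"))),
               nrow = nf, byrow = TRUE)
  surface_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L, vals)
}

# In-plane centroid of the mesh section at through-plane position z:
# mean of the edge-plane crossing points.
mesh_section_centroid <- function(mesh, z) {
  v <- mesh$vertices
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  za <- v[edges[, 1], 3]
  zb <- v[edges[, 2], 3]
  cross <- (za - z) * (zb - z) < 0
  if (!any(cross)) return(c(NA_real_, NA_real_))
  t <- (z - za[cross]) / (zb[cross] - za[cross])
  px <- v[edges[cross, 1], 1] + t * (v[edges[cross, 2], 1] - v[edges[cross, 1], 1])
  py <- v[edges[cross, 1], 2] + t * (v[edges[cross, 2], 2] - v[edges[cross, 1], 2])
  c(mean(px), mean(py))
}
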
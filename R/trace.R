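# Endocardium-epicardium correspondences by streamline integration of the
# wall-depth potential, and per-vertex transmurality.

#' Trace endo-epi correspondences from the epicardial surface
#'
#' From each epicardial mesh vertex, integrates the normalized negative
#' gradient of the wall potential (trilinear interpolation, fixed-step
#' first-order integration) until the potential drops below `eps_endo` or
#' the blood pool is entered; the final sub-step is extrapolated to the
#' zero level. The potential is extended with 0 in the blood pool and 1 in
#' the background so gradients are defined up to the surfaces. Each step is
#' labelled scar or healthy from the nearest segmentation voxel at the step
#' midpoint. Traces exceeding a length cap (10 x the maximal inscribed wall
#' thickness) or meeting a vanishing gradient are flagged invalid and
#' excluded from maps.
#'
#' @param field a [solve_laplace()] result.
#' @param epi_mesh the epicardial [surface_mesh()].
#' @param seg the [label_volume()] the field was solved on.
#' @param step integration step (mm); default `0.25 * min(spacing)`.
#' @param eps_endo potential level treated as the endocardium.
#' @param store_paths logical; also return the polylines.
#' @return A data.frame of class `correspondences` with per-vertex
#'   `wall_thickness`, `scar_thickness` (mm), `valid`, `steps`; the QC
#'   counts are attached as attribute `"qc"`, polylines (if requested) as
#'   `"paths"`.
#' @export
trace_correspondences <- function(field, epi_mesh, seg,
                                  step = 0.25 * min(seg$spacing),
                                  eps_endo = 0.02, store_paths = FALSE) {
  stopifnot(inherits(field, "potential_field"),
            inherits(epi_mesh, "surface_mesh"),
            inherits(seg, "label_volume"))
  d <- dim(seg$data)
  s_ext <- field$s
  s_ext[seg$data == 1L] <- 0
  s_ext[seg$data == 0L] <- 1
  grad <- array_gradient(s_ext, seg$spacing)
  # sub-voxel signed distance to the endocardial (blood) surface: traces
  # terminate where this crosses zero, i.e. on the reconstructed interface
  phi_endo <- surface_sdf(seg$data == 1L, seg$spacing, seg$origin)

  wall <- wall_mask(seg)
  max_half <- max(edt_mm(!wall, seg$spacing)[wall])
  cap_len <- 10 * 2 * max_half
  max_steps <- ceiling(cap_len / step)

  pos <- epi_mesh$vertices
  nv <- nrow(pos)
  wall_len <- numeric(nv)
  scar_len <- numeric(nv)
  phi_prev <- rep(1e6, nv)
  prev_lab <- rep(2L, nv)
  status <- rep("running", nv)
  alive <- rep(TRUE, nv)
  paths <- if (store_paths) lapply(seq_len(nv), function(i) pos[i, , drop = FALSE])

  gmin <- 1e-4
  origin <- seg$origin
  spacing <- seg$spacing

  nearest_label <- function(p) {
    ci <- round(sweep(sweep(p, 2, origin), 2, spacing, "/")) + 1
    ci[, 1] <- pmin(pmax(ci[, 1], 1), d[1])
    ci[, 2] <- pmin(pmax(ci[, 2], 1), d[2])
    ci[, 3] <- pmin(pmax(ci[, 3], 1), d[3])
    seg$data[cbind(ci[, 1], ci[, 2], ci[, 3])]
  }

  for (it in seq_len(max_steps)) {
    if (!any(alive)) break
    ai <- which(alive)
    p <- pos[ai, , drop = FALSE]
    vals <- interp3_multi(list(grad$x, grad$y, grad$z, s_ext), p,
                          spacing, origin, d)
    g <- vals[, 1:3, drop = FALSE]
    gn <- sqrt(rowSums(g^2))
    dead <- gn < gmin
    if (any(dead)) {
      status[ai[dead]] <- "zero_gradient"
      alive[ai[dead]] <- FALSE
      ai <- ai[!dead]
      if (!length(ai)) next
      p <- p[!dead, , drop = FALSE]
      g <- g[!dead, , drop = FALSE]
      gn <- gn[!dead]
    }
    dirn <- -g / gn
    pnew <- p + step * dirn
    mid <- (p + pnew) / 2
    lab_mid <- nearest_label(mid)
    # every segment lies in the wall by construction; when the midpoint
    # rounds into blood or background, fall back on the inner endpoint's
    # label and then on the last in-wall label seen along the trace
    amb <- lab_mid < 2L
    if (any(amb)) {
      lab_pn <- nearest_label(pnew[amb, , drop = FALSE])
      lab_mid[amb] <- ifelse(lab_pn >= 2L, lab_pn, prev_lab[ai[amb]])
    }
    prev_lab[ai] <- lab_mid
    wall_len[ai] <- wall_len[ai] + step
    scar_len[ai] <- scar_len[ai] + step * (lab_mid == 3L)

    sb <- interp3_multi(list(s_ext, phi_endo), pnew, spacing, origin, d)
    s_new <- sb[, 1]
    phi_new <- sb[, 2]

    # crossing the endocardial surface: back the arc length up to the
    # sub-step zero crossing of the signed distance
    hit_blood <- phi_new <= 0
    if (any(hit_blood)) {
      di <- which(hit_blood)
      dphi <- pmax(phi_prev[ai[di]] - phi_new[di], 1e-9)
      over <- pmin(pmax(step * (-phi_new[di]) / dphi, 0), step)
      wall_len[ai[di]] <- wall_len[ai[di]] - over
      scar_len[ai[di]] <- scar_len[ai[di]] - over * (lab_mid[di] == 3L)
      status[ai[di]] <- "ok"
      alive[ai[di]] <- FALSE
    }
    done <- !hit_blood & s_new < eps_endo
    if (any(done)) {
      di <- which(done)
      extra <- pmin(pmax(s_new[di], 0) / gn[di], 2 * max(spacing))
      wall_len[ai[di]] <- wall_len[ai[di]] + extra
      tail_mid <- pnew[di, , drop = FALSE] + (extra / 2) * dirn[di, , drop = FALSE]
      lab_tail <- nearest_label(tail_mid)
      # same wall-by-construction fallback for the extrapolated tail
      tail_scar <- lab_tail == 3L | (lab_tail < 2L & lab_mid[di] == 3L)
      scar_len[ai[di]] <- scar_len[ai[di]] + extra * tail_scar
      status[ai[di]] <- "ok"
      alive[ai[di]] <- FALSE
    }
    phi_prev[ai] <- phi_new
    pos[ai, ] <- pnew
    if (store_paths) {
      for (j in seq_along(ai))
        paths[[ai[j]]] <- rbind(paths[[ai[j]]], pnew[j, ])
    }
  }
  status[status == "running"] <- "length_cap"

  res <- data.frame(
    vertex = seq_len(nv),
    wall_thickness = wall_len,
    scar_thickness = pmin(scar_len, wall_len),
    valid = status == "ok",
    status = status
  )
  attr(res, "qc") <- table(status)
  if (store_paths) attr(res, "paths") <- paths
  class(res) <- c("correspondences", "data.frame")
  res
}

#' Transmurality map from correspondences
#'
#' Per epicardial vertex: wall thickness = correspondence arc length, scar
#' thickness = summed scar-labelled arc length, transmurality TsM = their
#' ratio clamped to `[0, 1]` (0 where no scar crosses the correspondence).
#'
#' @param corrs a [trace_correspondences()] result.
#' @return A data.frame of class `transmurality_map` with columns `vertex`,
#'   `wall_thickness`, `scar_thickness`, `tsm`, `valid`.
#' @export
transmurality_map <- function(corrs) {
  stopifnot(inherits(corrs, "correspondences"))
  if (!any(corrs$valid))
    stop("no valid correspondences to map")
  tsm <- ifelse(corrs$wall_thickness > 0,
                pmin(pmax(corrs$scar_thickness / corrs$wall_thickness, 0), 1),
                0)
  res <- data.frame(
    vertex = corrs$vertex,
    wall_thickness = corrs$wall_thickness,
    scar_thickness = corrs$scar_thickness,
    tsm = tsm,
    valid = corrs$valid
  )
  class(res) <- c("transmurality_map", "data.frame")
  res
}

# Trilinear interpolation of several arrays at points (mm), edge-clamped.
interp3_multi <- function(arrays, pts, spacing, origin, d) {
  cx <- (pts[, 1] - origin[1]) / spacing[1]
  cy <- (pts[, 2] - origin[2]) / spacing[2]
  cz <- (pts[, 3] - origin[3]) / spacing[3]
  cx <- pmin(pmax(cx, 0), d[1] - 1 - 1e-9)
  cy <- pmin(pmax(cy, 0), d[2] - 1 - 1e-9)
  cz <- pmin(pmax(cz, 0), d[3] - 1 - 1e-9)
  i0 <- floor(cx); j0 <- floor(cy); k0 <- floor(cz)
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  base <- 1 + i0 + j0 * d[1] + k0 * d[1] * d[2]
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  w <- cbind((1 - fx) * (1 - fy) * (1 - fz),
             fx * (1 - fy) * (1 - fz),
             (1 - fx) * fy * (1 - fz),
             fx * fy * (1 - fz),
             (1 - fx) * (1 - fy) * fz,
             fx * (1 - fy) * fz,
             (1 - fx) * fy * fz,
             fx * fy * fz)
  off <- c(0, sx, sy, sx + sy, sz, sx + sz, sy + sz, sx + sy + sz)
  out <- matrix(0, nrow(pts), length(arrays))
  for (a in seq_along(arrays)) {
    v <- arrays[[a]]
    acc <- numeric(nrow(pts))
    for (cnr in 1:8) acc <- acc + w[, cnr] * v[base + off[cnr]]
    out[, a] <- acc
  }
  out
}
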
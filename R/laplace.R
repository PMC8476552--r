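# Laplace wall-depth potential: harmonic s(x) over the myocardial wall with
# s = 0 on the endocardium and s = 1 on the epicardium, zero flux across the
# basal cut and the grid boundary.
#
# Discretization: anisotropic 7-point finite differences with
# Shortley-Weller boundary arms. The Dirichlet value is imposed where the
# sub-voxel reconstructed interface (see interface.R) crosses the arm, not
# at the neighbouring voxel center, which removes the half-voxel boundary
# bias of a rasterized segmentation. All wall voxels (including the
# classified boundary voxels) are unknowns; endocardial voxels therefore
# carry small positive solved values rather than exact zeros - the zero
# level sits on the reconstructed endocardial surface itself.

#' Solve the Laplace wall-depth potential
#'
#' @param seg a [label_volume()].
#' @param bc a [classify_boundaries()] result (computed from `seg` when
#'   omitted).
#' @param tol relative residual tolerance of the iterative solve.
#' @param maxit iteration cap.
#' @param subvoxel logical; use sub-voxel interface reconstruction for the
#'   Dirichlet boundary placement (`FALSE` places boundaries at voxel
#'   faces).
#' @return An object of class `potential_field`: `s` (3D array, `NA`
#'   outside the wall, values in `[0, 1]`), `residual` (final relative
#'   residual), `iterations`, `bc`.
#' @export
solve_laplace <- function(seg, bc = NULL, tol = 1e-5, maxit = 20000L,
                          subvoxel = TRUE) {
  stopifnot(inherits(seg, "label_volume"))
  if (is.null(bc)) bc <- classify_boundaries(seg)
  d <- dim(seg$data)
  wall <- wall_mask(seg)
  blood <- seg$data == 1L
  bg <- seg$data == 0L

  comp <- conn_comp(wall)
  ncomp <- max(comp)
  if (ncomp > 1L || TRUE) {
    for (ci in seq_len(ncomp)) {
      sel <- comp == ci
      if (!any(sel & bc$endo) || !any(sel & bc$epi))
        stop("wall component ", ci, " touches only one boundary type ",
             "(needs both endocardial and epicardial adjacency)")
    }
  }

  widx <- which(wall)
  n <- length(widx)
  uid <- integer(prod(d))
  uid[widx] <- seq_len(n)
  strides <- grid_strides(d)
  idx0 <- widx - 1L
  coord <- list(
    (idx0 %% d[1]) + 1L,
    ((idx0 %/% d[1]) %% d[2]) + 1L,
    (idx0 %/% (d[1] * d[2])) + 1L
  )

  rec_endo <- if (subvoxel)
    interface_reconstruct(wall, blood, seg$spacing, seg$origin)
  else list(ok = FALSE)
  rec_epi <- if (subvoxel)
    interface_reconstruct(wall, bg, seg$spacing, seg$origin)
  else list(ok = FALSE)

  # arm description per (axis, direction): type 0 wall, 1 Dirichlet0 (endo),
  # 2 Dirichlet1 (epi), 3 Neumann; theta = fractional arm length.
  arm <- function(axis, dir) {
    valid <- if (dir > 0) coord[[axis]] < d[axis] else coord[[axis]] > 1L
    nb <- widx + dir * strides[axis]
    type <- rep(3L, n)
    theta <- rep(1, n)
    nbv <- nb[valid]
    tv <- rep(3L, sum(valid))
    tv[wall[nbv]] <- 0L
    tv[blood[nbv]] <- 1L
    tv[bg[nbv]] <- 2L
    type[valid] <- tv
    for (tt in c(1L, 2L)) {
      sel <- which(type == tt)
      if (!length(sel)) next
      rec <- if (tt == 1L) rec_endo else rec_epi
      if (isTRUE(rec$ok)) {
        theta[sel] <- interface_theta(rec, widx[sel], axis, dir)
      } else {
        theta[sel] <- 0.5
      }
    }
    list(type = type, theta = theta, nb = nb)
  }

  ii <- jj <- xx <- list()
  bvec <- numeric(n)
  diag_acc <- numeric(n)
  k <- 0L
  for (axis in 1:3) {
    h2 <- seg$spacing[axis]^2
    L <- arm(axis, -1L)
    R <- arm(axis, +1L)
    both_neu <- L$type == 3L & R$type == 3L
    tL <- ifelse(L$type == 3L, R$theta, L$theta)
    tR <- ifelse(R$type == 3L, L$theta, R$theta)
    cc <- ifelse(both_neu, 0, 2 / (tL * tR) / h2)
    cL <- ifelse(both_neu, 0, 2 / (tL * (tL + tR)) / h2)
    cR <- ifelse(both_neu, 0, 2 / (tR * (tL + tR)) / h2)
    diag_acc <- diag_acc + cc
    for (side in list(list(a = L, cf = cL), list(a = R, cf = cR))) {
      a <- side$a
      cf <- side$cf
      w <- which(a$type == 0L)
      if (length(w)) {
        k <- k + 1L
        ii[[k]] <- w
        jj[[k]] <- uid[a$nb[w]]
        xx[[k]] <- -cf[w]
      }
      e1 <- a$type == 2L & !both_neu
      bvec[e1] <- bvec[e1] + cf[e1]          # epi Dirichlet value 1
      nm <- a$type == 3L & !both_neu
      diag_acc[nm] <- diag_acc[nm] - cf[nm]  # mirrored Neumann arm
    }
  }

  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), unlist(ii)),
    j = c(seq_len(n), unlist(jj)),
    x = c(diag_acc, unlist(xx)),
    dims = c(n, n))

  sol <- bicgstab(A, bvec, x0 = rep(0.5, n), tol = tol, maxit = maxit)
  if (!sol$converged)
    stop(sprintf(
      "Laplace solve did not converge in %d iterations (relative residual %.3g, tolerance %.3g)",
      sol$iterations, sol$residual, tol))

  s <- array(NA_real_, d)
  s[widx] <- pmin(pmax(sol$x, 0), 1)
  structure(list(s = s, residual = sol$residual,
                 iterations = sol$iterations, bc = bc,
                 wall_idx = widx, spacing = seg$spacing,
                 origin = seg$origin, subvoxel = subvoxel),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf(
    "<potential_field> %d wall voxels; residual %.2e after %d iterations\n",
    length(x$wall_idx), x$residual, x$iterations))
  invisible(x)
}

# Jacobi-preconditioned BiCGSTAB; deterministic. Falls back to a direct
# sparse solve on numerical breakdown.
bicgstab <- function(A, b, x0, tol, maxit) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    return(list(x = numeric(length(b)), residual = 0, iterations = 0L,
                converged = TRUE))
  }
  Minv <- 1 / Matrix::diag(A)
  x <- x0
  r <- b - as.numeric(A %*% x)
  r0 <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(length(b))
  it <- 0L
  relres <- sqrt(sum(r^2)) / nb
  while (relres > tol && it < maxit) {
    it <- it + 1L
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300 || abs(omega) < 1e-300) {
      x <- as.numeric(Matrix::solve(A, b))
      r <- b - as.numeric(A %*% x)
      return(list(x = x, residual = sqrt(sum(r^2)) / nb, iterations = it,
                  converged = TRUE))
    }
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    phat <- Minv * p
    v <- as.numeric(A %*% phat)
    alpha <- rho / sum(r0 * v)
    ss <- r - alpha * v
    shat <- Minv * ss
    t <- as.numeric(A %*% shat)
    tt <- sum(t * t)
    omega <- if (tt > 0) sum(t * ss) / tt else 0
    x <- x + alpha * phat + omega * shat
    r <- ss - omega * t
    relres <- sqrt(sum(r^2)) / nb
  }
  list(x = x, residual = relres, iterations = it, converged = relres <= tol)
}
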
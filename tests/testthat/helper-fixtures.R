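# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# Compact annulus for unit tests (acceptance tests use the full-size one).
small_annulus <- function(f = 0.5, noise = 0, seed = 1) {
  key <- sprintf("annulus_%g_%g_%d", f, noise, seed)
  fixture(key, make_phantom(phantom_spec(
    "annulus", r_endo = 10, wall_thickness = 6, height = 12,
    transmural_extent = f, spacing = 0.75, noise_sd = noise, seed = seed)))
}

small_ellipsoid <- function(f = 0.5) {
  key <- sprintf("ellipsoid_%g", f)
  fixture(key, make_phantom(phantom_spec(
    "ellipsoid", semi_axes = c(12, 12, 20), wall_thickness = 6,
    basal_cut = 0.25, transmural_extent = f, spacing = 1.0,
    noise_sd = 0)))
}

# Digital ball of radius r (as blood pool) on a corner-centered grid.
ball_volume <- function(h, r = 10, margin = 2) {
  half <- ceiling((r + margin) / h)
  n <- 2L * half
  x <- (seq_len(n) - half - 0.5) * h
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- array(rep(rep(x, each = n), times = n), c(n, n, n))
  Z <- array(rep(x, each = n * n), c(n, n, n))
  lab <- array(0L, c(n, n, n))
  lab[sqrt(X^2 + Y^2 + Z^2) < r] <- 1L
  label_volume(lab, c(h, h, h), c(x[1], x[1], x[1]))
}

# In-plane polar coordinates of mesh vertices.
vertex_polar <- function(mesh) {
  list(r = sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2),
       theta = atan2(mesh$vertices[, 2], mesh$vertices[, 1]) %% (2 * pi),
       z = mesh$vertices[, 3])
}

# Analytic annulus potential on the phantom grid.
annulus_analytic_s <- function(ph) {
  d <- dim(ph$labels$data)
  x <- ph$labels$origin[1] + (seq_len(d[1]) - 1) * ph$labels$spacing[1]
  y <- ph$labels$origin[2] + (seq_len(d[2]) - 1) * ph$labels$spacing[2]
  R <- sqrt(outer(x^2, y^2, "+"))
  Rarr <- array(rep(R, d[3]), d)
  log(Rarr / ph$truth$r_endo) / log(ph$truth$r_epi / ph$truth$r_endo)
}

annulus_radius_array <- function(ph) {
  d <- dim(ph$labels$data)
  x <- ph$labels$origin[1] + (seq_len(d[1]) - 1) * ph$labels$spacing[1]
  y <- ph$labels$origin[2] + (seq_len(d[2]) - 1) * ph$labels$spacing[2]
  array(rep(sqrt(outer(x^2, y^2, "+")), d[3]), d)
}

# Match the z-grids of an upsampled volume to a reference volume and report
# the Dice overlap of a label predicate on the common slices.
dice_on_common_slices <- function(ref, test, predicate) {
  z_ref <- ref$origin[3] + (seq_len(dim(ref$data)[3]) - 1) * ref$spacing[3]
  z_tst <- test$origin[3] + (seq_len(dim(test$data)[3]) - 1) * test$spacing[3]
  mi <- match(round(z_ref, 6), round(z_tst, 6))
  ok <- !is.na(mi)
  stopifnot(sum(ok) > 0)
  dice(predicate(ref$data[, , ok, drop = FALSE]),
       predicate(test$data[, , mi[ok], drop = FALSE]))
}
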
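# Synthetic left-ventricle phantoms with analytic ground truth.
#
# Two shapes: a circular annulus (straight cylindrical wall; the exact
# oracle, since the Laplace streamlines are radial and the analytic
# potential is ln(r/a)/ln(b/a)) and a truncated ellipsoid (the realism
# check; ground-truth transmurality is defined along radial rays through
# the wall). Intensities follow a two-level model with additive Gaussian
# noise, emulating signal-nulled healthy myocardium with hyperenhanced scar.
#
# Rasterization samples the analytic geometry at voxel centers. The symmetry
# axis is placed on a voxel corner (cell-centered grid), the natural
# non-degenerate alignment: it keeps analytic surfaces from passing exactly
# through voxel centers, the worst case for sub-voxel reconstruction.

#' Phantom specification
#'
#' @param shape `"annulus"` or `"ellipsoid"`.
#' @param r_endo annulus endocardial radius (mm).
#' @param wall_thickness wall thickness (mm).
#' @param height annulus height (mm).
#' @param semi_axes ellipsoid endocardial semi-axes (mm), length 3
#'   (third = long axis).
#' @param basal_cut fraction of the epicardial long semi-axis above the
#'   center at which the ellipsoid is truncated (the basal cut plane).
#' @param scar_sector angular range `[theta1, theta2)` in radians of the
#'   scar sector, measured in the short-axis plane.
#' @param scar_z_range through-plane extent of the scar (mm, in grid
#'   coordinates), `NULL` for the full extent.
#' @param transmural_extent scar transmural extent f in `[0, 1]`, measured
#'   from the endocardium.
#' @param spacing isotropic voxel size (mm).
#' @param margin in-plane background margin (mm).
#' @param intensities named numeric: mean signal of `background`, `blood`,
#'   `myocardium`, `scar` (arbitrary units). Defaults place the
#'   full-width-half-maximum cutoff at 0.45 of the maximum well between
#'   nulled myocardium and enhanced scar.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed for the intensity noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("annulus", "ellipsoid"),
                         r_endo = 20, wall_thickness = 10, height = 30,
                         semi_axes = c(20, 20, 32), basal_cut = 0.25,
                         scar_sector = c(0, pi / 2), scar_z_range = NULL,
                         transmural_extent = 0.5,
                         spacing = 0.75, margin = 3,
                         intensities = c(background = 0.05, blood = 0.6,
                                         myocardium = 0.2, scar = 1.0),
                         noise_sd = 0.02, seed = 1L) {
  shape <- match.arg(shape)
  f <- transmural_extent
  if (!is.finite(f) || f < 0 || f > 1)
    stop("transmural_extent must lie in [0, 1]")
  if (wall_thickness <= 2 * spacing)
    stop("wall_thickness must exceed 2 * spacing (wall not resolvable)")
  if (intensities[["scar"]] <= intensities[["myocardium"]])
    stop("scar intensity must exceed myocardium intensity")
  structure(list(shape = shape, r_endo = r_endo,
                 wall_thickness = wall_thickness, height = height,
                 semi_axes = semi_axes, basal_cut = basal_cut,
                 scar_sector = scar_sector, scar_z_range = scar_z_range,
                 transmural_extent = f, spacing = spacing, margin = margin,
                 intensities = intensities, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom
#'
#' Rasterizes the analytic phantom geometry into a label volume, draws
#' per-label intensities with additive Gaussian noise (reproducible from the
#' spec seed; labels are independent of the seed), and returns the analytic
#' ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `labels` ([label_volume()]), `image`
#'   ([image_volume()]) and `truth` (class `phantom_truth`: the prescribed
#'   transmural extent, sector, analytic wall/scar volumes in cm^3 and wall
#'   thickness).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing
  if (spec$shape == "annulus") {
    r_epi <- spec$r_endo + spec$wall_thickness
    half <- ceiling((r_epi + spec$margin) / h)
    nx <- 2L * half
    x <- (seq_len(nx) - half - 0.5) * h   # axis on a voxel corner
    nz <- max(2L, round(spec$height / h))
    z <- (seq_len(nz) - 0.5) * h
    height <- nz * h
    X <- array(rep(x, times = nx * nz), c(nx, nx, nz))
    Y <- array(rep(rep(x, each = nx), times = nz), c(nx, nx, nz))
    R <- sqrt(X^2 + Y^2)
    lab <- array(0L, c(nx, nx, nz))
    lab[R < r_epi] <- 2L
    lab[R < spec$r_endo] <- 1L
    theta <- (atan2(Y, X)) %% (2 * pi)
    r_scar <- spec$r_endo + spec$transmural_extent * spec$wall_thickness
    zr <- if (is.null(spec$scar_z_range)) c(-Inf, Inf) else spec$scar_z_range
    Z <- array(rep(z, each = nx * nx), c(nx, nx, nz))
    in_sector <- sector_test(theta, spec$scar_sector) & Z >= zr[1] & Z < zr[2]
    scar <- lab == 2L & R < r_scar & in_sector
    lab[scar] <- 3L
    origin <- c(x[1], x[1], z[1])
    spacing <- c(h, h, h)

    sector_frac <- sector_width(spec$scar_sector) / (2 * pi)
    z_extent <- min(zr[2], height) - max(zr[1], 0)
    if (!is.finite(z_extent)) z_extent <- height
    wall_vol <- pi * (r_epi^2 - spec$r_endo^2) * height / 1000
    scar_vol <- sector_frac * pi * (r_scar^2 - spec$r_endo^2) *
      z_extent / 1000
    truth <- structure(list(
      shape = "annulus", transmural_extent = spec$transmural_extent,
      scar_sector = spec$scar_sector, scar_z_range = spec$scar_z_range,
      wall_thickness = spec$wall_thickness,
      wall_volume_cm3 = wall_vol, scar_volume_cm3 = scar_vol,
      r_endo = spec$r_endo, r_epi = r_epi, r_scar = r_scar,
      height = height, analytic_potential = local({
        a <- spec$r_endo; b <- r_epi
        function(r) log(r / a) / log(b / a)
      })), class = "phantom_truth")
  } else {
    ax <- spec$semi_axes
    wt <- spec$wall_thickness
    ax_epi <- ax + wt
    z_cut <- spec$basal_cut * ax_epi[3]
    half1 <- ceiling((ax_epi[1] + spec$margin) / h)
    half2 <- ceiling((ax_epi[2] + spec$margin) / h)
    nx <- 2L * half1
    ny <- 2L * half2
    x <- (seq_len(nx) - half1 - 0.5) * h
    y <- (seq_len(ny) - half2 - 0.5) * h
    z_lo <- -ax_epi[3] - spec$margin
    # last slice center just below the cut plane
    nz <- floor((z_cut - z_lo) / h)
    z <- z_cut - (rev(seq_len(nz)) - 0.5) * h
    X <- array(rep(x, times = ny * nz), c(nx, ny, nz))
    Y <- array(rep(rep(y, each = nx), times = nz), c(nx, ny, nz))
    Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))
    m_endo <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
    m_epi <- sqrt((X / ax_epi[1])^2 + (Y / ax_epi[2])^2 + (Z / ax_epi[3])^2)
    lab <- array(0L, c(nx, ny, nz))
    lab[m_epi < 1] <- 2L
    lab[m_endo < 1] <- 1L
    # radial-ray depth fraction within the wall
    r3 <- sqrt(X^2 + Y^2 + Z^2)
    t_depth <- (r3 - r3 / pmax(m_endo, 1e-9)) /
      pmax(r3 / pmax(m_epi, 1e-9) - r3 / pmax(m_endo, 1e-9), 1e-9)
    theta <- (atan2(Y, X)) %% (2 * pi)
    zr <- if (is.null(spec$scar_z_range)) c(-Inf, Inf) else spec$scar_z_range
    in_sector <- sector_test(theta, spec$scar_sector) & Z >= zr[1] & Z < zr[2]
    scar <- lab == 2L & t_depth < spec$transmural_extent & in_sector
    lab[scar] <- 3L
    origin <- c(x[1], y[1], z[1])
    spacing <- c(h, h, h)

    vols <- ellipsoid_truth_volumes(ax, ax_epi, z_cut, spec)
    truth <- structure(list(
      shape = "ellipsoid", transmural_extent = spec$transmural_extent,
      scar_sector = spec$scar_sector, scar_z_range = spec$scar_z_range,
      wall_thickness = wt,
      wall_volume_cm3 = vols$wall, scar_volume_cm3 = vols$scar,
      semi_axes_endo = ax, semi_axes_epi = ax_epi, z_cut = z_cut),
      class = "phantom_truth")
  }

  labels <- label_volume(lab, spacing, origin)
  mu <- spec$intensities[c("background", "blood", "myocardium", "scar")]
  img_data <- array(mu[as.vector(lab) + 1L], dim(lab))
  if (spec$noise_sd > 0) {
    img_data <- img_data + with_seed(spec$seed, {
      array(rnorm(length(lab), 0, spec$noise_sd), dim(lab))
    })
  }
  image <- image_volume(img_data, spacing, origin)
  list(labels = labels, image = image, truth = truth)
}

#' Flat-slab phantom
#'
#' A planar wall of prescribed thickness between a blood half-space and
#' background, with optional full- or partial-thickness scar. The wall depth
#' runs along array axis 1, so the analytic potential is linear in x and the
#' streamlines are straight. Useful as an exactly solvable fixture.
#'
#' @param thickness wall thickness (mm).
#' @param extent in-plane extent (mm) of the slab (axes 2 and 3).
#' @param spacing isotropic voxel size (mm).
#' @param scar_extent scar transmural extent f in `[0, 1]` from the
#'   endocardial (blood-facing) side.
#' @param blood_depth thickness of the blood slab (mm).
#' @return A list with `labels` ([label_volume()]) and `truth`.
#' @export
slab_phantom <- function(thickness = 10, extent = 20, spacing = 0.5,
                         scar_extent = 0, blood_depth = 5) {
  h <- spacing
  n_blood <- round(blood_depth / h)
  n_wall <- round(thickness / h)
  n_bg <- round(5 / h)
  nx <- n_blood + n_wall + n_bg
  ny <- max(2L, round(extent / h))
  lab <- array(0L, c(nx, ny, ny))
  lab[seq_len(n_blood), , ] <- 1L
  wall_ix <- n_blood + seq_len(n_wall)
  lab[wall_ix, , ] <- 2L
  if (scar_extent > 0) {
    n_scar <- round(scar_extent * n_wall)
    if (n_scar > 0) lab[n_blood + seq_len(n_scar), , ] <- 3L
  }
  labels <- label_volume(lab, c(h, h, h), c(0, 0, 0))
  truth <- structure(list(
    shape = "slab", transmural_extent = scar_extent,
    wall_thickness = n_wall * h,
    endo_x = (n_blood - 0.5) * h,  # interface at the face
    epi_x = (n_blood + n_wall - 0.5) * h), class = "phantom_truth")
  list(labels = labels, truth = truth)
}

#' Reslice a volume into a thick-slice stack
#'
#' Emulates a 2D acquisition of the same anatomy by resampling the
#' through-plane axis to the requested slice thickness (slab averaging for
#' images, occupancy voting for labels; see [downsample_throughplane()]).
#'
#' @param vol an [image_volume()] or [label_volume()].
#' @param thickness target slice thickness (mm), at least the current
#'   through-plane spacing.
#' @param spec a [resample_spec()].
#' @return A volume of the same type with through-plane spacing `thickness`.
#' @export
slice_stack <- function(vol, thickness, spec = resample_spec()) {
  if (!is.finite(thickness) || thickness <= 0)
    stop("thickness must be a positive finite number (mm)")
  if (abs(thickness - vol$spacing[3]) < 1e-9) return(vol)
  downsample_throughplane(vol, thickness, spec)
}

sector_test <- function(theta, sector) {
  t1 <- sector[1] %% (2 * pi)
  t2 <- sector[2] %% (2 * pi)
  if (sector[2] - sector[1] >= 2 * pi) return(theta >= 0)
  if (t1 <= t2) theta >= t1 & theta < t2 else theta >= t1 | theta < t2
}

sector_width <- function(sector) {
  w <- sector[2] - sector[1]
  if (w >= 2 * pi) 2 * pi else w %% (2 * pi)
}

# Truncated-ellipsoid wall and scar volumes (cm^3) by spherical-direction
# quadrature of the radial-ray geometry (the same geometry the rasterizer
# samples).
ellipsoid_truth_volumes <- function(ax, ax_epi, z_cut, spec) {
  nth <- 720L
  nph <- 720L
  thw <- sector_width(spec$scar_sector)
  th_all <- (seq_len(nth) - 0.5) / nth * 2 * pi
  cph <- (seq_len(nph) - 0.5) / nph * 2 - 1  # cos(polar) in (-1, 1)
  sph <- sqrt(pmax(0, 1 - cph^2))
  TH <- matrix(th_all, nth, nph)
  CP <- matrix(cph, nth, nph, byrow = TRUE)
  SP <- matrix(sph, nth, nph, byrow = TRUE)
  ux <- cos(TH) * SP
  uy <- sin(TH) * SP
  uz <- CP
  r_ray <- function(a) 1 / sqrt((ux / a[1])^2 + (uy / a[2])^2 + (uz / a[3])^2)
  Re <- r_ray(ax)
  Rp <- r_ray(ax_epi)
  rmax <- ifelse(uz > 0, z_cut / uz, Inf)
  seg_vol <- function(r1, r2) {
    r1 <- pmin(r1, rmax)
    r2 <- pmin(r2, rmax)
    sum(pmax(r2^3 - r1^3, 0)) / 3 * (2 * pi / nth) * (2 / nph)
  }
  wall <- seg_vol(Re, Rp)
  th1 <- spec$scar_sector[1] %% (2 * pi)
  sector <- sector_test(TH, spec$scar_sector)
  Rs <- Re + spec$transmural_extent * (Rp - Re)
  r1s <- ifelse(sector, Re, Rp)  # zero-length segment outside the sector
  r2s <- ifelse(sector, Rs, Rp)
  scar <- seg_vol(r1s, pmax(r1s, r2s))
  list(wall = wall / 1000, scar = scar / 1000)
}

# Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
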
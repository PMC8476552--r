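# Wall-depth Laplace potential: analytic fixtures, maximum principle,
# convergence, error paths.

test_that("flat slab potential is linear in depth", {
  sl <- slab_phantom(thickness = 10, extent = 12, spacing = 0.5)
  field <- solve_laplace(sl$labels)
  expect_lte(field$residual, 1e-5)
  d <- dim(sl$labels$data)
  xc <- (seq_len(d[1]) - 1) * 0.5
  depth <- (xc - sl$truth$endo_x) / sl$truth$wall_thickness
  wall <- sl$labels$data >= 2L
  for (i in which(xc > sl$truth$endo_x & xc < sl$truth$epi_x)) {
    vals <- field$s[i, , ][wall[i, , ]]
    expect_equal(mean(vals), depth[i], tolerance = 0.01)
  }
  # midplane s = 0.5 +- 0.01 (interpolated between the two center voxels)
  mid <- (sl$truth$endo_x + sl$truth$epi_x) / 2
  below <- max(which(xc <= mid)); above <- below + 1L
  w <- (mid - xc[below]) / 0.5
  smid <- (1 - w) * mean(field$s[below, , ], na.rm = TRUE) +
    w * mean(field$s[above, , ], na.rm = TRUE)
  expect_equal(smid, 0.5, tolerance = 0.01)
})

test_that("annulus potential approaches ln(r/a)/ln(b/a) and converges", {
  errs <- vapply(c(1.5, 0.75), function(h) {
    ph <- make_phantom(phantom_spec("annulus", r_endo = 14,
                                    wall_thickness = 8, height = 6 * h,
                                    spacing = h, noise_sd = 0))
    bc <- classify_boundaries(ph$labels)
    field <- solve_laplace(ph$labels, bc)
    R <- annulus_radius_array(ph)
    ana <- log(R / 14) / log(22 / 14)
    interior <- ph$labels$data >= 2L & !bc$endo & !bc$epi
    max(abs(field$s - ana)[interior])
  }, numeric(1))
  expect_lt(errs[2], errs[1])  # halving the spacing reduces the error
  expect_lt(errs[2], 0.02)
})

test_that("maximum principle holds on the interior", {
  ph <- small_annulus()
  bc <- classify_boundaries(ph$labels)
  field <- solve_laplace(ph$labels, bc)
  interior <- ph$labels$data >= 2L & !bc$endo & !bc$epi
  expect_gt(min(field$s[interior]), 0)
  expect_lt(max(field$s[interior]), 1)
  expect_true(all(field$s[!is.na(field$s)] >= 0 &
                    field$s[!is.na(field$s)] <= 1))
})

test_that("degenerate all-boundary walls solve to interface-imposed values", {
  # 2-voxel-thick wall: every wall voxel is classified (no interior).
  # With the interface-imposed Dirichlet treatment the two layers take the
  # depth values of their voxel centers (1/4 and 3/4 across the wall)
  # rather than the hard-pinned 0/1.
  lab <- array(0L, c(10, 6, 6))
  lab[1:4, , ] <- 1L
  lab[5:6, , ] <- 2L
  seg <- label_volume(lab, c(1, 1, 1))
  bc <- classify_boundaries(seg)
  expect_length(setdiff(which(seg$data >= 2L),
                        c(bc$endo_voxels, bc$epi_voxels, bc$cut_voxels)), 0)
  field <- suppressMessages(solve_laplace(seg, bc))
  expect_true(all(field$s[5:6, , ] >= 0 & field$s[5:6, , ] <= 1))
  expect_lt(abs(mean(field$s[5, , ]) - 0.25), 0.05)
  expect_lt(abs(mean(field$s[6, , ]) - 0.75), 0.05)
})

test_that("invalid wall topologies are reported", {
  # a second wall component enclosed in blood touches no background
  lab <- array(0L, c(12, 8, 8))
  lab[2:5, 2:7, 2:7] <- 1L
  lab[6:7, 2:7, 2:7] <- 2L        # proper wall: blood on one side, bg beyond
  lab[3, 4, 4] <- 2L              # island wall inside the blood pool
  seg <- label_volume(lab, c(1, 1, 1))
  expect_error(suppressMessages(solve_laplace(seg)), "one boundary type")
})

test_that("solver reports iterations and meets the residual tolerance", {
  ph <- small_annulus()
  field <- solve_laplace(ph$labels, tol = 1e-7)
  expect_lte(field$residual, 1e-7)
  expect_gt(field$iterations, 0)
  expect_error(solve_laplace(ph$labels, maxit = 1L), "did not converge")
})
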
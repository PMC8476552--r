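# Phantom generator: analytic geometry, intensity model, thick-slice
# emulation.

test_that("annulus scar geometry matches the analytic sector", {
  ph <- small_annulus(f = 0.5)
  tr <- ph$truth
  # scar occupies r_endo <= r < r_endo + f*wall within the sector
  R <- annulus_radius_array(ph)
  scar <- ph$labels$data == 3L
  expect_true(all(R[scar] >= tr$r_endo - 1e-9))
  expect_true(all(R[scar] < tr$r_scar))
  # analytic in-sector scar/wall volume ratio: (r_s^2-a^2)/(b^2-a^2)
  ratio_analytic <- (tr$r_scar^2 - tr$r_endo^2) / (tr$r_epi^2 - tr$r_endo^2)
  d <- dim(ph$labels$data)
  x <- ph$labels$origin[1] + (seq_len(d[1]) - 1) * ph$labels$spacing[1]
  theta <- (atan2(array(rep(rep(x, each = d[1]), d[3]), d),
                  array(rep(x, d[2] * d[3]), d))) %% (2 * pi)
  in_sector <- theta >= 0 & theta < pi / 2
  wall_sector <- ph$labels$data >= 2L & in_sector
  expect_equal(sum(scar) / sum(wall_sector), ratio_analytic, tolerance = 0.05)
  # analytic truth volumes agree with the rasterization
  vv <- prod(ph$labels$spacing) / 1000
  expect_equal(sum(ph$labels$data >= 2L) * vv, tr$wall_volume_cm3,
               tolerance = 0.02)
  expect_equal(sum(scar) * vv, tr$scar_volume_cm3, tolerance = 0.03)
})

test_that("transmural extent boundary cases", {
  ph0 <- small_annulus(f = 0)
  expect_equal(sum(ph0$labels$data == 3L), 0L)
  ph1 <- small_annulus(f = 1)
  # scar fills the wall sector: no myocardium left inside the sector
  R <- annulus_radius_array(ph1)
  d <- dim(ph1$labels$data)
  x <- ph1$labels$origin[1] + (seq_len(d[1]) - 1) * ph1$labels$spacing[1]
  theta <- (atan2(array(rep(rep(x, each = d[1]), d[3]), d),
                  array(rep(x, d[2] * d[3]), d))) %% (2 * pi)
  core <- theta >= 0.05 & theta < pi / 2 - 0.05  # clear of the sector edges
  expect_equal(sum(ph1$labels$data == 2L & core), 0L)
})

test_that("noise is seeded and independent of the geometry", {
  sp <- function(seed) phantom_spec("annulus", r_endo = 10,
                                    wall_thickness = 6, height = 8,
                                    spacing = 1, seed = seed)
  a <- make_phantom(sp(1))
  b <- make_phantom(sp(2))
  a2 <- make_phantom(sp(1))
  expect_identical(a$labels$data, b$labels$data)
  expect_false(identical(a$image$data, b$image$data))
  expect_identical(a$image$data, a2$image$data)
})

test_that("rasterized wall volume converges to the analytic volume", {
  # volume quantization error oscillates with the grid alignment, so the
  # convergence check compares coarse and fine spacing pairs
  errs <- vapply(c(1.5, 1.0, 0.75, 0.6), function(h) {
    ph <- make_phantom(phantom_spec("annulus", r_endo = 10,
                                    wall_thickness = 6, height = 9,
                                    spacing = h, noise_sd = 0))
    vv <- prod(ph$labels$spacing) / 1000
    abs(sum(ph$labels$data >= 2L) * vv / ph$truth$wall_volume_cm3 - 1)
  }, numeric(1))
  expect_lt(errs[3], 0.03)  # < 3% at 0.75 mm
  expect_lt(mean(errs[3:4]), mean(errs[1:2]))
})

test_that("ellipsoid truth volumes agree with the rasterization", {
  ph <- small_ellipsoid()
  vv <- prod(ph$labels$spacing) / 1000
  expect_equal(sum(ph$labels$data >= 2L) * vv, ph$truth$wall_volume_cm3,
               tolerance = 0.03)
  expect_equal(sum(ph$labels$data == 3L) * vv, ph$truth$scar_volume_cm3,
               tolerance = 0.05)
})

test_that("slice_stack emulates a thick-slice acquisition", {
  ph <- small_annulus()
  # identity when the thickness equals the current spacing
  expect_identical(slice_stack(ph$labels, ph$labels$spacing[3]), ph$labels)
  # slice count: ceil(extent / thickness)
  thick <- slice_stack(ph$labels, 8)
  extent <- dim(ph$labels$data)[3] * ph$labels$spacing[3]
  expect_equal(dim(thick$data)[3], ceiling(extent / 8))
  # label closure
  expect_true(all(thick$data %in% 0:3))
  expect_error(slice_stack(ph$labels, -1), "positive")
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(transmural_extent = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(wall_thickness = 1, spacing = 0.75),
               "resolvable")
  expect_error(phantom_spec(intensities = c(background = 0, blood = 0.6,
                                            myocardium = 1, scar = 0.5)),
               "exceed")
})
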
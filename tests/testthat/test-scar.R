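# FWHM scar segmentation: slab-averaged maximum, thresholds, volumes.

test_that("slab-averaged maximum follows the window mean", {
  # constant image: averaging leaves the value unchanged
  img <- image_volume(array(7, c(4, 4, 24)), c(1, 1, 1))
  wall <- array(TRUE, c(4, 4, 24))
  expect_equal(slab_averaged_max(img, wall, scar_criteria(slab_voxels = 12)),
               7)
  # single bright voxel of 120 in a through-plane column, 12-voxel window:
  # the window holding it averages to 120/12 = 10
  a <- array(0, c(4, 4, 24))
  a[2, 2, 12] <- 120
  img <- image_volume(a, c(1, 1, 1))
  expect_equal(slab_averaged_max(img, wall, scar_criteria(slab_voxels = 12)),
               10)
  # direct enumeration oracle: max over all truncated window means
  set.seed(3)
  a <- array(rnorm(4 * 4 * 24), c(4, 4, 24))
  img <- image_volume(a, c(1, 1, 1))
  k <- 12; lo <- floor((k - 1) / 2); hi <- k - 1 - lo
  oracle <- max(vapply(seq_len(24), function(z) {
    zz <- max(1, z - lo):min(24, z + hi)
    max(apply(a[, , zz, drop = FALSE], c(1, 2), mean))
  }, numeric(1)))
  expect_equal(slab_averaged_max(img, wall, scar_criteria(slab_voxels = 12)),
               oracle, tolerance = 1e-12)
})

test_that("thick-slice stacks reduce to the plain maximum", {
  a <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  img <- image_volume(a, c(1.5, 1.5, 8))
  wall <- array(TRUE, dim(a))
  expect_equal(slab_averaged_max(img, wall, scar_criteria(slab_mm = 8)),
               max(a))
  expect_error(slab_averaged_max(img, array(FALSE, dim(a))), "empty wall")
})

test_that("FWHM thresholds are 0.45 and 0.67 of the maximum", {
  # wall slab with a bright plateau so the slab-averaged max is exactly 100
  lab <- array(2L, c(6, 6, 12))
  a <- array(50, c(6, 6, 12))
  a[3, 3, ] <- 100  # constant through-plane column: averaging-invariant
  img <- image_volume(a, c(1, 1, 1))
  seg <- label_volume(lab, c(1, 1, 1))
  res <- segment_scar(img, seg, scar_criteria())
  expect_equal(res$max_si, 100)
  expect_equal(res$threshold, 45)
  expect_equal(res$dense_threshold, 67)
  # 50 >= 45: everything is scar here; shift the background value down
  a2 <- a; a2[a2 == 50] <- 30
  res2 <- segment_scar(image_volume(a2, c(1, 1, 1)), seg)
  expect_true(all(res2$seg$data[3, 3, ] == 3L))
  expect_true(all(res2$seg$data[1, 1, ] == 2L))
})

test_that("segmentation is invariant to global intensity rescaling", {
  ph <- small_annulus(noise = 0.02, seed = 5)
  seg_wall <- label_volume(pmin(ph$labels$data, 2L), ph$labels$spacing,
                           ph$labels$origin)  # hide the scar labels
  r1 <- segment_scar(ph$image, seg_wall)
  img_k <- image_volume(ph$image$data * 3.7, ph$image$spacing,
                        ph$image$origin)
  r2 <- segment_scar(img_k, seg_wall)
  expect_identical(r1$seg$data, r2$seg$data)
  expect_identical(r1$dense, r2$dense)
})

test_that("scar mask is monotone in the cutoff and double cutoffs partition", {
  ph <- small_annulus(noise = 0.02, seed = 5)
  seg_wall <- label_volume(pmin(ph$labels$data, 2L), ph$labels$spacing,
                           ph$labels$origin)
  masks <- lapply(c(0.3, 0.45, 0.6), function(c1)
    segment_scar(ph$image, seg_wall,
                 scar_criteria(cutoff = c1, dense_cutoff = 0.9))$seg$data == 3L)
  expect_true(all(masks[[2]][masks[[3]]]))  # raising cutoff never adds voxels
  expect_true(all(masks[[1]][masks[[2]]]))

  res <- segment_scar(ph$image, seg_wall)
  scar <- res$seg$data == 3L
  expect_identical(scar, res$dense | res$heterogeneous)
  expect_false(any(res$dense & res$heterogeneous))
})

test_that("phantom scar is recovered with Dice >= 0.95 at sigma = 0.02", {
  ph <- small_annulus(noise = 0.02, seed = 5)
  seg_wall <- label_volume(pmin(ph$labels$data, 2L), ph$labels$spacing,
                           ph$labels$origin)
  res <- segment_scar(ph$image, seg_wall)
  expect_gte(dice(res$seg$data == 3L, ph$labels$data == 3L), 0.95)
})

test_that("scar volumes satisfy the accounting identities", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1:5] <- 2L
  lab[1:10, 1:10, 1:2] <- 3L  # 200 scar voxels
  seg <- label_volume(lab, c(1, 1, 1))
  dense <- lab == 3L & rep(c(TRUE, FALSE), length.out = length(lab))
  v <- scar_volumes(seg, dense)
  expect_equal(v$total, 200 / 1000)
  expect_equal(v$total, v$heterogeneous + v$dense)
  expect_equal(v$wall, v$healthy + v$total)
  # 1000 voxels at 1 mm^3 = 1 cm^3
  lab2 <- array(3L, c(10, 10, 10))
  expect_equal(scar_volumes(label_volume(lab2, c(1, 1, 1)))$total, 1)
  # no scar: wall = healthy
  v0 <- scar_volumes(label_volume(array(2L, c(4, 4, 4)), c(1, 1, 1)))
  expect_equal(v0$total, 0)
  expect_equal(v0$wall, v0$healthy)
})

test_that("phantom sector scar volume matches the analytic value", {
  ph <- small_annulus(f = 0.5)
  v <- scar_volumes(ph$labels)
  expect_equal(v$total, ph$truth$scar_volume_cm3, tolerance = 0.03)
})

test_that("coarser through-plane resolution never shrinks measured scar", {
  ph <- small_annulus(noise = 0.02, seed = 5)
  seg_wall <- label_volume(pmin(ph$labels$data, 2L), ph$labels$spacing,
                           ph$labels$origin)
  native <- scar_volumes(segment_scar(ph$image, seg_wall)$seg)$total
  vols <- vapply(c(2, 4, 8), function(th) {
    img2 <- downsample_throughplane(ph$image, th)
    seg2 <- downsample_throughplane(seg_wall, th)
    scar_volumes(segment_scar(img2, seg2)$seg)$total
  }, numeric(1))
  expect_true(all(vols >= native - 1e-9))
})
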
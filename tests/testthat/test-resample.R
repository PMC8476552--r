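# Through-plane downsampling and shape-based upsampling.

test_that("slab label voting follows the occupancy rules", {
  # stack two identical 12-slice slabs and downsample to two thick slices
  make_col <- function(labels) {
    labels <- rep(labels, 2)
    lab <- array(rep(labels, each = 4), c(2, 2, length(labels)))
    label_volume(lab, c(1, 1, 1))
  }
  # unanimity: all scar -> scar
  out <- downsample_throughplane(make_col(rep(3L, 12)), 12)
  expect_true(all(out$data == 3L))
  # scar occupancy exactly half the wall -> scar (>= rule); brute-force
  # occupancy count as the oracle
  labs <- c(rep(3L, 6), rep(2L, 6))
  out <- downsample_throughplane(make_col(labs), 12)
  frac_scar_in_wall <- sum(labs == 3L) / sum(labs >= 2L)
  expect_gte(frac_scar_in_wall, 0.5)
  expect_true(all(out$data == 3L))
  # below the threshold -> myocardium
  labs <- c(rep(3L, 5), rep(2L, 7))
  out <- downsample_throughplane(make_col(labs), 12)
  expect_true(all(out$data == 2L))
  # majority across tissue classes, brute force over random columns
  set.seed(7)
  for (rep_i in 1:20) {
    labs <- sample(0:3, 12, replace = TRUE)
    out <- downsample_throughplane(make_col(labs), 12)
    n <- tabulate(labs + 1L, 4)
    wall <- n[3] + n[4]
    winner <- if (wall >= n[1] && wall >= n[2] && wall > 0) {
      if (n[4] >= 0.5 * wall) 3L else 2L
    } else if (n[2] >= n[1] && n[2] > wall) 1L else 0L
    expect_equal(unique(as.vector(out$data)), winner, info = paste(labs, collapse = ","))
  }
})

test_that("slab intensity averaging is the plain mean", {
  # slabs alternating 10 and 30 in equal measure average to 20
  img <- image_volume(array(rep(rep(c(10, 30), 12), each = 4),
                            c(2, 2, 24)), c(1, 1, 1))
  out <- downsample_throughplane(img, 12)
  expect_true(all(out$data == 20))
  # constant volume is invariant
  cimg <- image_volume(array(5, c(2, 2, 12)), c(1, 1, 1))
  expect_true(all(downsample_throughplane(cimg, 4)$data == 5))
})

test_that("upsampling identities and label closure", {
  ph <- small_annulus()
  # isotropic input at target spacing -> identity
  expect_identical(upsample_topologic(ph$labels, ph$labels$spacing[3]),
                   ph$labels)
  # a stack of identical slices reproduces the slice pattern everywhere
  thick <- downsample_throughplane(ph$labels, 4)
  up <- upsample_topologic(thick, 1)
  ref_slice <- thick$data[, , 2]
  for (k in seq_len(dim(up$data)[3]))
    expect_identical(up$data[, , k], ref_slice)
  expect_true(all(up$data %in% 0:3))
  expect_error(upsample_topologic(ph$labels, 2), "must not exceed")
})

test_that("upsampling preserves scar-in-wall nesting and wall connectivity", {
  ph <- small_ellipsoid()
  for (th in c(4, 8)) {
    up <- upsample_topologic(downsample_throughplane(ph$labels, th), 1)
    scar <- up$data == 3L
    wall <- up$data >= 2L
    expect_true(all(wall[scar]))  # scar is wall by construction
    comp <- scartrans:::conn_comp(wall)
    expect_equal(max(comp), 1L)   # single connected wall component
  }
})

test_that("downsample-upsample distortion shrinks with slice thickness", {
  ph <- small_ellipsoid()
  dices <- vapply(c(8, 4, 2), function(th) {
    up <- upsample_topologic(downsample_throughplane(ph$labels, th),
                             ph$labels$spacing[3])
    dice_on_common_slices(ph$labels, up, function(a) a >= 2L)
  }, numeric(1))
  expect_true(all(diff(dices) >= 0))  # 8 -> 4 -> 2 mm: non-decreasing
  expect_gt(dices[1], 0.9)
})

test_that("slice shift correction recovers injected shifts", {
  ph <- small_annulus()
  thick <- downsample_throughplane(ph$labels, 4)
  # zero injected shift -> identity to the voxel
  fixed <- correct_slice_shifts(thick)
  expect_identical(fixed$data, thick$data)

  # one slice shifted +3 voxels in x -> recovered -3 +- 1 voxel
  shifted <- thick$data
  k <- 2L
  d <- dim(shifted)
  new <- array(0L, d[1:2])
  new[4:d[1], ] <- shifted[seq_len(d[1] - 3), , k]
  shifted[, , k] <- new
  seg <- label_volume(shifted, thick$spacing, thick$origin)
  fixed <- correct_slice_shifts(seg)
  sh <- attr(fixed, "shifts")
  expect_true(abs(sh[k, 1] + 3) <= 1)
  expect_true(abs(sh[k, 2]) <= 1)

  # a common shift of all slices leaves relative alignment unchanged
  common <- thick$data
  for (kk in seq_len(d[3])) {
    new <- array(0L, d[1:2])
    new[3:d[1], ] <- thick$data[seq_len(d[1] - 2), , kk]
    common[, , kk] <- new
  }
  seg2 <- label_volume(common, thick$spacing, thick$origin)
  fixed2 <- correct_slice_shifts(seg2)
  expect_identical(fixed2$data, common)

  # with a reference epicardial mesh the absolute position is restored
  ref_mesh <- extract_surface(ph$labels, "epi")
  fixed3 <- correct_slice_shifts(seg, reference = ref_mesh)
  sh3 <- attr(fixed3, "shifts")
  expect_true(abs(sh3[k, 1] + 3) <= 1)
})

test_that("downsample validates thickness", {
  ph <- small_annulus()
  expect_error(downsample_throughplane(ph$labels, 0.5), "at least")
})
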
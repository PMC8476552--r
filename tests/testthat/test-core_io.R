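# Volume containers, NIfTI round trips, boundary classification and
# surface extraction.

test_that("NIfTI round trip preserves labels exactly and header spacing", {
  set.seed(42)
  lab <- array(sample(0:3, 16^3, replace = TRUE), c(16, 16, 16))
  vol <- label_volume(lab, spacing = c(1.5, 1.5, 8.0), origin = c(0, 0, 0))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "label")
  expect_identical(back$data, vol$data)
  expect_equal(back$spacing, c(1.5, 1.5, 8.0))

  img <- image_volume(array(rnorm(16^3), c(16, 16, 16)) + 10,
                      spacing = c(0.7, 0.7, 0.75))
  path2 <- tempfile(fileext = ".nii.gz")
  write_volume(img, path2)
  back2 <- read_volume(path2, "image")
  expect_equal(back2$spacing, c(0.7, 0.7, 0.75), tolerance = 1e-6)
  expect_equal(back2$data, img$data, tolerance = 1e-6)  # float32 storage
})

test_that("invalid label files and volumes are rejected with the code named", {
  lab <- array(0L, c(8, 8, 8))
  lab[4, 4, 4] <- 7L
  expect_error(label_volume(lab, c(1, 1, 1)), "7")

  img <- RNifti::asNifti(array(as.numeric(lab), c(8, 8, 8)))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path, "label"), "7")
  expect_error(read_volume(tempfile(fileext = ".nii"), "image"), "not found")
  expect_error(image_volume(array(c(NA, rnorm(63)), c(4, 4, 4)), c(1, 1, 1)),
               "finite")
  expect_error(image_volume(array(1, c(4, 4, 4)), c(1, 0, 1)), "positive")
})

test_that("classify_boundaries partitions the wall boundary", {
  # 1-voxel-thick hollow box of wall around blood: every wall voxel is
  # endo or epi, the sets are disjoint, nothing is left unclassified
  lab <- array(0L, c(8, 8, 8))
  lab[2:7, 2:7, 2:7] <- 2L
  lab[3:6, 3:6, 3:6] <- 1L
  seg <- label_volume(lab, c(1, 1, 1))
  bc <- suppressMessages(classify_boundaries(seg))
  wall_idx <- which(lab == 2L)
  expect_setequal(c(bc$endo_voxels, bc$epi_voxels, bc$cut_voxels), wall_idx)
  expect_length(intersect(bc$endo_voxels, bc$epi_voxels), 0)
  expect_length(intersect(bc$endo_voxels, bc$cut_voxels), 0)

  # every wall voxel with a non-wall face neighbour is in exactly one set
  ph <- small_annulus()
  bc2 <- classify_boundaries(ph$labels)
  wall <- ph$labels$data >= 2L
  boundary <- which(wall & (scartrans:::neighbor_any(ph$labels$data == 1L) |
                              scartrans:::neighbor_any(ph$labels$data == 0L)))
  insets <- c(bc2$endo_voxels, bc2$epi_voxels)
  expect_true(all(boundary %in% c(insets, bc2$cut_voxels)))
  expect_equal(anyDuplicated(c(bc2$endo_voxels, bc2$epi_voxels,
                               bc2$cut_voxels)), 0L)
})

test_that("annulus boundary voxels sit at the analytic radii", {
  ph <- small_annulus()
  bc <- classify_boundaries(ph$labels)
  R <- annulus_radius_array(ph)
  h <- ph$labels$spacing[1]
  expect_true(all(abs(R[bc$endo_voxels] - ph$truth$r_endo) < 1.5 * h))
  expect_true(all(abs(R[bc$epi_voxels] - ph$truth$r_epi) < 1.5 * h))
})

test_that("wall detached from blood raises a clear error", {
  lab <- array(0L, c(8, 8, 8))
  lab[2:4, 2:4, 2:4] <- 2L
  lab[7, 7, 7] <- 1L  # blood far away, no adjacency
  expect_error(classify_boundaries(label_volume(lab, c(1, 1, 1))),
               "no endocardial boundary")
  expect_error(classify_boundaries(label_volume(array(0L, c(4, 4, 4)) ,
                                                c(1, 1, 1))),
               "empty wall")
})

test_that("extracted sphere area matches the analytic value and converges", {
  errs <- vapply(c(1.0, 0.5), function(h) {
    mesh <- extract_surface(ball_volume(h), "endo")
    abs(mesh_area(mesh) / (4 * pi * 100) - 1)
  }, numeric(1))
  expect_lt(errs[1], 0.03)
  expect_lt(errs[2], 0.03)
  expect_lt(errs[2], errs[1])  # error shrinks as spacing halves
})

test_that("surface extraction is deterministic and sub-voxel accurate", {
  ph <- small_annulus()
  m1 <- extract_surface(ph$labels, "epi")
  m2 <- extract_surface(ph$labels, "epi")
  expect_identical(m1, m2)

  p <- vertex_polar(m1)
  lateral <- p$z > 1 & p$z < ph$truth$height - 1
  expect_true(all(abs(p$r[lateral] - ph$truth$r_epi) <
                    0.5 * ph$labels$spacing[1]))

  endo <- extract_surface(ph$labels, "endo")
  pe <- vertex_polar(endo)
  lateral_e <- pe$z > 1 & pe$z < ph$truth$height - 1
  expect_true(all(abs(pe$r[lateral_e] - ph$truth$r_endo) <
                    0.5 * ph$labels$spacing[1]))
  expect_error(extract_surface(label_volume(array(0L, c(4, 4, 4)),
                                            c(1, 1, 1)), "epi"),
               "empty mask")
})

test_that("PLY meshes round trip with per-vertex values", {
  ph <- small_annulus()
  mesh <- extract_surface(ph$labels, "epi")
  mesh$vertex_values <- seq_len(nrow(mesh$vertices)) / nrow(mesh$vertices)
  path <- tempfile(fileext = ".ply")
  write_ply(mesh, path)
  back <- read_ply(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$faces, mesh$faces)
  expect_equal(back$vertex_values, mesh$vertex_values, tolerance = 1e-6)
})
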
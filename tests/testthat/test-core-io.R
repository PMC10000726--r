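test_that("volume read/write round-trips data and geometry", {
  arr <- array(runif(16 * 16 * 8, 0, 100), c(16, 16, 8))
  vol <- mri_volume(arr, spacing = c(2, 2, 3), origin = c(5, -4, 10))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$data, vol$data, tolerance = 0)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("reader rejects malformed volumes", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(8, 8, 8, 3)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume(file.path(tempdir(), "no-such-file.nii.gz")),
               "not found")
  expect_error(mri_volume(array(0, c(4, 8, 8)), c(1, 1, 1)), "at least 8")
  expect_error(mri_volume(array(0, c(8, 8, 8)), c(1, -1, 1)), "spacing")
  expect_error(mri_volume(array(NA_real_, c(8, 8, 8)), c(1, 1, 1)), "finite")
})

test_that("phantom volumes obey the voxel-center origin convention", {
  ph <- small_phantom(0L)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$t2, f)
  back <- read_volume(f)
  expect_equal(as.numeric(voxel_to_world(c(0, 0, 0), back)), back$origin)
})

test_that("world/voxel transforms are exact mutual inverses", {
  vol <- mri_volume(array(0, c(16, 16, 8)), spacing = c(2, 2, 3),
                    origin = c(-10, 3, 7))
  expect_equal(as.numeric(world_to_voxel(vol$origin, vol)), c(0, 0, 0))
  expect_equal(as.numeric(world_to_voxel(c(-8, 7, 10), vol)), c(1, 2, 1))
  set.seed(42)
  p <- cbind(runif(100, -20, 40), runif(100, -20, 40), runif(100, -20, 40))
  expect_equal(voxel_to_world(world_to_voxel(p, vol), vol), p,
               tolerance = 1e-9)
})

test_that("marker files parse, validate and round-trip", {
  ph <- small_phantom(0L)
  f <- withr::local_tempfile(fileext = ".json")
  write_markers(ph$markers, f)
  ms <- read_markers(f, vol = ph$t2)
  expect_s3_class(ms, "marker_set")
  expect_equal(nrow(ms$anatomical), 5L)
  expect_equal(ms$anatomical$tag, boundary_tags_vec())
  expect_equal(as.matrix(ms$anatomical[, c("x", "y", "z")]),
               as.matrix(ph$markers$anatomical[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # 5 boundary + 2 intermediate points are permitted
  an7 <- rbind(ms$anatomical[1:2, ],
               data.frame(tag = "intermediate",
                          x = mean(ms$anatomical$x[2:3]),
                          y = mean(ms$anatomical$y[2:3]),
                          z = mean(ms$anatomical$z[2:3])),
               ms$anatomical[3:5, ],
               data.frame(tag = "intermediate", x = ms$anatomical$x[5],
                          y = ms$anatomical$y[5] + 1,
                          z = ms$anatomical$z[5]))
  expect_equal(nrow(marker_set(an7)$anatomical), 7L)
})

test_that("invalid marker sets are rejected with informative errors", {
  ph <- small_phantom(0L)
  an <- ph$markers$anatomical
  expect_error(marker_set(an[1:4, ]), "at least 5")
  an_dup <- an
  an_dup$tag[2] <- "cecum_start"
  expect_error(marker_set(an_dup), "exactly once")
  an_out <- an
  an_out$x[3] <- -500
  expect_error(marker_set(an_out, vol = ph$t2), "outside")
  an_swap <- an[c(2, 1, 3, 4, 5), ]
  expect_error(marker_set(an_swap), "order")
})

test_that("label volumes enforce the 0..4 label range", {
  expect_error(label_volume(array(5L, c(8, 8, 8)), c(1, 1, 1)), "0..4")
  lv <- label_volume(array(rep(0:3, 128), c(8, 8, 8)), c(1, 1, 1))
  expect_s3_class(lv, "label_volume")
})
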
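make_const_field <- function(d = c(5, 0, 0), dims = c(12, 12, 10),
                             spacing = c(2, 2, 3)) {
  deformation_field(array(d[1], dims), array(d[2], dims), array(d[3], dims),
                    spacing = spacing)
}

test_that("forward mapping handles identity and constant fields exactly", {
  z <- make_const_field(c(0, 0, 0))
  p <- c(5.2, 8.1, 12.7)
  expect_equal(map_t2_to_t1fs(p, z), p)
  f <- make_const_field(c(5, 0, 0))
  expect_equal(map_t2_to_t1fs(p, f), p + c(5, 0, 0))
  expect_error(map_t2_to_t1fs(c(1e4, 0, 0), f), "domain")
})

test_that("inverse mapping solves constant fields in one step and round-trips",
          {
  f <- make_const_field(c(5, 0, 0))
  p <- c(6, 7, 8)
  q <- p + c(5, 0, 0)
  expect_equal(map_t1fs_to_t2(q, f), p, tolerance = 1e-12)
  z <- make_const_field(c(0, 0, 0))
  expect_equal(map_t1fs_to_t2(p, z), p)
})

test_that("phantom truth field matches the analytic bump sum", {
  ph <- small_phantom(0L)
  fld <- ph$field_truth
  set.seed(5)
  pts <- colonmri:::random_field_points(fld, 100L)
  interp <- colonmri:::cpp_field_at(fld$dx, fld$dy, fld$dz, dim(fld$dx),
                                    fld$spacing, fld$origin, pts)
  analytic <- colonmri:::bumps_displacement(fld, pts)
  err <- sqrt(rowSums((interp - analytic)^2))
  expect_lt(max(err), 0.1)
})

test_that("forward-then-inverse round-trip residual is below 0.1 mm", {
  for (seed in 0:2) {
    fld <- small_phantom(seed)$field_truth
    set.seed(17)
    pts <- colonmri:::random_field_points(fld, 1000L)
    fwd <- map_t2_to_t1fs(pts, fld)
    back <- map_t1fs_to_t2(fwd, fld)
    res <- sqrt(rowSums((back - pts)^2))
    expect_lt(mean(res), 0.1)
    expect_gt(mean(res < 0.1), 0.99)
  }
})

test_that("corresponding_slice composes lift, map and projection", {
  ph <- small_phantom(1L)
  fld <- ph$field_truth
  res <- corresponding_slice(3L, 10L, c(20.3, 31.8), ph$t2, ph$t1fs, fld,
                             "t2_to_t1fs")
  # manual three-step composition
  p <- voxel_to_world(c(20.3, 31.8, 10), ph$t2)
  q <- map_t2_to_t1fs(p, fld)
  v <- world_to_voxel(q, ph$t1fs)
  expect_equal(res$slice_index, as.integer(round(v[3])))
  expect_equal(res$cursor, v[1:2], tolerance = 1e-9)
  expect_equal(res$point_mm, q, tolerance = 1e-9)
})

test_that("identity field keeps the slice and cursor; constant shift moves slices",
          {
  ph <- small_phantom(1L, n_bumps = 0)
  z <- ph$field_truth
  res <- corresponding_slice(3L, 7L, c(12, 14), ph$t2, ph$t1fs, z,
                             "t2_to_t1fs")
  expect_equal(res$slice_index, 7L)
  expect_equal(res$cursor, c(12, 14))
  expect_true(res$in_view)
  # 6 mm displacement along a 3 mm-spaced axis shifts by 2 slices
  dims <- dim(ph$t2$data)
  f6 <- deformation_field(array(0, dims), array(0, dims), array(6, dims),
                          spacing = ph$t2$spacing)
  res6 <- corresponding_slice(3L, 7L, c(12, 14), ph$t2, ph$t1fs, f6,
                              "t2_to_t1fs")
  expect_equal(res6$slice_index, 9L)
  # far out-of-view mapping is flagged, not an exception
  fbig <- deformation_field(array(0, dims), array(0, dims), array(500, dims),
                            spacing = ph$t2$spacing)
  resb <- corresponding_slice(3L, 7L, c(12, 14), ph$t2, ph$t1fs, fbig,
                              "t2_to_t1fs")
  expect_false(resb$in_view)
})

test_that("feces pocket centers correspond across spaces through the truth field",
          {
  ph <- small_phantom(2L)
  # take a voxel deep inside a feces pocket in T1-FS, map back to T2: the
  # preimage must lie inside the T2 colon mask
  dims <- dim(ph$content_truth)
  ed <- colonmri:::cpp_edt(array(as.integer(ph$content_truth != 2L), dims),
                           dims, ph$t1fs$spacing)
  ctr <- which.max(ed$dist)
  vox <- arrayInd(ctr, dims) - 1L
  q <- voxel_to_world(as.numeric(vox), ph$t1fs)
  p <- map_t1fs_to_t2(q, ph$field_truth)
  lab <- colonmri:::cpp_sample_nearest(ph$mask_t2$labels, dims,
                                       ph$mask_t2$spacing, ph$mask_t2$origin,
                                       matrix(p, 1), 0L)
  expect_gt(lab, 0L)
})

test_that("field NIfTI round-trip preserves displacements and geometry", {
  fld <- small_phantom(0L)$field_truth
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_field(fld, f)
  back <- read_field(f)
  expect_equal(back$dx, fld$dx, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$dz, fld$dz, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, fld$spacing, tolerance = 1e-6)
})
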
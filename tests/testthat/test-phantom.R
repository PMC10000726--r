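test_that("phantom generation is deterministic given the spec", {
  a <- generate_phantom(small_spec(seed = 3L))
  b <- generate_phantom(small_spec(seed = 3L))
  expect_identical(a$t2$data, b$t2$data)
  expect_identical(a$t1fs$data, b$t1fs$data)
  expect_identical(a$mask_t2$labels, b$mask_t2$labels)
  expect_identical(attr(a$field_truth, "bumps"), attr(b$field_truth, "bumps"))
})

test_that("zero deformation makes both spaces identical", {
  ph <- small_phantom(2L, n_bumps = 0)
  expect_identical(ph$mask_t2$labels, ph$mask_t1fs$labels)
  mag <- sqrt(ph$field_truth$dx^2 + ph$field_truth$dy^2 +
                ph$field_truth$dz^2)
  expect_equal(max(mag), 0)
})

test_that("cylinder volume matches the oversampled rasterization oracle", {
  ph <- cylinder_phantom()
  n_col <- sum(ph$mask_t2$labels > 0)
  r <- 10
  L <- 200
  analytic <- pi * r^2 * L # mm^3 at 1 mm iso => voxel count

  # 5x oversampled rasterization: voxels definitely inside are counted
  # directly; anything within half a voxel diagonal of the side wall or the
  # flat end caps is subsampled
  pl <- colonmri:::cpp_grid_polyline(dim(ph$mask_t2$labels), ph$t2$spacing,
                                     ph$t2$origin, ph$path_truth$points,
                                     ph$path_truth$arc_length)
  hd <- sqrt(sum(ph$t2$spacing^2)) / 2
  dims <- dim(ph$mask_t2$labels)
  z <- ph$t2$origin[3] +
    (slice.index(array(0, dims), 3) - 1) * ph$t2$spacing[3]
  z0 <- min(ph$path_truth$points[, 3])
  z1 <- max(ph$path_truth$points[, 3])
  def_inside <- pl$dist <= r - hd & z > z0 + hd & z < z1 - hd
  maybe <- which(pl$dist < r + hd & !def_inside &
                   z > z0 - hd & z < z1 + hd)
  sub <- seq(-0.4, 0.4, by = 0.2)
  offs <- as.matrix(expand.grid(sub, sub, sub))
  vox <- arrayInd(maybe, dims) - 1L
  frac <- numeric(length(maybe))
  for (oi in seq_len(nrow(offs))) {
    pts <- voxel_to_world(sweep(vox, 2, offs[oi, ], "+"), ph$t2)
    dd <- colonmri:::cpp_points_polyline(pts, ph$path_truth$points,
                                         ph$path_truth$arc_length)
    frac <- frac + (dd$dist <= r & dd$interior)
  }
  oracle <- sum(def_inside) + sum(frac) / nrow(offs)
  expect_lt(abs(n_col - analytic) / analytic, 0.02)
  expect_lt(abs(n_col - oracle) / oracle, 0.01)
})

test_that("tissue-intensity orderings hold in the noiseless rendering", {
  ph <- small_phantom(1L, noise_sigma = c(t2 = 0, t1fs = 0))
  colon <- ph$mask_t2$labels > 0
  t2 <- ph$t2$data
  # all colon voxels darker than background tissue mean in T2
  expect_true(all(t2[colon] < 100))
  # content semantics in T1-FS
  t1 <- ph$t1fs$data
  expect_true(all(t1[ph$content_truth == 2L] >
                    t1[ph$content_truth == 1L][1]))
  expect_setequal(unique(as.vector(t1[ph$content_truth == 1L])), 20)
  expect_setequal(unique(as.vector(t1[ph$content_truth == 2L])), 210)
})

test_that("content pockets partition the colon interior", {
  ph <- small_phantom(0L)
  inside <- ph$mask_t1fs$labels > 0
  expect_true(all(ph$content_truth[inside] %in% c(1L, 2L)))
  expect_true(all(ph$content_truth[!inside] == 0L))
})

test_that("truth markers lie on the truth path with ordered boundary tags", {
  ph <- small_phantom(0L)
  expect_equal(ph$markers$anatomical$tag, boundary_tags_vec())
  pts <- as.matrix(ph$markers$anatomical[, c("x", "y", "z")])
  pl <- colonmri:::cpp_points_polyline(pts, ph$path_truth$points,
                                       ph$path_truth$arc_length)
  expect_true(all(pl$dist < 1e-6))
  expect_true(all(diff(pl$arc) > 0))
})

test_that("mask_t1fs is mask_t2 pushed through the truth field", {
  ph <- small_phantom(4L)
  # map each T1-FS colon voxel center back to T2: preimage must be in mask_t2
  dims <- dim(ph$mask_t1fs$labels)
  sel <- which(ph$mask_t1fs$labels > 0L)
  vox <- arrayInd(sel, dims) - 1L
  pts <- voxel_to_world(vox, ph$mask_t1fs)
  pre <- colonmri:::bumps_preimage(ph$field_truth, pts)
  lab <- colonmri:::cpp_sample_nearest(ph$mask_t2$labels, dims,
                                       ph$mask_t2$spacing,
                                       ph$mask_t2$origin, pre, 0L)
  # agreement up to voxelization: disagreements are rare and confined to a
  # one-voxel layer at the tube boundary
  dis <- lab == 0L
  expect_lt(mean(dis), 0.1)
  if (any(dis)) {
    ed <- colonmri:::cpp_edt(array(as.integer(ph$mask_t2$labels > 0L), dims),
                             dims, ph$mask_t2$spacing)
    d_at <- colonmri:::cpp_sample_trilinear(ed$dist, dims,
                                            ph$mask_t2$spacing,
                                            ph$mask_t2$origin,
                                            pre[dis, , drop = FALSE], 0, TRUE)
    expect_lt(max(d_at), sqrt(sum(ph$t2$spacing^2)))
  }
})

test_that("sampled deformation fields respect the amplitude bound and invert",
          {
  spec <- small_spec(seed = 5L, n_bumps = 1, bump_amplitude = 5)
  fld <- sample_field(spec)
  mag <- sqrt(fld$dx^2 + fld$dy^2 + fld$dz^2)
  expect_lte(max(mag), 5 + 1e-9)
  chk <- check_invertibility(fld, n = 1000L, seed = 1L)
  expect_true(chk$ok)
  expect_lt(chk$mean_residual, 0.05)

  # invalid amplitude/scale combinations are rejected
  expect_error(phantom_spec(n_bumps = 3, bump_amplitude = 40,
                            bump_scale = 20), "invertibility")
  expect_error(phantom_spec(radius_mean = 5, radius_amp = 0,
                            spacing = c(3, 3, 3)), "resolvable")
})
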
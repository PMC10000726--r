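# registration and T1-FS adaptation: recovery contracts on phantoms.
# registration tests run on the small phantom scale to stay fast; the
# acceptance suite exercises the default scale.

reg_small <- function(ph) {
  suppressWarnings(register_t2_to_t1fs(ph$t2, ph$t1fs))
}

test_that("registering a volume to itself yields a near-zero field", {
  ph <- small_phantom(0L, n_bumps = 0)
  f <- suppressWarnings(register_t2_to_t1fs(ph$t2, ph$t2))
  mag <- sqrt(f$dx^2 + f$dy^2 + f$dz^2)
  expect_lt(mean(mag), 0.5 * min(ph$t2$spacing))
})

test_that("zero-deformation cross-modality pair recovers a sub-voxel field", {
  ph <- small_phantom(1L, n_bumps = 0)
  f <- reg_small(ph)
  mag <- sqrt(f$dx^2 + f$dy^2 + f$dz^2)
  expect_lt(mean(mag), min(ph$t2$spacing))
})

test_that("a pure translation is recovered to within 1.5 mm mean error", {
  ph <- small_phantom(1L, n_bumps = 1, bump_amplitude = 5,
                      bump_scale = 1e4)
  f <- reg_small(ph)
  gp <- colonmri:::grid_points(ph$t2)
  tm <- colonmri:::bumps_displacement(ph$field_truth, gp)
  err <- sqrt((as.vector(f$dx) - tm[, 1])^2 +
                (as.vector(f$dy) - tm[, 2])^2 +
                (as.vector(f$dz) - tm[, 3])^2)
  expect_lt(mean(err), 1.5)
})

test_that("degenerate constant images are rejected", {
  flat <- mri_volume(array(5, c(16, 16, 8)), c(2, 2, 3))
  ph <- small_phantom(0L)
  expect_error(suppressWarnings(register_t2_to_t1fs(flat, ph$t1fs)),
               "degenerate")
})

test_that("content probability separates gas and feces and is monotone", {
  ph <- small_phantom(0L)
  cp <- build_content_probability(ph$t1fs, ph$mask_t1fs$labels > 0L)
  expect_lt(cp$posterior(20), 0.1)
  expect_gt(cp$posterior(210), 0.9)
  xs <- seq(min(ph$t1fs$data), max(ph$t1fs$data), length.out = 200)
  expect_true(all(diff(cp$posterior(xs)) >= -1e-9))
  expect_true(all(cp$prob >= 0 & cp$prob <= 1))
  expect_error(build_content_probability(ph$t1fs, array(0, dim(ph$t1fs$data))),
               "fewer than 50")
})

test_that("n_max = 0 reduces adaptation to the pure transfer", {
  ph <- small_phantom(0L)
  seg2 <- assign_segments(ph$mask_t2, ph$path_truth)
  out <- adapt_colon_to_t1fs(seg2, ph$field_truth, ph$t1fs,
                             adapt_config(n_max = 0L))
  tr <- transfer_labels(seg2, ph$field_truth, ph$t1fs)
  expect_identical(out$labels, tr$labels)
})

test_that("adaptation with the truth field reaches DSC >= 0.90 and stays in its corridor",
          {
  ph <- small_phantom(0L)
  seg2 <- assign_segments(ph$mask_t2, ph$path_truth)
  cfg <- adapt_config()
  out <- adapt_colon_to_t1fs(seg2, ph$field_truth, ph$t1fs, cfg)
  expect_gte(dice(out, ph$mask_t1fs), 0.90)
  # corridor bound: no adapted voxel farther than corridor + 1 voxel
  # diagonal from the transferred mask
  tr <- attr(out, "transferred")$labels > 0L
  dims <- dim(tr)
  ed <- colonmri:::cpp_edt(array(as.integer(tr), dims), dims,
                           ph$t1fs$spacing)
  diag_vox <- sqrt(sum(ph$t1fs$spacing^2))
  expect_lte(max(ed$dist[out$labels > 0L]), cfg$corridor + diag_vox)
})

test_that("uniform content probability of 0.5 leaves the transferred surface",
          {
  ph <- small_phantom(2L)
  seg2 <- assign_segments(ph$mask_t2, ph$path_truth)
  # a volume whose in-mask mixture sees two modes, then flattened: emulate
  # by intercepting with a constant-probability image: half gas, half feces
  # exactly balanced is impractical; instead test the speed law directly
  # via an adaptation on a synthetic probability plateau
  tr <- transfer_labels(seg2, ph$field_truth, ph$t1fs)
  mask0 <- tr$labels > 0L
  phi0 <- colonmri:::signed_distance(mask0, ph$t1fs$spacing)
  # with prob = 0.5 everywhere, speed = 0: one smoothing + clamp iteration
  # cannot move the zero level by more than one voxel
  dims <- dim(mask0)
  prob <- array(0.5, dims)
  phi <- phi0
  g <- 0.5 * phi + 0.5 * colonmri:::cpp_gauss3d(phi, dims, rep(0.7, 3))
  g <- pmax(g, phi0 - 6)
  g <- pmin(g, phi0)
  moved <- xor(g < 0, phi0 < 0)
  if (any(moved)) {
    ed <- colonmri:::cpp_edt(array(as.integer(mask0), dims), dims,
                             ph$t1fs$spacing)
    edo <- colonmri:::cpp_edt(array(as.integer(!mask0), dims), dims,
                              ph$t1fs$spacing)
    expect_lte(max(pmax(ed$dist[moved], edo$dist[moved])),
               sqrt(sum(ph$t1fs$spacing^2)))
  } else succeed()
})

test_that("adapted volume grows monotonically with corridor width", {
  ph <- small_phantom(3L)
  seg2 <- assign_segments(ph$mask_t2, ph$path_truth)
  vols <- vapply(c(2, 4, 6), function(cw) {
    out <- adapt_colon_to_t1fs(seg2, ph$field_truth, ph$t1fs,
                               adapt_config(corridor = cw))
    sum(out$labels > 0L)
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("full small-scale pipeline contains most ground-truth feces", {
  ph <- small_phantom(0L)
  seg2 <- segment_t2(ph$t2, ph$markers)
  f <- reg_small(ph)
  out <- adapt_colon_to_t1fs(seg2, f, ph$t1fs)
  expect_gte(containment_r(ph$content_truth == 2L, out), 90)
})
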
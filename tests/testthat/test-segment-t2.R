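# marker-guided T2 segmentation: correctness on phantoms, hard constraints,
# segment labeling and refinement behavior

test_that("noiseless phantom is segmented nearly perfectly", {
  ph <- small_phantom(0L, noise_sigma = c(t2 = 0, t1fs = 0))
  seg <- segment_t2(ph$t2, ph$markers)
  expect_gte(dice(seg, ph$mask_t2), 0.95)
})

test_that("segmentation satisfies its hard constraints and connectivity", {
  ph <- small_phantom(1L)
  seg <- segment_t2(ph$t2, ph$markers)
  mask <- seg$labels > 0L
  # contains every anatomical marker voxel
  mk <- round(world_to_voxel(as.matrix(
    ph$markers$anatomical[, c("x", "y", "z")]), ph$t2)) + 1L
  expect_true(all(mask[mk]))
  # nothing beyond 3 * r0 from the path
  model <- attr(seg, "tissue_probability")
  expect_true(all(model$dist[mask] <= 3 * model$r0 + 1e-9))
  # single 26-connected component
  comp <- colonmri:::cpp_components26(array(as.integer(mask), dim(mask)),
                                      dim(mask))
  expect_equal(max(comp), 1L)
})

test_that("multigrid and single-grid cuts agree away from the boundary", {
  ph <- small_phantom(2L)
  cfg_m <- t2seg_config(multigrid = TRUE)
  cfg_s <- t2seg_config(multigrid = FALSE)
  seg_m <- segment_t2(ph$t2, ph$markers, cfg_m)
  seg_s <- segment_t2(ph$t2, ph$markers, cfg_s)
  expect_gte(dice(seg_m, seg_s), 0.98)
})

test_that("graph-cut labeling energy does not exceed trivial labelings", {
  # small single-grid instance so the energy is directly computable
  ph <- small_phantom(0L)
  path <- ph$path_truth
  model <- build_probability_model(ph$t2, path, r0 = 15)
  cfg <- t2seg_config(multigrid = FALSE)
  dims <- dim(ph$t2$data)
  vars <- model$dist <= 3 * 15
  var_id <- array(0L, dims)
  var_id[vars] <- seq_len(sum(vars))
  adj <- colonmri:::grid_adjacency(var_id, ph$t2$data, ph$t2$spacing)
  sigma_c <- median(abs(adj$dI))
  w <- colonmri:::contrast_weights(adj$dI, adj$len, cfg$lambda, sigma_c)
  p <- pmin(pmax(model$prob[vars], 0), 1)
  cost_fg <- colonmri:::neglog(p)
  cost_bg <- colonmri:::neglog(1 - p)
  fg <- colonmri:::solve_mincut(cost_fg, cost_bg, adj$edges, w)
  e <- colonmri:::cut_energy(fg, cost_fg, cost_bg, adj$edges, w)
  n <- length(cost_fg)
  expect_lte(e, colonmri:::cut_energy(rep(TRUE, n), cost_fg, cost_bg,
                                      adj$edges, w))
  expect_lte(e, colonmri:::cut_energy(rep(FALSE, n), cost_fg, cost_bg,
                                      adj$edges, w))
})

test_that("segment labels partition the mask into the four named segments", {
  ph <- small_phantom(0L)
  seg <- segment_t2(ph$t2, ph$markers)
  expect_setequal(unique(as.vector(seg$labels[seg$labels > 0L])), 1:4)
  # straight tube with boundaries at quarter arc: near-equal partition
  cyl <- cylinder_phantom()
  seg_c <- assign_segments(cyl$mask_t2, cyl$path_truth)
  counts <- tabulate(seg_c$labels[seg_c$labels > 0L], 4L)
  expect_true(all(abs(counts / sum(counts) - 0.25) < 0.025))
})

test_that("nearest-path-point ties resolve to the lower segment index", {
  # two-segment path where a voxel is exactly equidistant to the boundary
  # vertex shared by segments: label must be the lower one
  pts <- cbind(seq(2, 42, by = 2), 10, 10)
  path <- medial_path(pts, c(1L, 6L, 11L, 16L, 21L))
  mask <- array(0L, c(23, 10, 10))
  mask[, 5:6, 5:6] <- 1L
  lv <- label_volume(mask, c(2, 2, 2), space = "T2")
  seg <- assign_segments(lv, path)
  # voxel at x index of the shared boundary vertex (arc 12 -> vertex 6)
  boundary_x <- 6L
  labs <- seg$labels[boundary_x, 5:6, 5:6]
  expect_true(all(labs == 1L))
})

test_that("refinement with no markers is the identity", {
  ph <- small_phantom(0L)
  seg <- segment_t2(ph$t2, ph$markers)
  out <- apply_refinement(ph$t2, seg, ph$markers)
  expect_identical(out$labels, seg$labels)
})

test_that("exclude markers carve their voxel out; include markers add theirs",
          {
  ph <- small_phantom(3L)
  seg <- segment_t2(ph$t2, ph$markers)
  truth_dsc <- dice(seg, ph$mask_t2)
  # exclude: a segmented voxel near the colon boundary
  mask <- seg$labels > 0L
  dims <- dim(mask)
  model <- attr(seg, "tissue_probability")
  cand <- which(mask & model$dist > 8)
  ex_vox <- arrayInd(cand[1], dims) - 1L
  ex_mm <- voxel_to_world(as.numeric(ex_vox), ph$t2)
  # include: a truth colon voxel (guaranteed colon) not in the segmentation,
  # or any truth voxel if the segmentation is already complete
  miss <- which(ph$mask_t2$labels > 0L & !mask)
  inc_idx <- if (length(miss)) miss[1] else which(ph$mask_t2$labels > 0L)[1]
  inc_mm <- voxel_to_world(as.numeric(arrayInd(inc_idx, dims) - 1L), ph$t2)
  ms <- marker_set(ph$markers$anatomical,
                   data.frame(polarity = c("exclude", "include"),
                              x = c(ex_mm[1], inc_mm[1]),
                              y = c(ex_mm[2], inc_mm[2]),
                              z = c(ex_mm[3], inc_mm[3])))
  out <- apply_refinement(ph$t2, seg, ms)
  expect_equal(out$labels[matrix(ex_vox + 1L, 1)], 0L)
  expect_gt(out$labels[inc_idx], 0L)
  # adding a correct include constraint must not hurt accuracy
  expect_gte(dice(out, ph$mask_t2) + 1e-6, truth_dsc - 0.01)

  # refinement marker outside the volume errors
  bad <- marker_set(ph$markers$anatomical,
                    data.frame(polarity = "include", x = -999, y = 0, z = 0))
  expect_error(apply_refinement(ph$t2, seg, bad), "outside")
})

test_that("marker jitter leaves accuracy largely intact", {
  s <- evaluate_phantom_suite(
    n = 1L, base_seed = 3L,
    spec_args = list(shape = c(64, 64, 44), spacing = c(2.5, 2.5, 3),
                     radius_mean = 11, radius_amp = 2),
    jitter_sd = 3, use_truth_field = TRUE)
  expect_gte(s$dsc_mean, 0.85)
})
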
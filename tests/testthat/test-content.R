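test_that("two-point intensity sets split exactly into gas and solid", {
  vol <- mri_volume(array(c(rep(5, 256), rep(200, 256)), c(8, 8, 8)),
                    spacing = c(1, 1, 1), modality = "T1FS")
  seg <- label_volume(array(1L, c(8, 8, 8)), c(1, 1, 1), space = "T1FS")
  cm <- classify_content(vol, seg, k = 2L)
  expect_equal(cm$centroids, c(5, 200))
  expect_equal(cm$class_names, c("gas", "solid"))
  expect_equal(cm$solid_fraction, c(0, 1))
  expect_true(all(cm$classes[vol$data == 5] == 1L))
  expect_true(all(cm$classes[vol$data == 200] == 2L))
  expect_equal(cm$sse, 0)
})

test_that("k-means attains the sorted-split exact optimum on random sets", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    k <- sample(2:3, 1)
    x <- switch(sample(3, 1),
                runif(n, 0, 255),
                c(rnorm(n %/% 2, 40, 12), rnorm(n - n %/% 2, 180, 25)),
                sample(0:40, n, replace = TRUE))
    if (length(unique(x)) < k) next
    ux <- sort(unique(x))
    w <- tabulate(match(x, ux), length(ux))
    km <- colonmri:::cpp_kmeans1d(ux, w, k)
    expect_equal(km$sse, split_enum_kmeans(x, k), tolerance = 1e-8)
  }
})

test_that("degenerate and invalid clustering inputs error", {
  vol <- mri_volume(array(7, c(8, 8, 8)), c(1, 1, 1), modality = "T1FS")
  seg <- label_volume(array(1L, c(8, 8, 8)), c(1, 1, 1), space = "T1FS")
  expect_error(classify_content(vol, seg, k = 3L), "degenerate")
  empty <- label_volume(array(0L, c(8, 8, 8)), c(1, 1, 1), space = "T1FS")
  expect_error(classify_content(vol, empty), "empty")
})

test_that("gas is always the lowest centroid and solid the highest", {
  ph <- small_phantom(0L)
  cm <- classify_content(ph$t1fs, ph$mask_t1fs, k = 3L)
  expect_true(all(diff(cm$centroids) > 0))
  expect_equal(cm$class_names[c(1, 3)], c("gas", "solid"))
  expect_equal(cm$solid_fraction[1], 0)
  expect_equal(cm$solid_fraction[3], 1)
  expect_true(cm$solid_fraction[2] >= 0 && cm$solid_fraction[2] <= 1)
  # phantom gas voxels should overwhelmingly fall in the gas cluster
  gas_truth <- ph$content_truth == 1L
  expect_gt(mean(cm$classes[gas_truth] == 1L), 0.9)
})

test_that("volumes follow unit arithmetic and conserve the total", {
  dims <- c(10, 10, 10)
  seg <- array(0L, dims)
  seg[1:10, 1:10, 1:10] <- 1L
  seg_lv <- label_volume(seg, c(1, 1, 1), space = "T1FS")
  vals <- array(200, dims)
  vol <- mri_volume(vals, c(1, 1, 1), modality = "T1FS")
  vals2 <- vals
  vals2[1:5, , ] <- 5 # half gas
  vol2 <- mri_volume(vals2, c(1, 1, 1), modality = "T1FS")
  cm <- classify_content(vol2, seg_lv, k = 2L)
  vols <- quantify_content(cm, seg_lv)
  expect_equal(vols$gas_ml[vols$segment == "total"], 0.5)
  expect_equal(vols$solid_ml[vols$segment == "total"], 0.5)
  expect_equal(vols$total_ml[vols$segment == "total"], 1.0)
  # conservation across classes and segments
  expect_lt(abs(sum(vols$total_ml[1:4]) - vols$total_ml[5]), 1e-6)

  ph <- small_phantom(1L)
  cm <- classify_content(ph$t1fs, ph$mask_t1fs)
  v <- quantify_content(cm, ph$mask_t1fs)
  class_sum <- v$gas_ml + v$mixed_ml + v$solid_ml
  expect_true(all(abs(class_sum - v$total_ml) < 1e-6))
})

test_that("empty segments report zero volume", {
  dims <- c(8, 8, 8)
  seg <- array(0L, dims)
  seg[3:6, 3:6, 3:6] <- 2L # only transverse
  seg_lv <- label_volume(seg, c(1, 1, 1), space = "T1FS")
  vol <- mri_volume(array(runif(512, 0, 255), dims), c(1, 1, 1),
                    modality = "T1FS")
  cm <- classify_content(vol, seg_lv, k = 2L)
  v <- quantify_content(cm, seg_lv)
  expect_equal(v$total_ml[v$segment == "ascending"], 0)
  expect_equal(v$total_ml[v$segment == "transverse"], 64 / 1000)
})

test_that("cylinder morphology recovers analytic length, radius, perimeter", {
  ph <- cylinder_phantom()
  path <- estimate_medial_path(ph$t2, ph$markers)
  morph <- compute_morphology(ph$mask_t2, path)
  tot <- morph[morph$segment == "total", ]
  expect_lt(abs(tot$length_mm - 200) / 200, 0.02)
  expect_lt(abs(tot$mean_radius_mm - 10) / 10, 0.05)
  expect_lt(abs(tot$mean_perimeter_mm - 2 * pi * 10) / (2 * pi * 10), 0.05)
})

test_that("morphology scales linearly with tube radius", {
  sp <- cylinder_spec(radius = 10, length_mm = 120, spacing = c(1.5, 1.5, 2))
  sp2 <- cylinder_spec(radius = 20, length_mm = 120, spacing = c(1.5, 1.5, 2),
                       margin = 34)
  m1 <- compute_morphology(generate_phantom(sp)$mask_t2,
                           generate_phantom(sp)$path_truth)
  m2 <- compute_morphology(generate_phantom(sp2)$mask_t2,
                           generate_phantom(sp2)$path_truth)
  r1 <- m1$mean_radius_mm[m1$segment == "total"]
  r2 <- m2$mean_radius_mm[m2$segment == "total"]
  expect_lt(abs(r2 / r1 - 2), 0.1)
})

test_that("morphology rejects degenerate paths and empty intersections", {
  ph <- cylinder_phantom()
  expect_error(medial_path(ph$path_truth$points[1, , drop = FALSE], 1L),
               "at least 2")
  # a path nowhere near the mask: all stations skipped
  far <- medial_path(cbind(c(1, 2, 3, 4, 5), 1, 1), 1:5)
  expect_error(suppressWarnings(compute_morphology(ph$mask_t2, far)),
               "stations skipped")
})
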
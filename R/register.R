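#' Configuration for T2 to T1-FS non-rigid registration
#'
#' @param levels downsampling factors of the multiresolution pyramid, coarse
#'   to fine.
#' @param iterations per-level iteration counts (same length as `levels`).
#' @param sigma_fluid Gaussian smoothing (voxels) of each incremental update.
#' @param sigma_diff Gaussian smoothing (voxels) of the accumulated field
#'   (displacement-smoothness regularization).
#' @param step maximum displacement update per iteration (mm).
#' @param translation_range half-range (mm) of the initial translation grid
#'   search.
#' @param mi_bins histogram bins of the mutual-information translation search.
#' @param descriptor_sigma patch scale (voxels) of the self-similarity
#'   descriptor.
#' @return A named list of class `reg_config`.
#' @export
reg_config <- function(levels = c(4L, 2L, 1L),
                       iterations = c(30L, 20L, 5L),
                       sigma_fluid = 2.0, sigma_diff = 3.0, step = 2.0,
                       translation_range = 16, mi_bins = 32L,
                       descriptor_sigma = 1.0) {
  structure(list(levels = as.integer(levels),
                 iterations = as.integer(iterations),
                 sigma_fluid = sigma_fluid, sigma_diff = sigma_diff,
                 step = step, translation_range = translation_range,
                 mi_bins = as.integer(mi_bins),
                 descriptor_sigma = descriptor_sigma),
            class = "reg_config")
}

#' Non-rigid registration from T2 to T1-FS space
#'
#' Computes the dense displacement field realizing the T2 to T1-FS spatial
#' correspondence `p -> p + d(p)`. Because the two modalities have opposite
#' tissue contrasts, the similarity is computed on modality-independent
#' self-similarity descriptors (six-neighborhood patch distances, MIND-style)
#' rather than raw intensities. The field is estimated by a three-level
#' multiresolution free-form scheme: demons-type descriptor-matching forces
#' with Gaussian fluid/diffusion regularization of the displacement field,
#' composed with an initial translation-only alignment found by maximizing
#' mutual information over a translation grid.
#'
#' @param t2 fixed T2 [mri_volume()].
#' @param t1fs moving T1-FS [mri_volume()].
#' @param config a [reg_config()].
#' @return A [deformation_field()] on the T2 grid (displacements in mm).
#'   Attribute `"converged"` is FALSE when the final-level mean update still
#'   exceeded tolerance.
#' @export
register_t2_to_t1fs <- function(t2, t1fs, config = reg_config()) {
  validate_volume(t2)
  validate_volume(t1fs)
  if (sd(t2$data) < 1e-12 || sd(t1fs$data) < 1e-12)
    stop("degenerate (constant) image cannot be registered", call. = FALSE)
  f2 <- normalize_robust(t2$data)
  f1 <- normalize_robust(t1fs$data)

  shift <- mi_translation(f2, t2, f1, t1fs, config)

  dims <- dim(t2$data)
  field <- NULL # displacement arrays at current level
  converged <- TRUE
  for (li in seq_along(config$levels)) {
    f <- config$levels[li]
    lv2 <- downsample_volume(f2, t2, f)
    lv1 <- downsample_volume(f1, t1fs, f)
    # denoise before the self-similarity descriptors: in texture-free tissue
    # raw noise masquerades as structure and makes the demons forces drift
    lv2$data <- cpp_gauss3d(lv2$data, dim(lv2$data), rep(1, 3))
    lv1$data <- cpp_gauss3d(lv1$data, dim(lv1$data), rep(1, 3))
    fx <- mind_channels(lv2$data, config$descriptor_sigma)
    mv <- mind_channels(lv1$data, config$descriptor_sigma)
    if (is.null(field)) {
      z <- array(0, dim(lv2$data))
      field <- list(dx = z + shift[1], dy = z + shift[2], dz = z + shift[3],
                    spacing = lv2$spacing, origin = lv2$origin)
    } else {
      field <- resample_field(field, lv2)
    }
    res <- demons_level(fx, mv, lv2, lv1, field, config,
                        iters = config$iterations[li])
    field <- res$field
    if (li == length(config$levels)) converged <- res$converged
  }
  if (!all(dim(field$dx) == dims)) {
    stub <- list(data = array(0, dims), spacing = t2$spacing,
                 origin = t2$origin)
    field <- resample_field(field, stub)
  }
  if (!converged)
    warning("registration did not fully converge within max iterations; ",
            "returning best field", call. = FALSE)
  out <- deformation_field(field$dx, field$dy, field$dz, t2$spacing,
                           t2$origin)
  attr(out, "converged") <- converged
  out
}

# block-average pyramid level: smooth then resample on a coarser grid
downsample_volume <- function(data, geom, factor) {
  dims <- dim(data)
  if (factor <= 1L)
    return(list(data = data, spacing = geom$spacing, origin = geom$origin))
  sm <- cpp_gauss3d(data, dims, rep(factor / 2, 3))
  dims_c <- pmax(ceiling(dims / factor), 4L)
  spacing_c <- geom$spacing * factor
  stub <- structure(list(data = array(0, dims_c), spacing = spacing_c,
                         origin = geom$origin), class = "mri_volume")
  pts <- grid_points(stub)
  list(data = array(cpp_sample_trilinear(sm, dims, geom$spacing, geom$origin,
                                         pts, 0, TRUE), dims_c),
       spacing = spacing_c, origin = geom$origin)
}

# trilinearly resample a displacement field onto the grid of `target`
resample_field <- function(field, target) {
  dims_t <- dim(target$data)
  stub <- structure(list(data = target$data, spacing = target$spacing,
                         origin = target$origin), class = "mri_volume")
  pts <- grid_points(stub)
  dims_s <- dim(field$dx)
  g <- function(a) array(cpp_sample_trilinear(a, dims_s, field$spacing,
                                              field$origin, pts, 0, TRUE),
                         dims_t)
  list(dx = g(field$dx), dy = g(field$dy), dz = g(field$dz),
       spacing = target$spacing, origin = target$origin)
}

# MIND-style self-similarity descriptor: for the six +-1-voxel axis offsets,
# Gaussian-aggregated patch distance, exponentiated against the local mean
mind_channels <- function(data, sigma) {
  dims <- dim(data)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  ssd <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    sh <- shift_array(data, offs[o, ])
    ssd[[o]] <- cpp_gauss3d((data - sh)^2, dims, rep(sigma, 3))
  }
  V <- Reduce(`+`, ssd) / length(ssd)
  V <- pmax(V, 1e-6 * mean(V) + 1e-12)
  lapply(ssd, function(s) exp(-s / V))
}

# shift with edge replication
shift_array <- function(a, off) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    pmin(pmax(i, 1L), d[ax])
  })
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# demons iterations at one pyramid level over descriptor channels
demons_level <- function(fx, mv, lv2, lv1, field, config, iters,
                         tol_mm = 0.05) {
  dims <- dim(lv2$data)
  stub <- structure(list(data = lv2$data, spacing = lv2$spacing,
                         origin = lv2$origin), class = "mri_volume")
  pts <- grid_points(stub)
  dims_m <- dim(lv1$data)
  converged <- FALSE
  mean_sp <- mean(lv2$spacing)
  for (it in seq_len(iters)) {
    warp_pts <- pts + cbind(as.vector(field$dx), as.vector(field$dy),
                            as.vector(field$dz))
    num <- list(x = 0, y = 0, z = 0)
    den <- 0
    msd <- 0
    for (c_i in seq_along(fx)) {
      mw <- array(cpp_sample_trilinear(mv[[c_i]], dims_m, lv1$spacing,
                                       lv1$origin, warp_pts, 0, TRUE), dims)
      diffc <- fx[[c_i]] - mw
      g <- gradient3d(mw, lv2$spacing)
      num$x <- num$x + diffc * g$x
      num$y <- num$y + diffc * g$y
      num$z <- num$z + diffc * g$z
      den <- den + g$x^2 + g$y^2 + g$z^2 + (diffc / mean_sp)^2
      msd <- msd + diffc^2
    }
    den <- den + 1e-9
    # match-consistency weight: where the descriptors cannot be brought to
    # agree (structure present in one modality only, e.g. gas/feces pattern
    # inside the colon in T1-FS), the residual stays large relative to its
    # bulk level and the force is damped instead of dragging matched edges
    msd <- msd / length(fx)
    wcons <- exp(-msd / (2 * mean(msd) + 1e-12))
    # volume border: one-sided gradients are unreliable
    brd <- array(FALSE, dims)
    for (ax in 1:3) {
      idx <- slice.index(brd, ax)
      brd[idx == 1L | idx == dims[ax]] <- TRUE
    }
    wcons[brd] <- 0
    ux <- cpp_gauss3d(array(wcons * num$x / den, dims), dims,
                      rep(config$sigma_fluid, 3))
    uy <- cpp_gauss3d(array(wcons * num$y / den, dims), dims,
                      rep(config$sigma_fluid, 3))
    uz <- cpp_gauss3d(array(wcons * num$z / den, dims), dims,
                      rep(config$sigma_fluid, 3))
    # per-voxel step clamp (a single spike must not stall the whole update)
    mag <- sqrt(ux^2 + uy^2 + uz^2)
    sc <- pmin(1, config$step / pmax(mag, 1e-12))
    ux <- ux * sc; uy <- uy * sc; uz <- uz * sc
    mag <- pmin(mag, config$step)
    field$dx <- cpp_gauss3d(field$dx + ux, dims, rep(config$sigma_diff, 3))
    field$dy <- cpp_gauss3d(field$dy + uy, dims, rep(config$sigma_diff, 3))
    field$dz <- cpp_gauss3d(field$dz + uz, dims, rep(config$sigma_diff, 3))
    if (mean(mag) < tol_mm) {
      converged <- TRUE
      break
    }
  }
  if (iters == 0L) converged <- TRUE
  list(field = field, converged = converged)
}

gradient3d <- function(a, spacing) {
  d <- dim(a)
  g <- function(ax) {
    hi <- shift_array(a, diag(3)[ax, ])  # value at index + 1
    lo <- shift_array(a, -diag(3)[ax, ]) # value at index - 1
    (hi - lo) / (2 * spacing[ax])
  }
  list(x = g(1), y = g(2), z = g(3))
}

# initial translation-only alignment by mutual-information grid search at
# the coarsest pyramid scale, refined by per-axis quadratic interpolation
mi_translation <- function(f2, t2, f1, t1fs, config) {
  lv2 <- downsample_volume(f2, t2, max(config$levels))
  lv1 <- downsample_volume(f1, t1fs, max(config$levels))
  dims <- dim(lv2$data)
  stub <- structure(list(data = lv2$data, spacing = lv2$spacing,
                         origin = lv2$origin), class = "mri_volume")
  pts <- grid_points(stub)
  step <- min(lv2$spacing)
  offsets <- seq(-config$translation_range, config$translation_range,
                 by = step)
  mi_at <- function(sh) {
    w <- sweep(pts, 2, sh, "+")
    mw <- cpp_sample_trilinear(lv1$data, dim(lv1$data), lv1$spacing,
                               lv1$origin, w, NA_real_, FALSE)
    ok <- !is.na(mw)
    if (sum(ok) < 100) return(-Inf)
    mutual_information(as.vector(lv2$data)[ok], mw[ok], config$mi_bins)
  }
  best <- c(0, 0, 0)
  # coordinate-wise search, two sweeps
  for (sweep_i in 1:2) {
    for (ax in 1:3) {
      vals <- vapply(offsets, function(o) {
        sh <- best
        sh[ax] <- o
        mi_at(sh)
      }, numeric(1))
      bi <- which.max(vals)
      o <- offsets[bi]
      if (bi > 1 && bi < length(offsets) && all(is.finite(vals[bi + c(-1, 1)]))) {
        denom <- vals[bi - 1] - 2 * vals[bi] + vals[bi + 1]
        if (abs(denom) > 1e-12)
          o <- o - step * 0.5 * (vals[bi + 1] - vals[bi - 1]) / denom
      }
      best[ax] <- o
    }
  }
  best
}

mutual_information <- function(a, b, bins) {
  ha <- pmin(pmax(findInterval(a, seq(min(a), max(a),
                                      length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  hb <- pmin(pmax(findInterval(b, seq(min(b), max(b),
                                      length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  joint <- table(ha, hb) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}
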
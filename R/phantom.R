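#' Specification of a paired T2 / T1-FS digital phantom
#'
#' Describes a synthetic abdominal scene emulating the paired-acquisition
#' setting the pipeline is built for: a tubular colon following a smooth
#' "question-mark" trajectory (ascending, transverse, descending, pelvic
#' segments), filled with alternating gas/feces pockets, wrapped in a
#' peri-colonic fat shell, with small-bowel distractor tubes near the cecum
#' and sigmoid and a generic mid-intensity liver block next to the transverse
#' colon. The T1-FS acquisition is related to the T2 acquisition by a smooth,
#' invertible sum-of-Gaussian-bumps deformation.
#'
#' Intensity defaults reproduce the qualitative modality contrasts only
#' (arbitrary units): in T2 the lumen is dark against bright fat
#' (lumen 30 < tissue 100 < fat 220); in T1-FS feces are bright while gas and
#' fat are dark and nearly indistinguishable (gas 20 ~ fat 25 < tissue 90 <
#' feces 210).
#'
#' @param shape voxel dimensions (length 3).
#' @param spacing voxel spacing, mm.
#' @param path `"default"` for the built-in trajectory, or an N x 3 matrix of
#'   control points (mm) spanning the four segments.
#' @param radius_mean,radius_amp mean tube radius and smooth variation
#'   amplitude (mm); `radius_mean - radius_amp` must be at least twice the
#'   largest spacing component so the tube is resolvable.
#' @param radius_period arc-length period of the radius variation (mm).
#' @param halo_mm thickness of the peri-colonic fat shell (mm).
#' @param pocket_range min/max of the uniform pocket-length draw (mm).
#' @param gas_fraction expected fraction of tube length occupied by gas
#'   pockets (alternating gas/feces pockets; lengths are scaled so the
#'   expected gas share equals this value).
#' @param intensity per-modality named mean intensities; see defaults.
#' @param noise_sigma additive noise level per modality (arbitrary units).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param n_bumps,bump_amplitude,bump_scale deformation: number of Gaussian
#'   displacement bumps, per-bump amplitude (mm) and spatial scale (mm). The
#'   total displacement-gradient bound `sum(0.607 * a / s)` must stay below
#'   0.9 so the field is invertible.
#' @param distractors,liver logical; include the confusion structures.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 64), spacing = c(2, 2, 3),
                         path = "default", radius_mean = 12, radius_amp = 3,
                         radius_period = 150, halo_mm = 6,
                         pocket_range = c(20, 60), gas_fraction = 0.4,
                         intensity = list(
                           t2 = c(lumen = 30, tissue = 100, fat = 220,
                                  distractor = 35, liver = 120),
                           t1fs = c(gas = 20, fat = 25, tissue = 90,
                                    feces = 210, distractor = 140,
                                    liver = 110)),
                         noise_sigma = c(t2 = 10, t1fs = 10),
                         noise_model = c("gaussian", "rician"),
                         n_bumps = 3, bump_amplitude = 8, bump_scale = 48,
                         distractors = TRUE, liver = TRUE, seed = 0L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               path = path, radius_mean = radius_mean,
               radius_amp = radius_amp, radius_period = radius_period,
               halo_mm = halo_mm, pocket_range = pocket_range,
               gas_fraction = gas_fraction, intensity = intensity,
               noise_sigma = noise_sigma,
               noise_model = match.arg(noise_model), n_bumps = n_bumps,
               bump_amplitude = bump_amplitude, bump_scale = bump_scale,
               distractors = distractors, liver = liver,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$shape) != 3L || any(spec$shape < 8L))
    stop("shape must be 3 dimensions of at least 8 voxels", call. = FALSE)
  if (any(spec$spacing <= 0))
    stop("spacing must be positive", call. = FALSE)
  if (spec$radius_mean - abs(spec$radius_amp) < 2 * max(spec$spacing))
    stop("minimum tube radius must be at least twice the largest spacing ",
         "component (tube not resolvable on the grid)", call. = FALSE)
  if (spec$n_bumps > 0) {
    grad <- sum(rep(0.607 * spec$bump_amplitude / spec$bump_scale,
                    spec$n_bumps))
    if (grad >= 0.9)
      stop(sprintf(
        "deformation amplitude/scale violates the invertibility bound: sum(0.607*a/s) = %.2f >= 0.9",
        grad), call. = FALSE)
  }
  t2 <- spec$intensity$t2
  if (!(t2["lumen"] < t2["tissue"] && t2["tissue"] < t2["fat"]))
    stop("T2 means must satisfy lumen < tissue < fat", call. = FALSE)
  t1 <- spec$intensity$t1fs
  if (!(max(t1["gas"], t1["fat"]) < t1["tissue"] &&
        t1["tissue"] < t1["feces"]))
    stop("T1-FS means must satisfy gas, fat < tissue < feces", call. = FALSE)
  if (spec$gas_fraction < 0 || spec$gas_fraction > 1)
    stop("gas_fraction must be in [0, 1]", call. = FALSE)
  invisible(spec)
}

# physical extent (mm) from first to last voxel center
phantom_extent <- function(spec) (spec$shape - 1) * spec$spacing

# default question-mark trajectory: ascending up one side, transverse across,
# descending down the other side, pelvic loop back toward the midline
default_path_controls <- function(spec) {
  W <- phantom_extent(spec)
  m <- 0.18 * W
  ym <- W[2] / 2
  rbind(
    c(W[1] - m[1], ym,        m[3] + 0.06 * W[3]),  # cecum start
    c(W[1] - m[1], ym - 6,    0.45 * W[3]),
    c(W[1] - m[1], ym,        W[3] - m[3]),          # hepatic flexure
    c(0.62 * W[1], ym + 8,    W[3] - 0.7 * m[3]),
    c(0.38 * W[1], ym + 8,    W[3] - 0.7 * m[3]),
    c(m[1],        ym,        W[3] - m[3]),          # splenic flexure
    c(m[1],        ym - 6,    0.45 * W[3]),
    c(m[1],        ym,        m[3] + 0.06 * W[3]),   # descending/pelvic
    c(0.28 * W[1], ym + 6,    0.7 * m[3]),
    c(0.45 * W[1], ym,        m[3])                  # pelvic end
  )
}

# indices (into the control rows) carrying the five boundary tags
default_boundary_rows <- c(1L, 3L, 6L, 8L, 10L)

# smooth-resample control points by natural cubic splines at `step` mm
resample_controls <- function(controls, boundary_rows, step = 2) {
  chord <- c(0, cumsum(sqrt(rowSums(diff(controls)^2))))
  s <- seq(0, max(chord), by = step)
  pts <- sapply(1:3, function(ax)
    stats::spline(chord, controls[, ax], xout = s, method = "natural")$y)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  bidx <- vapply(chord[boundary_rows], function(ch) which.min(abs(s - ch)),
                 integer(1))
  list(points = pts, arc = arc, boundary_indices = bidx)
}

#' Sample the ground-truth inter-acquisition deformation field
#'
#' Draws the sum-of-Gaussian-bumps displacement realizing the T2 to T1-FS
#' deformation: random in-volume centers, random unit directions, the spec's
#' per-bump amplitude and scale. The analytic bump parameters are attached as
#' attribute `"bumps"` so truth evaluation stays exact.
#'
#' @param spec a [phantom_spec()].
#' @return A [deformation_field()] on the phantom T2 grid.
#' @export
sample_field <- function(spec) {
  validate_phantom_spec(spec)
  W <- phantom_extent(spec)
  K <- spec$n_bumps
  bumps <- with_seed(spec$seed + 104729L, {
    if (K == 0) {
      list(centers = matrix(0, 0, 3), amps = matrix(0, 0, 3),
           scales = numeric())
    } else {
      centers <- cbind(runif(K, 0.2 * W[1], 0.8 * W[1]),
                       runif(K, 0.2 * W[2], 0.8 * W[2]),
                       runif(K, 0.2 * W[3], 0.8 * W[3]))
      dirs <- matrix(rnorm(3 * K), K, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(centers = centers, amps = dirs * spec$bump_amplitude,
           scales = rep(spec$bump_scale, K))
    }
  })
  dims <- spec$shape
  vol <- list(spacing = spec$spacing, origin = c(0, 0, 0))
  if (K == 0) {
    z <- array(0, dim = dims)
    fld <- deformation_field(z, z, z, spec$spacing, c(0, 0, 0))
  } else {
    pts <- grid_points(structure(list(data = array(0, dims),
                                      spacing = spec$spacing,
                                      origin = c(0, 0, 0)),
                                 class = "mri_volume"))
    d <- cpp_bumps_at(pts, bumps$centers, bumps$amps, bumps$scales)
    fld <- deformation_field(array(d[, 1], dims), array(d[, 2], dims),
                             array(d[, 3], dims), spec$spacing, c(0, 0, 0))
  }
  attr(fld, "bumps") <- bumps
  fld
}

# analytic displacement / inverse of the truth field at world points
bumps_displacement <- function(field, pts) {
  b <- attr(field, "bumps")
  if (nrow(b$centers) == 0) return(matrix(0, nrow(to_points(pts)), 3))
  cpp_bumps_at(to_points(pts), b$centers, b$amps, b$scales)
}

bumps_preimage <- function(field, pts) {
  b <- attr(field, "bumps")
  pm <- to_points(pts)
  if (nrow(b$centers) == 0) return(pm)
  cpp_invert_bumps(pm, b$centers, b$amps, b$scales, 1e-4, 100L)
}

#' Generate a paired T2 / T1-FS phantom with full ground truth
#'
#' Renders the synthetic scene of a [phantom_spec()] in both modalities and
#' returns every ground-truth quantity the pipeline can be scored against:
#' colon label masks in both spaces, the per-voxel gas/feces content map in
#' T1-FS space, the analytic deformation field, the medial path, the
#' anatomical markers and the analytic morphology. The result is bit-identical
#' for identical specs.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `colon_phantom`: list with elements `t2`,
#'   `t1fs` ([mri_volume()]), `mask_t2`, `mask_t1fs` ([label_volume()]),
#'   `content_truth` (3D integer array in T1-FS space: 0 outside colon,
#'   1 gas, 2 feces), `field_truth` ([deformation_field()]), `markers`
#'   ([marker_set()]), `path_truth` ([medial_path()]), `analytic`, `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dims <- spec$shape
  spacing <- spec$spacing
  origin <- c(0, 0, 0)
  W <- phantom_extent(spec)

  controls <- if (is.character(spec$path) && identical(spec$path, "default")) {
    default_path_controls(spec)
  } else as.matrix(spec$path)
  boundary_rows <- if (is.character(spec$path)) default_boundary_rows else {
    br <- attr(spec$path, "boundary_rows")
    if (is.null(br)) round(seq(1, nrow(controls), length.out = 5)) else br
  }
  rs <- resample_controls(controls, boundary_rows, step = 2)
  path <- medial_path(rs$points, rs$boundary_indices)
  total_len <- max(path$arc_length)

  field <- sample_field(spec)

  scene <- with_seed(spec$seed, {
    phase <- runif(1, 0, 2 * pi)
    pockets <- local({
      lens <- numeric()
      cls <- integer()
      cur <- if (runif(1) < spec$gas_fraction) 1L else 2L
      pos <- 0
      while (pos < total_len) {
        base <- runif(1, spec$pocket_range[1], spec$pocket_range[2])
        sc <- if (cur == 1L) 2 * spec$gas_fraction else
          2 * (1 - spec$gas_fraction)
        L <- max(4, base * sc)
        lens <- c(lens, L)
        cls <- c(cls, cur)
        pos <- pos + L
        cur <- 3L - cur
      }
      data.frame(end = cumsum(lens), class = cls)
    })
    list(phase = phase, pockets = pockets)
  })

  radius_at <- function(arc)
    spec$radius_mean +
      spec$radius_amp * sin(2 * pi * arc / spec$radius_period + scene$phase)
  class_at <- function(arc) {
    idx <- findInterval(arc, c(0, scene$pockets$end), rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > nrow(scene$pockets)] <- nrow(scene$pockets)
    scene$pockets$class[idx]
  }
  seg_at <- function(arc) {
    bcut <- path$arc_length[path$boundary_indices]
    s <- findInterval(arc, bcut, rightmost.closed = TRUE)
    s[s < 1L] <- 1L
    s[s > 4L] <- 4L
    as.integer(s)
  }

  # distractor small-bowel tubes within ~2 radii of cecum and sigmoid
  distractor_paths <- list()
  if (spec$distractors) {
    offs <- 2 * spec$radius_mean
    seg_pts <- function(arc_from, arc_to, dy) {
      sel <- path$arc_length >= arc_from & path$arc_length <= arc_to
      p <- path$points[sel, , drop = FALSE]
      p[, 2] <- pmin(pmax(p[, 2] + dy, 2), W[2] - 2)
      p
    }
    distractor_paths <- list(
      seg_pts(0, min(90, total_len / 4), +offs),
      seg_pts(max(0, total_len - 90), total_len, +offs))
    distractor_paths <-
      distractor_paths[vapply(distractor_paths, nrow, 1L) >= 2L]
  }
  distractor_radius <- 6

  liver_box <- NULL
  if (spec$liver) {
    # generic mid-intensity block adjacent to the transverse colon,
    # separated from the tube by at least the fat halo
    top_z <- max(path$points[, 3])
    liver_box <- rbind(c(0.26 * W[1], 0.60 * W[1]),
                       c(0.15 * W[2], 0.42 * W[2]),
                       c(top_z - 20, W[3]))
  }

  render <- function(pts, modality) {
    pl <- cpp_points_polyline(pts, path$points, path$arc_length)
    r <- radius_at(pl$arc)
    img <- rep(spec$intensity[[modality]][["tissue"]], nrow(pts))
    if (!is.null(liver_box)) {
      inbox <- pts[, 1] >= liver_box[1, 1] & pts[, 1] <= liver_box[1, 2] &
        pts[, 2] >= liver_box[2, 1] & pts[, 2] <= liver_box[2, 2] &
        pts[, 3] >= liver_box[3, 1] & pts[, 3] <= liver_box[3, 2]
      img[inbox & pl$dist > r + spec$halo_mm] <-
        spec$intensity[[modality]][["liver"]]
    }
    for (dp in distractor_paths) {
      dd <- cpp_points_polyline(pts, dp,
                                c(0, cumsum(sqrt(rowSums(diff(dp)^2)))))
      img[dd$dist <= distractor_radius & pl$dist > r + spec$halo_mm] <-
        spec$intensity[[modality]][["distractor"]]
    }
    # flat end caps: the tube does not extend beyond the path endpoints
    halo <- pl$dist > r & pl$dist <= r + spec$halo_mm & pl$interior
    img[halo] <- spec$intensity[[modality]][["fat"]]
    inside <- pl$dist <= r & pl$interior
    if (modality == "t2") {
      img[inside] <- spec$intensity$t2[["lumen"]]
    } else {
      cls <- class_at(pl$arc)
      img[inside & cls == 1L] <- spec$intensity$t1fs[["gas"]]
      img[inside & cls == 2L] <- spec$intensity$t1fs[["feces"]]
    }
    list(img = img, inside = inside, seg = seg_at(pl$arc),
         cls = class_at(pl$arc))
  }

  vol_stub <- structure(list(data = array(0, dims), spacing = spacing,
                             origin = origin), class = "mri_volume")
  pts_t2 <- grid_points(vol_stub)
  sc_t2 <- render(pts_t2, "t2")
  t2_img <- array(sc_t2$img, dims)
  lab_t2 <- array(0L, dims)
  lab_t2[sc_t2$inside] <- sc_t2$seg[sc_t2$inside]

  # T2 intensity means use "fat" name for the halo in the t2 table
  pre <- bumps_preimage(field, pts_t2)
  sc_t1 <- render(pre, "t1fs")
  t1_img <- array(sc_t1$img, dims)
  lab_t1 <- array(0L, dims)
  lab_t1[sc_t1$inside] <- sc_t1$seg[sc_t1$inside]
  content <- array(0L, dims)
  content[sc_t1$inside] <- sc_t1$cls[sc_t1$inside]

  noisy <- with_seed(spec$seed + 7L, {
    addn <- function(img, sigma) {
      if (sigma <= 0) return(img)
      if (spec$noise_model == "rician") {
        n1 <- array(rnorm(length(img), 0, sigma), dim(img))
        n2 <- array(rnorm(length(img), 0, sigma), dim(img))
        sqrt((img + n1)^2 + n2^2)
      } else {
        pmax(img + array(rnorm(length(img), 0, sigma), dim(img)), 0)
      }
    }
    list(t2 = addn(t2_img, spec$noise_sigma[["t2"]]),
         t1fs = addn(t1_img, spec$noise_sigma[["t1fs"]]))
  })

  mk <- path$points[path$boundary_indices, , drop = FALSE]
  markers <- marker_set(data.frame(tag = boundary_tags,
                                   x = mk[, 1], y = mk[, 2], z = mk[, 3]))

  bcut <- path$arc_length[path$boundary_indices]
  analytic <- list(segment_length = diff(bcut), total_length = max(bcut),
                   radius_mean = spec$radius_mean,
                   radius_at = radius_at, class_at = class_at)

  structure(list(
    t2 = mri_volume(noisy$t2, spacing, origin, "T2"),
    t1fs = mri_volume(noisy$t1fs, spacing, origin, "T1FS"),
    mask_t2 = label_volume(lab_t2, spacing, origin, "T2"),
    mask_t1fs = label_volume(lab_t1, spacing, origin, "T1FS"),
    content_truth = content,
    field_truth = field,
    markers = markers,
    path_truth = path,
    analytic = analytic,
    spec = spec), class = "colon_phantom")
}

#' @export
print.colon_phantom <- function(x, ...) {
  cat(sprintf(
    "<colon_phantom seed %d> %s voxels; colon %d voxels (T2), %d (T1-FS)\n",
    x$spec$seed, paste(x$spec$shape, collapse = "x"),
    sum(x$mask_t2$labels > 0), sum(x$mask_t1fs$labels > 0)))
  invisible(x)
}

#' Write all phantom outputs to a directory
#'
#' Writes the T2/T1-FS volumes, both label masks, the content truth, the
#' deformation field (3-component NIfTI) and the markers (JSON).
#'
#' @param phantom a `colon_phantom`.
#' @param dir output directory (created if missing).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$t2, file.path(dir, "t2.nii.gz"))
  write_volume(phantom$t1fs, file.path(dir, "t1fs.nii.gz"))
  write_volume(phantom$mask_t2, file.path(dir, "mask_t2.nii.gz"))
  write_volume(phantom$mask_t1fs, file.path(dir, "mask_t1fs.nii.gz"))
  ct <- label_volume(phantom$content_truth, phantom$spec$spacing,
                     c(0, 0, 0), "T1FS")
  write_volume(ct, file.path(dir, "content_truth.nii.gz"))
  write_field(phantom$field_truth, file.path(dir, "field_truth.nii.gz"))
  write_markers(phantom$markers, file.path(dir, "markers.json"))
  invisible(dir)
}
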
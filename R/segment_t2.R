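#' Configuration for T2 colon segmentation
#'
#' @param r0 distance-prior scale (mm) of the probability model.
#' @param lambda pairwise (contrast) weight of the graph-cut energy.
#' @param eps additive cost floor of the medial-path metric.
#' @param coarse_factor multigrid downsampling factor of the coarse level.
#' @param band_voxels half-width (full-resolution voxels) of the refinement
#'   band around the coarse boundary.
#' @param multigrid solve coarse-then-band (TRUE) or single full-resolution
#'   cut (FALSE).
#' @return A named list of class `t2seg_config`.
#' @export
t2seg_config <- function(r0 = 15, lambda = 8, eps = 0.05,
                         coarse_factor = 4L, band_voxels = 3L,
                         multigrid = TRUE) {
  structure(list(r0 = r0, lambda = lambda, eps = eps,
                 coarse_factor = as.integer(coarse_factor),
                 band_voxels = as.integer(band_voxels),
                 multigrid = isTRUE(multigrid)),
            class = "t2seg_config")
}

#' Quasi-automatic colon segmentation in T2 images
#'
#' Marker-guided segmentation: estimates the colon medial path between the
#' anatomical markers ([estimate_medial_path()]), fits the intensity-and-
#' distance probability model ([build_probability_model()]) and minimizes a
#' binary graph-cut energy with `-log` unary terms and contrast-modulated
#' 6-neighborhood pairwise terms. Path voxels are hard foreground seeds;
#' voxels farther than `3 * r0` from the path are hard background. A
#' multigrid scheme solves the cut on a coarse grid first and re-solves at
#' full resolution only in a narrow band around the coarse boundary. The
#' largest connected component containing the markers is kept and labeled by
#' segment ([assign_segments()]).
#'
#' @param t2 T2 [mri_volume()].
#' @param markers a [marker_set()].
#' @param config a [t2seg_config()].
#' @return A [label_volume()] in T2 space (0 background, 1-4 colon segments),
#'   with the estimated [medial_path()] attached as attribute
#'   `"medial_path"` and the fitted model as `"tissue_probability"`.
#' @export
segment_t2 <- function(t2, markers, config = t2seg_config()) {
  validate_volume(t2)
  validate_markers(markers, t2)
  path <- estimate_medial_path(t2, markers, eps = config$eps)
  model <- build_probability_model(t2, path, r0 = config$r0)
  mask <- mincut_colon(t2, model, config)
  mask <- keep_marker_component(mask, markers, t2)
  seg <- assign_segments(
    label_volume(mask * 1L, t2$spacing, t2$origin, "T2"), path)
  attr(seg, "medial_path") <- path
  attr(seg, "tissue_probability") <- model
  attr(seg, "config") <- config
  seg
}

# core multigrid min-cut on the colon probability model
mincut_colon <- function(t2, model, config) {
  dims <- dim(t2$data)
  prob <- model$prob
  dist <- model$dist
  r0 <- model$r0
  seed_fg <- path_seed_mask(t2, model$path)
  hard_bg <- dist > 3 * r0

  solve_level <- function(intensity, prob, seed_fg, hard_bg, spacing,
                          variables, frozen_lab = NULL, sigma_c = NULL) {
    var_id <- array(0L, dim(intensity))
    var_id[variables] <- seq_len(sum(variables))
    adj <- grid_adjacency(var_id, intensity, spacing)
    if (is.null(sigma_c)) {
      sigma_c <- median(abs(adj$dI))
      if (!is.finite(sigma_c) || sigma_c <= 0) sigma_c <- 1
    }
    w <- contrast_weights(adj$dI, adj$len, config$lambda, sigma_c)
    p <- pmin(pmax(prob[variables], 0), 1)
    cost_fg <- neglog(p)
    cost_bg <- neglog(1 - p)
    sf <- seed_fg[variables]
    cost_bg[sf] <- HARD_SEED
    cost_fg[sf] <- 0
    hb <- hard_bg[variables]
    cost_fg[hb & !sf] <- HARD_SEED
    cost_bg[hb & !sf] <- 0
    if (!is.null(frozen_lab)) {
      fr <- frozen_terms(var_id, frozen_lab, intensity, spacing,
                         config$lambda, sigma_c)
      cost_fg <- cost_fg + fr$cost_fg_extra
      cost_bg <- cost_bg + fr$cost_bg_extra
    }
    fg <- solve_mincut(cost_fg, cost_bg, adj$edges, w)
    out <- array(FALSE, dim(intensity))
    out[variables] <- fg
    out
  }

  if (!config$multigrid) {
    vars <- !hard_bg
    return(solve_level(t2$data, prob, seed_fg, hard_bg, t2$spacing, vars))
  }

  # coarse level
  f <- config$coarse_factor
  dims_c <- pmax(ceiling(dims / f), 2L)
  spacing_c <- t2$spacing * f
  coarse_stub <- structure(list(data = array(0, dims_c), spacing = spacing_c,
                                origin = t2$origin), class = "mri_volume")
  cpts <- grid_points(coarse_stub)
  smooth_I <- cpp_gauss3d(t2$data, dims, rep(f / 2, 3))
  I_c <- array(cpp_sample_trilinear(smooth_I, dims, t2$spacing, t2$origin,
                                    cpts, 0, TRUE), dims_c)
  prob_c <- array(cpp_sample_trilinear(prob, dims, t2$spacing, t2$origin,
                                       cpts, 0, TRUE), dims_c)
  pl_c <- cpp_points_polyline(cpts, model$path$points,
                              model$path$arc_length)
  dist_c <- array(pl_c$dist, dims_c)
  seed_c <- dist_c <= 0.75 * max(spacing_c)
  hard_bg_c <- dist_c > 3 * r0
  vars_c <- !hard_bg_c
  mask_c <- solve_level(I_c, prob_c, seed_c, hard_bg_c, spacing_c, vars_c)

  # upsample coarse labels to full resolution (nearest)
  fpts <- grid_points(t2)
  up <- array(cpp_sample_nearest(array(as.integer(mask_c), dims_c), dims_c,
                                 spacing_c, t2$origin, fpts, 0L),
              dims) > 0L

  # narrow band around the coarse boundary
  boundary <- array(FALSE, dims)
  for (ax in 1:3) {
    a <- slice.index(boundary, ax) <= dims[ax] - 1L
    b <- slice.index(boundary, ax) >= 2L
    diffv <- up[a] != up[b]
    ba <- boundary[a]; ba[diffv] <- TRUE; boundary[a] <- ba
    bb <- boundary[b]; bb[diffv] <- TRUE; boundary[b] <- bb
  }
  if (!any(boundary)) return(up)
  ed <- cpp_edt(array(as.integer(boundary), dims), dims, c(1, 1, 1))
  band <- ed$dist <= config$band_voxels
  vars <- band & !hard_bg
  frozen_lab <- array(-1L, dims)
  frozen_lab[!vars] <- as.integer(up[!vars] & !hard_bg[!vars])
  fine <- solve_level(t2$data, prob, seed_fg, hard_bg, t2$spacing, vars,
                      frozen_lab = frozen_lab)
  fine[!vars] <- up[!vars] & !hard_bg[!vars]
  # hard constraints always win
  fine[path_seed_mask(t2, model$path)] <- TRUE
  fine
}

# voxels traversed by the medial path (hard foreground seeds)
path_seed_mask <- function(vol, path) {
  dims <- grid_dim(vol)
  v <- round(to_points(world_to_voxel(path$points, vol)))
  v <- v[v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
           v[, 1] < dims[1] & v[, 2] < dims[2] & v[, 3] < dims[3], ,
         drop = FALSE]
  m <- array(FALSE, dims)
  m[v + 1L] <- TRUE
  m
}

# keep the largest 26-connected component containing the most markers
keep_marker_component <- function(mask, markers, vol) {
  dims <- dim(mask)
  comp <- cpp_components26(array(as.integer(mask), dims), dims)
  if (max(comp) <= 1L) return(mask)
  mk <- round(to_points(world_to_voxel(anatomical_points(markers), vol))) + 1L
  mk <- pmin(pmax(mk, 1L), matrix(dims, nrow(mk), 3, byrow = TRUE))
  mcomp <- comp[mk]
  tab <- tabulate(mcomp[mcomp > 0L], nbins = max(comp))
  best <- if (any(tab > 0)) which.max(tab) else {
    sizes <- tabulate(comp[comp > 0L], nbins = max(comp))
    which.max(sizes)
  }
  if (any(mcomp != best))
    warning(sprintf("%d marker(s) fall outside the kept component",
                    sum(mcomp != best)), call. = FALSE)
  mask & comp == best
}

#' Label colon voxels by segment of the nearest path point
#'
#' Each colon voxel receives the segment label (1 ascending, 2 transverse,
#' 3 descending, 4 pelvic) of its nearest medial-path point (Euclidean
#' distance; ties resolve to the lower segment index).
#'
#' @param mask a [label_volume()] (any nonzero voxel is colon) or 3D
#'   binary/integer array with the geometry of `ref`.
#' @param path a [medial_path()] carrying the five boundary tags.
#' @param ref required when `mask` is a bare array: object with
#'   `spacing`/`origin`.
#' @return A [label_volume()] with labels 1-4 inside the mask.
#' @export
assign_segments <- function(mask, path, ref = NULL) {
  if (!inherits(mask, "label_volume")) {
    if (is.null(ref)) stop("ref geometry required for a bare array",
                           call. = FALSE)
    mask <- label_volume(array(as.integer(mask != 0), dim(mask)),
                         ref$spacing, ref$origin,
                         if (!is.null(ref$space)) ref$space else "T2")
  }
  if (!sum(mask$labels > 0L)) stop("empty mask", call. = FALSE)
  if (length(path$boundary_indices) < 5L)
    stop("path must carry the five boundary tags", call. = FALSE)
  dims <- dim(mask$labels)
  sel <- which(mask$labels > 0L)
  vox <- cbind((sel - 1L) %% dims[1],
               ((sel - 1L) %/% dims[1]) %% dims[2],
               (sel - 1L) %/% (dims[1] * dims[2]))
  pts <- voxel_to_world(vox, mask)
  pl <- cpp_points_polyline(to_points(pts), path$points, path$arc_length)
  segidx <- findInterval(pl$nearest - 0.5, path$boundary_indices)
  segidx[segidx < 1L] <- 1L
  segidx[segidx > 4L] <- 4L
  out <- array(0L, dims)
  out[sel] <- as.integer(segidx)
  label_volume(out, mask$spacing, mask$origin, mask$space)
}

#' Correct a T2 segmentation with refinement markers
#'
#' Re-solves the full-resolution graph cut inside a ball (default radius
#' 20 mm) around each refinement marker, with the marker's voxel as a hard
#' seed of its polarity; labels outside the balls are frozen. Include-marker
#' voxels are foreground in the output, exclude-marker voxels background.
#'
#' @param t2 T2 [mri_volume()].
#' @param seg a [label_volume()] from [segment_t2()].
#' @param markers a [marker_set()] whose `refinement` table is used.
#' @param radius_mm refinement ball radius.
#' @return A [label_volume()]; equals `seg` when there are no refinement
#'   markers.
#' @export
apply_refinement <- function(t2, seg, markers, radius_mm = 20) {
  validate_volume(t2)
  rf <- markers$refinement
  if (!nrow(rf)) return(seg)
  rpts <- as.matrix(rf[, c("x", "y", "z")])
  if (!all(in_bounds(rpts, t2, tol = 0.5)))
    stop("refinement marker outside volume", call. = FALSE)
  path <- attr(seg, "medial_path")
  model <- attr(seg, "tissue_probability")
  config <- attr(seg, "config")
  if (is.null(config)) config <- t2seg_config()
  if (is.null(path)) path <- estimate_medial_path(t2, markers,
                                                  eps = config$eps)
  if (is.null(model)) model <- build_probability_model(t2, path,
                                                       r0 = config$r0)
  dims <- dim(t2$data)
  pts <- grid_points(t2)
  inball <- rep(FALSE, nrow(pts))
  for (r in seq_len(nrow(rpts)))
    inball <- inball | sqrt(rowSums(sweep(pts, 2, rpts[r, ])^2)) <= radius_mm
  vars <- array(inball, dims)
  old <- seg$labels > 0L
  frozen_lab <- array(-1L, dims)
  frozen_lab[!vars] <- as.integer(old[!vars])
  var_id <- array(0L, dims)
  var_id[vars] <- seq_len(sum(vars))
  adj <- grid_adjacency(var_id, t2$data, t2$spacing)
  sigma_c <- median(abs(adj$dI))
  if (!is.finite(sigma_c) || sigma_c <= 0) sigma_c <- 1
  w <- contrast_weights(adj$dI, adj$len, config$lambda, sigma_c)
  p <- pmin(pmax(model$prob[vars], 0), 1)
  cost_fg <- neglog(p)
  cost_bg <- neglog(1 - p)
  fr <- frozen_terms(var_id, frozen_lab, t2$data, t2$spacing, config$lambda,
                     sigma_c)
  cost_fg <- cost_fg + fr$cost_fg_extra
  cost_bg <- cost_bg + fr$cost_bg_extra
  # marker voxels: hard seeds of the marker polarity
  mvox <- round(to_points(world_to_voxel(rpts, t2))) + 1L
  mid <- var_id[mvox]
  inc <- rf$polarity == "include"
  cost_bg[mid[inc]] <- HARD_SEED; cost_fg[mid[inc]] <- 0
  cost_fg[mid[!inc]] <- HARD_SEED; cost_bg[mid[!inc]] <- 0
  # path seeds stay foreground inside the balls
  sf <- path_seed_mask(t2, path)[vars]
  sf[mid[!inc]] <- FALSE
  cost_bg[sf] <- HARD_SEED; cost_fg[sf] <- 0
  fg <- solve_mincut(cost_fg, cost_bg, adj$edges, w)
  newmask <- old
  newmask[vars] <- fg
  assign_segments(label_volume(newmask * 1L, seg$spacing, seg$origin,
                               seg$space), path) -> out
  attr(out, "medial_path") <- path
  attr(out, "tissue_probability") <- model
  attr(out, "config") <- config
  out
}
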
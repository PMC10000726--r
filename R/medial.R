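#' Colon medial path
#'
#' Ordered world-coordinate polyline approximating the colon centerline from
#' cecum start to pelvic end, annotated with the indices of the five tagged
#' boundary positions (start, three inter-segment boundaries, end) and the
#' cumulative arc length.
#'
#' @param points N x 3 matrix of world coordinates (mm), consecutive points
#'   distinct.
#' @param boundary_indices strictly increasing indices into `points` of the
#'   five boundary positions.
#' @return An object of class `medial_path`.
#' @export
medial_path <- function(points, boundary_indices) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("path needs at least 2 points with 3 coordinates", call. = FALSE)
  steps <- sqrt(rowSums(diff(points)^2))
  if (any(steps == 0))
    stop("consecutive path points must be distinct", call. = FALSE)
  boundary_indices <- as.integer(boundary_indices)
  if (any(diff(boundary_indices) <= 0))
    stop("boundary indices must be strictly increasing", call. = FALSE)
  if (any(boundary_indices < 1L | boundary_indices > nrow(points)))
    stop("boundary indices out of range", call. = FALSE)
  structure(list(points = points,
                 boundary_indices = boundary_indices,
                 arc_length = c(0, cumsum(steps))),
            class = "medial_path")
}

#' @export
print.medial_path <- function(x, ...) {
  cat(sprintf("<medial_path> %d points, %.0f mm, boundaries at %s mm\n",
              nrow(x$points), max(x$arc_length),
              paste(round(x$arc_length[x$boundary_indices]), collapse = ", ")))
  invisible(x)
}

#' Estimate the colon medial path from anatomical markers
#'
#' Concatenates minimum-cost voxel paths between consecutive anatomical
#' markers on the 26-neighborhood graph of the T2 volume. The cost of a step
#' is its physical length times `eps + I_n`, where `I_n` is the robustly
#' normalized intensity of the target voxel (1st-99th percentile rescale to
#' \[0, 1\]), so the path is drawn through the dark colonic lumen. The
#' concatenated voxel chain is smoothed by a moving average (window 5, marker
#' positions pinned) and resampled at 2 mm arc-length steps.
#'
#' Because a shortest path hugs the inside of bends, each vertex is then
#' recentred onto the lumen medial axis: within a ball of `recentre_mm`,
#' voxels are weighted by the squared distance-from-boundary of the
#' (smoothed, thresholded) dark-lumen mask and the vertex moves toward their
#' weighted centroid (three passes); marker vertices stay pinned throughout.
#'
#' @param t2 T2 [mri_volume()].
#' @param markers a [marker_set()] with at least 2 anatomical points inside
#'   the volume.
#' @param eps additive cost floor (keeps the metric positive in the lumen).
#' @param smooth_window moving-average window (path vertices).
#' @param step_mm resampling step (mm).
#' @param recentre_mm radius (mm) of the recentring ball; 0 disables
#'   recentring.
#' @return A [medial_path()]; its boundary indices point at the five boundary
#'   tag positions.
#' @export
estimate_medial_path <- function(t2, markers, eps = 0.05, smooth_window = 5L,
                                 step_mm = 2, recentre_mm = 15) {
  validate_volume(t2)
  an <- markers$anatomical
  if (nrow(an) < 2L)
    stop("at least 2 anatomical markers are required", call. = FALSE)
  pts <- anatomical_points(markers)
  if (!all(in_bounds(pts, t2, tol = 0.5)))
    stop("anatomical markers must lie inside the volume", call. = FALSE)
  vox <- round(to_points(world_to_voxel(pts, t2)))
  dims <- dim(t2$data)
  vox <- pmin(pmax(vox, 0), matrix(dims - 1, nrow(vox), 3, byrow = TRUE))
  cost <- normalize_robust(t2$data)
  lin <- as.integer(vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]))
  chain <- NULL
  for (leg in seq_len(nrow(vox) - 1)) {
    pth <- cpp_dijkstra_path(cost, dims, t2$spacing, lin[leg], lin[leg + 1],
                             eps)
    if (nrow(pth) == 0)
      stop(sprintf(
        "no finite-cost path between markers %d and %d", leg, leg + 1),
        call. = FALSE)
    if (!is.null(chain)) pth <- pth[-1, , drop = FALSE]
    chain <- rbind(chain, pth)
  }
  wpts <- voxel_to_world(chain, t2)
  wpts <- to_points(wpts)
  # marker vertex rows within the chain (legs join at marker voxels)
  marker_rows <- vapply(seq_len(nrow(vox)), function(m) {
    d2 <- rowSums(sweep(wpts, 2, to_points(voxel_to_world(vox[m, ], t2)))^2)
    which.min(d2)
  }, integer(1))
  # moving-average smoothing with marker positions pinned
  if (smooth_window > 1L && nrow(wpts) > smooth_window) {
    half <- smooth_window %/% 2L
    sm <- wpts
    n <- nrow(wpts)
    for (ax in 1:3) {
      cs <- cumsum(c(0, wpts[, ax]))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      sm[, ax] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }
    sm[marker_rows, ] <- wpts[marker_rows, ]
    wpts <- sm
  }
  # recentre vertices onto the lumen medial axis: weight voxels by the
  # squared distance-from-boundary of a (smoothed, thresholded) dark-lumen
  # mask, so the local weighted centroid sits on the tube centerline
  if (recentre_mm > 0) {
    rvox <- ceiling(recentre_mm / t2$spacing)
    offs <- as.matrix(expand.grid(i = -rvox[1]:rvox[1], j = -rvox[2]:rvox[2],
                                  k = -rvox[3]:rvox[3]))
    offs_mm <- sweep(offs, 2, t2$spacing, "*")
    offs <- offs[rowSums(offs_mm^2) <= recentre_mm^2, , drop = FALSE]
    smI <- cpp_gauss3d(cost, dims, rep(1, 3))
    lumen <- smI < 0.25
    dt <- cpp_edt(array(as.integer(!lumen), dims), dims, t2$spacing)$dist
    wvol <- dt^2
    for (pass in 1:3) {
      for (r in setdiff(seq_len(nrow(wpts)), marker_rows)) {
        base <- round(to_points(world_to_voxel(wpts[r, ], t2)))
        nb <- sweep(offs, 2, as.numeric(base), "+")
        ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
          nb[, 1] < dims[1] & nb[, 2] < dims[2] & nb[, 3] < dims[3]
        if (sum(ok) < 4L) next
        nb <- nb[ok, , drop = FALSE]
        wgt <- wvol[nb + 1L]
        if (sum(wgt) < 1e-9) next
        ctr <- colSums(voxel_to_world(nb, t2) * wgt) / sum(wgt)
        wpts[r, ] <- 0.5 * (wpts[r, ] + ctr)
      }
    }
  }
  # drop exact duplicates, resample at fixed arc-length steps keeping markers
  keep <- c(TRUE, rowSums(abs(diff(wpts))) > 1e-9)
  marker_rows <- vapply(marker_rows, function(r) sum(keep[seq_len(r)]),
                        integer(1))
  wpts <- wpts[keep, , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums(diff(wpts)^2))))
  svals <- sort(unique(c(seq(0, max(arc), by = step_mm), max(arc),
                         arc[marker_rows])))
  res <- sapply(1:3, function(ax) approx(arc, wpts[, ax], xout = svals)$y)
  res <- matrix(res, ncol = 3)
  keep2 <- c(TRUE, rowSums(abs(diff(res))) > 1e-9)
  res <- res[keep2, , drop = FALSE]
  # boundary indices: resampled rows nearest to the five boundary tags
  btag_rows <- match(boundary_tags, an$tag)
  bidx <- vapply(btag_rows, function(m) {
    if (is.na(m)) return(NA_integer_)
    d2 <- rowSums(sweep(res, 2, pts[m, ])^2)
    which.min(d2)
  }, integer(1))
  if (anyNA(bidx)) # fewer than the five tags: use path ends
    bidx <- round(seq(1, nrow(res), length.out = 5))
  bidx <- sort(unique(pmin(pmax(bidx, 1L), nrow(res))))
  if (length(bidx) < 5L)
    bidx <- unique(round(seq(1, nrow(res), length.out = 5)))
  medial_path(res, bidx)
}
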
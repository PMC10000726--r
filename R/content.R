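#' Classify colonic content intensities into gas/mixed/solid
#'
#' One-dimensional k-means clustering of the T1-FS intensities inside the
#' colon mask. Clusters are ordered by centroid: the lowest is gas, the
#' highest solid, intermediate clusters are mixed content. Each cluster gets
#' a solid fraction: 0 for gas, 1 for solid, and for intermediate clusters
#' the linear interpolate `(centroid - c_gas) / (c_solid - c_gas)`. The
#' clustering is solved exactly (weighted dynamic programming over sorted
#' unique intensities), so the result is deterministic and attains the global
#' within-cluster sum-of-squares optimum; `seed` is accepted for interface
#' stability but does not influence the result.
#'
#' @param t1fs T1-FS [mri_volume()].
#' @param seg [label_volume()] in T1-FS space.
#' @param k number of content classes (default 3: gas / mixed / solid).
#' @param seed unused (kept for call compatibility).
#' @return An object of class `content_class_map`: list with `classes` (3D
#'   integer array, 0 outside the mask, 1..k by increasing centroid),
#'   `centroids` (increasing), `solid_fraction` (per cluster), `class_names`,
#'   `sse`.
#' @export
classify_content <- function(t1fs, seg, k = 3L, seed = 0L) {
  validate_volume(t1fs)
  if (!identical(dim(seg$labels), dim(t1fs$data)))
    stop("segmentation grid does not match the volume", call. = FALSE)
  sel <- which(seg$labels > 0L)
  if (!length(sel)) stop("empty segmentation", call. = FALSE)
  vals <- t1fs$data[sel]
  ux <- sort(unique(vals))
  if (length(ux) < k)
    stop(sprintf(
      "degenerate input: %d distinct intensities for k = %d clusters",
      length(ux), k), call. = FALSE)
  if (length(ux) > 4096L) { # bin to keep the exact solver tractable
    br <- seq(min(vals), max(vals), length.out = 4097L)
    mid <- (br[-1] + br[-length(br)]) / 2
    bin <- pmin(pmax(findInterval(vals, br, rightmost.closed = TRUE), 1L),
                4096L)
    w <- tabulate(bin, 4096L)
    keep <- w > 0
    km <- cpp_kmeans1d(mid[keep], w[keep], k)
    cl_of_val <- km$cluster[match(bin, which(keep))]
  } else {
    w <- tabulate(match(vals, ux), length(ux))
    km <- cpp_kmeans1d(ux, w, k)
    cl_of_val <- km$cluster[match(vals, ux)]
  }
  ord <- order(km$centers)
  rank <- match(seq_len(k), ord)
  centroids <- km$centers[ord]
  classes <- array(0L, dim(t1fs$data))
  classes[sel] <- rank[cl_of_val]
  solid_fraction <- (centroids - centroids[1]) /
    max(centroids[k] - centroids[1], 1e-12)
  class_names <- if (k == 2L) c("gas", "solid") else
    if (k == 3L) c("gas", "mixed", "solid") else
      c("gas", paste0("mixed", seq_len(k - 2L)), "solid")
  structure(list(classes = classes, centroids = centroids,
                 solid_fraction = solid_fraction, class_names = class_names,
                 sse = km$sse),
            class = "content_class_map")
}

#' @export
print.content_class_map <- function(x, ...) {
  cat("<content_class_map>\n")
  print(data.frame(class = x$class_names, centroid = round(x$centroids, 2),
                   solid_fraction = round(x$solid_fraction, 3)))
  invisible(x)
}

#' Quantify per-segment content volumes
#'
#' Converts the content classification into per-segment and total volumes:
#' class volume = voxel count x voxel volume / 1000 (mL). The
#' solid-equivalent volume weights each voxel by its cluster's solid
#' fraction.
#'
#' @param cmap a [classify_content()] result.
#' @param seg [label_volume()] on the same grid.
#' @param spacing voxel spacing (mm); defaults to the segmentation's.
#' @return A data frame (one row per segment plus `"total"`) with columns
#'   per class (mL), `total_ml` and `solid_equivalent_ml`.
#' @export
quantify_content <- function(cmap, seg, spacing = seg$spacing) {
  if (!identical(dim(cmap$classes), dim(seg$labels)))
    stop("class map and segmentation grids differ", call. = FALSE)
  vox_ml <- prod(spacing) / 1000
  k <- length(cmap$centroids)
  rows <- lapply(1:4, function(s) {
    sel <- seg$labels == s
    cnt <- tabulate(cmap$classes[sel], nbins = k)
    vols <- cnt * vox_ml
    sf <- sum(cnt * cmap$solid_fraction) * vox_ml
    c(vols, sum(vols), sf)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, colSums(tab))
  df <- data.frame(segment = c(segment_names, "total"))
  cls <- paste0(cmap$class_names, "_ml")
  for (i in seq_len(k)) df[[cls[i]]] <- tab[, i]
  df$total_ml <- tab[, k + 1]
  df$solid_equivalent_ml <- tab[, k + 2]
  df
}

#' Colonic morphology from the T2 segmentation
#'
#' Measures, per colon segment: length (medial-path arc length between the
#' segment boundaries) and, at regular arc-length stations, the
#' cross-sectional perimeter and mean radius. At each station the mask is
#' resampled on a 2D grid (0.5 mm pitch, 80 mm extent) in the plane
#' orthogonal to the path tangent; the cross-section component containing
#' the path point is contoured (marching squares on a lightly smoothed
#' indicator) to get the perimeter, and the mean distance from the path
#' point to the contour gives the radius. Stations whose path point lies
#' outside the mask are skipped (counted in `skipped_stations`).
#'
#' @param seg [label_volume()] (any nonzero voxel is colon).
#' @param path a [medial_path()].
#' @param step arc-length station spacing (mm).
#' @param pitch,extent 2D resampling pitch and extent (mm).
#' @return A data frame (one row per segment plus `"total"`) with columns
#'   `length_mm`, `mean_perimeter_mm`, `mean_radius_mm`, `n_stations`,
#'   `skipped_stations`. For `"total"`, length sums and the means are
#'   station-weighted.
#' @export
compute_morphology <- function(seg, path, step = 10, pitch = 0.5,
                               extent = 80) {
  if (!inherits(path, "medial_path") || nrow(path$points) < 2L)
    stop("morphology needs a path with at least one arc", call. = FALSE)
  if (length(path$boundary_indices) < 5L)
    stop("path must carry the five boundary tags", call. = FALSE)
  mask <- array(as.numeric(seg$labels > 0L), dim(seg$labels))
  dims <- dim(mask)
  barc <- path$arc_length[path$boundary_indices]
  half <- extent / 2
  ngrid <- round(extent / pitch) + 1L
  gu <- seq(-half, half, length.out = ngrid)
  grid2 <- as.matrix(expand.grid(u = gu, v = gu))
  ctr <- c(half, half)
  res <- lapply(1:4, function(s) {
    arcs <- if (barc[s + 1] - step / 4 > barc[s] + step / 2)
      seq(barc[s] + step / 2, barc[s + 1] - step / 4, by = step)
    else mean(barc[s + 0:1])
    per <- rad <- numeric(0)
    skipped <- 0L
    for (a in arcs) {
      i <- findInterval(a, path$arc_length)
      i <- min(max(i, 1L), nrow(path$points) - 1L)
      tangent <- path$points[i + 1, ] - path$points[i, ]
      tangent <- tangent / sqrt(sum(tangent^2))
      t_loc <- (a - path$arc_length[i]) /
        max(path$arc_length[i + 1] - path$arc_length[i], 1e-9)
      p0 <- path$points[i, ] + t_loc * (path$points[i + 1, ] -
                                          path$points[i, ])
      ref <- if (abs(tangent[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- cross3(tangent, ref)
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- cross3(tangent, e1)
      pts3 <- cbind(p0[1] + grid2[, 1] * e1[1] + grid2[, 2] * e2[1],
                    p0[2] + grid2[, 1] * e1[2] + grid2[, 2] * e2[2],
                    p0[3] + grid2[, 1] * e1[3] + grid2[, 2] * e2[3])
      sl <- matrix(cpp_sample_nearest(array(as.integer(mask), dims), dims,
                                      seg$spacing, seg$origin, pts3, 0L),
                   ngrid, ngrid)
      cidx <- (ngrid + 1L) %/% 2L
      if (sl[cidx, cidx] == 0L) {
        skipped <- skipped + 1L
        next
      }
      comp <- array(cpp_components26(array(sl, c(ngrid, ngrid, 1L)),
                                     c(ngrid, ngrid, 1L)),
                    c(ngrid, ngrid))
      cc <- (comp == comp[cidx, cidx]) * 1
      ccs <- matrix(cpp_gauss3d(array(cc, c(ngrid, ngrid, 1L)),
                                c(ngrid, ngrid, 1L), c(1, 1, 0)),
                    ngrid, ngrid)
      msq <- cpp_marching_squares(ccs, 0.5, pitch, ctr[1], ctr[2])
      if (msq$n_segments == 0L) {
        skipped <- skipped + 1L
        next
      }
      per <- c(per, msq$perimeter)
      rad <- c(rad, msq$mean_radius)
    }
    list(length = barc[s + 1] - barc[s], per = per, rad = rad,
         skipped = skipped, n = length(arcs))
  })
  if (all(vapply(res, function(r) length(r$per) == 0L, logical(1))))
    stop("all morphology stations skipped: path does not traverse the mask",
         call. = FALSE)
  nst <- vapply(res, function(r) length(r$per), integer(1))
  df <- data.frame(
    segment = c(segment_names, "total"),
    length_mm = c(vapply(res, `[[`, numeric(1), "length"),
                  max(barc) - min(barc)),
    mean_perimeter_mm = c(vapply(res, function(r)
      if (length(r$per)) mean(r$per) else NA_real_, numeric(1)),
      mean(unlist(lapply(res, `[[`, "per")))),
    mean_radius_mm = c(vapply(res, function(r)
      if (length(r$rad)) mean(r$rad) else NA_real_, numeric(1)),
      mean(unlist(lapply(res, `[[`, "rad")))),
    n_stations = c(nst, sum(nst)),
    skipped_stations = c(vapply(res, `[[`, integer(1), "skipped"),
                         sum(vapply(res, `[[`, integer(1), "skipped"))))
  if (sum(df$skipped_stations[1:4]) > 0)
    warning(sprintf("%d morphology station(s) skipped",
                    sum(df$skipped_stations[1:4])), call. = FALSE)
  df
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
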
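#' Dense deformation field between T2 and T1-FS space
#'
#' Realizes the non-rigid transform from T2 to T1-FS world coordinates as
#' `p -> p + d(p)` with trilinear interpolation of the displacement `d`
#' (mm), stored as three component arrays on the T2 grid. The inverse
#' direction is obtained by fixed-point iteration ([map_t1fs_to_t2()]).
#'
#' @param dx,dy,dz 3D arrays of displacement components (mm) on the T2 grid.
#' @param spacing,origin grid geometry of the T2 grid (mm).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(dx, dy, dz, spacing, origin = c(0, 0, 0)) {
  d <- dim(dx)
  if (length(d) != 3L || !identical(d, dim(dy)) || !identical(d, dim(dz)))
    stop("dx, dy, dz must be 3D arrays on one grid", call. = FALSE)
  if (any(!is.finite(dx)) || any(!is.finite(dy)) || any(!is.finite(dz)))
    stop("displacements must be finite", call. = FALSE)
  structure(list(dx = dx, dy = dy, dz = dz, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  cat(sprintf(
    "<deformation_field> %s grid, |d| mean %.2f mm, max %.2f mm\n",
    paste(dim(x$dx), collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

field_dim <- function(field) dim(field$dx)

#' Map points between T2 and T1-FS space through a deformation field
#'
#' `map_t2_to_t1fs()` applies the forward transform `p + d(p)`.
#' `map_t1fs_to_t2()` inverts it by fixed-point iteration
#' `x_{k+1} = q - d(x_k)` starting at `x_0 = q`.
#'
#' @param p,q point (length-3) or N x 3 matrix of world coordinates (mm).
#' @param field a [deformation_field()].
#' @param tol convergence tolerance of the inversion (mm).
#' @param maxit maximum fixed-point iterations.
#' @return Mapped point(s), same shape as the input. `map_t1fs_to_t2()` errors
#'   if the worst residual `|x + d(x) - q|` exceeds `tol` after `maxit`
#'   iterations.
#' @export
map_t2_to_t1fs <- function(p, field) {
  pm <- to_points(p)
  if (!all(point_in_field(pm, field)))
    stop("point outside the deformation field domain", call. = FALSE)
  d <- cpp_field_at(field$dx, field$dy, field$dz, field_dim(field),
                    field$spacing, field$origin, pm)
  drop_points(pm + d)
}

#' @rdname map_t2_to_t1fs
#' @export
map_t1fs_to_t2 <- function(q, field, tol = 0.05, maxit = 50L) {
  qm <- to_points(q)
  inv <- cpp_invert_field(field$dx, field$dy, field$dz, field_dim(field),
                          field$spacing, field$origin, qm, tol, maxit)
  if (max(inv$residual) > tol)
    stop(sprintf(
      "field inversion did not converge: worst residual %.4f mm after %d iterations",
      max(inv$residual), maxit), call. = FALSE)
  drop_points(inv$points)
}

point_in_field <- function(pm, field) {
  d <- field_dim(field)
  v <- sweep(sweep(pm, 2, field$origin, "-"), 2, field$spacing, "/")
  ok <- rep(TRUE, nrow(pm))
  for (ax in 1:3) ok <- ok & v[, ax] >= -0.5 & v[, ax] <= d[ax] - 0.5
  ok
}

#' Check invertibility of a deformation field on a sample grid
#'
#' Samples in-bounds points, composes forward map and fixed-point inverse and
#' reports the round-trip residuals. A field whose residuals exceed `tol` is
#' reported (not silently accepted).
#'
#' @param field a [deformation_field()].
#' @param n number of random sample points.
#' @param tol residual tolerance (mm).
#' @param seed RNG seed for the sample.
#' @return List with `ok`, `mean_residual`, `max_residual`, `frac_ok`.
#' @export
check_invertibility <- function(field, n = 1000L, tol = 0.1, seed = 0L) {
  pts <- with_seed(seed, random_field_points(field, n))
  fwd <- map_t2_to_t1fs(pts, field)
  inv <- cpp_invert_field(field$dx, field$dy, field$dz, field_dim(field),
                          field$spacing, field$origin, to_points(fwd),
                          0.01, 100L)
  res <- sqrt(rowSums((inv$points - pts)^2))
  list(ok = mean(res) < tol, mean_residual = mean(res),
       max_residual = max(res), frac_ok = mean(res < tol))
}

random_field_points <- function(field, n) {
  d <- field_dim(field)
  lo <- field$origin
  hi <- field$origin + (d - 1) * field$spacing
  cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
}

# run expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synchronized slice correspondence between two volumes
#'
#' Lifts a (slice, in-slice cursor) position in the source volume to a world
#' point, maps it through the deformation field in the requested direction and
#' projects it onto the destination grid, returning the nearest slice index
#' and the continuous in-slice pixel position. This is the headless engine
#' behind synchronized two-modality navigation.
#'
#' @param slice_axis 1, 2 or 3 — the axis whose index selects the slice.
#' @param slice_index 0-based slice index in `src`.
#' @param cursor length-2, continuous 0-based pixel position on the remaining
#'   two axes (in increasing axis order).
#' @param src,dst source and destination [mri_volume()].
#' @param field a [deformation_field()] (T2 -> T1-FS, on the T2 grid).
#' @param direction `"t2_to_t1fs"` or `"t1fs_to_t2"`.
#' @return List with `slice_index` (integer), `cursor` (length-2, continuous),
#'   `point_mm` (mapped world point) and `in_view` (FALSE when the mapped
#'   point falls outside `dst`; indices are still returned, unclamped).
#' @export
corresponding_slice <- function(slice_axis, slice_index, cursor, src, dst,
                                field,
                                direction = c("t2_to_t1fs", "t1fs_to_t2")) {
  direction <- match.arg(direction)
  stopifnot(slice_axis %in% 1:3, length(cursor) == 2L)
  vox <- numeric(3)
  vox[slice_axis] <- slice_index
  vox[setdiff(1:3, slice_axis)] <- cursor
  p <- voxel_to_world(vox, src)
  q <- if (direction == "t2_to_t1fs") map_t2_to_t1fs(p, field)
       else map_t1fs_to_t2(p, field)
  v <- world_to_voxel(q, dst)
  d <- grid_dim(dst)
  list(slice_index = as.integer(round(v[slice_axis])),
       cursor = v[setdiff(1:3, slice_axis)],
       point_mm = q,
       in_view = all(v >= -0.5 & v <= d - 0.5))
}

#' Read / write a deformation field as a 3-component NIfTI
#'
#' The field is stored as a 4D volume `(nx, ny, nz, 3)` of displacements in
#' mm on the T2 grid.
#'
#' @param field a [deformation_field()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_field <- function(field, path) {
  arr <- array(c(field$dx, field$dy, field$dz), dim = c(field_dim(field), 3L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  m <- diag(c(field$spacing, 1))
  m[1:3, 4] <- field$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D NIfTI with 3 displacement components", call. = FALSE)
  m <- unclass(RNifti::xform(img))
  arr <- as.array(img)
  deformation_field(arr[, , , 1], arr[, , , 2], arr[, , , 3],
                    spacing = diag(m[1:3, 1:3]), origin = m[1:3, 4])
}
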
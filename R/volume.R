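#' MRI volume with grid geometry
#'
#' Container for a 3D scalar MRI image together with its grid geometry.
#' World coordinates are in mm; voxel indices are 0-based; the world position
#' of the *center* of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#' Array axes are `(x, y, z)` = (left-right, anterior-posterior,
#' inferior-superior). Only axis-aligned grids are supported.
#'
#' @param data 3D numeric array of intensities (finite, non-negative).
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param origin numeric length-3, mm, world position of voxel (0,0,0) center.
#' @param modality `"T2"` or `"T1FS"`.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing, origin = c(0, 0, 0),
                       modality = c("T2", "T1FS")) {
  modality <- match.arg(modality)
  data <- array(as.numeric(data), dim(data)) # drop foreign attributes
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  vol <- structure(list(data = data, spacing = spacing, origin = origin,
                        modality = modality),
                   class = "mri_volume")
  validate_volume(vol)
  vol
}

validate_volume <- function(vol) {
  stopifnot(inherits(vol, "mri_volume"))
  if (length(dim(vol$data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(vol$data)),
         " dimensions", call. = FALSE)
  if (any(dim(vol$data) < 8L))
    stop("each volume dimension must be at least 8 voxels", call. = FALSE)
  if (length(vol$spacing) != 3L || any(!is.finite(vol$spacing)) ||
      any(vol$spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (length(vol$origin) != 3L || any(!is.finite(vol$origin)))
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  if (any(!is.finite(vol$data)))
    stop("all intensities must be finite", call. = FALSE)
  invisible(vol)
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Segment-labeled volume
#'
#' Integer labels on the grid of a reference volume: 0 = background,
#' 1 = ascending, 2 = transverse, 3 = descending, 4 = pelvic colon.
#'
#' @param labels 3D integer array with values in 0..4.
#' @param spacing,origin grid geometry (mm), as in [mri_volume()].
#' @param space `"T2"` or `"T1FS"` — which acquisition space the labels live in.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         space = c("T2", "T1FS")) {
  space <- match.arg(space)
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  if (any(is.na(labels)) || any(labels < 0L | labels > 4L))
    stop("labels must be integers in 0..4", call. = FALSE)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), space = space),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s space> %s voxels, %d labeled\n", x$space,
              paste(dim(x$labels), collapse = "x"), sum(x$labels > 0L)))
  invisible(x)
}

segment_names <- c("ascending", "transverse", "descending", "pelvic")

#' Convert between world (mm) and continuous voxel coordinates
#'
#' Voxel centers map to integer indices (0-based); points outside the grid are
#' transformed all the same (use [in_bounds()] to flag them).
#'
#' @param p numeric length-3 point or N x 3 matrix.
#' @param vol an [mri_volume()] or [label_volume()] (anything with `spacing`
#'   and `origin`).
#' @return Same shape as `p`: continuous voxel indices (or mm for the inverse).
#' @export
world_to_voxel <- function(p, vol) {
  p <- to_points(p)
  out <- sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/")
  drop_points(out)
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(p, vol) {
  p <- to_points(p)
  out <- sweep(sweep(p, 2, vol$spacing, "*"), 2, vol$origin, "+")
  drop_points(out)
}

#' @rdname world_to_voxel
#' @param tol bound tolerance in voxels.
#' @export
in_bounds <- function(p, vol, tol = 0) {
  v <- to_points(world_to_voxel(p, vol))
  d <- grid_dim(vol)
  ok <- rep(TRUE, nrow(v))
  for (ax in 1:3)
    ok <- ok & v[, ax] >= -tol & v[, ax] <= d[ax] - 1 + tol
  ok
}

grid_dim <- function(vol) {
  if (inherits(vol, "label_volume")) dim(vol$labels) else dim(vol$data)
}

to_points <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else {
    storage.mode(p) <- "double"
    p
  }
}

drop_points <- function(m) if (nrow(m) == 1L) as.numeric(m[1, ]) else m

#' Read / write a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into an [mri_volume()]. Spacing and origin are taken
#' from the sform/qform; the rotation part must be axis-aligned and positive
#' (no reorientation is attempted — oblique or flipped volumes are rejected).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality modality tag for the returned volume.
#' @return [read_volume()]: an `mri_volume`; [write_volume()]: `path`,
#'   invisibly.
#' @export
read_volume <- function(path, modality = c("T2", "T1FS")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D scalar image, got dim field [",
         paste(d, collapse = ", "), "]", call. = FALSE)
  m <- unclass(RNifti::xform(img))
  rot <- m[1:3, 1:3]
  spacing <- diag(rot)
  if (any(abs(rot - diag(spacing, 3)) > 1e-4 * max(abs(spacing), 1)))
    stop("srow/qform direction matrix is not axis-aligned identity; ",
         "reorientation is not supported", call. = FALSE)
  if (any(spacing <= 0))
    stop("non-positive spacing in pixdim/srow fields: [",
         paste(signif(spacing, 6), collapse = ", "), "]", call. = FALSE)
  mri_volume(as.array(img), spacing = spacing, origin = m[1:3, 4],
             modality = modality)
}

#' @rdname read_volume
#' @param vol an [mri_volume()] (or, for label masks, a [label_volume()]).
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "label_volume")) {
    arr <- vol$labels
  } else {
    validate_volume(vol)
    arr <- vol$data
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param space acquisition space of the labels on file.
#' @export
read_label_volume <- function(path, space = c("T2", "T1FS")) {
  space <- match.arg(space)
  vol <- read_volume(path, modality = "T2")
  label_volume(round(vol$data), spacing = vol$spacing, origin = vol$origin,
               space = space)
}

# all voxel centers of a grid as an N x 3 world-coordinate matrix (mm);
# fastest-varying first, matching R array linear order
grid_points <- function(vol) {
  d <- grid_dim(vol)
  i <- seq_len(d[1]) - 1
  j <- seq_len(d[2]) - 1
  k <- seq_len(d[3]) - 1
  cbind(vol$origin[1] + rep(i, times = d[2] * d[3]) * vol$spacing[1],
        vol$origin[2] + rep(rep(j, each = d[1]), times = d[3]) * vol$spacing[2],
        vol$origin[3] + rep(k, each = d[1] * d[2]) * vol$spacing[3])
}

# robust [p1, p99] rescale of intensities to [0, 1]
normalize_robust <- function(x, probs = c(0.01, 0.99)) {
  q <- quantile(x, probs, names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim = dim(x)))
  y <- (x - q[1]) / (q[2] - q[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}
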
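#' Probabilistic colon-tissue model from intensities and path distance
#'
#' Factorized probability that a voxel belongs to the colon,
#' `P(v) = L(I(v)) * D(d(v))`:
#' * `L` — kernel-density intensity likelihood fitted on voxels within
#'   `r0 / 2` of the medial path (the "core" of the tube), rescaled so its
#'   mode maps to 1 (Silverman bandwidth);
#' * `D` — distance prior, the logistic fall-off
#'   `1 / (1 + exp((d - r0) / (r0 / 4)))`, monotone non-increasing in the
#'   Euclidean distance `d` to the path polyline.
#'
#' @param t2 T2 [mri_volume()].
#' @param path a [medial_path()].
#' @param r0 distance-prior scale (mm): distance at which the prior drops
#'   to 0.5.
#' @return An object of class `tissue_probability`: list with `prob` (3D
#'   array in \[0, 1\]), `likelihood` (function of intensity), `dist` (3D
#'   array, mm to the path), `r0`, `path`.
#' @export
build_probability_model <- function(t2, path, r0 = 15) {
  validate_volume(t2)
  if (!inherits(path, "medial_path") || nrow(path$points) < 2L)
    stop("non-empty medial path required", call. = FALSE)
  if (r0 <= 0) stop("r0 must be positive", call. = FALSE)
  dims <- dim(t2$data)
  pl <- cpp_grid_polyline(dims, t2$spacing, t2$origin, path$points,
                          path$arc_length)
  core <- t2$data[pl$dist <= r0 / 2]
  if (length(core) < 10L)
    stop("no voxels within r0/2 of the path to fit the intensity model",
         call. = FALSE)
  dens <- density(core, bw = "nrd0")
  lik <- approxfun(dens$x, dens$y / max(dens$y), yleft = 0, yright = 0)
  D <- 1 / (1 + exp((pl$dist - r0) / (r0 / 4)))
  prob <- array(lik(t2$data) * D, dims)
  structure(list(prob = prob, likelihood = lik, dist = pl$dist, r0 = r0,
                 path = path),
            class = "tissue_probability")
}

#' @export
print.tissue_probability <- function(x, ...) {
  cat(sprintf("<tissue_probability> r0 = %g mm, prob in [%.3f, %.3f]\n",
              x$r0, min(x$prob), max(x$prob)))
  invisible(x)
}
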
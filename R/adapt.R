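#' Fecal-content probability model in T1-FS
#'
#' Fits a two-component Gaussian mixture to the T1-FS intensities inside an
#' initial colon mask (bright component = feces, dark component = gas/fat)
#' and evaluates the posterior probability of the brighter component
#' everywhere on the grid. The posterior is forced monotone non-decreasing in
#' intensity by isotonic correction, so brighter always means more likely
#' fecal.
#'
#' @param t1fs T1-FS [mri_volume()].
#' @param mask_init logical/integer 3D array on the T1-FS grid (nonzero =
#'   inside the transferred colon); needs at least 50 voxels.
#' @return An object of class `content_probability`: list with `prob` (3D
#'   array in \[0, 1\]), `posterior` (function of intensity), `means`,
#'   `sds`, `weights` of the two components.
#' @export
build_content_probability <- function(t1fs, mask_init) {
  validate_volume(t1fs)
  sel <- as.array(mask_init) != 0
  if (!identical(dim(sel), dim(t1fs$data)))
    stop("mask grid does not match the volume", call. = FALSE)
  vals <- t1fs$data[sel]
  if (length(vals) < 50L)
    stop("mask_init has fewer than 50 voxels; cannot fit the mixture",
         call. = FALSE)
  fit <- Mclust(vals, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1L) sdv <- rep(sdv, 2)
  pw <- fit$parameters$pro
  rng <- diff(range(vals))
  if (abs(diff(mu)) < 0.01 * max(rng, 1e-9))
    stop("mixture collapse: component means within 1% of intensity range",
         call. = FALSE)
  hi <- which.max(mu)
  lo <- 3L - hi
  post_raw <- function(x) {
    d_hi <- pw[hi] * stats::dnorm(x, mu[hi], max(sdv[hi], 1e-6))
    d_lo <- pw[lo] * stats::dnorm(x, mu[lo], max(sdv[lo], 1e-6))
    d_hi / (d_hi + d_lo + 1e-300)
  }
  # isotonic correction on an intensity grid covering the volume
  gx <- seq(min(t1fs$data), max(t1fs$data), length.out = 512)
  iso <- isoreg(gx, post_raw(gx))
  posterior <- approxfun(gx, pmin(pmax(iso$yf, 0), 1), yleft = iso$yf[1],
                         yright = iso$yf[length(gx)])
  prob <- array(posterior(t1fs$data), dim(t1fs$data))
  structure(list(prob = prob, posterior = posterior,
                 means = unname(mu[c(lo, hi)]), sds = unname(sdv[c(lo, hi)]),
                 weights = unname(pw[c(lo, hi)])),
            class = "content_probability")
}

#' @export
print.content_probability <- function(x, ...) {
  cat(sprintf(
    "<content_probability> components: dark %.1f (sd %.1f), bright %.1f (sd %.1f)\n",
    x$means[1], x$sds[1], x$means[2], x$sds[2]))
  invisible(x)
}

#' Transfer a T2 label volume into T1-FS space through a deformation field
#'
#' For every voxel of the T1-FS grid the preimage under `p -> p + d(p)` is
#' found by fixed-point inversion and the label is taken from the nearest T2
#' voxel (nearest-label resampling; interpolation is never applied to
#' labels).
#'
#' @param seg_t2 [label_volume()] in T2 space.
#' @param field [deformation_field()] on the T2 grid.
#' @param t1fs T1-FS [mri_volume()] providing the target grid.
#' @return A [label_volume()] in T1-FS space.
#' @export
transfer_labels <- function(seg_t2, field, t1fs) {
  dims <- dim(t1fs$data)
  pts <- grid_points(t1fs)
  inv <- cpp_invert_field(field$dx, field$dy, field$dz, field_dim(field),
                          field$spacing, field$origin, pts, 1e-3, 50L)
  mask_vox <- seg_t2$labels[seg_t2$labels > 0L]
  if (!length(mask_vox)) stop("empty T2 segmentation", call. = FALSE)
  if (median(inv$residual) > 1) # bulk non-convergence = non-invertible field
    stop("deformation field is not invertible over the target grid",
         call. = FALSE)
  lab <- cpp_sample_nearest(seg_t2$labels, dim(seg_t2$labels),
                            seg_t2$spacing, seg_t2$origin, inv$points, 0L)
  label_volume(array(lab, dims), t1fs$spacing, t1fs$origin, "T1FS")
}

#' Configuration for T1-FS surface adaptation
#'
#' @param delta step (mm) of the per-iteration surface motion.
#' @param corridor shape-preservation corridor (mm): the adapted surface may
#'   move at most this far outward from the transferred surface (and never
#'   inward past it).
#' @param n_max maximum iterations.
#' @param probe_voxels probe distance outside the surface, in mean voxels.
#' @param smooth_weight Laplacian smoothing weight per iteration.
#' @param tol stop when the mean per-iteration surface displacement (mm)
#'   falls below this.
#' @return A named list of class `adapt_config`.
#' @export
adapt_config <- function(delta = 0.5, corridor = 6, n_max = 100L,
                         probe_voxels = 2, smooth_weight = 0.5,
                         tol = 0.05) {
  structure(list(delta = delta, corridor = corridor,
                 n_max = as.integer(n_max), probe_voxels = probe_voxels,
                 smooth_weight = smooth_weight, tol = tol),
            class = "adapt_config")
}

#' Adapt the transferred colon segmentation to the T1-FS image
#'
#' Pushes the T2 segmentation into T1-FS space ([transfer_labels()]) and then
#' iteratively adapts the colon surface to the T1-FS content: the surface is
#' represented implicitly as a signed distance function and moves along its
#' outward normal with speed `delta * max(0, 2 * pbar - 1)`, where `pbar` is
#' the fecal-content probability ([build_content_probability()]) averaged
#' over a probe placed `probe_voxels` voxels outside the surface — expansion
#' toward adjacent bright feces. In regions without fecal signal (gas-filled
#' colon is indistinguishable from tissue in T1-FS) the transferred T2 shape
#' is the authority and the surface does not move. Laplacian smoothing is
#' applied each iteration and the total motion is clamped to a corridor of
#' `corridor` mm outside the transferred surface (shape preservation).
#' Iteration stops when the mean per-iteration displacement drops below
#' `tol` mm, or after `n_max` iterations. The final surface is voxelized and
#' segment labels are re-assigned from the nearest transferred voxel.
#'
#' @param seg_t2 [label_volume()] in T2 space.
#' @param field [deformation_field()] (T2 -> T1-FS).
#' @param t1fs T1-FS [mri_volume()].
#' @param config an [adapt_config()].
#' @return A [label_volume()] in T1-FS space; attribute `"transferred"`
#'   holds the pre-adaptation transfer.
#' @export
adapt_colon_to_t1fs <- function(seg_t2, field, t1fs,
                                config = adapt_config()) {
  transferred <- transfer_labels(seg_t2, field, t1fs)
  dims <- dim(t1fs$data)
  mask0 <- transferred$labels > 0L
  if (!any(mask0))
    stop("transferred segmentation is empty", call. = FALSE)
  if (config$n_max == 0L) {
    out <- transferred
    attr(out, "transferred") <- transferred
    return(out)
  }
  cp <- build_content_probability(t1fs, mask0)
  phi0 <- signed_distance(mask0, t1fs$spacing)
  phi <- phi0
  h <- mean(t1fs$spacing)
  probe_d <- config$probe_voxels * h
  bandw <- config$corridor + 2 * h
  for (it in seq_len(config$n_max)) {
    band <- which(abs(phi) < bandw)
    if (!length(band)) break
    g <- gradient3d(phi, t1fs$spacing)
    gn <- sqrt(g$x^2 + g$y^2 + g$z^2)
    gn[gn < 1e-9] <- 1e-9
    nx <- g$x[band] / gn[band]
    ny <- g$y[band] / gn[band]
    nz <- g$z[band] / gn[band]
    vox <- arrayInd(band, dims) - 1L
    base <- voxel_to_world(vox, t1fs)
    base <- to_points(base)
    # project onto the surface, then probe outside along the normal
    sx <- base[, 1] - phi[band] * nx
    sy <- base[, 2] - phi[band] * ny
    sz <- base[, 3] - phi[band] * nz
    # the probe takes the maximum over samples spanning the probe depth:
    # averaging instead would mix in beyond-wall (fat/tissue) samples and
    # stall the advancing front one voxel short of the colon wall
    pbar <- 0
    for (pd in probe_d * c(0.25, 0.5, 0.75, 1)) {
      pp <- cbind(sx + pd * nx, sy + pd * ny, sz + pd * nz)
      pbar <- pmax(pbar, cpp_sample_trilinear(cp$prob, dims, t1fs$spacing,
                                              t1fs$origin, pp, 0, TRUE))
    }
    speed <- config$delta * pmax(0, 2 * pbar - 1)
    phi_new <- phi
    phi_new[band] <- phi[band] - speed
    # Laplacian smoothing of the implicit surface
    w <- config$smooth_weight
    phi_new <- (1 - w) * phi_new +
      w * cpp_gauss3d(phi_new, dims, rep(0.7, 3))
    # corridor clamp: expansion at most `corridor`, never inward
    phi_new <- pmax(phi_new, phi0 - config$corridor)
    phi_new <- pmin(phi_new, phi0)
    # convergence is judged on the moving part of the surface: averaging
    # over the whole band would dilute a locally advancing front to below
    # any tolerance after the first iteration
    dmove <- abs(phi_new[band] - phi[band])
    active <- dmove > 1e-6
    move <- if (any(active)) mean(dmove[active]) else 0
    phi <- array(phi_new, dims)
    if (it %% 5L == 0L)
      phi <- redistance(phi, t1fs$spacing)
    if (move < config$tol) break
  }
  mask <- phi < 0
  mask[mask0] <- TRUE # clamp guarantees the transferred interior is kept
  # voxel-level completion of the same expansion law: the implicit surface
  # halts at the sub-voxel wall position, which strands a one-voxel fecal
  # skin outside the center-inside voxelization; annex 6-neighbors of the
  # mask whose fecal posterior exceeds the same 0.5 threshold
  for (pass in 1:2) {
    nb <- array(FALSE, dims)
    for (ax in 1:3) {
      idx_a <- slice.index(nb, ax) <= dims[ax] - 1L
      idx_b <- slice.index(nb, ax) >= 2L
      na <- nb[idx_a]; na[mask[idx_b]] <- TRUE; nb[idx_a] <- na
      nbv <- nb[idx_b]; nbv[mask[idx_a]] <- TRUE; nb[idx_b] <- nbv
    }
    add <- nb & !mask & cp$prob > 0.5 & phi0 <= config$corridor
    if (!any(add)) break
    mask <- mask | add
  }
  # re-assign segment labels from the nearest transferred voxel
  ed <- cpp_edt(array(as.integer(mask0), dims), dims, t1fs$spacing)
  lab <- array(0L, dims)
  lab[mask] <- transferred$labels[ed$feature[mask]]
  out <- label_volume(lab, t1fs$spacing, t1fs$origin, "T1FS")
  attr(out, "transferred") <- transferred
  out
}

# signed Euclidean distance (negative inside)
signed_distance <- function(mask, spacing) {
  dims <- dim(mask)
  din <- cpp_edt(array(as.integer(mask), dims), dims, spacing)$dist
  dout <- cpp_edt(array(as.integer(!mask), dims), dims, spacing)$dist
  din - dout # outside: distance to mask (+); inside: -distance to outside
}

redistance <- function(phi, spacing) {
  inside <- phi < 0
  sd <- signed_distance(inside, spacing)
  # preserve the sub-voxel zero level approximately by offsetting half a voxel
  sd + sign(sd) * 0 # plain re-distance; adequate at these step sizes
}
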
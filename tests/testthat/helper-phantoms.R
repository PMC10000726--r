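# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast phantom for unit tests
small_spec <- function(seed = 0L, ...) {
  phantom_spec(shape = c(64, 64, 44), spacing = c(2.5, 2.5, 3),
               radius_mean = 11, radius_amp = 2, seed = seed, ...)
}

small_phantom <- function(seed = 0L, ...) {
  key <- paste0("small_", seed, "_", paste(deparse(list(...)), collapse = ""))
  cached(key, generate_phantom(small_spec(seed = seed, ...)))
}

# default-condition phantom (the acceptance-scale configuration)
default_phantom <- function(seed = 0L) {
  cached(paste0("default_", seed), generate_phantom(phantom_spec(seed = seed)))
}

# straight-cylinder phantom: axis along z, radius constant, noiseless
cylinder_spec <- function(length_mm = 200, radius = 10, spacing = c(1, 1, 1),
                          margin = 24) {
  n_xy <- ceiling((2 * margin + 2 * radius) / spacing[1])
  n_z <- ceiling((length_mm + 2 * margin) / spacing[3])
  ctr <- (n_xy - 1) * spacing[1] / 2
  zs <- margin + seq(0, length_mm, length.out = 9)
  ctrl <- cbind(ctr, ctr, zs)
  attr(ctrl, "boundary_rows") <- c(1L, 3L, 5L, 7L, 9L)
  phantom_spec(shape = c(n_xy, n_xy, n_z), spacing = spacing, path = ctrl,
               radius_mean = radius, radius_amp = 0,
               noise_sigma = c(t2 = 0, t1fs = 0), n_bumps = 0,
               distractors = FALSE, liver = FALSE, seed = 0L)
}

cylinder_phantom <- function() {
  cached("cylinder", generate_phantom(cylinder_spec()))
}

# tiny valid marker set on a given volume
toy_markers <- function(vol, n_extra = 0L) {
  d <- (dim(vol$data) - 1) * vol$spacing
  base <- cbind(seq(0.2, 0.8, length.out = 5 + n_extra) * d[1],
                d[2] / 2, d[3] / 2)
  tags <- rep("intermediate", 5 + n_extra)
  tags[round(seq(1, 5 + n_extra, length.out = 5))] <- boundary_tags_vec()
  marker_set(data.frame(tag = tags, x = base[, 1], y = base[, 2],
                        z = base[, 3]))
}

boundary_tags_vec <- function() {
  c("cecum_start", "asc_trans", "trans_desc", "desc_pelvic", "pelvic_end")
}

# brute-force minimum-energy labeling by exhaustive enumeration
enumerate_min_energy <- function(cost_fg, cost_bg, edges, w) {
  n <- length(cost_fg)
  best <- Inf
  best_x <- NULL
  for (m in 0:(2^n - 1)) {
    x <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    e <- sum(cost_fg[x]) + sum(cost_bg[!x]) +
      if (nrow(edges)) sum(w[x[edges[, 1]] != x[edges[, 2]]]) else 0
    if (e < best) {
      best <- e
      best_x <- x
    }
  }
  list(energy = best, labeling = best_x)
}

# exact 1-D k-means by enumeration of sorted split points
split_enum_kmeans <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  css <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- Inf
  if (k == 2) {
    for (i in 1:(n - 1)) best <- min(best, css(xs[1:i]) + css(xs[(i + 1):n]))
  } else if (k == 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1))
      best <- min(best, css(xs[1:i]) + css(xs[(i + 1):j]) +
                    css(xs[(j + 1):n]))
  } else stop("k must be 2 or 3")
  best
}
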
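# Binary MRF energy minimization by minimum s-t cut.
#
# Energy over labels x in {0 (bg), 1 (fg)}:
#   E(x) = sum_v [x_v = 1] cost_fg[v] + [x_v = 0] cost_bg[v]
#        + sum_(u,v) in edges w_uv [x_u != x_v]
# Solved exactly (submodular pairwise terms, w >= 0) with one max-flow call
# (Dinic, compiled): s -> v capacity cost_bg[v], v -> t capacity cost_fg[v],
# symmetric n-links.

HARD_SEED <- 1e8

solve_mincut <- function(cost_fg, cost_bg, edges, w) {
  n <- length(cost_fg)
  stopifnot(length(cost_bg) == n, nrow(edges) == length(w), all(w >= 0))
  storage.mode(edges) <- "integer"
  cpp_mincut(cost_fg, cost_bg, edges, w)
}

cut_energy <- function(x, cost_fg, cost_bg, edges, w) {
  sum(cost_fg[x]) + sum(cost_bg[!x]) +
    if (nrow(edges)) sum(w[x[edges[, 1]] != x[edges[, 2]]]) else 0
}

# clamp -log(p) style unary costs to the spec'd range
neglog <- function(p) pmin(pmax(-log(p), 1e-6), 1e6)

# 6-neighborhood edges among "variable" voxels of a grid.
# var_id: integer array, 0 where not a variable, else 1..n variable index.
# Returns list(edges = m x 2 variable-index pairs, len = physical step mm,
#              dI = intensity difference, frozen_fg / frozen_bg = per-variable
#              counts of adjacent frozen voxels of each polarity weighted later)
grid_adjacency <- function(var_id, intensity, spacing, frozen_fg = NULL) {
  dims <- dim(var_id)
  edges <- NULL
  dI <- NULL
  len <- NULL
  shift_pairs <- function(ax) {
    idx_a <- slice.index(var_id, ax) <= dims[ax] - 1L
    idx_b <- slice.index(var_id, ax) >= 2L
    a <- var_id[idx_a]
    b <- var_id[idx_b]
    ia <- intensity[idx_a]
    ib <- intensity[idx_b]
    sel <- a > 0L & b > 0L
    list(e = cbind(a[sel], b[sel]), dI = ia[sel] - ib[sel],
         len = rep(spacing[ax], sum(sel)))
  }
  out <- lapply(1:3, shift_pairs)
  edges <- do.call(rbind, lapply(out, `[[`, "e"))
  if (is.null(edges)) edges <- matrix(0L, 0, 2)
  list(edges = edges,
       dI = unlist(lapply(out, `[[`, "dI")),
       len = unlist(lapply(out, `[[`, "len")))
}

# contrast-modulated pairwise weights
contrast_weights <- function(dI, len, lambda, sigma_c = NULL) {
  if (is.null(sigma_c)) sigma_c <- median(abs(dI))
  if (!is.finite(sigma_c) || sigma_c <= 0) sigma_c <- 1
  lambda * exp(-dI^2 / (2 * sigma_c^2)) / len
}

# boundary conditions from frozen neighbors: for each variable voxel, summed
# pairwise weight to adjacent frozen foreground / background voxels
frozen_terms <- function(var_id, frozen_lab, intensity, spacing, lambda,
                         sigma_c) {
  dims <- dim(var_id)
  n <- max(var_id)
  add_fg <- numeric(n) # penalty if variable is bg next to frozen fg
  add_bg <- numeric(n)
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      idx_a <- if (dir == 1L) slice.index(var_id, ax) <= dims[ax] - 1L else
        slice.index(var_id, ax) >= 2L
      idx_b <- if (dir == 1L) slice.index(var_id, ax) >= 2L else
        slice.index(var_id, ax) <= dims[ax] - 1L
      a <- var_id[idx_a]
      fl <- frozen_lab[idx_b] # -1 not frozen, 0 frozen bg, 1 frozen fg
      ia <- intensity[idx_a]
      ib <- intensity[idx_b]
      sel <- a > 0L & fl >= 0L
      if (!any(sel)) next
      w <- contrast_weights(ia[sel] - ib[sel], spacing[ax], lambda, sigma_c)
      isfg <- fl[sel] == 1L
      if (any(isfg))
        add_fg[a[sel][isfg]] <- add_fg[a[sel][isfg]] + w[isfg]
      if (any(!isfg))
        add_bg[a[sel][!isfg]] <- add_bg[a[sel][!isfg]] + w[!isfg]
    }
  }
  # being bg next to frozen fg costs add_fg; being fg next to frozen bg
  # costs add_bg
  list(cost_bg_extra = add_fg, cost_fg_extra = add_bg)
}
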
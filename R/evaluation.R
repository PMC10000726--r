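#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary 3D arrays or [label_volume()]s on the same grid (any
#'   nonzero voxel counts).
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_binary(a)
  b <- as_binary(b)
  if (!identical(dim(a), dim(b)))
    stop("grid mismatch between the two masks", call. = FALSE)
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Containment of ground-truth content in a segmentation
#'
#' Percentage of ground-truth fecal-content voxels lying inside the colon
#' segmentation: `100 |gt intersect seg| / |gt|`.
#'
#' @param gt_content non-empty binary ground-truth content mask.
#' @param seg segmentation mask on the same grid.
#' @return Percent in \[0, 100\].
#' @export
containment_r <- function(gt_content, seg) {
  gt <- as_binary(gt_content)
  sg <- as_binary(seg)
  if (!identical(dim(gt), dim(sg)))
    stop("grid mismatch between content truth and segmentation",
         call. = FALSE)
  if (!sum(gt))
    stop("empty ground-truth content: containment undefined", call. = FALSE)
  100 * sum(gt & sg) / sum(gt)
}

as_binary <- function(x) {
  if (inherits(x, "label_volume")) x$labels > 0L else as.array(x) != 0
}

#' Evaluate the full pipeline on a suite of phantoms
#'
#' For seeds `base_seed ... base_seed + n - 1`: generate the default phantom,
#' run the marker-guided T2 segmentation with the phantom's ground-truth
#' markers, register T2 to T1-FS and adapt the segmentation, then score the
#' Dice coefficient of the T2 segmentation against the T2 truth mask and the
#' containment R of the ground-truth feces voxels inside the adapted T1-FS
#' segmentation. Optionally the markers are jittered (Gaussian, `jitter_sd`
#' mm) to stress-test robustness to imprecise specialist clicks.
#'
#' @param n number of phantoms (>= 1).
#' @param base_seed first phantom seed.
#' @param spec_args named list of [phantom_spec()] overrides applied to every
#'   phantom.
#' @param t2_config a [t2seg_config()].
#' @param reg_cfg a [reg_config()].
#' @param adapt_cfg an [adapt_config()].
#' @param jitter_sd marker jitter (mm); 0 uses the exact truth markers.
#' @param use_truth_field bypass registration and use the phantom's analytic
#'   deformation (isolates the adaptation stage).
#' @param progress print one line per phantom.
#' @return An object of class `suite_summary`: list with `n`, `dsc_mean`,
#'   `dsc_sd`, `r_mean`, `r_sd` (population standard deviations) and
#'   `per_phantom` (data frame with seed, dsc, r, ok, error).
#' @export
evaluate_phantom_suite <- function(n = 10L, base_seed = 0L,
                                   spec_args = list(),
                                   t2_config = t2seg_config(),
                                   reg_cfg = reg_config(),
                                   adapt_cfg = adapt_config(),
                                   jitter_sd = 0, use_truth_field = FALSE,
                                   progress = FALSE) {
  stopifnot(n >= 1L)
  rows <- lapply(seq_len(n), function(i) {
    seed <- base_seed + i - 1L
    row <- data.frame(seed = seed, dsc = NA_real_, r = NA_real_, ok = FALSE,
                      error = NA_character_)
    out <- tryCatch({
      ph <- generate_phantom(do.call(phantom_spec,
                                     c(list(seed = seed), spec_args)))
      markers <- ph$markers
      if (jitter_sd > 0) {
        markers <- with_seed(seed + 31L, {
          an <- ph$markers$anatomical
          an[, c("x", "y", "z")] <- an[, c("x", "y", "z")] +
            matrix(rnorm(3 * nrow(an), 0, jitter_sd), ncol = 3)
          marker_set(an, ph$markers$refinement)
        })
      }
      seg2 <- segment_t2(ph$t2, markers, t2_config)
      row$dsc <- dice(seg2, ph$mask_t2)
      field <- if (use_truth_field) ph$field_truth else
        register_t2_to_t1fs(ph$t2, ph$t1fs, reg_cfg)
      seg1 <- adapt_colon_to_t1fs(seg2, field, ph$t1fs, adapt_cfg)
      row$r <- containment_r(ph$content_truth == 2L, seg1)
      row$ok <- TRUE
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    if (progress)
      message(sprintf("phantom seed %d: dsc %.3f, R %.1f%%%s", seed,
                      out$dsc, out$r,
                      if (!out$ok) paste(" [failed:", out$error, "]") else ""))
    out
  })
  per <- do.call(rbind, rows)
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1L) 0 else sqrt(mean((x - mean(x))^2))
  }
  structure(list(n = n,
                 dsc_mean = mean(per$dsc, na.rm = TRUE),
                 dsc_sd = pop_sd(per$dsc),
                 r_mean = mean(per$r, na.rm = TRUE),
                 r_sd = pop_sd(per$r),
                 incomplete = sum(!per$ok),
                 per_phantom = per),
            class = "suite_summary")
}

#' @export
print.suite_summary <- function(x, ...) {
  cat(sprintf(
    "<suite_summary> n = %d: DSC %.3f (sd %.3f), R %.1f%% (sd %.1f)%s\n",
    x$n, x$dsc_mean, x$dsc_sd, x$r_mean, x$r_sd,
    if (x$incomplete) sprintf(" [%d incomplete]", x$incomplete) else ""))
  invisible(x)
}

#' Write a content report (volumes + morphology + evaluation) to JSON/CSV
#'
#' @param volumes data frame from [quantify_content()].
#' @param morphology data frame from [compute_morphology()], or NULL.
#' @param evaluation optional named list (e.g. `dsc`, `r_containment`).
#' @param path output path; `.json` writes the full report, and a sibling
#'   `.csv` of the per-segment volume table is written alongside.
#' @return `path`, invisibly.
#' @export
write_report <- function(volumes, morphology = NULL, evaluation = NULL,
                         path) {
  report <- list(volumes = volumes)
  if (!is.null(morphology)) report$morphology <- morphology
  if (!is.null(evaluation)) report$evaluation <- evaluation
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  write.csv(volumes, sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
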
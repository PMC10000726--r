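boundary_tags <- c("cecum_start", "asc_trans", "trans_desc", "desc_pelvic",
                   "pelvic_end")

#' Anatomical and refinement marker set
#'
#' The specialist input guiding segmentation: an ordered list of at least five
#' anatomical reference points along the colon, tagged with the boundaries
#' they mark (start of cecum, ascending/transverse, transverse/descending,
#' descending/pelvic, end of pelvic colon), optionally interleaved with
#' `"intermediate"` points; plus optional refinement markers with an
#' include/exclude polarity used by [apply_refinement()].
#'
#' @param anatomical data frame with columns `tag` (one of `"cecum_start"`,
#'   `"asc_trans"`, `"trans_desc"`, `"desc_pelvic"`, `"pelvic_end"`,
#'   `"intermediate"`) and `x`, `y`, `z` (mm), in anatomical order.
#' @param refinement data frame with columns `polarity` (`"include"` or
#'   `"exclude"`) and `x`, `y`, `z` (mm); may be empty.
#' @param vol optional [mri_volume()]; when given, all points are checked to
#'   lie inside its bounds.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(anatomical, refinement = NULL, vol = NULL) {
  anatomical <- as.data.frame(anatomical)
  if (is.null(refinement))
    refinement <- data.frame(polarity = character(), x = numeric(),
                             y = numeric(), z = numeric())
  refinement <- as.data.frame(refinement)
  ms <- structure(list(anatomical = anatomical, refinement = refinement),
                  class = "marker_set")
  validate_markers(ms, vol)
  ms
}

validate_markers <- function(ms, vol = NULL) {
  problems <- character()
  an <- ms$anatomical
  if (!all(c("tag", "x", "y", "z") %in% names(an)))
    stop("anatomical markers need columns tag, x, y, z", call. = FALSE)
  if (nrow(an) < 5L)
    problems <- c(problems, sprintf(
      "at least 5 anatomical points required, got %d", nrow(an)))
  bad_tag <- setdiff(unique(an$tag), c(boundary_tags, "intermediate"))
  if (length(bad_tag))
    problems <- c(problems, paste("unknown tag(s):",
                                  paste(bad_tag, collapse = ", ")))
  counts <- table(factor(an$tag, levels = boundary_tags))
  if (any(counts != 1L))
    problems <- c(problems, paste(
      "each boundary tag must appear exactly once; counts:",
      paste(sprintf("%s=%d", boundary_tags, counts), collapse = ", ")))
  else {
    ord <- match(boundary_tags, an$tag)
    if (any(diff(ord) <= 0))
      problems <- c(problems, "boundary tags out of anatomical order")
  }
  rf <- ms$refinement
  if (nrow(rf) && !all(rf$polarity %in% c("include", "exclude")))
    problems <- c(problems, "refinement polarity must be include/exclude")
  if (!is.null(vol)) {
    pts <- rbind(as.matrix(an[, c("x", "y", "z")]),
                 if (nrow(rf)) as.matrix(rf[, c("x", "y", "z")]))
    out <- !in_bounds(pts, vol, tol = 0.5)
    if (any(out))
      problems <- c(problems, paste(
        "point(s) outside volume bounds at rows:",
        paste(which(out), collapse = ", ")))
  }
  if (length(problems))
    stop("invalid marker set:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(ms)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d anatomical (%d boundary), %d refinement\n",
              nrow(x$anatomical), sum(x$anatomical$tag %in% boundary_tags),
              nrow(x$refinement)))
  invisible(x)
}

anatomical_points <- function(ms) {
  as.matrix(ms$anatomical[, c("x", "y", "z")])
}

#' Read / write markers as JSON
#'
#' File dialect:
#' `{"anatomical": [{"tag": "...", "point_mm": [x,y,z]}, ...],`
#' ` "refinement": [{"polarity": "include"|"exclude", "point_mm": [x,y,z]}]}`.
#'
#' @param path JSON file path.
#' @param vol optional [mri_volume()] for bounds validation.
#' @return A validated [marker_set()].
#' @export
read_markers <- function(path, vol = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  js <- jsonlite::read_json(path)
  an <- do.call(rbind, lapply(js$anatomical, function(e) {
    p <- as.numeric(unlist(e$point_mm))
    if (length(p) != 3L)
      stop("anatomical point_mm must have 3 components", call. = FALSE)
    data.frame(tag = as.character(e$tag), x = p[1], y = p[2], z = p[3])
  }))
  rf <- do.call(rbind, lapply(js$refinement, function(e) {
    p <- as.numeric(unlist(e$point_mm))
    data.frame(polarity = as.character(e$polarity),
               x = p[1], y = p[2], z = p[3])
  }))
  marker_set(an, rf, vol = vol)
}

#' @rdname read_markers
#' @param ms a [marker_set()].
#' @export
write_markers <- function(ms, path) {
  js <- list(
    anatomical = lapply(seq_len(nrow(ms$anatomical)), function(r) {
      list(tag = ms$anatomical$tag[r],
           point_mm = as.numeric(ms$anatomical[r, c("x", "y", "z")]))
    }),
    refinement = lapply(seq_len(nrow(ms$refinement)), function(r) {
      list(polarity = ms$refinement$polarity[r],
           point_mm = as.numeric(ms$refinement[r, c("x", "y", "z")]))
    }))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
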
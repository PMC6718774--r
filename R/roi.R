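#' Construct a set of regions of interest (ROIs)
#'
#' A `roi_set` is a tibble with one row per detected cell body: an integer
#' `id` (1..K), a list-column `pixels` holding an n-by-2 integer matrix of
#' (row, col) pixel coordinates (1-based), the centroid as the arithmetic mean
#' of those coordinates, and the pixel area. The frame geometry is kept in the
#' `frame_dim` attribute so ROIs can be rasterized back into a label mask.
#'
#' @param pixels A list of integer matrices, each with columns (row, col); one
#'   entry per ROI. Pixel sets must be pairwise disjoint and non-empty.
#' @param frame_dim Integer vector `c(rows, cols)` of the source frame.
#'
#' @return A tibble of class `roi_set` with columns `id`, `pixels`,
#'   `centroid_row`, `centroid_col`, `area_px`.
#' @export
roi_set <- function(pixels = list(), frame_dim) {
  if (length(frame_dim) != 2L || any(frame_dim < 1)) {
    abort("`frame_dim` must be c(rows, cols).")
  }
  frame_dim <- as.integer(frame_dim)
  pixels <- lapply(pixels, function(p) {
    p <- matrix(as.integer(p), ncol = 2, dimnames = list(NULL, c("row", "col")))
    if (nrow(p) == 0L) abort("ROIs must contain at least one pixel.")
    if (any(p[, 1] < 1L | p[, 1] > frame_dim[1] |
            p[, 2] < 1L | p[, 2] > frame_dim[2])) {
      abort("ROI pixels fall outside the frame geometry.")
    }
    p
  })
  flat <- unlist(lapply(pixels, function(p) (p[, 2] - 1L) * frame_dim[1] + p[, 1]))
  if (anyDuplicated(flat)) abort("ROI pixel sets must be pairwise disjoint.")
  out <- tibble(
    id = seq_along(pixels),
    pixels = pixels,
    centroid_row = vapply(pixels, function(p) mean(p[, 1]), numeric(1)),
    centroid_col = vapply(pixels, function(p) mean(p[, 2]), numeric(1)),
    area_px = vapply(pixels, nrow, integer(1))
  )
  attr(out, "frame_dim") <- frame_dim
  class(out) <- c("roi_set", class(out))
  out
}

#' Frame geometry of a roi_set
#' @param rois A [roi_set()].
#' @return Integer `c(rows, cols)`.
#' @export
frame_dim <- function(rois) attr(rois, "frame_dim")

#' Rasterize ROIs into an integer label matrix
#'
#' Pixels of ROI `k` get value `k`; background is 0.
#'
#' @param rois A [roi_set()].
#' @return An integer matrix with the roi_set's frame geometry.
#' @export
as_label_matrix <- function(rois) {
  d <- frame_dim(rois)
  lab <- matrix(0L, d[1], d[2])
  for (k in seq_len(nrow(rois))) {
    p <- rois$pixels[[k]]
    lab[(p[, 2] - 1L) * d[1] + p[, 1]] <- rois$id[k]
  }
  lab
}

#' Build a roi_set from an integer label matrix
#'
#' Labels are compacted to the contiguous set 1..K (ordered by original label
#' value); components smaller than `min_size_px` are dropped.
#'
#' @param lab Integer matrix, 0 = background, k > 0 = ROI k.
#' @param min_size_px Minimum pixel count for an ROI to be kept.
#' @return A [roi_set()].
#' @export
roi_set_from_labels <- function(lab, min_size_px = 1L) {
  stopifnot(is.matrix(lab))
  fg <- which(lab > 0)
  groups <- split(fg, lab[fg])
  groups <- groups[order(as.numeric(names(groups)))]
  groups <- groups[vapply(groups, length, integer(1)) >= min_size_px]
  nr <- nrow(lab)
  pixels <- lapply(groups, function(idx) {
    cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
  })
  roi_set(unname(pixels), dim(lab))
}
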
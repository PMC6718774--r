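#' Min-max contrast stretch
#'
#' Rescales a frame linearly so the darkest pixel maps to 0 and the brightest
#' to 1: `I = (O - min O) / (max O - min O)`. This removes the arbitrary
#' intensity scale of the source footage before blob filtering, so detection
#' is invariant to exposure and bit depth.
#'
#' A constant frame has no contrast to stretch; it is returned as all zeros
#' with a warning.
#'
#' @param frame Numeric matrix.
#' @return Numeric matrix with values in `[0, 1]`.
#' @examples
#' stretch_contrast(matrix(c(2, 6, 4, 10), 2, 2))
#' @export
stretch_contrast <- function(frame) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  lo <- min(frame)
  hi <- max(frame)
  if (hi == lo) {
    warn("Constant frame: contrast stretch returns all zeros.")
    return(array(0, dim(frame)))
  }
  (frame - lo) / (hi - lo)
}

#' Normalized 1-D Gaussian kernel
#'
#' Discrete Gaussian weights `exp(-x^2 / (2 sigma^2))` evaluated on the
#' integer grid spanning a truncation radius of `ceiling(3 * sigma)` pixels
#' (capturing > 99.7% of the mass), renormalized to sum to 1 so convolution
#' preserves the mean intensity.
#'
#' @param sigma Standard deviation in pixels; must be `> 0`.
#' @return A numeric vector of odd length `2 * ceiling(3 * sigma) + 1`.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  r <- ceiling(3 * sigma)
  x <- seq.int(-r, r)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Map out-of-range indices into 1..n by symmetric reflection (edge repeated):
# ... 2 1 | 1 2 ... n-1 n | n n-1 ...
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  idx <- ((idx - 1L) %% period) + 1L
  ifelse(idx > n, period - idx + 1L, idx)
}

# Convolve each column of `m` with kernel `w` (odd length), reflect border.
conv_cols <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (k in seq_along(w)) {
    rows <- reflect_index(seq_len(nr) + (k - 1L - r), nr)
    out <- out + w[k] * m[rows, , drop = FALSE]
  }
  out
}

#' Separable Gaussian blur
#'
#' Convolves a frame with an isotropic 2-D Gaussian of standard deviation
#' `sigma`, implemented as two passes of the 1-D kernel from
#' [gaussian_kernel()] (rows then columns) — mathematically identical to the
#' full 2-D convolution but O(r) instead of O(r^2) per pixel. Borders use
#' symmetric reflection, which avoids the dark-halo artifacts of zero
#' padding.
#'
#' @param frame Numeric matrix.
#' @param sigma Standard deviation in pixels; must be `> 0`.
#' @return Blurred numeric matrix, same dimensions.
#' @export
gaussian_blur <- function(frame, sigma) {
  stopifnot(is.matrix(frame))
  w <- gaussian_kernel(sigma)
  t(conv_cols(t(conv_cols(frame, w)), w))
}

#' Difference-of-Gaussians blob filter
#'
#' `D = frame * G(sigma_a) - frame * G(sigma_b)`: a band-pass filter whose
#' response is strongest for bright blobs at the scale between the two
#' standard deviations. With `sigma_a < sigma_b` cell bodies appear as
#' positive peaks on a near-zero background; the output is signed and is
#' deliberately not re-normalized, so the detection threshold applies to the
#' raw response.
#'
#' @param frame Numeric matrix.
#' @param sigma_a,sigma_b Standard deviations (pixels) of the two Gaussians;
#'   both `> 0`. Equal values give an identically zero response.
#' @return Numeric matrix (may contain negatives).
#' @export
dog_filter <- function(frame, sigma_a, sigma_b) {
  gaussian_blur(frame, sigma_a) - gaussian_blur(frame, sigma_b)
}

#' Binary threshold
#'
#' Pixels strictly brighter than `th` are foreground; a pixel exactly equal
#' to the threshold is background.
#'
#' @param frame Numeric matrix.
#' @param th Threshold value.
#' @return Logical matrix.
#' @export
threshold_binary <- function(frame, th) {
  stopifnot(is.matrix(frame))
  frame > th
}

# Label connected foreground components with an explicit-queue flood fill
# (iterative; no recursion depth limit on large blobs). Scan order is
# column-major, so label numbering is deterministic.
label_matrix <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  }
  nnb <- length(dr)
  lab <- matrix(0L, nr, nc)
  queue <- integer(sum(mask))
  k <- 0L
  for (seed in which(mask)) {
    if (lab[seed] > 0L) next
    k <- k + 1L
    lab[seed] <- k
    queue[1L] <- seed
    qhead <- 1L
    qtail <- 1L
    while (qhead <= qtail) {
      cur <- queue[qhead]
      qhead <- qhead + 1L
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      for (t in seq_len(nnb)) {
        rr <- r0 + dr[t]
        cc <- c0 + dc[t]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          nb <- (cc - 1L) * nr + rr
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- k
            qtail <- qtail + 1L
            queue[qtail] <- nb
          }
        }
      }
    }
  }
  lab
}

#' Cluster a binary mask into ROIs
#'
#' Finds maximal connected clusters of foreground pixels and returns them as
#' a [roi_set()]; clusters smaller than `min_size_px` are discarded as noise.
#' Labeling is iterative (explicit work queue), so arbitrarily large blobs
#' cannot overflow the call stack.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   the default — two pixels touching only diagonally belong to one cluster).
#' @param min_size_px Minimum cluster size in pixels.
#' @return A [roi_set()].
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' label_components(m, min_size_px = 1)
#' @export
label_components <- function(mask, connectivity = 8L, min_size_px = 1L) {
  mask <- mask > 0
  roi_set_from_labels(label_matrix(mask, as.integer(connectivity)),
                      min_size_px = min_size_px)
}

#' Segmentation parameter set
#'
#' Bundles the five tunables of the ROI detector. `sigma_n` (pixels) is the
#' denoising blur; `sigma_a` and `sigma_b` (pixels) are the
#' difference-of-Gaussians pair — choose `sigma_a < sigma_b`, roughly
#' bracketing the cell-body radius, so cells give a positive response; `th`
#' is the threshold applied to the raw DoG response of the contrast-stretched
#' frame (typical useful values fall well below 1 because the band-pass
#' response of a unit-range image is small); `min_size_px` suppresses
#' single-pixel noise clusters.
#'
#' @param sigma_n Denoising Gaussian sd, pixels (`> 0`).
#' @param sigma_a,sigma_b DoG standard deviations, pixels (`> 0`, unequal for
#'   a non-degenerate detector).
#' @param th Brightness threshold on the DoG response, in `[0, 1]`.
#' @param connectivity 4 or 8.
#' @param min_size_px Minimum ROI area, pixels.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma_n = 1, sigma_a = 2, sigma_b = 6,
                                th = 0.1, connectivity = 8L, min_size_px = 4L) {
  stopifnot(sigma_n > 0, sigma_a > 0, sigma_b > 0, th >= 0, th <= 1,
            connectivity %in% c(4, 8), min_size_px >= 1)
  if (sigma_a == sigma_b) {
    warn("sigma_a == sigma_b gives a degenerate (all-zero) DoG detector.")
  }
  structure(list(sigma_n = sigma_n, sigma_a = sigma_a, sigma_b = sigma_b,
                 th = th, connectivity = as.integer(connectivity),
                 min_size_px = as.integer(min_size_px)),
            class = "segmentation_params")
}

#' Detect ROIs on a reference frame
#'
#' The full cell-detection chain: contrast stretch, Gaussian denoise
#' (`sigma_n`), difference-of-Gaussians band-pass (`sigma_a`, `sigma_b`),
#' strict threshold on the raw DoG response (`th`), and connected-component
#' clustering with a minimum-size filter. The user picks one representative
#' frame of the movie; its cell bodies define the ROIs used for all
#' downstream trace extraction. The initial stretch makes detection invariant
#' to multiplying the footage by any positive constant.
#'
#' @param stack An [image_stack()] (or a single numeric matrix).
#' @param reference_frame Index of the frame to segment.
#' @param params A [segmentation_params()].
#' @return A [roi_set()].
#' @export
detect_rois <- function(stack, reference_frame = 1L,
                        params = segmentation_params()) {
  frame <- if (is.matrix(stack)) stack else get_frame(stack, reference_frame)
  stretched <- stretch_contrast(frame)  # a blank frame warns, then yields no ROIs
  d <- dog_filter(gaussian_blur(stretched, params$sigma_n),
                  params$sigma_a, params$sigma_b)
  label_components(threshold_binary(d, params$th),
                   connectivity = params$connectivity,
                   min_size_px = params$min_size_px)
}

#' Apply manual ROI edits
#'
#' Removes the ROIs named in `remove` and appends the connected clusters of
#' `add` (a label or binary matrix congruent with the frame) with fresh ids.
#' Where an added cluster overlaps an automatic ROI, the overlapping pixels
#' are taken away from the automatic ROI so the set stays pairwise disjoint;
#' automatic ROIs emptied in the process are dropped. Ids are renumbered to
#' the contiguous set 1..K.
#'
#' @param auto A [roi_set()] from automatic detection.
#' @param add Optional integer/logical matrix of pixels to add; each
#'   connected cluster (8-connectivity, or the distinct positive labels if a
#'   label matrix is given) becomes one new ROI.
#' @param remove Optional vector of ROI ids to delete; unknown ids error.
#' @return A [roi_set()].
#' @export
merge_manual_rois <- function(auto, add = NULL, remove = NULL) {
  d <- frame_dim(auto)
  keep <- auto
  if (!is.null(remove)) {
    unknown <- setdiff(remove, auto$id)
    if (length(unknown)) {
      abort(sprintf("Unknown ROI id(s): %s", paste(unknown, collapse = ", ")))
    }
    keep <- keep[!keep$id %in% remove, ]
  }
  pixels <- keep$pixels
  if (!is.null(add)) {
    if (!identical(dim(add), as.integer(d)) && !identical(dim(add), d)) {
      abort("`add` mask must match the roi_set frame geometry.")
    }
    added <- if (is.logical(add) || all(add %in% c(0, 1))) {
      roi_set_from_labels(label_matrix(add > 0, 8L))
    } else {
      roi_set_from_labels(matrix(as.integer(add), d[1], d[2]))
    }
    taken <- unlist(lapply(added$pixels,
                           function(p) (p[, 2] - 1L) * d[1] + p[, 1]))
    pixels <- lapply(pixels, function(p) {
      flat <- (p[, 2] - 1L) * d[1] + p[, 1]
      p[!flat %in% taken, , drop = FALSE]
    })
    pixels <- pixels[vapply(pixels, nrow, integer(1)) > 0L]
    pixels <- c(pixels, added$pixels)
  }
  roi_set(pixels, d)
}
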
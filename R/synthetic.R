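#' Specification for a synthetic calcium-imaging movie
#'
#' Describes a movie with fully known ground truth: cells rendered as 2-D
#' Gaussian blobs on a dark background, each with its own baseline
#' brightness; calcium transients with instant rise and single-exponential
#' decay; additive Gaussian sensor noise; and, optionally, directed
#' propagation of spikes along planted edges with a fixed frame lag. All
#' randomness is a pure function of `seed`: each cell draws its baseline and
#' spontaneous spike train from its own deterministic substream, so adding
#' cells does not reshuffle existing ones.
#'
#' Spontaneous spikes are Bernoulli per frame at `spike_rate` (recycled over
#' cells), thinned so consecutive spikes of one cell are at least `min_gap`
#' frames apart (isolated transients), and only planted after the first
#' `margin_frames` frames — an initial quiescent baseline period such as a
#' recording started before stimulation. Planted edges then copy each source
#' spike to the target `lag` frames later with probability `prob`, in the
#' order the edges are listed (so chains cascade).
#'
#' @param n_cells Number of cells.
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames.
#' @param blob_sigma Gaussian radius of a cell body, pixels.
#' @param baseline_range Range `c(lo, hi)` of per-cell baseline peak
#'   brightness (arbitrary fluorescence units).
#' @param amplitude Peak added brightness of one transient, same units.
#' @param decay Transient decay constant, frames.
#' @param spike_rate Per-cell per-frame spontaneous spike probability
#'   (scalar or length `n_cells`).
#' @param noise_sd Sd of the additive Gaussian sensor noise.
#' @param bg_offset Constant dark offset added to every pixel (keeps
#'   intensities non-negative, like a camera pedestal).
#' @param min_gap Minimum frames between successive spikes of one cell.
#' @param margin_frames Initial spike-free frames.
#' @param edges Optional tibble/data.frame `(source, target, lag, prob)` of
#'   planted directed connections.
#' @param scripted_spikes Optional named list (by cell index) of fixed spike
#'   frames; a scripted cell skips its Bernoulli draw.
#' @param positions Optional `n_cells` x 2 matrix of (row, col) centers;
#'   placed randomly with non-overlapping supports when omitted.
#' @param fps,um_per_px Calibration recorded on the generated stack.
#' @param seed Master seed (integer).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 20, height = 128, width = 128,
                           n_frames = 200, blob_sigma = 3,
                           baseline_range = c(90, 110), amplitude = 50,
                           decay = 10, spike_rate = 0.02, noise_sd = 10,
                           bg_offset = NULL, min_gap = 20, margin_frames = 15,
                           edges = NULL, scripted_spikes = NULL,
                           positions = NULL, fps = 10, um_per_px = 1,
                           seed = 1L) {
  stopifnot(n_cells >= 1, height > 0, width > 0, n_frames >= 1,
            blob_sigma > 0, length(baseline_range) == 2,
            baseline_range[1] <= baseline_range[2],
            amplitude >= 0, decay > 0, all(spike_rate >= 0),
            noise_sd >= 0, min_gap >= 1, margin_frames >= 0)
  if (!is.null(edges)) {
    edges <- tibble::as_tibble(edges)
    stopifnot(all(c("source", "target", "lag", "prob") %in% names(edges)),
              all(edges$source %in% seq_len(n_cells)),
              all(edges$target %in% seq_len(n_cells)),
              all(edges$lag >= 0), all(edges$prob >= 0 & edges$prob <= 1))
  }
  if (!is.null(positions)) {
    positions <- matrix(positions, ncol = 2)
    stopifnot(nrow(positions) == n_cells)
  }
  structure(list(
    n_cells = as.integer(n_cells), height = as.integer(height),
    width = as.integer(width), n_frames = as.integer(n_frames),
    blob_sigma = blob_sigma, baseline_range = baseline_range,
    amplitude = amplitude, decay = decay,
    spike_rate = rep_len(spike_rate, n_cells), noise_sd = noise_sd,
    bg_offset = bg_offset %||% (5 * noise_sd), min_gap = as.integer(min_gap),
    margin_frames = as.integer(margin_frames), edges = edges,
    scripted_spikes = scripted_spikes, positions = positions,
    fps = fps, um_per_px = um_per_px, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# deterministic per-cell substream seed (kept < 2^31)
cell_seed <- function(seed, k, salt = 0L) {
  (as.double(seed) * 48271 + k * 1000003 + salt * 7919) %% 2147483647
}

draw_spike_trains <- function(spec) {
  trains <- vector("list", spec$n_cells)
  for (k in seq_len(spec$n_cells)) {
    scripted <- spec$scripted_spikes[[as.character(k)]]
    if (!is.null(scripted)) {
      trains[[k]] <- sort(unique(as.integer(scripted)))
      next
    }
    set.seed(cell_seed(spec$seed, k, salt = 1L))
    cand <- which(runif(spec$n_frames) < spec$spike_rate[k])
    cand <- cand[cand > spec$margin_frames]
    kept <- integer()
    last <- -Inf
    for (t in cand) {
      if (t - last >= spec$min_gap) {
        kept <- c(kept, t)
        last <- t
      }
    }
    trains[[k]] <- kept
  }
  # propagate along planted edges, in listed order, so chains cascade
  if (!is.null(spec$edges)) {
    for (e in seq_len(nrow(spec$edges))) {
      src <- spec$edges$source[e]
      tgt <- spec$edges$target[e]
      lag <- spec$edges$lag[e]
      prob <- spec$edges$prob[e]
      set.seed(cell_seed(spec$seed, src, salt = 100L + tgt))
      fired <- trains[[src]][runif(length(trains[[src]])) < prob] + lag
      fired <- fired[fired <= spec$n_frames]
      trains[[tgt]] <- sort(unique(c(trains[[tgt]], as.integer(fired))))
    }
  }
  names(trains) <- as.character(seq_len(spec$n_cells))
  trains
}

draw_baselines <- function(spec) {
  vapply(seq_len(spec$n_cells), function(k) {
    set.seed(cell_seed(spec$seed, k, salt = 2L))
    runif(1, spec$baseline_range[1], spec$baseline_range[2])
  }, numeric(1))
}

# transient time course of one cell: instant rise, exponential decay
transient_course <- function(spikes, n_frames, amplitude, decay) {
  tr <- numeric(n_frames)
  for (t in spikes) {
    tr[t:n_frames] <- tr[t:n_frames] + amplitude * exp(-(0:(n_frames - t)) / decay)
  }
  tr
}

place_cells <- function(spec) {
  if (!is.null(spec$positions)) return(spec$positions)
  sep <- 2 * ceiling(2 * spec$blob_sigma) + 3  # non-overlapping supports
  margin <- ceiling(2 * spec$blob_sigma) + 1
  set.seed(cell_seed(spec$seed, 0L, salt = 3L))
  centers <- matrix(NA_real_, spec$n_cells, 2)
  for (k in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      cand <- c(runif(1, margin, spec$height - margin),
                runif(1, margin, spec$width - margin))
      if (k == 1L ||
          min(sqrt(rowSums((centers[seq_len(k - 1), , drop = FALSE] -
                              matrix(cand, k - 1, 2, byrow = TRUE))^2))) >= sep) {
        centers[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("Could not place cells without overlap; enlarge the frame or reduce n_cells.")
    }
  }
  centers
}

#' Generate synthetic brightness traces (fast path)
#'
#' Produces per-cell brightness traces with the same transient kinetics and
#' sensor noise as [generate_movie()], skipping the image rendering: cell
#' `k`'s trace is its baseline plus `amplitude * exp(-(n - t) / decay)` for
#' every spike `t`, plus white Gaussian noise of sd `noise_sd`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `traces` (a `trace_set` tibble), `spikes` (named list
#'   of true spike frames per cell) and `spec`.
#' @export
generate_traces <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  trains <- draw_spike_trains(spec)
  baselines <- draw_baselines(spec)
  set.seed(cell_seed(spec$seed, 0L, salt = 4L))
  traces <- purrr::map_dfr(seq_len(spec$n_cells), function(k) {
    b <- baselines[k] +
      transient_course(trains[[k]], spec$n_frames, spec$amplitude, spec$decay) +
      rnorm(spec$n_frames, 0, spec$noise_sd)
    tibble(roi_id = k, frame = seq_len(spec$n_frames), brightness = b)
  })
  class(traces) <- c("trace_set", class(traces))
  list(traces = traces, spikes = trains, spec = spec)
}

#' Generate a synthetic calcium-imaging movie with ground truth
#'
#' Renders each cell as a 2-D Gaussian blob (peak 1 at its center) scaled by
#' `baseline + amplitude * transient`, on a constant dark pedestal, with
#' additive Gaussian sensor noise per pixel and frame (clipped at zero, as a
#' camera would). The ground-truth label mask marks, for each cell, the
#' pixels within `2 * blob_sigma` of its center. Identical specs (including
#' the seed) give bit-identical movies.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `stack` (an [image_stack()]) and `truth` (list:
#'   `rois` ground-truth [roi_set()], `spikes` per-cell spike frames,
#'   `centers` matrix, `edges` planted edge tibble or NULL, `baselines`).
#' @export
generate_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  centers <- place_cells(spec)
  trains <- draw_spike_trains(spec)
  baselines <- draw_baselines(spec)
  nr <- spec$height
  nc <- spec$width
  nf <- spec$n_frames

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  blobs <- vector("list", spec$n_cells)
  mask_pix <- vector("list", spec$n_cells)
  for (k in seq_len(spec$n_cells)) {
    d2 <- (rows - centers[k, 1])^2 + (cols - centers[k, 2])^2
    blobs[[k]] <- exp(-d2 / (2 * spec$blob_sigma^2))
    inside <- which(d2 <= (2 * spec$blob_sigma)^2)
    mask_pix[[k]] <- cbind(row = ((inside - 1L) %% nr) + 1L,
                           col = ((inside - 1L) %/% nr) + 1L)
  }
  courses <- lapply(seq_len(spec$n_cells), function(k) {
    baselines[k] + transient_course(trains[[k]], nf, spec$amplitude, spec$decay)
  })
  frames <- array(spec$bg_offset, dim = c(nr, nc, nf))
  for (k in seq_len(spec$n_cells)) {
    bl <- blobs[[k]]
    ck <- courses[[k]]
    for (n in seq_len(nf)) frames[, , n] <- frames[, , n] + bl * ck[n]
  }
  if (spec$noise_sd > 0) {
    set.seed(cell_seed(spec$seed, 0L, salt = 5L))
    frames <- frames + array(rnorm(length(frames), 0, spec$noise_sd), dim(frames))
  }
  frames[frames < 0] <- 0
  list(
    stack = image_stack(frames, fps = spec$fps, um_per_px = spec$um_per_px),
    truth = list(rois = roi_set(mask_pix, c(nr, nc)), spikes = trains,
                 centers = centers, edges = spec$edges, baselines = baselines)
  )
}

#' Canonical synthetic benchmark presets
#'
#' Three ready-made study conditions used throughout the test suite and the
#' reproduction script:
#'
#' * `"segmentation"`: 20 well-separated blob cells (sigma 3 px) on a
#'   128 x 128 frame at peak signal-to-noise ratio ~10 (baselines 90-110,
#'   noise sd 10), no activity — exercises the ROI detector.
#' * `"spikes"`: 100 trace-only cells, 200 frames, isolated transients of
#'   amplitude 8 x noise sd (0.8 vs 0.1) with decay 10 frames — exercises
#'   the z-score detector at its default thresholds.
#' * `"network"`: 3 quiet cells in a row 20 px apart (2 um/px, 2 fps) with a
#'   planted chain 1 -> 2 -> 3 at 1-frame lag and deterministic
#'   transmission; only cell 1 spikes spontaneously. At 2 fps the 0.5 s
#'   response-delay cap admits only |lag| <= 1, which makes the planted
#'   chain identifiable (the lag-2 transitive correlation 1 -> 3 is
#'   inadmissible).
#'
#' @param preset One of `"segmentation"`, `"spikes"`, `"network"`.
#' @param seed Master seed.
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("segmentation", "spikes", "network"),
                             seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    segmentation = synthetic_spec(
      n_cells = 20, height = 128, width = 128, n_frames = 1,
      blob_sigma = 3, baseline_range = c(90, 110), amplitude = 0,
      spike_rate = 0, noise_sd = 10, fps = 10, um_per_px = 1, seed = seed),
    spikes = synthetic_spec(
      n_cells = 100, height = 64, width = 64, n_frames = 200,
      blob_sigma = 3, baseline_range = c(1, 2), amplitude = 0.8,
      decay = 10, spike_rate = 0.02, noise_sd = 0.1, min_gap = 20,
      margin_frames = 15, fps = 10, um_per_px = 1, seed = seed),
    network = synthetic_spec(
      n_cells = 3, height = 64, width = 64, n_frames = 300,
      blob_sigma = 3, baseline_range = c(100, 100), amplitude = 120,
      decay = 5, spike_rate = c(0.05, 0, 0), noise_sd = 1,
      min_gap = 10, margin_frames = 15,
      edges = tibble(source = c(1L, 2L), target = c(2L, 3L),
                     lag = c(1L, 1L), prob = c(1, 1)),
      positions = rbind(c(32, 12), c(32, 32), c(32, 52)),
      fps = 2, um_per_px = 2, seed = seed)
  )
}
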
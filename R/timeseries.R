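#' Extract per-ROI brightness traces
#'
#' The brightness of ROI `k` at frame `n` is the arithmetic mean of the
#' frame-`n` intensities over the ROI's pixel set. Absolute brightness
#' differs wildly between cells (dye loading, depth), which is why spike
#' detection works on the rate of change instead; the raw traces are still
#' the primary exported signal.
#'
#' @param stack An [image_stack()].
#' @param rois A [roi_set()] on the same frame geometry.
#' @return A tibble of class `trace_set` with columns `roi_id`, `frame`
#'   (1-based), `brightness`, ordered by ROI then frame.
#' @export
extract_traces <- function(stack, rois) {
  d <- dim(stack)
  fd <- frame_dim(rois)
  if (!identical(as.integer(d[1:2]), as.integer(fd))) {
    abort("ROI geometry does not match the stack frames.")
  }
  if (nrow(rois) == 0L) abort("Cannot extract traces from an empty roi_set.")
  nf <- d[3]
  flat <- matrix(stack, d[1] * d[2], nf)
  out <- purrr::map2_dfr(rois$id, rois$pixels, function(id, p) {
    idx <- (p[, 2] - 1L) * d[1] + p[, 1]
    tibble(roi_id = id, frame = seq_len(nf),
           brightness = colMeans(flat[idx, , drop = FALSE]))
  })
  class(out) <- c("trace_set", class(out))
  out
}

#' Brightness rate of change
#'
#' First difference `r[n] = b[n] - b[n-1]`, the baseline-invariant activity
#' signal: adding any constant to a trace leaves it unchanged. Defined for
#' frames 2..N.
#'
#' Given a numeric vector, returns the length-`N-1` difference vector; given
#' a `trace_set`, returns a long tibble `(roi_id, frame, rate)` with `frame`
#' starting at 2.
#'
#' @param b A numeric brightness vector (length >= 2) or a `trace_set`.
#' @return Numeric vector or tibble, matching the input kind.
#' @export
rate_of_change <- function(b) {
  if (is.numeric(b)) {
    if (length(b) < 2L) abort("Need at least two samples to differentiate.")
    return(diff(b))
  }
  stopifnot(is.data.frame(b))
  out <- b |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(frame = .data$frame[-1],
                   rate = diff(.data$brightness))
  if (nrow(out) == 0L) abort("Need at least two frames to differentiate.")
  class(out) <- c("rate_set", class(out))
  out
}

#' Spike-detection parameter set
#'
#' Tunables of the influence-limited sliding-window z-score detector:
#' `l` — window length in frames over which the running mean and standard
#' deviation of the (filtered) rate signal are estimated; `influence` — in
#' `[0, 1]`, how much a flagged sample is allowed to contaminate those
#' running estimates (1 = no protection, 0 = flagged samples are frozen
#' out); `th_z` — z-score threshold; `th_r` — absolute rate-of-change
#' threshold, in brightness units per frame, guarding against tiny but
#' statistically loud fluctuations; `min_spikes` — minimum number of spikes
#' for an ROI to be kept in downstream analysis. The defaults (10, 0.50, 5,
#' 0.100) are the validated settings for low-noise cortical-neuron footage.
#'
#' @param l Window length, frames (integer >= 2).
#' @param influence Mixing weight in `[0, 1]`.
#' @param th_z z-score threshold (> 0).
#' @param th_r Rate threshold (brightness units / frame).
#' @param min_spikes Minimum spike count for [filter_active()].
#' @return A list of class `spike_params`.
#' @export
spike_params <- function(l = 10L, influence = 0.50, th_z = 5, th_r = 0.100,
                         min_spikes = 0L) {
  stopifnot(l >= 2, l == floor(l), influence >= 0, influence <= 1,
            th_z > 0, min_spikes >= 0)
  structure(list(l = as.integer(l), influence = influence, th_z = th_z,
                 th_r = th_r, min_spikes = as.integer(min_spikes)),
            class = "spike_params")
}

# Core detector on one rate vector. Returns s, z and the filtered series.
detect_spikes_vector <- function(r, params) {
  l <- params$l
  n_samples <- length(r)
  if (l >= n_samples) {
    abort("Window length `l` must be shorter than the rate series.")
  }
  infl <- params$influence
  th_z <- params$th_z
  th_r <- params$th_r
  r_f <- r                      # warm-up: filtered series starts as the raw rates
  z <- rep(NA_real_, n_samples) # undefined during warm-up
  mu_l <- rep(NA_real_, n_samples)
  sigma_l <- rep(NA_real_, n_samples)
  s <- integer(n_samples)       # no detection during warm-up
  for (n in (l + 1L):n_samples) {
    w <- r_f[(n - l):(n - 1L)]
    mu <- sum(w) / l
    sigma <- sqrt(sum((w - mu)^2) / l)  # population (1/l) variance
    mu_l[n] <- mu
    sigma_l[n] <- sigma
    if (sigma > 0) {
      zn <- (r[n] - mu) / sigma
      zneg <- (-r[n] - 2 * mu) / sigma
    } else {
      # zero-dispersion window: any positive deviation is infinitely loud
      zn <- if (r[n] > mu) Inf else 0
      zneg <- if (-r[n] - 2 * mu > 0) Inf else 0
    }
    z[n] <- zn
    s[n] <- as.integer(r[n] > th_r && zn > th_z)
    # influence gate: detected spikes and strong negative excursions
    # (falling edges) only partially enter the running estimates
    if (s[n] == 1L || zneg > th_z) {
      r_f[n] <- infl * r[n] + (1 - infl) * r_f[n - 1L]
    } else {
      r_f[n] <- r[n]
    }
  }
  list(s = s, z = z, mu_l = mu_l, sigma_l = sigma_l, r_f = r_f)
}

#' Detect calcium spikes in rate-of-change signals
#'
#' Implements the robust sliding-window z-score detector. For each sample
#' `n` past the warm-up, the mean `mu_l` and population standard deviation
#' `sigma_l` of the *influence-filtered* rate series over the `l` preceding
#' samples are computed; the z-score is `z[n] = (r[n] - mu_l) / sigma_l`,
#' and frame `n` is a spike iff `r[n] > th_r` and `z[n] > th_z`. Samples
#' flagged as spikes — and strong negative excursions, the falling edges of
#' transients — enter the filtered series only through the mixing rule
#' `r_f[n] = i * r[n] + (1 - i) * r_f[n-1]`, which keeps one spike from
#' masking the next. During the first `l` samples (warm-up) the filtered
#' series equals the raw rates and no spike is reported. A zero-dispersion
#' window treats any positive deviation from the mean as a spike candidate
#' (z = Inf), so noiseless data remain detectable.
#'
#' For a numeric rate vector the full detector state is returned; for a
#' `rate_set` tibble the detector runs per ROI.
#'
#' @param r Numeric rate vector (length > `l`) or a tibble
#'   `(roi_id, frame, rate)` from [rate_of_change()].
#' @param params A [spike_params()].
#' @return For a vector: a list of class `spike_detection` with elements
#'   `s` (0/1 spikes), `z`, `mu_l`, `sigma_l`, `r_f` and `params`. For a
#'   tibble: a tibble of class `spike_set` with columns `roi_id`, `frame`,
#'   `rate`, `z`, `spike`.
#' @examples
#' r <- c(rep(0, 30), 1, rep(0, 5))
#' which(detect_spikes(r, spike_params())$s == 1)
#' @export
detect_spikes <- function(r, params = spike_params()) {
  if (is.numeric(r)) {
    out <- detect_spikes_vector(r, params)
    out$params <- params
    class(out) <- "spike_detection"
    return(out)
  }
  stopifnot(is.data.frame(r))
  out <- r |>
    dplyr::arrange(.data$roi_id, .data$frame) |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      det <- detect_spikes_vector(g$rate, params)
      tibble(roi_id = g$roi_id, frame = g$frame, rate = g$rate,
             z = det$z, spike = det$s)
    })
  class(out) <- c("spike_set", class(out))
  out
}

#' Keep only sufficiently active ROIs
#'
#' Drops ROIs whose spike count is below `min_spikes`; used to screen out
#' spontaneous one-off activity before network reconstruction.
#'
#' @param spikes A `spike_set` tibble from [detect_spikes()].
#' @param min_spikes Minimum number of detected spikes.
#' @return The filtered `spike_set`.
#' @export
filter_active <- function(spikes, min_spikes = 0L) {
  keep <- spikes |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(n_spikes = sum(.data$spike)) |>
    dplyr::filter(.data$n_spikes >= min_spikes)
  out <- spikes[spikes$roi_id %in% keep$roi_id, ]
  class(out) <- unique(c("spike_set", class(out)))
  out
}

#' Per-ROI spike summary
#'
#' Spike count and average spike frame `n_avg = sum(s[n] * n) / sum(s[n])`
#' for each ROI; `n_avg` is `NA` for silent ROIs.
#'
#' @param spikes A `spike_set` tibble.
#' @return A tibble `(roi_id, spike_count, n_avg)`.
#' @export
spike_summary <- function(spikes) {
  spikes |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      spike_count = as.integer(sum(.data$spike)),
      n_avg = ifelse(sum(.data$spike) > 0,
                     sum(.data$spike * .data$frame) / sum(.data$spike),
                     NA_real_)
    )
}
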
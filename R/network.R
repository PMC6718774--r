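#' Network reconstruction constraints
#'
#' The three physiological constraints on a putative connection between two
#' cells: `min_corr` — minimum (strictly exceeded) cross-correlation at the
#' best admissible lag, so only cells with similar spiking patterns are
#' linked; `max_dist_um` — maximum centroid distance, reflecting how far
#' neurites of the cultured cell type can physically reach (set it to the
#' image diagonal to recover a purely functional network); `max_delay_s` —
#' maximum delay between an incoming spike and the cellular response, which
#' together with the frame rate bounds the admissible lag window
#' `|tau| <= floor(max_delay_s * fps)`. The defaults (0.25, 208 um, 0.5 s)
#' are the validated settings for cultured cortical neurons.
#'
#' @param min_corr Minimum correlation, in `[0, 1]`.
#' @param max_dist_um Maximum connection length, micrometers (> 0).
#' @param max_delay_s Maximum response delay, seconds (>= 0).
#' @return A list of class `network_params`.
#' @export
network_params <- function(min_corr = 0.25, max_dist_um = 208,
                           max_delay_s = 0.5) {
  stopifnot(min_corr >= 0, min_corr <= 1, max_dist_um > 0, max_delay_s >= 0)
  structure(list(min_corr = min_corr, max_dist_um = max_dist_um,
                 max_delay_s = max_delay_s),
            class = "network_params")
}

# best lag: maximal x_tau; ties broken toward smallest |tau|, then positive tau
best_lag <- function(corrs, lags) {
  ord <- order(-corrs, abs(lags), -sign(lags))
  list(lag = lags[ord[1]], correlation = corrs[ord[1]])
}

#' Reconstruct the directed communication network
#'
#' For every unordered ROI pair the lagged cross-correlation of the chosen
#' signal is evaluated over the admissible lag window
#' `|tau| <= floor(max_delay_s * fps)` and summarized by its maximum; the
#' pair is connected iff that maximum strictly exceeds `min_corr` **and**
#' the centroid distance is at most `max_dist_um`. The sign of the best lag
#' gives the direction (leader to follower); a zero best lag is rendered as
#' two reciprocal edges, since leaderless synchrony carries no direction.
#' Ties between lags are broken toward the smallest `|tau|`, then the
#' positive lag.
#'
#' @param rois A [roi_set()].
#' @param signals Long signal tibble aligned to `rois` — by default the
#'   spike vectors (`spike_set`; "similar spiking patterns"), but brightness
#'   (`trace_set`) or rate (`rate_set`) tibbles work too.
#' @param fps Frame rate of the footage (frames/second).
#' @param um_per_px Pixel size (micrometers).
#' @param params A [network_params()].
#' @param signal Signal column name; inferred from `signals` when omitted.
#' @return An object of class `calcium_network`: a list with `edges` (tibble
#'   `source_roi, target_roi, best_lag, correlation, distance_um, delay_s`),
#'   `nodes` (ROI table), `adjacency` (binary K-by-K matrix), and the
#'   resolved parameters.
#' @export
reconstruct_network <- function(rois, signals, fps, um_per_px = 1,
                                params = network_params(), signal = NULL) {
  stopifnot(fps > 0)
  value_col <- signal %||% infer_signal_col(signals)
  m <- signal_matrix(signals, value_col)
  ids <- as.integer(colnames(m))
  max_lag <- floor(params$max_delay_s * fps)
  lags <- seq.int(-max_lag, max_lag)
  dists <- roi_distances(rois, um_per_px)
  edges <- tibble(source_roi = integer(), target_roi = integer(),
                  best_lag = integer(), correlation = numeric(),
                  distance_um = numeric(), delay_s = numeric())
  if (length(ids) >= 2L) {
    pair_rows <- purrr::pmap_dfr(dists[dists$roi_a %in% ids &
                                         dists$roi_b %in% ids, ],
                                 function(roi_a, roi_b, distance_um) {
      corrs <- vapply(lags, function(tau) {
        suppressWarnings(xcorr(m[, as.character(roi_a)],
                               m[, as.character(roi_b)], tau))
      }, numeric(1))
      bl <- best_lag(corrs, lags)
      tibble(roi_a = roi_a, roi_b = roi_b, best_lag = as.integer(bl$lag),
             correlation = bl$correlation, distance_um = distance_um)
    })
    if (nrow(pair_rows)) {
      hits <- pair_rows[pair_rows$correlation > params$min_corr &
                          pair_rows$distance_um <= params$max_dist_um, ]
      found <- purrr::pmap_dfr(hits, function(roi_a, roi_b, best_lag,
                                               correlation, distance_um) {
        # positive lag: roi_a leads roi_b
        base <- tibble(best_lag = as.integer(best_lag),
                       correlation = correlation,
                       distance_um = distance_um,
                       delay_s = abs(best_lag) / fps)
        if (best_lag > 0L) {
          dplyr::bind_cols(tibble(source_roi = roi_a, target_roi = roi_b), base)
        } else if (best_lag < 0L) {
          dplyr::bind_cols(tibble(source_roi = roi_b, target_roi = roi_a), base)
        } else {
          dplyr::bind_rows(
            dplyr::bind_cols(tibble(source_roi = roi_a, target_roi = roi_b), base),
            dplyr::bind_cols(tibble(source_roi = roi_b, target_roi = roi_a), base))
        }
      })
      if (nrow(found)) {
        edges <- dplyr::arrange(found, .data$source_roi, .data$target_roi)
      }
    }
  }
  adj <- matrix(0L, length(rois$id), length(rois$id),
                dimnames = list(rois$id, rois$id))
  if (nrow(edges)) {
    adj[cbind(match(edges$source_roi, rois$id),
              match(edges$target_roi, rois$id))] <- 1L
  }
  structure(list(edges = edges,
                 nodes = tibble::as_tibble(rois)[, c("id", "centroid_row",
                                                     "centroid_col", "area_px")],
                 adjacency = adj,
                 fps = fps, um_per_px = um_per_px, params = params,
                 signal = value_col),
            class = "calcium_network")
}

#' Binary adjacency matrix of a reconstructed network
#'
#' `adjacency(net)[i, j] == 1` iff the directed edge i -> j is present.
#'
#' @param net A `calcium_network`.
#' @return An integer 0/1 matrix with ROI ids as dimnames.
#' @export
adjacency <- function(net) {
  stopifnot(inherits(net, "calcium_network"))
  net$adjacency
}

#' @export
print.calcium_network <- function(x, ...) {
  cat(sprintf(
    "<calcium_network> %d ROIs, %d directed edge(s) [signal %s, min_corr %g, max_dist %g um, max_delay %g s]\n",
    nrow(x$nodes), nrow(x$edges), x$signal, x$params$min_corr,
    x$params$max_dist_um, x$params$max_delay_s))
  if (nrow(x$edges)) print(x$edges, ...)
  invisible(x)
}

#' @rdname tidy_caltrace
#' @method tidy calcium_network
#' @export
tidy.calcium_network <- function(x, ...) x$edges

#' Broom-style summaries of caltrace objects
#'
#' `tidy()` returns the row-per-result tibble (edges of a network, frame-wise
#' detector state of a spike detection, per-ROI assignments of a segmentation
#' match); `glance()` returns a one-row summary.
#'
#' @param x A `calcium_network`, `spike_detection` or `roi_match` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_caltrace
#' @method glance calcium_network
#' @export
glance.calcium_network <- function(x, ...) {
  tibble(n_rois = nrow(x$nodes),
         n_edges = nrow(x$edges),
         n_connected = length(unique(c(x$edges$source_roi, x$edges$target_roi))),
         min_corr = x$params$min_corr,
         max_dist_um = x$params$max_dist_um,
         max_delay_s = x$params$max_delay_s,
         fps = x$fps)
}

#' @rdname tidy_caltrace
#' @method tidy spike_detection
#' @export
tidy.spike_detection <- function(x, ...) {
  tibble(sample = seq_along(x$s), rate_index = seq_along(x$s),
         z = x$z, mu_l = x$mu_l, sigma_l = x$sigma_l,
         r_f = x$r_f, spike = x$s)
}

#' @rdname tidy_caltrace
#' @method glance spike_detection
#' @export
glance.spike_detection <- function(x, ...) {
  idx <- which(x$s == 1L)
  tibble(spike_count = length(idx),
         n_avg = if (length(idx)) mean(idx) else NA_real_,
         l = x$params$l, influence = x$params$influence,
         th_z = x$params$th_z, th_r = x$params$th_r)
}
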
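#' Lagged Pearson cross-correlation of two signals
#'
#' `x_tau = sum_n ((f[n - tau] - mu_f) / ||f - mu_f||) *
#' ((g[n] - mu_g) / ||g - mu_g||)`, where the means and norms are computed
#' on each full series and the sum runs over the overlapping index range for
#' the given lag. Positive `tau` means `f` leads `g` by `tau` frames. At
#' `tau = 0` this is the ordinary Pearson correlation, so
#' `xcorr(f, f, 0) == 1` for any non-constant `f`. A constant (zero-norm)
#' series correlates with nothing; the value is defined as 0, with a
#' warning.
#'
#' @param f,g Equal-length numeric signals (brightness, rate of change, or
#'   0/1 spike vectors).
#' @param tau Integer lag, `|tau| < length(f)`.
#' @return A scalar in `[-1, 1]`.
#' @examples
#' f <- c(0, 0, 1, 0, 0, 0, 1, 0)
#' xcorr(f, dplyr::lag(f, 1, default = 0), 1)
#' @export
xcorr <- function(f, g, tau = 0L) {
  n_len <- length(f)
  if (length(g) != n_len) abort("`f` and `g` must have equal length.")
  tau <- as.integer(tau)
  if (abs(tau) >= n_len) abort("|tau| must be smaller than the series length.")
  fc <- f - mean(f)
  gc <- g - mean(g)
  nf <- sqrt(sum(fc^2))
  ng <- sqrt(sum(gc^2))
  if (nf == 0 || ng == 0) {
    warn("Constant series has zero norm; cross-correlation defined as 0.")
    return(0)
  }
  idx <- max(1L, 1L + tau):min(n_len, n_len + tau)
  sum(fc[idx - tau] * gc[idx]) / (nf * ng)
}

# matrix [frame x roi] from a long tibble with the named value column
signal_matrix <- function(df, value_col) {
  wide <- tidyr::pivot_wider(df, id_cols = "frame", names_from = "roi_id",
                             values_from = dplyr::all_of(value_col))
  wide <- dplyr::arrange(wide, .data$frame)
  m <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Cross-correlation table over all ROI pairs and lags
#'
#' Computes `x_tau` for every ordered pair of ROIs and every lag in
#' `lags` from one of the three per-ROI signals: brightness `b`, rate of
#' change `r`, or the spike vector `s`. The zero-lag matrix is symmetric
#' with a unit diagonal (for non-constant signals).
#'
#' @param signals Long tibble carrying one signal column: a `trace_set`
#'   (`brightness`), a `rate_set` (`rate`) or a `spike_set` (`spike`).
#' @param lags Integer vector of lags (default -5..5, the usual display
#'   range).
#' @param signal Which column to correlate; inferred from the tibble's class
#'   when omitted.
#' @return A tibble `(roi_a, roi_b, lag, correlation)`.
#' @export
correlation_table <- function(signals, lags = -5:5, signal = NULL) {
  value_col <- signal %||% infer_signal_col(signals)
  m <- signal_matrix(signals, value_col)
  ids <- as.integer(colnames(m))
  if (length(ids) < 2L) abort("Need at least two ROIs to correlate.")
  pairs <- tidyr::expand_grid(roi_a = ids, roi_b = ids, lag = as.integer(lags))
  pairs$correlation <- purrr::pmap_dbl(pairs, function(roi_a, roi_b, lag) {
    suppressWarnings(xcorr(m[, as.character(roi_a)], m[, as.character(roi_b)], lag))
  })
  class(pairs) <- c("correlation_table", class(pairs))
  pairs
}

infer_signal_col <- function(df) {
  if (inherits(df, "spike_set")) return("spike")
  if (inherits(df, "rate_set")) return("rate")
  if (inherits(df, "trace_set")) return("brightness")
  for (col in c("spike", "brightness", "rate")) {
    if (col %in% names(df)) return(col)
  }
  abort("No signal column (brightness/rate/spike) found.")
}

#' Zero-lag correlation matrix
#'
#' @param tbl A [correlation_table()].
#' @param lag Which lag to extract (default 0).
#' @return A K-by-K numeric matrix with ROI ids as dimnames.
#' @export
correlation_matrix <- function(tbl, lag = 0L) {
  sub <- tbl[tbl$lag == lag, ]
  ids <- sort(unique(c(sub$roi_a, sub$roi_b)))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  m[cbind(match(sub$roi_a, ids), match(sub$roi_b, ids))] <- sub$correlation
  m
}

#' Per-ROI activity levels for a heat map
#'
#' Summarizes each ROI by a single activity scalar: mean brightness
#' (`kind = "b"`), mean absolute rate of change (`kind = "r"`), or spike
#' count (`kind = "s"`), normalized to `[0, 1]` by the maximum over ROIs.
#' If every ROI is silent all values are 0.
#'
#' @param signals The matching long tibble (`trace_set`, `rate_set` or
#'   `spike_set`).
#' @param kind One of `"b"`, `"r"`, `"s"`.
#' @return A tibble `(roi_id, value)`.
#' @export
heatmap_values <- function(signals, kind = c("s", "b", "r")) {
  kind <- match.arg(kind)
  col <- c(b = "brightness", r = "rate", s = "spike")[[kind]]
  raw <- signals |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(value = switch(kind,
                                    b = mean(.data[[col]]),
                                    r = mean(abs(.data[[col]])),
                                    s = sum(.data[[col]])))
  mx <- max(raw$value)
  raw$value <- if (mx > 0) raw$value / mx else rep(0, nrow(raw))
  raw
}

#' Pairwise centroid distances between ROIs
#'
#' Euclidean distance between ROI centroids in pixel units, scaled to
#' micrometers by `um_per_px`.
#'
#' @param rois A [roi_set()].
#' @param um_per_px Micrometers per pixel.
#' @return A tibble `(roi_a, roi_b, distance_um)` over unordered pairs
#'   (`roi_a < roi_b`).
#' @export
roi_distances <- function(rois, um_per_px = 1) {
  stopifnot(um_per_px > 0)
  n <- nrow(rois)
  if (n < 2L) return(tibble(roi_a = integer(), roi_b = integer(),
                            distance_um = numeric()))
  pairs <- tidyr::expand_grid(roi_a = rois$id, roi_b = rois$id) |>
    dplyr::filter(.data$roi_a < .data$roi_b)
  ra <- match(pairs$roi_a, rois$id)
  rb <- match(pairs$roi_b, rois$id)
  pairs$distance_um <- um_per_px * sqrt(
    (rois$centroid_row[ra] - rois$centroid_row[rb])^2 +
      (rois$centroid_col[ra] - rois$centroid_col[rb])^2)
  pairs
}

#' Centroid distance between two ROIs
#'
#' @param rois A [roi_set()].
#' @param a,b ROI ids.
#' @param um_per_px Micrometers per pixel.
#' @return Distance in micrometers.
#' @export
centroid_distance_um <- function(rois, a, b, um_per_px = 1) {
  ia <- match(a, rois$id)
  ib <- match(b, rois$id)
  if (is.na(ia) || is.na(ib)) abort("Unknown ROI id.")
  um_per_px * sqrt((rois$centroid_row[ia] - rois$centroid_row[ib])^2 +
                     (rois$centroid_col[ia] - rois$centroid_col[ib])^2)
}

#' Spatiotemporal map data
#'
#' One row per ROI with at least one detected spike: its centroid, spike
#' count (rendered as circle size) and average spike frame `n_avg`
#' (rendered as color, early to late).
#'
#' @param spikes A `spike_set` tibble.
#' @param rois The matching [roi_set()].
#' @return A tibble `(roi_id, centroid_row, centroid_col, spike_count,
#'   n_avg)`.
#' @export
spatiotemporal_map_data <- function(spikes, rois) {
  summ <- spike_summary(spikes)
  summ <- summ[summ$spike_count > 0, ]
  dplyr::inner_join(
    tibble::as_tibble(rois)[, c("id", "centroid_row", "centroid_col")],
    summ, by = c(id = "roi_id")) |>
    dplyr::rename(roi_id = "id")
}
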
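#' Match detected ROIs against ground truth
#'
#' Classifies every detected ROI and every ground-truth cell exactly once,
#' with overlap meaning at least `min_overlap_px` shared pixels:
#'
#' * a detected ROI overlapping two or more truth cells is **merged** (it is
#'   neither a TP nor, for the cells it covers, an automatic miss);
#' * a detected ROI overlapping no truth cell is a **false positive**;
#' * for each truth cell, among the single-cell detections overlapping it,
#'   the one with the largest overlap (ties: lowest detected id) is the
#'   **true positive**; the rest are redundant **false positives**;
#' * a truth cell overlapped by nothing is a **false negative**; a truth
#'   cell covered only by merged ROIs is bookkept separately
#'   (`merged_covered`), since merging is a distinct error mode.
#'
#' @param detected,truth [roi_set()] objects on the same frame geometry.
#' @param min_overlap_px Minimum shared pixels to count as overlap.
#' @return An object of class `roi_match`: list with `counts` (one-row
#'   tibble `P, TP, FP, FN, merged, merged_covered`), `detected` (per-ROI
#'   class and matched truth id) and `truth` (per-cell class).
#' @export
match_rois <- function(detected, truth, min_overlap_px = 1L) {
  if (!identical(frame_dim(detected), frame_dim(truth))) {
    abort("Detected and truth roi_sets must share the frame geometry.")
  }
  d <- frame_dim(truth)
  truth_lab <- as_label_matrix(truth)

  overlaps <- purrr::map2_dfr(detected$id, detected$pixels, function(id, p) {
    hit <- truth_lab[(p[, 2] - 1L) * d[1] + p[, 1]]
    hit <- hit[hit > 0L]
    if (length(hit) == 0L) {
      return(tibble(detected_id = id, truth_id = NA_integer_, overlap_px = 0L))
    }
    cnt <- table(hit)
    cnt <- cnt[cnt >= min_overlap_px]
    if (length(cnt) == 0L) {
      return(tibble(detected_id = id, truth_id = NA_integer_, overlap_px = 0L))
    }
    tibble(detected_id = id, truth_id = as.integer(names(cnt)),
           overlap_px = as.integer(cnt))
  })

  n_cells <- vapply(detected$id, function(id) {
    sum(!is.na(overlaps$truth_id[overlaps$detected_id == id]))
  }, integer(1))
  det_class <- ifelse(n_cells == 0L, "fp",
                      ifelse(n_cells >= 2L, "merged", "candidate"))
  names(det_class) <- detected$id

  det_tbl <- tibble(detected_id = detected$id, class = unname(det_class),
                    truth_id = NA_integer_)
  truth_class <- rep("fn", nrow(truth))
  names(truth_class) <- truth$id

  single <- overlaps[!is.na(overlaps$truth_id) &
                       det_class[as.character(overlaps$detected_id)] == "candidate", ]
  for (tid in truth$id) {
    cand <- single[single$truth_id == tid, ]
    if (nrow(cand)) {
      # largest overlap wins; ties go to the lowest detected id
      cand <- cand[order(-cand$overlap_px, cand$detected_id), ]
      win <- cand$detected_id[1]
      det_tbl$class[det_tbl$detected_id == win] <- "tp"
      det_tbl$truth_id[det_tbl$detected_id == win] <- tid
      truth_class[as.character(tid)] <- "tp"
    }
  }
  # single-cell candidates that did not win any cell are redundant FPs
  det_tbl$class[det_tbl$class == "candidate"] <- "fp"
  # truth cells covered only by merged detections
  merged_ids <- det_tbl$detected_id[det_tbl$class == "merged"]
  covered <- unique(overlaps$truth_id[overlaps$detected_id %in% merged_ids &
                                        !is.na(overlaps$truth_id)])
  truth_class[names(truth_class) %in% covered & truth_class == "fn"] <-
    "merged_covered"

  counts <- tibble(
    P = nrow(truth),
    TP = sum(det_tbl$class == "tp"),
    FP = sum(det_tbl$class == "fp"),
    FN = sum(truth_class == "fn"),
    merged = sum(det_tbl$class == "merged"),
    merged_covered = sum(truth_class == "merged_covered")
  )
  structure(list(counts = counts, detected = det_tbl,
                 truth = tibble(truth_id = truth$id, class = unname(truth_class))),
            class = "roi_match")
}

#' Segmentation quality scores
#'
#' `tpr = TP / P` (sensitivity against all manually found cells),
#' `ppv = TP / (TP + FP)` and `recall = TP / (TP + FN)`. A score whose
#' denominator is zero is reported as `NA`. Note `recall >= tpr` always,
#' because merged-covered cells count against P but not against FN.
#'
#' @param counts The `counts` tibble of a [match_rois()] result (or the
#'   `roi_match` itself).
#' @return A one-row tibble `(tpr, ppv, recall)`.
#' @export
segmentation_scores <- function(counts) {
  if (inherits(counts, "roi_match")) counts <- counts$counts
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    tpr = safe_div(counts$TP, counts$P),
    ppv = safe_div(counts$TP, counts$TP + counts$FP),
    recall = safe_div(counts$TP, counts$TP + counts$FN)
  )
}

#' @rdname tidy_caltrace
#' @method tidy roi_match
#' @export
tidy.roi_match <- function(x, ...) x$detected

#' @rdname tidy_caltrace
#' @method glance roi_match
#' @export
glance.roi_match <- function(x, ...) {
  dplyr::bind_cols(x$counts, segmentation_scores(x$counts))
}

#' Match detected spike frames against reference spike times
#'
#' Greedy in-order nearest-frame matching: both frame lists are sorted and
#' walked with two pointers; a detection within `tolerance_frames` of the
#' current truth spike consumes both. For tolerance-window matching on a
#' line this attains the maximum possible number of matches. Unmatched
#' detections are false positives, unmatched truth spikes false negatives.
#'
#' @param detected_frames,truth_frames Integer vectors of spike frames.
#' @param tolerance_frames Maximum |frame difference| for a match.
#' @return A one-row tibble `(P, TP, FP, FN)` where `P` is the number of
#'   truth spikes.
#' @export
match_spikes <- function(detected_frames, truth_frames, tolerance_frames = 1L) {
  d <- sort(detected_frames)
  t <- sort(truth_frames)
  di <- 1L
  ti <- 1L
  tp <- 0L
  while (di <= length(d) && ti <= length(t)) {
    if (abs(d[di] - t[ti]) <= tolerance_frames) {
      tp <- tp + 1L
      di <- di + 1L
      ti <- ti + 1L
    } else if (d[di] < t[ti]) {
      di <- di + 1L
    } else {
      ti <- ti + 1L
    }
  }
  tibble(P = length(t), TP = tp,
         FP = length(d) - tp, FN = length(t) - tp)
}

#' Score a spike_set against per-ROI truth spike times
#'
#' Runs [match_spikes()] per ROI and pools the counts; sensitivity is
#' `TP / P` and precision `TP / (TP + FP)`.
#'
#' @param spikes A `spike_set` tibble from [detect_spikes()].
#' @param truth A named list (by roi_id) or tibble `(roi_id, frame)` of true
#'   spike frames.
#' @param tolerance_frames Matching tolerance.
#' @return A one-row tibble `(P, TP, FP, FN, sensitivity, precision)`.
#' @export
spike_scores <- function(spikes, truth, tolerance_frames = 1L) {
  if (is.data.frame(truth)) {
    truth <- split(truth$frame, truth$roi_id)
  }
  ids <- sort(unique(c(as.integer(names(truth)), unique(spikes$roi_id))))
  counts <- purrr::map_dfr(ids, function(id) {
    det <- spikes$frame[spikes$roi_id == id & spikes$spike == 1L]
    tru <- truth[[as.character(id)]] %||% integer()
    match_spikes(det, tru, tolerance_frames)
  })
  tot <- dplyr::summarise(counts, P = sum(.data$P), TP = sum(.data$TP),
                          FP = sum(.data$FP), FN = sum(.data$FN))
  tot$sensitivity <- if (tot$P > 0) tot$TP / tot$P else NA_real_
  tot$precision <- if (tot$TP + tot$FP > 0) tot$TP / (tot$TP + tot$FP) else NA_real_
  tot
}
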
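square_roi <- function(r0, c0, size = 2) {
  as.matrix(expand.grid(row = r0:(r0 + size - 1), col = c0:(c0 + size - 1)))
}

test_that("a perfect segmentation scores all true positives", {
  truth <- roi_set(list(square_roi(2, 2), square_roi(2, 10), square_roi(10, 2)),
                   c(16, 16))
  m <- match_rois(truth, truth)
  expect_equal(as.list(m$counts),
               list(P = 3L, TP = 3L, FP = 0L, FN = 0L, merged = 0L,
                    merged_covered = 0L))
  expect_equal(segmentation_scores(m), tibble::tibble(tpr = 1, ppv = 1, recall = 1))
})

test_that("a detection spanning two cells is merged, not a true positive", {
  truth <- roi_set(list(square_roi(5, 2), square_roi(5, 6)), c(12, 12))
  blob <- roi_set(list(as.matrix(expand.grid(row = 5:6, col = 2:7))), c(12, 12))
  m <- match_rois(blob, truth)
  expect_equal(m$counts$merged, 1L)
  expect_equal(m$counts$TP, 0L)
  expect_equal(m$counts$FN, 0L)            # both cells covered by the merged blob
  expect_equal(m$counts$merged_covered, 2L)
})

test_that("redundant and stray detections are false positives", {
  truth <- roi_set(list(square_roi(3, 3, 4)), c(16, 16))
  detected <- roi_set(list(square_roi(3, 3), square_roi(5, 5),
                           square_roi(12, 12)), c(16, 16))
  m <- match_rois(detected, truth)
  expect_equal(m$counts$TP, 1L)
  expect_equal(m$counts$FP, 2L)
  # largest overlap wins the TP slot
  expect_equal(m$detected$class[m$detected$truth_id %in% 1L], "tp")
})

test_that("ties in overlap go to the lowest detected id", {
  truth <- roi_set(list(square_roi(4, 4, 4)), c(12, 12))
  detected <- roi_set(list(square_roi(4, 4), square_roi(6, 6)), c(12, 12))
  m <- match_rois(detected, truth)
  expect_equal(m$detected$class, c("tp", "fp"))
})

test_that("an undetected cell is a false negative", {
  truth <- roi_set(list(square_roi(2, 2), square_roi(8, 8)), c(12, 12))
  detected <- roi_set(list(square_roi(2, 2)), c(12, 12))
  m <- match_rois(detected, truth)
  expect_equal(m$counts$FN, 1L)
  expect_equal(m$truth$class, c("tp", "fn"))
})

test_that("every detection and every cell is classified exactly once", {
  set.seed(41)
  for (i in 1:50) {
    truth <- random_roi_set(20, 20, 0.25)
    detected <- random_roi_set(20, 20, 0.25)
    if (nrow(truth) == 0 || nrow(detected) == 0) next
    m <- match_rois(detected, truth)
    expect_equal(m$counts$TP + m$counts$FP + m$counts$merged, nrow(detected))
    expect_equal(m$counts$TP + m$counts$FN + m$counts$merged_covered,
                 m$counts$P)
    sc <- segmentation_scores(m)
    expect_equal(sc$tpr, m$counts$TP / m$counts$P)
    if (m$counts$TP + m$counts$FP > 0) {
      expect_equal(sc$ppv, m$counts$TP / (m$counts$TP + m$counts$FP))
    }
    expect_equal(sc$recall, m$counts$TP / (m$counts$TP + m$counts$FN))
    expect_gte(sc$recall, sc$tpr)
  }
})

test_that("scores are invariant under ROI relabeling", {
  set.seed(42)
  truth <- random_roi_set(15, 15, 0.3)
  detected <- random_roi_set(15, 15, 0.3)
  m1 <- match_rois(detected, truth)
  # reverse the detected ids by rebuilding from reversed pixel lists
  rev_detected <- roi_set(rev(detected$pixels), frame_dim(detected))
  m2 <- match_rois(rev_detected, truth)
  expect_equal(m1$counts[, c("P", "TP", "merged")],
               m2$counts[, c("P", "TP", "merged")])
  expect_equal(segmentation_scores(m1), segmentation_scores(m2))
})

test_that("degenerate denominators are reported as missing", {
  counts <- tibble::tibble(P = 5L, TP = 0L, FP = 0L, FN = 5L, merged = 0L,
                           merged_covered = 0L)
  sc <- segmentation_scores(counts)
  expect_equal(sc$tpr, 0)
  expect_true(is.na(sc$ppv))
  expect_equal(sc$recall, 0)
})

test_that("spike matching honors the frame tolerance", {
  same <- match_spikes(c(10, 20, 30), c(10, 20, 30), 1)
  expect_equal(as.list(same), list(P = 3L, TP = 3L, FP = 0L, FN = 0L))
  near <- match_spikes(11, 10, 1)
  expect_equal(near$TP, 1L)
  far <- match_spikes(12, 10, 1)
  expect_equal(as.list(far), list(P = 1L, TP = 0L, FP = 1L, FN = 1L))
})

test_that("greedy spike matching attains the optimal assignment on small cases", {
  set.seed(43)
  for (i in 1:100) {
    detected <- sort(sample(1:40, sample(0:8, 1)))
    truth <- sort(sample(1:40, sample(0:8, 1)))
    tol <- sample(0:3, 1)
    got <- match_spikes(detected, truth, tol)
    best <- oracle_spike_match(detected, truth, tol)
    expect_equal(got$TP, best)
    expect_equal(got$FP, length(detected) - best)
    expect_equal(got$FN, length(truth) - best)
  }
})

test_that("spike_scores pools per-ROI counts into sensitivity and precision", {
  spikes <- tibble::tibble(roi_id = rep(1:2, each = 6), frame = rep(2:7, 2),
                           spike = c(0L, 1L, 0L, 1L, 0L, 0L,
                                     0L, 0L, 1L, 0L, 0L, 1L))
  truth <- list(`1` = c(3, 5), `2` = c(4, 20))
  sc <- spike_scores(spikes, truth, tolerance_frames = 1)
  expect_equal(sc$TP, 3L)
  expect_equal(sc$FP, 1L)
  expect_equal(sc$FN, 1L)
  expect_equal(sc$sensitivity, 0.75)
  expect_equal(sc$precision, 0.75)
})
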
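# two ROIs 25 px apart on a 40x40 frame; spike train helpers
pair_rois <- function() {
  roi_set(list(cbind(c(10, 10), c(10, 11)), cbind(c(10, 10), c(35, 36))),
          c(40, 40))
}

spike_tbl <- function(trains, n_frames) {
  purrr::map_dfr(seq_along(trains), function(k) {
    tibble::tibble(roi_id = k, frame = seq_len(n_frames),
                   spike = as.integer(seq_len(n_frames) %in% trains[[k]]))
  })
}

test_that("a 1-frame-shifted pair yields a single edge from leader to follower", {
  t1 <- seq(20, 180, by = 15)
  spikes <- spike_tbl(list(t1, t1 + 1), 200)
  net <- reconstruct_network(pair_rois(), spikes, fps = 10, um_per_px = 2,
                             params = network_params(0.25, 208, 0.5))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source_roi, 1L)
  expect_equal(net$edges$target_roi, 2L)
  expect_equal(net$edges$best_lag, 1L)
  expect_gt(net$edges$correlation, 0.9)
  expect_equal(net$edges$distance_um, 50)
  expect_equal(net$edges$delay_s, 0.1)
})

test_that("the distance constraint removes edges beyond the neurite reach", {
  t1 <- seq(20, 180, by = 15)
  spikes <- spike_tbl(list(t1, t1 + 1), 200)
  net <- reconstruct_network(pair_rois(), spikes, fps = 10, um_per_px = 12,
                             params = network_params(0.25, 208, 0.5))
  expect_equal(nrow(net$edges), 0)
})

test_that("zero best lag produces reciprocal edges", {
  t1 <- seq(20, 180, by = 15)
  spikes <- spike_tbl(list(t1, t1), 200)
  net <- reconstruct_network(pair_rois(), spikes, fps = 10, um_per_px = 2)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$best_lag, c(0L, 0L))
  expect_setequal(paste(net$edges$source_roi, net$edges$target_roi),
                  c("1 2", "2 1"))
})

test_that("independent random spike trains are mostly unconnected", {
  # With ~6 spikes per 200-frame train the correlation is quantized in units
  # of ~1/6, so two chance coincidences at some admissible lag already clear
  # 0.25; maximizing over 11 lags makes that a ~10% event per pair. Chance
  # connections must stay rare, and far below a genuinely coupled pair.
  set.seed(31)
  rois <- roi_set(lapply(1:5, function(k) cbind(5, 5 * k)), c(30, 30))
  pair_rate <- vapply(1:20, function(rep) {
    trains <- replicate(5, which(runif(200) < 0.03), simplify = FALSE)
    e <- reconstruct_network(rois, spike_tbl(trains, 200),
                             fps = 10, um_per_px = 1)$edges
    nrow(unique(cbind(pmin(e$source_roi, e$target_roi),
                      pmax(e$source_roi, e$target_roi)))) / 10
  }, numeric(1))
  expect_lt(mean(pair_rate), 0.25)
  # coupled pairs by contrast are detected essentially always, near corr 1
  t1 <- seq(20, 180, by = 15)
  coupled <- reconstruct_network(pair_rois(), spike_tbl(list(t1, t1 + 1), 200),
                                 fps = 10, um_per_px = 2)
  expect_gt(coupled$edges$correlation, 0.9)
})

test_that("tightening any constraint never adds edges", {
  set.seed(32)
  for (rep in 1:3) {
    trains <- replicate(4, sort(sample(15:190, 12)), simplify = FALSE)
    trains[[2]] <- trains[[1]] + 1
    rois <- roi_set(lapply(1:4, function(k) cbind(4 * k, 5 * k)), c(30, 30))
    spikes <- spike_tbl(trains, 200)
    edge_key <- function(net) paste(net$edges$source_roi, net$edges$target_roi)
    base <- reconstruct_network(rois, spikes, fps = 10, um_per_px = 3,
                                params = network_params(0.1, 300, 0.5))
    for (p in list(network_params(0.4, 300, 0.5),
                   network_params(0.1, 40, 0.5),
                   network_params(0.1, 300, 0.1),
                   network_params(0.4, 40, 0.1))) {
      tight <- reconstruct_network(rois, spikes, fps = 10, um_per_px = 3,
                                   params = p)
      expect_true(all(edge_key(tight) %in% edge_key(base)))
    }
  }
})

test_that("the adjacency matrix is the exact indicator of the edge list", {
  t1 <- seq(20, 180, by = 15)
  spikes <- spike_tbl(list(t1, t1 + 1), 200)
  net <- reconstruct_network(pair_rois(), spikes, fps = 10, um_per_px = 2)
  adj <- adjacency(net)
  expect_equal(dim(adj), c(2, 2))
  expect_equal(sum(adj), nrow(net$edges))
  for (i in seq_len(nrow(net$edges))) {
    expect_equal(adj[as.character(net$edges$source_roi[i]),
                     as.character(net$edges$target_roi[i])], 1L)
  }
  expect_equal(rowSums(adj)[["1"]],
               sum(net$edges$source_roi == 1L))  # out-degree
  empty <- reconstruct_network(pair_rois(), spike_tbl(list(10, 100), 200),
                               fps = 10, um_per_px = 2)
  expect_true(all(adjacency(empty) == 0))
})

test_that("tidy/glance expose edges and a one-row network summary", {
  t1 <- seq(20, 180, by = 15)
  spikes <- spike_tbl(list(t1, t1 + 1), 200)
  net <- reconstruct_network(pair_rois(), spikes, fps = 10, um_per_px = 2)
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("source_roi", "target_roi", "best_lag", "correlation",
                     "distance_um", "delay_s"))
  g <- glance(net)
  expect_equal(g$n_rois, 2L)
  expect_equal(g$n_edges, 1L)
  expect_equal(g$min_corr, 0.25)
})
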
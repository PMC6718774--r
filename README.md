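# caltrace

Scriptable analysis of time-lapse calcium-imaging movies of cultured cells
(neurons, cardiomyocytes, neuroblastoma lines). When cells loaded with a
calcium-sensitive fluorescent dye fire, they transiently brighten; from a
recorded movie, caltrace

1. **segments** cell bodies (regions of interest, ROIs) on a reference
   frame with a difference-of-Gaussians blob filter,
2. **extracts** per-ROI mean-brightness traces `b[n]`,
3. **detects calcium spikes** on the rate of change `r[n] = b[n] − b[n−1]`
   with a robust sliding-window z-score: frame `n` is a spike iff
   `r[n] > th_r` and `z[n] = (r[n] − μ_l)/σ_l > th_z`, where `μ_l`, `σ_l`
   are windowed statistics of an influence-filtered rate series that
   limits how much detected spikes contaminate their own null estimate,
4. **reconstructs a directed communication network**: two cells are
   connected when the lagged Pearson cross-correlation `x_τ` of their
   spike trains, maximized over the physiologically admissible lag window
   `|τ| ≤ floor(max_delay_s · fps)`, strictly exceeds `min_corr` **and**
   their centroid distance is at most `max_dist_um` (of order a neurite
   length). The sign of the best lag orients the edge, leader → follower.

It also ships ground-truth benchmarking (TPR / PPV / recall with merged
ROIs bookkept separately; spike matching within a frame tolerance) and a
seeded synthetic-movie generator, so the entire pipeline is testable
without any external recordings. All tabular results are tibbles; fitted
networks support `tidy()` / `glance()`; `autoplot()` and `plot_*()` draw
traces, correlation matrices, activity maps and the network.

## Worked example

A synthetic movie with a planted communication chain 1 → 2 → 3 (one-frame
lag, 2 fps, cells 40 µm apart) is analyzed end to end:

```r
library(caltrace)

mv    <- generate_movie(synthetic_preset("network", seed = 1))
rois  <- detect_rois(mv$stack, reference_frame = 1)
traces <- extract_traces(mv$stack, rois)
spikes <- traces |> rate_of_change() |> detect_spikes(spike_params())
spike_summary(spikes)
#> # A tibble: 3 × 3
#>   roi_id spike_count n_avg
#>    <int>       <int> <dbl>
#> 1      1           8  178.
#> 2      2           8  179.
#> 3      3           7  162.

net <- reconstruct_network(rois, spikes, fps = 2, um_per_px = 2)
net
#> <calcium_network> 3 ROIs, 2 directed edge(s) [signal spike, min_corr 0.25, max_dist 208 um, max_delay 0.5 s]
#> # A tibble: 2 × 6
#>   source_roi target_roi best_lag correlation distance_um delay_s
#>        <int>      <int>    <int>       <dbl>       <dbl>   <dbl>
#> 1          1          2        1       1.000        40.3     0.5
#> 2          2          3        1       0.937        40.4     0.5

adjacency(net)
#>   1 2 3
#> 1 0 1 0
#> 2 0 0 1
#> 3 0 0 0
```

Each detected ROI spiked 7–8 times; the reconstructed edges recover the
planted chain exactly — cell 1 drives cell 2 which drives cell 3, each at
a one-frame (0.5 s) delay with near-unit spike-train correlation, and no
spurious 1 → 3 shortcut because a lag of 2 frames exceeds the 0.5 s
response-delay cap. `autoplot(net)` overlays the arrows on the centroids;
`autoplot(traces, spikes = spikes)` shows the traces with detected spikes.

The same pipeline runs from the shell on real footage:

```sh
inst/cli/caltrace run --config run.json --out results/
```

writing `rois.csv`, `mask.tiff`, `traces.csv`, `rates.csv`, `spikes.csv`,
`correlations.csv`, `edges.csv`, `adjacency.csv`, the resolved
`config.json` and `run.log`. Subcommands `segment`, `spikes`, `network`,
`eval-seg`, `eval-spikes` and `synth` expose the individual stages.

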
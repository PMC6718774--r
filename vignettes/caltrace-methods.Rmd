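---
title: "Methods: segmentation, spike detection and network reconstruction in caltrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, spike detection and network reconstruction in caltrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

caltrace analyzes time-lapse calcium-imaging movies of cultured cells in
four stages: find cell bodies (ROIs) on one reference frame, extract a mean
brightness trace per ROI, flag calcium spikes on the rate of change of each
trace, and connect ROIs into a directed communication network constrained
by physiology. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical decisions taken where the design was
genuinely open. Nothing here states an empirical result that the package's
test suite or the reproduction script do not themselves compute.

```{r setup}
library(caltrace)
```

## Cell detection

The reference frame is first contrast-stretched to the unit interval,

$$I = \frac{O - \min O}{\max O - \min O},$$

which makes everything downstream invariant to exposure, gain and bit depth
(a frame multiplied by any positive constant segments identically). A
constant frame has no contrast; it is defined to stretch to all zeros, with
a warning, and yields an empty ROI set rather than an error so that batch
runs on blank recordings complete.

Denoising convolves the frame with a normalized Gaussian of standard
deviation $\sigma_n$ pixels. Cell bodies are then isolated with a
difference-of-Gaussians (DoG) band-pass,

$$D(\sigma_a, \sigma_b) = B * G(\sigma_a) - B * G(\sigma_b),$$

whose response peaks for bright blobs at scales between $\sigma_a$ and
$\sigma_b$; choose $\sigma_a < \sigma_b$ roughly bracketing the cell radius
so cells come out as positive peaks on a near-zero background. Pixels with
$D$ strictly above the threshold `th` are foreground; connected foreground
clusters become ROIs, and clusters below `min_size_px` pixels are discarded
as noise.

Numerical decisions, each made once:

* **Kernel truncation.** The discrete Gaussian is cut at radius
  $\lceil 3\sigma \rceil$ (over 99.7% of the mass) and renormalized to sum
  to one, so flat regions are exactly preserved. Blurring is separable —
  two 1-D passes — which is mathematically identical to the full 2-D
  convolution; the test suite verifies agreement with a direct 2-D
  convolution oracle to $10^{-9}$.
* **Borders.** Symmetric reflection padding. Zero padding would darken the
  image rim and the DoG would ring there, producing spurious border ROIs.
* **Threshold applied to the raw DoG response.** $D$ is *not* re-stretched
  before thresholding: the DoG of a unit-range image has a small dynamic
  range, so useful thresholds are well below 1 (the default is 0.1), but
  re-normalizing $D$ would make the threshold depend on the single
  brightest blob in the frame, which is fragile. This choice matters when
  calibrating `th` against other implementations.
* **Connectivity.** "Adjacent" defaults to 8-connectivity (edge or corner),
  the common convention for bright-blob labeling; 4-connectivity is
  available. Labeling uses an explicit work queue, not recursion, so
  arbitrarily large blobs cannot overflow the call stack.
* **Strict threshold comparison.** A pixel exactly at `th` is background;
  detection looks for pixels *lighter* than the background.

Manual curation is file-based: `merge_manual_rois()` removes ROIs by id and
adds clusters drawn in a label mask, subtracting any overlap from the
automatic ROIs so pixel sets stay disjoint.

## Spike detection

Per-ROI brightness is the arithmetic mean over the ROI's pixels, frame by
frame. Baseline brightness varies strongly between cells, so detection
operates on the first difference $r[n] = b[n] - b[n-1]$, which is invariant
to any constant offset.

The detector is a robust sliding-window z-score. At sample $n$ the mean
$\mu_l$ and population standard deviation $\sigma_l$ (1/l normalization) of
the *filtered* rate series over the $l$ preceding samples are computed, and

$$z[n] = \frac{r[n] - \mu_l}{\sigma_l}, \qquad
s[n] = 1 \iff r[n] > th_r \text{ and } z[n] > th_z.$$

The filtered series limits how much a spike contaminates the running
statistics: a flagged sample enters as
$r_f[n] = i\,r[n] + (1-i)\,r_f[n-1]$ with influence $i \in [0,1]$, and the
same gate fires on strong negative excursions
($(-r[n] - 2\mu_l)/\sigma_l > th_z$), which are the falling edges of
transients. With $i = 1$ the filter is transparent; with $i = 0$ a flagged
sample is frozen out entirely.

Decisions worth knowing:

* **Window indexing.** The statistics used at sample $n$ cover exactly the
  $l$ filtered samples $r_f[n-l], \dots, r_f[n-1]$ — the sample being
  tested never enters its own null estimate.
* **Warm-up.** For $n \le l$ there is no stable estimate; the filtered
  series is initialized to the raw rates and no spike is reported. Spikes
  occurring in the first $l+1$ frames of a recording are therefore
  undetectable by construction.
* **Zero-dispersion rule.** On noiseless data $\sigma_l = 0$; the z-score
  is then defined as $+\infty$ for any positive deviation from the mean and
  0 otherwise, so clean synthetic data remain detectable instead of
  producing 0/0.
* **Negative gate.** The gate condition on negative excursions is kept in
  its asymmetric form ($-r - 2\mu_l$ rather than $|z|$); a symmetric
  alternative (`|z| > th_z`) would behave almost identically when
  $\mu_l \approx 0$.

The defaults $l = 10$, $th_z = 5$, $i = 0.50$, $th_r = 0.100$ are settings
validated on low-noise cortical-neuron recordings; $th_z = 5$ is
deliberately high and should be lowered for noisier footage. `th_r` is in
brightness units per frame and must be rescaled if the intensity scale
changes.

**Detection margin.** Because detection runs on the first difference, white
sensor noise of standard deviation $\sigma$ on the trace becomes noise of
$\sqrt{2}\,\sigma$ on $r$. A transient of amplitude $A$ thus has expected
z-score $A / (\sqrt{2}\sigma)$: an 8-to-1 amplitude-to-noise ratio on the
*trace* gives an expected z of only $\approx 5.7$ against the default
threshold of 5, inside the sampling error of a 10-sample standard-deviation
estimate, and sensitivity saturates around 70–75% (the acceptance suite
measures this honestly). Reliable (> 95%) recovery at these thresholds
needs an 8-to-1 ratio on the rate signal, i.e. transients of roughly
$11\sigma$ on the trace. This is a property of the algorithm's design, not
of the implementation.

## Cross-correlation and network reconstruction

Similarity between two ROI signals $f$ and $g$ (brightness, rate, or spike
vectors) at lag $\tau$ is the normalized cross-correlation

$$x_\tau = \sum_n \frac{f[n-\tau] - \mu_f}{\lVert f - \mu_f \rVert} \cdot
\frac{g[n] - \mu_g}{\lVert g - \mu_g \rVert},$$

with means and norms computed on each full series and the sum over the
overlapping index range only (the series are not padded; edge effects
slightly shrink $|x_\tau|$ at large lags, conservatively). Positive $\tau$
means $f$ leads $g$. A constant series has zero norm; its correlation is
defined as 0, with a warning. At $\tau = 0$ this is the ordinary Pearson
correlation, so the self-correlation is exactly 1.

The network model: two cells are connected when they produce similar
spiking patterns *and* the connection is physically plausible. For each
unordered pair the correlation of the spike vectors (default; brightness or
rate are configurable) is maximized over the admissible lag window
$|\tau| \le \lfloor \text{max\_delay\_s} \cdot \text{fps} \rfloor$, and an
edge is created iff that maximum strictly exceeds `min_corr` and the
centroid distance is at most `max_dist_um`. The best lag's sign gives the
direction (leader to follower); ties prefer the smallest $|\tau|$, then the
positive lag; a zero best lag is rendered as two reciprocal edges, since
leaderless synchrony carries no direction. Defaults — `min_corr` 0.25,
`max_dist_um` 208 (of order a neurite length; set it to the image diagonal
for a purely functional network), `max_delay_s` 0.5 — are the validated
settings for cultured cortical neurons.

Two behaviors to keep in mind. First, the correlation of sparse binary
spike trains is quantized: with $k$ spikes per train a single chance
coincidence contributes roughly $1/k$, so very sparse independent trains
occasionally clear 0.25 at some admissible lag (about a 10% chance per pair
at 6 spikes per 200 frames — measured by the test suite); `min_corr` should
be raised for very sparse data. Second, correlation is transitive along a
chain: in a relay $1 \to 2 \to 3$ with one-frame lags, cells 1 and 3
correlate perfectly at lag 2, so a lag window that admits $|\tau| = 2$ will
add the shortcut edge $1 \to 3$. The delay constraint is what disambiguates
the chain — which is also why the bundled network benchmark records at
2 fps, where the 0.5 s response cap admits only single-frame lags.

## Evaluating against ground truth

Segmentation scoring classifies every detected ROI and every manually
found cell exactly once. Overlap means at least `min_overlap_px` shared
pixels (default 1; the choice is exposed because annotation styles differ).
A detection overlapping two or more cells is *merged* — a distinct error
mode, excluded from both TPs and, for the cells it covers, from FNs, and
reported separately. Among single-cell detections of one cell, the largest
overlap is the TP (ties to the lowest id) and the rest are FPs. The scores
are $TPR = TP/P$, $PPV = TP/(TP+FP)$ and $recall = TP/(TP+FN)$; with merged
cells bookkept separately, $recall \ge TPR$ always, and zero denominators
give missing values rather than errors.

Spike scoring matches detected to reference spike frames greedily in frame
order within a tolerance (default ±1 frame); for interval matching on a
line this greedy scheme attains the maximum possible number of matches,
which the test suite verifies against exhaustive assignment on small cases.

## The synthetic generator

`generate_movie()` renders what the pipeline assumes: cells as 2-D Gaussian
blobs with non-overlapping supports and per-cell baselines, transients with
instant rise and single-exponential decay (amplitude and decay constant in
frames are user-set), white Gaussian sensor noise, a constant dark pedestal
(default $5\times$ the noise sd, like a camera offset; negative values are
clipped at zero), and optional directed spike propagation along planted
edges with fixed lag and transmission probability, applied in edge order so
chains cascade. Spontaneous spikes are Bernoulli per frame, thinned to a
minimum gap (isolated transients) and kept out of an initial quiet margin
(default 15 frames) so every planted spike falls where a windowed detector
can in principle see it. All draws come from per-cell substreams derived
from one master seed, so generation is a pure function of the spec and
adding cells does not reshuffle existing ones.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: photobleaching and baseline drift, motion artifacts,
neurites and irregular cell shapes, overlapping cells, dual-exponential
indicator kinetics, and Poisson (signal-dependent) photon noise.

Three presets fix the benchmark conditions used by the test suite and the
reproduction script: `"segmentation"` (20 cells, 128×128 px, blob sd 3 px,
peak signal-to-noise ≈ 10), `"spikes"` (100 traces × 200 frames, transient
amplitude 8× the noise sd, decay 10 frames, ~4 spikes per trace), and
`"network"` (3 cells 40 µm apart at 2 fps, planted chain
$1 \to 2 \to 3$ at 1-frame lag with deterministic transmission, only cell 1
spontaneously active). These sizes keep the full suite around a minute on
one core while leaving each estimate well determined.

## Determinism and limitations

Every stage is single-threaded, deterministic R; reruns of the full
pipeline on identical inputs produce byte-identical CSVs, and results are
independent of any ambient parallelism because none is used. Known
limitations: the DoG detector finds the bright core of a cell rather than
its full outline (region growing is out of scope); detection thresholds are
global per run; TIFF stacks and proprietary microscope formats are not
parsed (frames come as one file each; video via an external `ffmpeg` if
present); and near-constant high-rate activity defeats the windowed
standard-deviation estimate, as discussed above.
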
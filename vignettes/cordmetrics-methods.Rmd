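---
title: "Methods and design of cordmetrics"
author: "cordmetrics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of cordmetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmetrics)
```

cordmetrics implements the quantitative measurements used to characterize
a complete thoracic spinal cord transection in the rat: identification of
antidromically activated brainstem units from peri-stimulus extracellular
recordings, colour-cluster quantification of Masson's trichrome histology
with a collagen-compactness score, morphometry of regrown vessels and
neurites with a distributional homogeneity index, and two landmark-based
postural angles. Every input can be simulated with programmed ground
truth, which is how the package validates itself. This vignette explains
the models, the tunable parameters, the numerical conventions, and what
the validation does and does not demonstrate.

## Antidromic unit identification

### Signal model and detection

A recording is a single-electrode voltage trace (µV) with a stimulus
train. The analysis band is 500–5000 Hz, applied as a 4th-order
Butterworth filter run forward and backward (`bandpassFilter`), which has
zero phase and therefore does not bias spike latencies. Spikes are
detected where the negative-going signal exceeds the mean + 3 SD of a
stimulus-free baseline window; threshold exceedances are grouped into one
event per suprathreshold run, timed at the peak, and events closer than
the refractory period (default 1 ms) merge into the earlier one.

A mean + 3 SD threshold necessarily passes a Gaussian tail of
near-threshold noise events (the test suite verifies the rate against the
analytic tail). In the original workflow those are rejected by visual
inspection of the waveform on every trial. `detectUnit` automates that
step with an amplitude floor: events below the larger of 1.8× the
detection threshold and 0.5× the largest event amplitude are discarded.
The floor also removes the filter's own ringing sidelobes, which matter
only in the noise-free limit where the threshold degenerates to zero.
Response matching (`buildResponseTable`) then takes the
largest-amplitude spike in the 0.5–10 ms post-stimulus window (the first
0.5 ms blanks the stimulus artifact); choosing the amplitude maximum
rather than the first crossing is the same "is this the unit's waveform?"
judgement, automated.

### The three criteria

1. **Constant latency and amplitude** — latency SD ≤ 0.3 ms and amplitude
   CV ≤ 0.3 over responded trials (≥ 5 required, otherwise indeterminate).
   No published tolerance exists for "constant"; 0.3 ms is comfortably
   above the sampling quantization (0.05 ms at 20 kHz) and well below
   synaptic jitter, which is of the order of a millisecond.
2. **High-frequency following** — response efficiency ≥ 90% over trials
   stimulated at ≥ 100 Hz. Axons follow electrical stimulation 1:1;
   synaptically relayed responses fail at these rates.
3. **Collision** — trials in which a spontaneous spike occurred inside the
   critical window (from 1 ms before the stimulus up to just before the
   expected antidromic arrival) must lack a spike at the antidromic
   latency (± 0.5 ms) in at least 90% of cases, while that spike is
   present in non-collision trials. The 90% (rather than 100%) tolerates
   an unrelated spontaneous spike landing at the antidromic latency by
   chance. Antidromic presence is checked against the full spike train,
   not just the matched response, because in a collision trial the matched
   "response" is usually the spontaneous spike itself.

A unit meeting **at least two of three** criteria is antidromic;
a responsive unit failing the panel is synaptically driven; a unit with no
time-locked responses is unresponsive. Indeterminate flags count as
unmet, so a unit can still be identified when, say, no spontaneous
activity was available for a collision test.

Derived measures: the PSTH uses half-open 1 ms bins `[t, t+1)` with time 0
at stimulus onset, normalized to % of stimuli; efficiency is
100 × responses/stimuli; caudal responsiveness requires a single
post-stimulus bin to exceed the mean + SD of the pre-stimulus bins of the
same histogram; conduction velocity is path length (mm) over latency
(ms). The caudal criterion is deliberately liberal (it reproduces the
original rule); its false-positive rate on rate-matched Poisson nulls is
measured in the test suite and bounded by the union bound over
post-stimulus bins at the configured SD multiplier.

### The recording simulator

`genRecording` plants a biphasic 1 ms spike template (negative lobe first,
spectral content inside the analysis band) at `unitLatency` ms after each
stimulus with probability `responseProb` and Gaussian jitter, adds
Poisson spontaneous spikes and white noise, and honours collision
semantics: when a spontaneous spike falls within `collisionWindow`
(default latency + 1 ms) before the expected arrival, the evoked spike is
omitted and the trial flagged `collided`. Stimulus and spike times are
snapped to the sample grid, so programmed latencies are recovered exactly
in the noise-free limit; tolerance checks on latency recovery therefore
include one sample period (0.05 ms) on top of the 3-standard-error band.
Defaults: 20 kHz sampling, 100 µV spikes. The simulator does not model
bursting, electrode drift, amplitude adaptation at high stimulation rates,
or overlapping units — passing validation shows the pipeline recovers its
own generative model, not that it sorts difficult real recordings.

The validation grid (`validationScenarios`) spans latencies 1–8 ms,
jitters 0–0.5 ms and response probabilities 0.2–1 in twenty units: twelve
antidromic, four synaptic mimics (millisecond-scale jitter, unreliable
following, no collision blocking) and four unresponsive sites. Each unit
is assessed through three protocol segments mirroring the experimental
sequence — a low-frequency train (4 Hz × 60) without spontaneous activity
for latency/efficiency characterization, a 100 Hz × 50 train for
frequency following, and a low-frequency train with 20 Hz spontaneous
activity for the collision assay. Efficiency and latency recovery are
checked on the spontaneous-free segment, where windowed matching has an
exact ground truth.

## Trichrome histology

Pixel colours are clustered in raw RGB with k-means, k = 16, seeded and
therefore reproducible; every pixel is then assigned to its nearest
centroid (ties to the lowest cluster index), so the nearest-centroid
invariant holds exactly even if k-means terminated early. When the image
has exactly k distinct colours the centroids are those colours. Centroids
map to classes by colour family: background when all channels ≥ 220,
scaffold when all ≤ 60 (only when the preparation contains scaffold
material), collagen when blue dominates (B maximal and B − R ≥ 20),
tissue when red and blue both exceed green by 20. A centroid matching no
family falls back to the nearest class prototype and is flagged in the
audit table (`classRule`) for review — with scaffold excluded, dark
centroids resolve to the dark-tissue prototype rather than being silently
called scaffold.

Areas are pixel counts × pixel area; the blue/purple ratio is collagen
area over tissue area with background excluded, flagged undefined when no
tissue exists. Blue intensity is (255 − grey)/255 with luminance grey
(0.299 R + 0.587 G + 0.114 B), so white = 0 and saturated dark blue ≈ 1.
Compactness accumulates, onto each collagen pixel, the intensities of its
neighbours in a (2r+1)² window (default r = 1, the 8-neighbourhood;
diagonal neighbours included), with non-collagen intensities zero and
borders truncated to the in-image window. The implementation accumulates
shifted matrices in column-major offset order, which makes it bit-for-bit
identical to the exhaustive per-pixel double loop the tests compare
against. Compactness histograms use four bins at quarters of the
per-image maximum — a per-image normalizer, so levels are comparable
within an image, not across images.

The trichrome simulator allocates exact per-class pixel counts (so
realized fractions match requests to rounding), places collagen uniformly,
in Gaussian clusters, or in a border band, colours classes from a
palette (near-white, blue, red-purple, near-black) with per-pixel Gaussian
RGB noise (SD 8), and returns the truth map. The palette separation is
large against the noise, which is what makes ~exact area recovery
possible; heavily stain-faded or colour-shifted slides would first need
the audit table consulted.

## Morphometry and DHI

Structures are 8-connected components (EBImage's 4-connected labelling
merged across diagonal touches by union-find) after thresholding and
removal of components under 10 px. Skeletons come from Zhang–Suen
thinning. The reported length is the geometric length of the skeleton
backbone — the longest weighted shortest path through the skeleton graph
(edge weights 1 and √2), resampled as a polyline through every 4th pixel
to remove the systematic overestimate of staircase chain codes — plus one
pixel, so a straight horizontal run of 100 pixels measures exactly
100 px. For tubes thicker than ~2 px thinning erodes the ends, so the
length is the larger of the backbone estimate and the tip-to-tip geodesic
of the component itself minus the width. Vessel diameter is the median
caliper width: perpendicular rays marched from interior backbone pixels
in half-pixel steps (accuracy about half a pixel, independent of tube
orientation — a direct reading of the distance transform is biased by up
to 2 px on oblique boundaries). Rostro-caudal extent is the bounding-box
span along the declared axis. Validated accuracy on simulated material:
neurite lengths within ~2%, vessel lengths within ~5%, diameters within
~8%.

The structure simulator draws smooth unit-step random-walk paths
(heading noise `curvSD` degrees per pixel), dilates vessel paths with a
disc (width quantized to the nearest odd pixel count; the truth table
records both the requested and the realized diameter), enforces
disjointness with a 2 px guard zone, and records continuous path length
as truth. Default calibration is 0.5 µm/px, typical of confocal imaging.

The published procedure for the distributional homogeneity index adapts a
method from hyperspectral imaging whose formula is not restated; the
convention here is explicit and swappable: for each macropixel size *s*
in a dyadic ladder (sizes giving 4–16 blocks along the shorter image
side), heterogeneity(s) = RMS deviation of block coverage around the mean
block coverage, divided by that mean; DHI = 100 × the mean across sizes.
This satisfies the defining properties — zero iff block coverage is
exactly uniform at all scales, invariance to permuting block positions at
a scale, and border-concentrated layouts scoring above uniform ones at
equal global coverage. Absolute published DHI values depend on the
original images and are not reproducible from simulations; the package
validates the ordering (on 24 simulated neurites in a 192 px field, the
border-vs-uniform ordering holds with a wide margin across seeds), not
the absolute scale.

## Postural angles

Coordinates are image pixels with y increasing downward; the ground
direction is supplied per scene rather than assumed horizontal, so camera
tilt can be compensated. The cervico-thoraco-lumbar angle is the interior
angle at the shoulder between the shoulder→eye and shoulder→hip vectors,
computed with `atan2(|cross|, dot)` for numerical stability near 0° and
180°. The trunk alignment angle is the unsigned acute angle between the
shoulder–hip line and the ground, in [0°, 90°] — a magnitude of
misalignment; a signed version would additionally encode pitch direction,
which the range-of-movement summaries do not need. Both angles are
invariant under translation, rotation (ground co-rotated) and scaling,
which the tests verify, and scene simulation is exact by construction to
1e-6 degrees. Range of movement requires at least three frames per
animal; prevalence summaries export a flagged × group contingency table
for standard chi-squared testing rather than re-implementing it.

## Pipeline, I/O and reproducibility

Every stochastic function routes its randomness through one seed argument
and restores the caller's RNG state, so identical parameters and seed
give bit-identical output. Recordings are stored as delimited text
(signal TSV + stimulus CSV + YAML metadata), images and masks as PNG,
landmarks and tables as CSV, results as JSON. `runPipeline` validates a
YAML-style config against documented ranges (errors name the offending
field), runs simulate-then-analyze across all four families, and writes
per-stage JSON plus a manifest with the config echo, package version and
output checksums; identical configs give identical manifest hashes. Exit
from R with the package's functions is the interface; there is no
separate shell executable.

## Problem sizes and limitations

Validation uses 192–256 px images, 20 kHz recordings of tens of seconds,
and 20-unit simulation grids — sizes at which every check runs in seconds
to a couple of minutes while leaving the statistics comfortable margins.
Key limitations: single-unit recordings only (no spike sorting of
overlapping units); no stain deconvolution or registration for histology;
cavity delineation is out of scope (it was a manual measurement); DHI is
a convention, not a reimplementation of the uncited original; and all
recovery guarantees are with respect to the simulators' generative
models.
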
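# cordmetrics

Quantitative metrics for spinal cord injury studies in the rat: the
analysis pipeline that accompanies electrophysiological, histological and
behavioral characterization of a complete thoracic transection, with or
without an implanted scaffold in the lesion gap.

The package covers four measurement families, plus simulators that generate
every input with programmed ground truth:

- **Antidromic unit identification.** Extracellular recordings from
  brainstem neurons are band-pass filtered (500–5000 Hz), spikes are
  detected at a threshold of baseline mean + 3 SD, and each stimulus is
  matched to its time-locked response. A unit is classified as
  antidromically activated when it satisfies at least **two of three
  criteria**: (1) constant latency and amplitude, (2) reliable following of
  high-frequency stimulation (≥ 100 Hz), and (3) a positive collision test —
  a spontaneous orthodromic spike shortly before the expected antidromic
  arrival cancels the antidromic spike. Derived quantities: the
  peristimulus time histogram (1 ms bins, normalized to % of stimuli),
  response efficiency (% of stimuli evoking a spike), caudal responsiveness
  (any post-stimulus bin above baseline mean + SD), and conduction velocity
  *v = d / t* (path length in mm over latency in ms, numerically m/s).
- **Trichrome histology.** Masson's-trichrome images are reduced to 16
  colours by k-means in RGB space; centroids are classed as background,
  collagen (blue tones), preserved tissue (red-purple tones) or scaffold
  (black tones). Areas per class and the blue/purple ratio are quantified
  with the background excluded. Collagen *compactness* at a blue pixel is
  its stain intensity — the inverse grey-scale value, (255 − grey)/255 —
  plus the summed intensities of its neighbours (non-blue pixels counting
  as zero), binned into four levels at quarters of the per-image maximum.
- **Morphometry and DHI.** Binary masks of neurites or blood vessels are
  labelled (8-connected), skeletonized, and measured: per-structure length,
  vessel diameter (caliper width perpendicular to the skeleton backbone),
  rostro-caudal extent, and total length per image. The distributional
  homogeneity index (DHI) tiles the image with macropixels at a dyadic
  ladder of sizes and averages the coefficient of variation of block
  coverage: 0 for perfectly even colonization, high when structures clump
  at the lesion borders.
- **Postural angles.** From eye/shoulder/hip landmarks: the
  cervico-thoraco-lumbar angle (interior angle at the shoulder) and the
  trunk alignment angle (unsigned angle between the shoulder–hip line and
  the ground), with per-animal ranges of movement and group prevalence
  summaries.

## Worked example

Simulate the full stimulation protocol for one antidromically activated
unit (3 ms latency, 0.05 ms jitter, full response probability, SNR 10) and
run the identification panel:

```r
library(cordmetrics)

study <- simulateUnitStudy("antidromic", latency = 3, jitter = 0.05,
                           p = 1, snr = 10, seed = 42)
panel <- antidromicPanel(study$low$recording, study$high$recording,
                         study$coll$recording)
panel$verdict
#> AntidromicVerdict: antidromic (3/3 criteria)
#>   constant latency/amplitude: pass
#>   high-frequency following:   pass
#>   collision test:             pass
conductionVelocity(57.3, panel$meanLatency)   # path 57.3 mm
#> [1] 19.2
```

The unit follows every stimulus (efficiency 100%), its mean recovered
latency is 2.99 ms, and over a 57.3 mm spinal path that latency implies a
conduction velocity of 19.2 m/s — a fast reticulospinal-range axon.

Histology on a simulated trichrome section with known composition
(38% background, 30% collagen, 27% tissue, 5% scaffold):

```r
sim <- genTrichromeImage(192, 192, pixelSize = 1,
                         fractions = c(0.38, 0.30, 0.27, 0.05),
                         collagenLayout = "clustered", seed = 42)
cm <- classifyClusters(clusterColors(sim$image, k = 16, seed = 1),
                       pixelSize = 1)
quantifyAreas(cm)
#> AreaReport (um^2):
#> background   collagen     tissue   scaffold
#>      14009      11059       9953       1843
#> blue/purple ratio: 1.111
```

The recovered blue/purple ratio (1.111) matches the programmed 0.30/0.27 =
1.111: more collagen than preserved tissue, the signature of fibrotic
colonization of the lesion. The same masks drive the homogeneity index —
border-concentrated neurites score DHI 116.6 against 85.6 for a uniformly
colonized lesion with the same coverage (seed 42), reproducing the
direction injured-only vs scaffold-colonized lesions show.

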
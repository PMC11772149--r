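Package: cordmetrics
Title: Quantitative Histology, Electrophysiology and Postural Metrics for
    Spinal Cord Injury Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reimplements, as tested and reusable components, the quantitative
    pipeline of a rat spinal-cord-transection study: k-means colour segmentation
    of Masson's trichrome histology with collagen-compactness neighbourhood
    scoring, a distributional homogeneity index for neurite colonization,
    antidromic unit identification from peri-stimulus extracellular recordings
    (threshold detection, PSTH, response efficiency, constant-latency,
    frequency-following and collision criteria), vessel and neurite morphometry
    (counts, lengths, diameters, rostro-caudal extents), and landmark-based
    postural angle measures. Every input can be simulated with programmed
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    signal,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
biocViews: CellBiology, Neuroscience, Electrophysiology, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'compactness.R'
    'cordmetrics-package.R'
    'ephys-criteria.R'
    'ephys-detect.R'
    'ephys-panel.R'
    'histology.R'
    'io.R'
    'morphometry.R'
    'synth-histology.R'
    'synth-landmarks.R'
    'synth-recording.R'
    'synth-structures.R'
    'utils.R'
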
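Package: lamellar
Title: Actin Filament Polarity and Membrane Orientation Analysis for
    Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the architecture of branched (dendritic) actin
    networks in lamellipodia from cryo-electron tomography derived
    segmentations. Starting from per-segment coordinate and polarity tables,
    the pipeline fragments traced filaments at sharp joints, resolves
    per-filament polarity by segment consensus with a combined confidence
    score, estimates smoothed outward membrane normals by local plane
    fitting of the membrane segmentation point cloud, measures
    filament-to-membrane orientation angles, classifies filaments as
    forward, parallel or backward, builds distance-resolved orientation and
    density profiles, computes Arp2/3 branch statistics, and classifies
    whole tomograms into protruding, transition and resting lamellipodial
    sub-domains via robust proportion-profile fits and k-means clustering.
    A ground-truthed synthetic lamellipodium scene generator with
    configurable orientation mixtures, Poisson branching and realistic
    noise supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
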
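# lamellar

Quantitative architecture of branched actin networks in lamellipodia from
cryo-electron tomography derived segmentations.

## The problem

The lamellipodium — the thin (~100–150 nm) actin sheet at the edge of a
spreading or migrating cell — is built from short, polar actin filaments
nucleated by the Arp2/3 complex. Modern cryo-ET workflows can trace every
filament in a tomogram and, by back-mapping refined filament structures,
assign each 11 nm filament segment a *polarity vector* pointing toward the
fast-growing barbed end. What remains is the quantitative question this
package answers: **how are filament polarities organised relative to the
plasma membrane, and how does that organisation vary along the cell
edge?**

`lamellar` consumes three plain-text tables per tomogram — filament
segments (coordinate + polarity), a membrane segmentation point cloud, and
optionally an Arp2/3 branch table — and computes:

1. **Filament fragmentation.** Traced polylines are truncated wherever
   consecutive step vectors turn by ≥ 90°, so branch joints do not merge
   physical filaments.
2. **Polarity consensus.** With the end-to-end chord *S(F) = C_last − C_1*
   as the filament axis, each segment gets an agreement label
   ε = 1 if its polarity vector lies within 30° of *S*, else 0. The
   combined confidence score `ccs = max(mean ε, 1 − mean ε)` must exceed
   0.6 (strictly) for the filament to enter orientation statistics; the
   resolved direction is +S or −S by majority, and the barbed end is the
   endpoint it points toward.
3. **Membrane normals.** Local total-least-squares plane fits within a
   40 nm sphere around each membrane point, one smoothing pass over the
   same neighbourhood, and outward orientation against a cytoplasmic
   reference point.
4. **Orientation categories.** The mean angle between a filament's
   resolved direction and the smoothed outward normal of each segment's
   nearest membrane point classifies it as **forward** (≤ 80°, barbed end
   toward the membrane), **parallel** (80–100°) or **backward** (≥ 100°).
5. **Profiles and branch statistics.** Category fractions in 40 nm slabs
   up to 400 nm from the membrane, normalised orientation histograms
   (p = count/total), barbed-end/segment/length densities, and Arp2/3
   branch-to-filament ratio, density and spacing.
6. **Sub-domain classification.** Per tomogram, category proportions are
   computed in 100 sliding 40 nm frames, robustly fit (IRLS, bisquare)
   against distance, and the first-frame estimates are clustered by
   k-means (k = 3) into **protruding / transition / resting** sub-domains,
   labelled by decreasing forward fraction.

Because real tomogram segmentations of this kind are not publicly
available as tables, the package ships a ground-truthed synthetic scene
generator (`simulate_scene`) that emulates the statistical structure of
lamellipodial networks — thin-slab geometry, 11 nm segment spacing,
configurable forward/parallel/backward mixtures per sub-domain, Poisson
branching calibrated to a branch per ~0.6 µm of filament, polarity flips,
segment dropout, coordinate jitter and false-positive dust — so every
pipeline stage is testable end to end.

## Worked example

```r
library(lamellar)

scene <- simulate_scene(scene_params(seed = 42))   # 300 filaments, defaults
fit   <- analyze_tomogram(scene$segments, scene$membrane)
fit
#> Tomogram analysis: sim_seed42
#>   4498 segments -> 319 fragments, 316 passed the polarity confidence test (ccs > 0.6)
#>   orientation mixture (all 316 filaments): 58.9% forward / 24.7% parallel / 16.5% backward
#>   robust first-frame estimate: 58.2% / 26.3% / 15.5%

arp_statistics(scene$branches, fit$filaments, analysis_volume_um3 = 0.04)
#> Arp2/3 branch statistics
#>   branches: 86  filaments: 316
#>   branch:filament ratio  0.272 (1:3.7)
#>   branch density         2150 per um^3
#>   filament length/branch 0.62 um (total 53.3 um)
```

The scene was generated with a 60/25/15 forward/parallel/backward target
mixture; the pipeline recovers 58.9/24.7/16.5 after fragmentation,
consensus filtering and orientation measurement. The robust first-frame
estimate is the tomogram's coordinate for sub-domain clustering
(`classify_subdomains`), and the branch statistics sit at the scale
typical of lamellipodial networks (a branch per ~0.6 µm of filament,
roughly one Arp2/3 per three filaments, ~2000–2500 branches per µm³).

`summary(fit)` prints the 40 nm distance profile, `plot(fit)` draws the
orientation histogram and the sliding-frame proportion profile, and
`run_pipeline()` executes the whole analysis (including sub-domain
classification) over multi-tomogram tables or files.

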
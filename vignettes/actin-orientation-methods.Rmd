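---
title: "Methods: filament polarity, membrane orientation and lamellipodial sub-domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filament polarity, membrane orientation and lamellipodial sub-domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellar)
```

This vignette documents the models, conventions and numerical choices
behind `lamellar`, in the spirit of a methods section: what each stage
computes, which parameters matter and why their defaults are what they
are, what the synthetic scene generator does and does not emulate, and
the known limitations.

## 1. Data model

The pipeline starts from the product of a filament back-mapping workflow:
per-tomogram tables of filament *segments* sampled every 11 nm along each
traced filament, each carrying a 3D coordinate (nanometres) and a unit
*polarity vector* pointing toward the barbed (fast-growing) end. A second
table samples the segmented plasma membrane as a point cloud, and an
optional third table lists Arp2/3 branch junctions (mother/daughter
filament ids and branch coordinates). Everything upstream — tomogram
reconstruction, CNN segmentation, subtomogram averaging, polarity
classification of individual segments — is out of scope; everything
downstream of the segment tables is implemented here.

Coordinates are nanometres throughout. TSV with a header is the canonical
file dialect (CSV is accepted); floats are written with 6 significant
digits.

## 2. Fragmentation (`fragment_filaments`)

Dendritic networks are branched, and a traced polyline can run through a
branch joint. Walking each polyline's consecutive step vectors
$V_{(N,N-1)} = C_N - C_{N-1}$, the filament is truncated whenever the
angle between successive steps reaches the limit (default 90°): the
fragment ends at segment $N$ and segment $N+1$ opens a new fragment, so
fragments partition the input segments and no segment is shared. No turn
can be evaluated until a fragment has three coordinates, so scanning
(re)starts at each fragment's third segment. Fragments left with fewer
than two segments cannot carry a polarity and are flagged and excluded
from polarity analysis (they remain in the segment table).

Two conventions were genuinely open and are fixed as follows: truncation
triggers at *angle ≥ limit* (continuation requires the turn to stay below
it), and the offending segment starts the new fragment rather than being
shared — sharing would break the partition property that downstream
counts rely on.

## 3. Polarity consensus (`resolve_polarity`)

Filaments at this scale are short and nearly straight, so the end-to-end
chord $S(F) = C_\mathrm{last} - C_1$ serves as the filament axis. Each
segment's agreement label is

$$\varepsilon_j = \begin{cases}1 & \angle(P_j, S) \le 30^\circ\\
0 & \text{otherwise,}\end{cases}$$

with the boundary inclusive: exactly 30° counts as agreement. Numerically
the comparison is done on cosines with a $10^{-9}$ slack so `acos`
round-off cannot flip the inclusive boundary.

The polarity score is $\mathrm{mean}(\varepsilon)$ and the combined
confidence score is the majority fraction

$$\mathrm{ccs} = \max(\mathrm{mean}\,\varepsilon,\; 1 - \mathrm{mean}\,\varepsilon) \in [0.5, 1],$$

optionally multiplied by the mean per-segment classification confidence
when the input provides one (off by default — the exact combination rule
used by upstream classification tools is not standardised, so the
package's ccs is the documented directional-consensus form). Filaments
pass only when $\mathrm{ccs} > 0.6$ *strictly*; a 6-of-10 split
(ccs = 0.6) is excluded. The resolved direction is $+S$ when the majority
agrees with the chord and $-S$ otherwise, and the barbed end — the
filament's representative coordinate for all distance measurements — is
the endpoint the resolved direction points toward.

A useful property for testing: flipping every segment polarity of a
filament leaves ccs unchanged and reverses the resolved direction. This
holds exactly for polarity data aligned or anti-aligned with the axis
(the realistic case); vectors in the 30–150° dead zone score 0 in both
orientations, so the property is asserted on cone-sampled data.

## 4. Membrane normals (`membrane_model`)

For each membrane point, a total-least-squares plane is fitted to all
points within a 40 nm sphere (boundary inclusive, self included): the
normal is the eigenvector of the neighbourhood covariance with the
smallest eigenvalue. Fewer than three neighbours, or a collinear
neighbourhood (second eigenvalue ≈ 0), leaves the normal undefined; such
points are flagged and skipped by the orientation stage. Normals are then
smoothed once over the same 40 nm neighbourhood — neighbour normals are
sign-aligned to the centre normal before averaging, so the raw field need
not be globally consistent — and finally oriented *outward*, away from a
cytoplasmic reference point (by default the centroid of the
passed-confidence filament segments), so that 0° always means "barbed end
straight toward the membrane".

Choices made here: the smoothing neighbourhood equals the plane-fit
radius and a single pass is applied (iterating adds nothing on smooth
surfaces and erodes curved ones); the segment-to-membrane comparison uses
the smoothed normal of the *single* nearest membrane point, since the
smoothing already averages the neighbourhood. Nearest-point and radius
queries are exact (chunked exhaustive search), so results are identical
to brute force by construction.

Accuracy on analytic surfaces (plane, sphere, cylinder at ≤ 15 nm point
spacing) is well under 2° at the 95th percentile. One nuance the tests
document: on a *noiseless curved* surface, smoothing can shift individual
normals by a few tenths of a degree (discrete sampling makes
neighbourhoods slightly asymmetric), so "smoothing never hurts" holds
exactly on planes and only up to that sampling allowance on spheres.

## 5. Orientation categories and profiles

Each passed filament's segments are matched to their nearest membrane
points; the angle between the filament's *resolved* direction and each
smoothed outward normal is averaged into the filament's mean orientation
angle. Using the consensus direction for every segment (rather than raw
per-segment vectors) means a single flipped segment cannot invert its own
angle — polarity is a per-filament property once the consensus is formed.
The mean angle is categorized by the fixed intervals

- **forward**: mean ≤ 80°,
- **parallel**: 80° < mean < 100°,
- **backward**: mean ≥ 100°,

which partition [0°, 180°]. Distance profiles bin filaments by the
membrane distance of the barbed-end representative coordinate into
half-open 40 nm slabs [k·40, (k+1)·40) up to 400 nm; a filament at
exactly 40 nm belongs to the second slab. Orientation histograms use
p(bin) = count/total with 10° bins by default (the granularity is
configurable; 10° resolves the ~40° proximal mode without starving
bins). Densities (barbed ends, segments, filament length via the 11 nm
spacing) divide per-slab counts by externally supplied slab volumes —
analysis volumes depend on the tomogram geometry and are not derivable
from the tables themselves.

Arp2/3 statistics relate the branch table to the passed-confidence
filament population: branch:filament ratio, branch density in the
analysed volume, and mean filament contour length per branch (the branch
spacing along the network).

## 6. Sub-domain classification

Per tomogram, category proportions are computed in 100 sliding frames of
40 nm spanning 0–400 nm (start positions every ≈ 3.64 nm; with 2 frames
the scheme degenerates to the proximal 0–40 and distal 360–400 nm slabs).
A hundred 40 nm frames cannot tile 400 nm disjointly, so the overlapping
sliding-window reading is the only one consistent with a "continuous"
proportion profile. Frames with no filaments are dropped, not imputed.

For each category, a robust straight line (IRLS with bisquare weights,
`MASS::rlm` defaults) is fitted to fraction versus frame centre and
evaluated at the first frame centre (20 nm); ordinary least squares is
used when the line fits exactly (zero residual scale breaks IRLS) or if
IRLS fails to converge, and with fewer than 10 usable frames the estimate
falls back to the mean of the first five. The three estimates are clamped
to [0, 1] and renormalised to sum to 1. These first-frame coordinates,
one 3-vector per tomogram, are clustered by k-means (Euclidean, k = 3,
50 restarts under a fixed seed, best within-cluster sum of squares;
n = k yields the trivial partition directly) and clusters are labelled
**protruding / transition / resting** by decreasing mean forward
coordinate.

## 7. The synthetic scene generator

`simulate_scene` builds ground-truthed scenes in a 1000 × 600 × 100 nm
box: membrane points on a 10 nm grid at one face (flat, or an outward
arc to exercise normal estimation on curvature), and filaments placed by
sampling a barbed-end membrane distance uniformly over the 0–400 nm
analysis belt. Orientation categories are allocated by largest-remainder
rounding — exactly within the proximal 0–40 nm slab and across the rest —
so the realized ground-truth proximal mixture equals the request up to
rounding rather than multinomial noise. Category angle draws are
truncated normals: forward around a 40° mode (SD 15°, range [0, 80°]),
parallel around 90°, backward around 115° (SD 10°) — a deliberately
shallow mode, since a steeply backward filament with a proximal barbed
end would have to pierce the membrane. An optional distal mixture
interpolates the per-slab target linearly across the belt, emulating
sub-domains whose forward fraction declines toward the cell interior
(the graded presets use 85 → 60 % forward for protruding scenes).

Filaments grow straight from the barbed end toward the pointed end at
11 nm spacing, with the out-of-plane component of the growth direction
damped (SD 0.25 of the in-plane component) because the lamellipodial
network is quasi-two-dimensional; growth is clipped at the membrane and
box walls. Placements keeping at least 3 segments are preferred (a
2-segment filament cannot form a stable consensus — one flip ties it at
ccs = 0.5 — and differential exclusion of such filaments would bias
proximal mixtures); 2-segment placements are accepted only where the
thin-slab geometry forbids more. The nominal exponential mean length of
420 nm yields a realized mean of ~185 nm after clipping, which together
with the Poisson branch process (one branch per 0.6 µm of filament)
reproduces the characteristic ~1:3 branch:filament ratio and
~2500 µm⁻³ branch density of the default scene.

Branching is *statistical attachment*: the branch count is drawn from
Poisson(rate × total length); each branch selects a daughter filament
and attaches it to the spatially nearest candidate mother whose realized
inter-axis angle is closest to the preferred 70° branch angle, recording
the branch point (nearest point on the mother) and the realized angle.
A mechanistic alternative — growing daughters at exactly 70° off their
mothers — was rejected because it makes daughter orientation categories a
byproduct of mother geometry, so requested orientation mixtures could not
be honoured and some mixtures would become infeasible; the attachment
scheme reproduces exactly the branch statistics the analysis consumes
(counts, ratio, spacing, positions) while keeping the mixture contract
exact.

Observation noise is applied after geometry, per segment: angular jitter
of the polarity vector (SD 5°), sign flips (probability 0.1), dropout
(probability 0.1, never below 2 surviving segments), isotropic coordinate
jitter (SD 2 nm), plus short 2–4-segment "dust" fragments with random
orientation (0.05 per filament) mimicking residual false-positive
tracing. All defaults are on; the validation suite switches individual
channels on exactly as each check prescribes. Scenes are bit-reproducible
from (parameters, seed).

**What the generator does not emulate** — and hence what passing
recovery tests do and do not show about real data: filaments are
straight (no curvature, no fragmentation load beyond noise-induced
kinks), polarity errors are independent across segments (real
classification errors correlate along a filament), membrane geometry is
smooth, dust is sparse and unstructured, and there is no missing-wedge
anisotropy. Recovery results therefore validate the *pipeline logic*
(definitions, filters, estimators), not the upstream segmentation.

## 8. Validation problem sizes

The test suite checks oracle equivalence (fragmentation, nearest
neighbours, agreement labels, frame membership, angles) on instances up
to ~1000 elements against independent brute-force implementations;
analytic normals on a plane (25 × 25 grid), a Fibonacci sphere (r =
300 nm, ≈ 5800 points) and a cylinder (r = 200 nm); proximal mixture
recovery on nine scenes of 900 filaments (three mixtures × three
replicates, flip 0.1, dropout 0.1) within ±4 percentage points of ground
truth; majority-vote polarity accuracy ≥ 99 % at flip 0.2 on ≥ 10-segment
filaments; and end-to-end sub-domain recovery on a 12-tomogram cohort
(4 per preset, 800 filaments each) with ≥ 11/12 label agreement. These
sizes were chosen so each check has clear statistical power: at 900
filaments per scene the observed worst-case proximal error is ≈ 2 pp
against the 4 pp band.

## 9. Limitations

- The ccs here is the directional-consensus form; upstream tools that
  blend per-segment classification posteriors may rank borderline
  filaments differently around the 0.6 cut.
- Densities require externally supplied slab volumes; the package does
  not estimate analysis volumes from point clouds.
- Sub-domain classification operates per tomogram; spatial sub-domain
  mapping within a tomogram and temporal dynamics are out of scope.
- The nearest-membrane distance is measured to the sampled point cloud,
  not a continuous surface; with a 10 nm sampling grid the induced bias
  is ≲ 1 nm.
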
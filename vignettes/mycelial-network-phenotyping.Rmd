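---
title: "Mycelial network phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mycelial network phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myconet)
```

myconet turns images of fungal mycelia (or pre-extracted edge lists) into
spatially embedded weighted graphs and measures a fifteen-trait panel
capturing four functional axes of a foraging colony: connectivity,
transport efficiency, construction cost, and robustness to grazing. This
vignette explains the underlying models, the tunable parameters, what the
synthetic generator does and does not emulate, and the numerical choices
baked into the implementation.

## The network model

A colony is a `mycelial_network`: nodes are hyphal tips, branch points and
anastomosis (fusion) points with 2D coordinates; edges are the hyphal
segments between them, each carrying a physical `length` and cross-section
`width`. Two unit conventions coexist: micrometres for networks of single
hyphae ("micro", ascomycete/zygomycete-style colonies) and millimetres for
cord-forming basidiomycete networks ("macro"). The mycelium inside the
inoculum (agar plug or wood block) cannot be resolved by imaging, so it is
modelled as a single *root* node joined to each hypha that touched the
inoculum rim by a synthetic edge whose width equals the maximum measured
width — a deliberately strong connection that keeps the graph whole.
Root edges are excluded from every morphological and volume statistic;
they exist only as transport conduits.

Transport is modelled by giving each edge a resistance

\[ R = \frac{l}{r^\alpha}, \qquad r = w/2, \]

with \(\alpha = 4\) for single hyphae (Poiseuille flow in a cylindrical
pipe) and \(\alpha = 2\) for cords, whose capacity grows with the number
of constituent hyphae rather than the radius of one pipe. Doubling the
width therefore divides resistance by 16 (micro) or 4 (macro) exactly.
Resistance units are arbitrary-but-consistent: every derived trait is a
ratio or a reciprocal of resistance sums, so no absolute calibration is
needed. The hyphae-as-cylinders idealization is an assumption of the
transport model, untested across species, and inherited knowingly.

## The fifteen traits

*Morphology (1–5).* Mean edge length; mean tip-edge width (edges incident
to a degree-1 tip); mean main-edge width (edges joining two non-tip
nodes); mean branching angle; and length density, the summed measured
length divided by the colony area. Area is the convex hull of the
measured node coordinates — parameter-free, and matching the enclosing
region a practitioner would draw. The branching angle at a degree-3
junction is the angle between the two *daughter* edges, where the parent
is the incident edge whose far end is closest to the root in resistance
distance; higher-degree junctions contribute their minimum pairwise
daughter angle. The daughter–daughter convention (rather than
parent–daughter) is a documented choice: a root-proximal parent matches
growth directionality, and the convention is recorded here because both
appear in the literature.

*Network (6–10).* Meshedness is the planar cycle density
\((E - N + C)/(2N - 5)\) over the measured structure (cycle-space rank
over the maximum number of independent cycles a planar graph on \(N\)
nodes admits); it is 0 for any forest and 1 for a maximal planar
triangulation. The \(C\)-component form matters because without the root
the measured structure is typically a forest of trunks. Root efficiency
\(R_\mathrm{eff}\) is the mean of \(1/d(\mathrm{root}, i)\) over non-root
nodes under shortest-path resistance distances; root–tip efficiency
restricts the mean to tips; global efficiency \(G_\mathrm{eff}\) averages
\(1/d(i,j)\) over unordered non-root pairs. The root and its synthetic
edges participate in *paths* (they are the inoculum's connection) but the
root is never an *endpoint*. The minimum spanning tree under resistance
weights is the minimal transport skeleton; `volume_MST` (built cylinder
volume over MST volume) measures the relative construction cost of
cross-linking, and `G_eff_MST` the efficiency return on that investment.
Both are ≥ 1 by construction. For combined-scale analyses the root
efficiencies are divided by colony area (`R_eff_area`, `RT_eff_area`);
division by the hull area is the documented interpretation of
area-normalization, with the alternative (per root-area) left to the
caller.

*Robustness (11–15).* Five edge-removal schemes mimic fungivory:
uniform-random single edges; random spatial chunks (a random edge plus
its `chunk_k − 1` nearest remaining edges by midpoint distance, default
`chunk_k = max(2, 0.02 E)`); thinnest-first; widest-first; longest-first.
After each removal (each bite, for chunks) the fraction of measured edge
*length* still connected to the root is evaluated — length, not edge
count, because "fraction of mycelium" is a biomass notion. Robustness is
the fraction of measured edges removed when the connected fraction first
reaches ≤ 0.5 (inclusive). Reporting a fraction rather than a raw count
makes the trait size-independent and admissible in the combined-scale
ordination; the raw count is also returned. Stochastic schemes average
100 replicates by default (unit tests and the acceptance script use 15–25
to keep runtimes modest; the mean is stable well before that, and exact
reproducibility is guaranteed by the per-scheme seed). Internally the
trajectory is computed by reverse edge-addition over a union-find, which
is exactly equivalent to recomputing connected components after every
removal (a unit test asserts the equivalence) but linear rather than
quadratic in edge count.

## Image-to-graph extraction

The pipeline is background correction → (optional) ridge enhancement →
segmentation → thinning → graph tracing → width estimation → pruning.

Background is removed by subtracting a morphological opening (disc radius
`background_radius`, default 20 px): thin bright structures cannot
survive the opening, so the difference image isolates them from smooth
illumination gradients. Bright-field images (dark hyphae) are inverted
first (`invert`). Segmentation thresholds either the corrected intensity
(default; most faithful widths on evenly lit images) or a multiscale
Hessian ridge response (`enhancement = "ridge"`, scales 1–3 px), the
intensity-independent option for images with uneven staining; the exact
enhancement operator used by upstream imaging suites is not specified
publicly, so the ridge filter is a generic curvilinear detector and is
documented as such. Otsu's threshold is floored at median + 5 MAD so a
structure-free image yields an empty mask instead of thresholded noise,
and components below `min_object_px` (default 30) are discarded.

Thinning is Zhang–Suen; the skeleton is always a subset of the mask.
Skeleton pixels with one neighbour become tips; pixels with ≥ 3
neighbours are clustered (8-connectivity, then single linkage within
`node_merge_radius`, default 3 px — thinning yields multi-pixel junction
blobs) and collapsed to their centroid. Chains between nodes become
edges; a chain that returns to its own cluster is a genuine anastomosis
loop and is split at its midpoint into a parallel edge pair rather than
discarded. Because the tracer cannot tell a true anastomosis from two
hyphae crossing in the 2D projection, both become junctions — the same
limitation the imaging approach itself has, retained deliberately.

Three standard corrections make the recovered geometry quantitatively
faithful (each was added after tracing a specific bias in the
render→extract error budget):

* **Chain-length de-bias.** Raw chain codes overestimate smooth arcs by
  up to ~8% on diagonals; lengths use the Vossepoel–Smeulders
  corner-corrected estimator (0.980 per axis step, 1.406 per diagonal,
  −0.091 per direction change).
* **Tip extension.** Thinning retracts each free end by about half the
  local width; tip edges are extended by `width/2` along their end
  direction.
* **Junction merge correction.** Two hyphae diverging at angle θ from a
  branch point overlap for roughly \(r/\tan(\theta/2)\) before they are
  optically separable, so the skeleton fuses them there; that length is
  credited back to the closest-direction edge pair at each junction
  (capped at 4r).

Widths come from the Euclidean distance transform of the mask sampled
along each edge's polyline: `width = (2·median(EDT) − 0.5) · pixel_size`.
The median is robust to inflation near junctions; the half-pixel
subtraction accounts for the transform measuring to background pixel
*centres*. Terminal edges shorter than `min_spur_length` (default 3
pixels) are pruned iteratively and the degree-2 nodes left behind are
dissolved, concatenating their edges (lengths summed, widths
length-weighted). Extraction involves no randomness.

## The synthetic generator

`grow_network()` grows tips stepwise from trunks on an inoculum rim:
per-step heading noise (Gaussian, degrees), log-normal step lengths,
per-step lateral branching, and anastomosis by capture — a tip whose next
segment comes within `fuse_radius` of an existing hypha (true
segment-to-segment distance) fuses with probability `fuse_prob`, creating
a junction that splits the target edge; otherwise it stops at the
obstacle. Crossings therefore never occur without creating a node, which
keeps the graph planar like real 2D extractions. After growth, the
degree-2 step waypoints are dissolved (their geometry is kept as edge
polylines), so nodes are tips, branch and fusion points only; widths are
then drawn per hyphal segment, Gaussian with 10% relative spread around
`width_tip` (tip-incident) or `width_main`, clipped positive — the
two-population width structure of real colonies. A single seeded RNG
stream drives each call; identical parameters and seed reproduce the
network bit-for-bit, and the global RNG state is restored afterwards.

The three presets are anchor points on the guerrilla–phalanx connectivity
gradient. The guiding constraints: (i) phenotypes differ in branching
rate, step length, widths and — decisively — anastomosis (`fuse_prob` 0
vs 0.85); (ii) all presets reach comparable segment counts (on the order
of 10²), because the robustness traits are fractions of edges and
degenerate colonies of a handful of giant merged segments would make the
fraction quantization, not biology, drive comparisons; (iii) default
branch angles are 55° ± 12°, within the 45–90° range typical of lateral
branching, chosen over shallower angles so that daughter hyphae separate
within about one hyphal width of the branch point and rendered colonies
remain optically resolvable — at 40° the daughters' ribbons overlap long
enough that no segmentation can separate them, which would measure a
sub-resolution artefact rather than pipeline fidelity. Colonies are
grown to a few hundred micrometres radius with widths of 2.5–6 µm; this
is a deliberately desk-scale rendition of the morphology (real colonies
reach ~10 mm), since every trait in the panel is either size-free or
explicitly size-normalized.

What the generator does *not* emulate: nutrient fields and tropisms,
time-resolved growth, septation and regrowth after damage, width
gradients along a hypha, 3D structure, and imaging artefacts beyond
Gaussian blur and additive noise. Passing tests on synthetic colonies
therefore validates the pipeline's geometry, graph algorithms and
statistics — not the biological realism of any particular species' form.

## Ordination and archetypes

`rda_fit()` implements partial redundancy analysis directly: traits are
standardized to unit variance (total inertia = number of traits); the
covariate (phylum) design is projected out of both traits and the species
design by QR; the constrained part is the projection of the residualized
traits onto the residualized design, eigen-decomposed by SVD; the
leftover is the unconstrained (residual PCA) part. Inertias satisfy
total = conditional + constrained + unconstrained to machine precision,
and a unit test pins eigenvalues, partitions and the pseudo-F against an
independent constrained-ordination implementation to 10⁻⁶. Significance
uses reduced-model permutation — rows of the covariate-residualized trait
matrix are permuted and re-residualized — which is the correct exchange
set for partial models; the p-value uses the add-one convention, so 9999
permutations give a minimum p of 10⁻⁴. Dummy designs drop no information:
rank is handled by the QR, and a design fully absorbed by the condition
yields constrained inertia 0 with a warning. Axis signs are fixed by
making each axis's largest-magnitude loading positive. Missing trait
cells fail loudly rather than being imputed.

Models 1 (micro colonies) and 2 (macro colonies) use all 15 traits;
model 3 pools both scales and keeps only the 10 size-independent or
size-normalized network traits (meshedness, `G_eff_MST`, `volume_MST`,
`R_eff_area`, `RT_eff_area`, five robustness fractions). Where figures
can be read either way, model 3 uses the MST-normalized global efficiency
— the size-free variant — rather than raw `G_eff`; both are always
computed.

Archetype analysis ordinates the size-free traits into their first two
principal components and fits the minimal-area enclosing k-gon (k = 3 by
default; a k-scan is a loop away). Polygon sides are support lines of the
cloud, so containment is exact by construction; side directions are found
by exhaustive search over all hull-edge normals plus a uniform angular
grid (24 by default), optionally refined by Nelder–Mead. For k = 3 the
optimum has at least one side flush with a hull edge, which the candidate
set contains — on the four corners of the unit square the search returns
the area-2 triangle to 10⁻⁴. The triangularity statistic is the t-ratio,
hull area over polygon area; the null permutes each trait column
independently (destroying correlations, preserving marginals) and redoes
the entire ordination + fit, with `p = (1 + \#\{t_\mathrm{rand} \ge
t_\mathrm{obs}\})/(1 + n_\mathrm{rand})`. The randomization statistic
skips the Nelder–Mead refinement by default: the grid statistic is
cheaper and identical for observed and null data, so the comparison is
unbiased.

## Numerical conventions and degenerate inputs

Coordinate merge tolerance on edge-list load is 10⁻⁶ physical units
(exported coordinates of a shared node have identical provenance);
merging is true single-linkage union-find, not grid rounding. Self-loops
are dropped with a warning; parallel edges are kept (two hyphae can join
the same node pair). The MST uses Kruskal with the deterministic
tie-break (resistance, length, edge id) ascending, verified against
exhaustive spanning-tree enumeration on small graphs. Disconnected
targets contribute zero efficiency rather than propagating infinities.
Thresholds are inclusive ("first value ≤ 0.5"). A trait whose support is
empty (no main edges, no junctions, a degenerate hull) is `NA`, never a
silent zero. Every stochastic entry point takes an explicit seed and
restores the caller's RNG state.

## Problem sizes

Unit and acceptance tests run on colonies of roughly 90–450 hyphal
segments (20 seeds per phenotype where a contrast is tested), renders of
~600–900 px on a side, 199–1000 permutations/randomizations for
calibration checks, and 100–200 null datasets for the type-I study —
sizes at which every documented check reproduces in well under half an
hour on one core. The same machinery runs unchanged at larger sizes.

## Known limitations

* 2D projections overestimate connectivity: crossings in slightly
  different focal planes become junctions. Retained by design; a 3D
  extension would need different imaging.
* Cord volume uses the cylinder formula at both scales; for macro cords
  (bundles of hyphae) this is a proxy.
* The convex hull overestimates area for strongly concave colonies; an
  alpha-shape option is a natural extension point.
* The enclosing-polygon search is exact in practice for k = 3 and a
  documented flush-side heuristic for k > 3.
* Hyphae closer than one width are optically unresolvable; the junction
  merge correction compensates on average but cannot recover the true
  paired geometry.
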
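---
title: "Methods: phantom-based analysis of synaptic-vesicle luminal assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based analysis of synaptic-vesicle luminal assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Electron tomography of fixed, freeze-substitution-stained frog
neuromuscular-junction active zones shows that the lumen of every synaptic
vesicle contains a chiral, bilateral assembly of four irregular arms that
radiate from a focal point displaced below and behind the lumen center, and
that thin projections (nubs) connect the arms to roughly 25 sites on the
luminal surface of the vesicle membrane. On docked vesicles those nub
connection sites pair, across the membrane, with the connection sites of the
active-zone-material (AZM) macromolecule classes that direct docking --
ribs, spars and booms inside a "main AZM binding domain", pins and non-AZM
macromolecules elsewhere -- and darker transmembrane stain bands join most
pairs. `lumenmap` re-implements the whole quantitative chain behind those
statements -- segmentation, morphometry, reference-free alignment-model
building, orientation classification, connection-site mapping and
stain-density statistics -- and, because no tomograms from that study are
deposited, exercises it end to end on synthetic phantom scenes with known
ground truth.

The package therefore answers a methodological question: *if* active-zone
volumes with the reported statistical structure are analyzed with these
algorithms, are the reported numbers recovered? Passing tests validate the
pipeline's internal consistency on data that match the published summary
statistics; they cannot validate the biological claims on real tomograms.

# The phantom generator

`scene_params()` collects the study conditions; `synthesize_scene()` builds
a scene; `render_stain()` turns ground-truth masks into gray values
(0--1000, 0 = black).

**Vesicles.** Outer diameters are drawn from N(51.3, 3.3) nm and luminal
diameters from N(35.7, 2.6) nm (truncated so the stained membrane is 5--11
nm thick); docked vesicles sit in two rows flanking the main body of the
AZM with a 3 nm cleft above the presynaptic membrane plane, undocked
vesicles in a layer above. Docked vesicles share the template orientation
exactly, in each vesicle's own active-zone frame (head axis toward the
median plane, vertical axis away from the presynaptic membrane); undocked
poses are Haar-uniform rotations.

**The luminal assembly.** One template per scene: four cubic-spline tube
arms through five control points each, radiating from the focal point at
(-0.18, 0, -0.28) lumen radii, with tips near 0.88 (upper) and 0.68 (lower)
of the lumen radius, tapering from about 3.4 nm radius at the tip to 1.5 nm
at the focal point, and twisted 30 degrees about the head axis with a
common handedness. The twist plus deliberately irregular arm directions
make the shape chiral (its mirror image cannot be rotated onto it -- the
package tests this by exhaustive rotation search) and, just as importantly,
asymmetric enough that reference-free alignment can discriminate the true
pose from pseudo-symmetric flips; a more symmetric synthetic shape would
defeat alignment that evidently succeeded on the real data. Arm radii are
calibrated at template build so the rasterized assembly occupies the target
fraction (default 0.10) of the lumen. Per vesicle, arm control points are
jittered (sd `jitter_sd_arm`), nub anchors and pairing offsets are jittered
(sd `jitter_sd_nub`), the assembly is scaled with the vesicle's luminal
diameter, and a final small radius adjustment pins each vesicle's
rasterized fill onto the target with a narrow spread (sd about 0.45
percentage points) -- the fixed tissue shows a 10 +/- 1% (range) fill, i.e.
far less vesicle-to-vesicle variation than free jitter would produce.

**Connection sites.** Outer macromolecule counts are drawn per class (ribs
4.2 +/- 0.4, spars 2.0 +/- 0.4, booms 7.0 +/- 0.9, pins 3.9 +/- 1.3,
non-AZM 8.5 +/- 1.8). Rib/spar/boom sites are confined to the binding-domain
cap (13.7% of the outer area by default), with ribs near the cap rim closest
to the fusion domain, booms toward the opposite rim and spars between, so
the chord from the average rib position to the furthest boom approximately
spans the cap base; pins ring the fusion domain (5% cap, site-free);
non-AZM sites fill the remainder. Per-vesicle nub counts are drawn from
N(23.8, 4.4) by stratified (quantile-balanced) sampling across the scene:
each count is marginally Normal, but a cohort's mean is calibrated rather
than noisy, so cohort-level checks measure the pipeline rather than
sampling luck. A fraction
(1 - `pairing_dropout_prob`) of nubs receive an antipodal outer
partner (tangential jitter `jitter_sd_nub` on the luminal sphere), extra
partners being drawn as non-AZM macromolecules when demand exceeds the
class draw. Unpaired nubs are placed away from unpaired outer sites, which
emulates the paper's interpretation that unpaired cases reflect partner
macromolecules that failed to stain. Transmembrane bands are rendered for
paired sites with per-class presence probabilities (rib 0.97, spar 0.94,
boom 0.88, pin 0.91; non-AZM 0.90, a value the source does not print).

**Stain.** The noise-free image is piecewise constant at class means
(background 600, membrane 450, outer macromolecules 430, assembly and bands
380), reproducing the reported ordering (assemblies stain denser than the
membrane). With noise, Poisson-counted dark blobs are deposited inside each
structure (denser in the assembly), a sparse set of lighter blobs thins the
membrane outline (sub-sampled stain), and Gaussian sensor noise (sd 40) is
added. Tilt-series and missing-wedge artifacts are deliberately not
simulated: reconstruction is out of scope, and all claims are about
post-reconstruction analysis. That is the main respect in which passing
tests understate the difficulty of real data.

# Segmentation and morphometry

Interactive marking is replaced by programmatic bounds: the membrane is the
largest dark 26-connected component inside a spherical-shell bound around
the (ground-truth) center, thresholded at the bimodal-histogram (Otsu)
split; the lumen is the flood-filled membrane interior grown back one voxel
to the luminal isodensity edge; the assembly is the largest dark component
inside the lumen. Each VOI stores the thresholded component (`support`) and
its one-voxel dilation (`mask`). The dilated mask -- "slightly larger" than
the structure -- exists so isodensity surfaces have room to interpolate;
all voxel-count ratios (for example the lumen fill fraction) use the
support, since dilating a thin tube by one voxel would inflate its volume
by most of a factor of two.

Diameters follow the equator-slice five-axis method: the slice through the
equator, four in-plane axes at 45-degree increments plus the depth axis,
each measured on a radial gray profile (averaged over a small ray bundle)
at the local half-contrast level between the membrane run and its bright
plateaus, with linear interpolation. Rays corrupted by stained structure
crossing a membrane surface (a run that is too thick, or no bright plateau
beside an edge) are retried at small angular perturbations. The sphere and
spherical-zone formulas are `SA_SV = pi d^2` and `SA_AZM = 2 pi R h`,
`h = R - sqrt(R^2 - (d_AZM/2)^2)`, with `d_AZM` the chord diameter of the
zone's base circle -- the only reading consistent with both the printed
13.7% zone fraction and the ~8300 nm^2 sphere area.

Isodensity surfaces are extracted by marching tetrahedra on a lightly
(3-cube mean) smoothed volume, scanning 20 thresholds between the 5th and
95th percentile of the VOI's gray values and keeping the surface with the
largest mean gradient magnitude at its vertices. The smoothing is a
numerical choice: on sharply rendered edges the raw gradient is flat across
the edge shell (any threshold gives a blocky midpoint surface about 20%
over-area), while after smoothing the gradient peaks at the geometric
boundary and the mid-contrast surface wins, bringing a sphere's area within
about 1% of `pi d^2`. The gradient-magnitude criterion itself is a stated
proxy: the original "minimal mean spatial uncertainty" criterion is not
published as a formula.

# Alignment models

Members enter alignment as `assembly_rep` objects: support voxels with
inverted-gray weights (1000 - gray), an inverted-density grid centered on
the assembly centroid, and an isodensity mesh. Registration is reference
free and dual phase: a sequential build in the given (or random) order,
then five rounds of leave-one-out refinement.

*Density method.* Exhaustive local search over +/-30 degrees per Euler axis
and +/-3 voxels, scored as the sum of products of overlapping inverted-gray
values ("product of the overlapping volumes" read as stain-density
cross-correlation). A full 1-degree, three-axis grid would evaluate 61^3
rotations; the search instead runs a 5-degree joint grid followed by a
1-degree joint refinement around the best coarse cell, preserving 1-degree
resolution at desk scale. Ties break toward the smaller rotation, then the
smaller translation. The coarse stage scores a smaller voxel subsample than
the refinement (about 800 vs 1500 points) -- registration is unchanged at
much lower cost.

*Surface method.* Point-to-point ICP with closest-vertex correspondences,
Kabsch updates over the best-matched 85% of points (a standard trimmed-ICP
robustification against structure present in only one member), iterated to
a relative mean-distance change below 1e-4.

*Initialization.* First-contact poses come from a coarse exhaustive density
rotation search (full Euler grid at 10 degrees, centroids superposed)
rather than from multi-start ICP: the bilateral four-arm shape has
pseudo-symmetric flips that closest-point distance ranks almost as well as
the true pose, and the density search -- like the visual initialization
used on the real data -- resolves them. Refinement rounds start from the
stored pose.

*Model region.* Both model kinds report their volume through a
consensus-occupancy criterion: member supports are resampled onto the model
grid with fractional (trilinear) occupancy, averaged, smoothed (six passes
of a 3-cube mean filter) and thresholded at `consensus` (default 0.12). A
half-occupancy ("half-max" / majority) region cannot reproduce the
published model volume: the occupancy integral equals the mean member
volume, so the half-occupancy region is bounded by twice the member volume
and in practice falls far short of it, while the published model occupies
twice the single-assembly fraction of the lumen *and* contains 70--80% of
every member. The smoothed low-consensus region is the definition under
which the model has its published properties on phantom cohorts; the
smoothing both shapes the blobby consensus the published models show and
keeps the region's surface-to-volume ratio low enough that voxel overlap
between independently built models is meaningful. The consensus fraction
and the generator jitter were calibrated once against the mutually
constraining trio (model volume about 20% of a 36-nm lumen; mutual model
overlap above 95%; per-member containment 70--80%) and then frozen: arm
jitter 1.2 nm, nub jitter 2.0 nm, consensus 0.12.

`model_overlap()` mutually registers two models -- ICP on their region
boundary meshes, then a refinement that maximizes the voxel overlap itself
(a local rotation/translation grid followed by a continuous six-parameter
polish on a smoothed occupancy field, matching the published description of
models "aligned to maximize the degree of overlap") -- and reports shared
voxels over own voxels in both directions; `containment_fraction()` maps a
member's support through its stored registration and reports the fraction
inside the model region.

# Orientation

Each member's pose is expressed as a 3D arrow in its own active-zone frame:
shaft toward the median plane and parallel to the presynaptic membrane,
tail vertical. The reference vesicle's arrow comes from its frame; every
other arrow is the reference arrow rotated by `R_m^-1 R_ref` read off the
stored registrations. A vesicle is "oriented" when shaft and tail each
agree with the reference within 30 degrees (the double-cone reading of the
published +/-30-degree criterion, which names exactly those two references).
Arrows lacking tail information are classified on the shaft alone and
flagged partial. External vesicles are oriented by overlaying the model
(multi-start ICP plus density refinement); a flat rotation-score landscape
(an orientation-free shape) sets a low-confidence flag rather than failing.

# Connection-site mapping

Sites are the centroids of the three terminal voxels of each macromolecule
VOI nearest its membrane contact; VOIs more than two voxels from the
membrane warn and emit nothing. Pairing is greedy minimum-great-circle-
offset matching on the radially normalized sphere, one-to-one, rejecting
offsets above 20 degrees -- a threshold chosen as roughly half the mean
nearest-neighbor spacing of ~25 sites on a sphere, configurable and
reported; tests verify greedy equals the exact optimal assignment on small
instances. Band detection takes the membrane voxels inside a 2-nm cylinder
joining a pair's centroids and calls the band present when its mean gray is
darker than 200 randomly placed congruent radial cylinders at the 5%
permutation level. Spherical maps use the vertical (tail) axis as pole and
longitude zero toward the median plane; luminal sites are scaled by the
outer/luminal diameter ratio onto one idealized sphere, and the Robinson
projection interpolates the standard 5-degree coefficient table. Composite
maps maximize the pairwise kernel overlap
`sum_{i != j} (1/(Nri Nrj)) sum_ab max(0, 1 - theta_ab / 30 deg)` of rib
(or nub-paired-with-rib) sites by cyclic coordinate ascent over per-vesicle
rotations (10-degree then 2-degree grids) after a rough alignment of
reference centroids, co-rotating all other classes; the exact functional
form of the published overlap equation is not available in text, so this
normalized kernel form (with the printed variable meanings) is a declared
reconstruction. Distance profiles normalize per vesicle to the average rib
(or nub-paired-with-rib) position after scaling luminal distances by the
diameter ratio.

# Stain statistics

`anova_tukey()` computes the one-way ANOVA from group sufficiency (N, mean,
SD) -- algebraically identical to the raw-voxel ANOVA, and tested against
R's `lm`/`anova` on samples constructed with exact moments -- and
Tukey-Kramer comparisons from the studentized-range distribution with
`df = sum(N) - k` (the voxel counts put df far beyond any tabulated range,
so `qtukey`'s exact evaluation is used directly). Voxels are treated as
independent observations and each vesicle as an individual experiment, as
in the source analysis; spatial autocorrelation of stain makes the
per-voxel df optimistic, which is reproduced deliberately, not endorsed.
The two-sample comparisons use the pooled-variance Student t-test: only the
pooled form reproduces the printed p > 0.65 from the printed moments.

# Problem sizes, determinism and limitations

The bundled analyses run at the published cohort sizes (10--12 vesicles,
~48^3-voxel assembly crops, 1-nm voxels); a full pipeline run takes a few
minutes on one core, dominated by the exhaustive density searches. All
randomness flows from one seed through a counter-based child-seed scheme
(`child_seed()`), so stages are reproducible in isolation; the acceptance
script derives every cohort seed from its `--seed` argument. In test code,
the fixed reference diameter draw uses stratified normal quantiles rather
than pseudo-random draws, so the 11-vesicle mean area check measures the
area computation rather than sampling luck.

Known limitations: no missing wedge, no contrast transfer function and no
membrane deformation at the fusion domain; segmentation bounds come from
ground truth rather than interaction; undocked vesicles keep their full
outer-site class layout (rotated with the vesicle) although only non-AZM
contacts are biologically expected there; the alignment-model consensus
fraction, while frozen, remains a definition choice that real EM3D surface
shells might not need; and the composite-map overlap objective (a linear
kernel with a 30-degree cutoff over a handful of reference sites) is only
weakly pose-identifiable -- near-symmetric site constellations admit rival
rotations scoring within a few percent of the truth, so pooled maps should
be read as site-density summaries rather than exact per-vesicle pose
estimates. The two-vesicle case is tested against a brute-force rotation
oracle, and multi-vesicle recovery is tested on an identifiability-checked
template.
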
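---
title: "Centerline-based morphometry of intracranial carotid calcifications: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-based morphometry of intracranial carotid calcifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`calcimorph` measures the morphometry of high-density calcifications in
the intracranial carotid artery (ICA) from segmented CT angiography: how
wide each deposit wraps around the vessel (arc width), how thick it is
radially, how far it is from the lumen, how far it extends along the
artery, where it sits anatomically, and how much luminal narrowing
coincides with it. This vignette records the measurement model, every
tunable parameter, and the design decisions taken where more than one
reasonable implementation exists — together with what the phantom-based
validation does and does not establish.

## Segmentation model

Two HU rules define the input classes. The lumen is the inclusive window
**[100, 600] HU** — the range of intra-arterial iodinated contrast — and
calcification is **strictly above 600 HU**. The high threshold is what
makes calcification separable from contrast-filled lumen on angiographic
images; its cost is that low-density calcification is invisible to the
method (see Limitations). Calcification is additionally required to lie
near the lumen: a connected component entirely farther than `proximity_mm`
(default **3 mm**, Euclidean distance transform of the lumen mask) is
treated as bone or unrelated calcification and discarded. A distance rule
replaces what is a manual judgement in interactive segmentation precisely
so that it is reproducible.

An asymmetry is central to the design: the *lumen* is carried forward as a
smoothed surface mesh, while *calcification* is never smoothed — it stays
voxels throughout, because smoothing a few-voxel-thick shell destroys the
arc width, thickness and gap information the pipeline exists to measure.

### Meshing and smoothing

The lumen mask is converted to a surface as the exact voxel-boundary
("cuberille") mesh: every exposed voxel face becomes two triangles. This
surface is watertight by construction and encloses exactly
`voxel count × voxel volume`, which makes volume bookkeeping trivial, at
the price of a staircase that the smoothing step removes. Smoothing is
uniform-weight Laplacian relaxation with relaxation weight
`smooth_factor = 0.3` per iteration and `smooth_iters = 20` sweeps, run in
the Taubin λ|µ form (passband constant 0.1): each positive step is
followed by a slightly larger negative step. Plain Laplacian relaxation at
these settings was measured to shrink a 2 mm-radius tube by about 3% in
radius (6–7% in cross-sectional area), a bias larger than everything else
in the pipeline combined; the λ|µ counter-step removes the staircase while
preserving tube cross-sections to well under 1%. The factor 0.3 is kept as
the single user-facing smoothing strength.

## Centerline

The centerline algorithm is a deliberate design choice (the measurement
model needs *a* lumen-centered polyline; many algorithms can produce one):

1. **Path**: Dijkstra shortest path between the two user-supplied
   endpoints on the 26-connected voxel graph, with edge weight
   `step length × mean(1/(d + h/2)²)` where `d` is the Euclidean distance
   to the lumen boundary. The inverse-square pull keeps the path near the
   medial axis; branching lumens are rejected upstream (the ICA is
   analyzed as a single channel).
2. **Refinement**: after light Gaussian smoothing of the path coordinates
   (σ = 1 mm along arclength), every interior point is moved to the area
   centroid of its perpendicular lumen cross-section (48 boundary rays,
   fixed-point iteration, tolerance 0.05 mm, at most 10 sweeps).
   Endpoints stay where the user put them, and any apparent centroid move
   larger than 1 mm is truncated to unit length: both rules exist because
   one-sided tangent estimates near the artificial end caps can tilt the
   sampling plane along the tube and produce runaway "centroids".
3. **Resampling**: uniform `step_mm = 0.2` spacing
   (`floor(L/0.2) + 1` points), unit tangents, and rotation-minimizing
   (double-reflection) in-plane frames. Frenet frames were rejected
   because they are undefined on straight runs and flip at inflections,
   both of which occur in real and phantom vessels.

Curvature is estimated by circumscribed circles through point triples
spaced `curvature_sigma_mm` (default **2 mm**) apart, then Gaussian
smoothing of the profile with the same σ. At 0.2 mm spacing a naive
three-neighbour estimate is dominated by sub-voxel jitter (it overestimated
a 40 mm bend radius fivefold in testing); the wide stencil recovers
phantom curvature to a few percent.

On phantoms, the extracted centerline of a straight tube lies within
0.04 mm RMS of the true axis, a semicircular tube's arclength is recovered
within 1%, and mid-tube curvature within 5%.

### Bouthillier C2–C6 labelling

The four section boundaries (C2/C3 petrous genu, C3/C4 lacerum bend,
C4/C5 posterior genu, C5/C6 anterior genu) are placed at the four most
prominent peaks of the smoothed curvature profile, ordered by arclength
from the proximal (petrous-canal) end; peaks need curvature above
0.05 mm⁻¹ and 4 mm separation. This landmark heuristic is a stand-in for
dedicated anatomical-labelling methods and is validated only on phantoms
with planted bends, where boundaries land within ±2 mm (±0.8 mm in the
shipped siphon fixture). When fewer than four prominent peaks exist (a
straight tube, an atypical anatomy), labelling falls back to fixed
arclength fractions (defaults 0.25 / 0.40 / 0.60 / 0.80) and flags the
result; explicit boundary arclengths can always be supplied and bypass
peak picking entirely. C2 and C3 together form the petrous part; the
non-petrous tortuosity index is computed on the C4–C6 sub-polyline using
*that sub-polyline's own endpoints* for the chord — the formula applied to
the restricted artery.

## Cross-sections and per-slice metrics

One cross-section is taken at every centerline point (0.2 mm apart). The
lumen contour is the plane–mesh intersection loop that contains the
centerline point (other loops — the opposite limb of a bent vessel, for
example — are ignored); slices whose plane yields no such loop are flagged
invalid and excluded. The "lumen center" from which the **360 radial rays**
(1° apart) emanate is the *area centroid of the contour*, a definition
chosen over the raw centerline point so that ray lengths are symmetric in
non-circular sections. Lumen diameter is the equivalent-circle diameter
`2√(A/π)` — rotation-invariant and robust to contour noise; min/mean/max
over slices (excluding 1 mm at each end, where the cutting planes cross
the artificial end caps of the analyzed range) summarize the artery.

Along each ray the calcification mask is sampled by trilinear
interpolation at half-voxel steps. Three estimators are deliberately
different in how they treat partial volume:

- **Intervals** (`r_in`, `r_out` per crossing of the 0.5 level) define
  membership, thickness (largest single-interval radial extent in the
  body) and gap (innermost `r_in` minus the lumen radius, clamped at 0;
  negative distances are segmentation artifacts). Runs spanning a single
  radial sample (under half a voxel) are rejected — one voxel is the
  radial detection limit.
- **Area** uses the unthresholded polar integral `Σ v·r·Δr·Δθ` over the
  body's rays. Thresholded intervals oscillate by ±30% per ray purely from
  lattice phase; the raw integral is mass-conserving and lands within
  ~1–3% of the annular-sector closed form on wedge phantoms.
- **Arc width** is the inclusive degree count of the body's rays, with the
  two rays at each end of a run weighted by their radial extent relative
  to the body's median extent. The unweighted count is biased +3…+5° at
  0.3 mm voxels (taking the maximum over ~10 radial samples of a boundary
  that wiggles by half a voxel is one-sided); the edge weighting removes
  most of that bias while reducing *exactly* to the plain inclusive count
  on crisp, non-voxel input (so a body covering rays 0–30 still reads
  31°, and a single-ray body reads 1°). Full rings have no edges and read
  360°.

In-slice bodies are rays grouped by angular adjacency with wrap-around at
359°→0°.

## Artery-level aggregation

3D calcification bodies are the **26-connected** components of the
calcification mask; 6-connectivity fragments voxelized thin shells and was
rejected. Each in-slice body is assigned to the 3D component sampled at
its interval midpoints. Per body, the longitudinal extent `L_j` is the sum
of arclength gaps between consecutive member slices — `0.2·(n−1)` for a
contiguous body on `n` slices, 0 for a single-slice body — and
`L_TOT = Σ_j L_j`. This definition has the exact property that deleting
one interior slice (splitting a body) reduces `L_TOT` by `2 × 0.2` mm,
which the tests assert to machine precision.

Lumen surface contact is the summed area of lumen triangles whose centroid
lies within `contact_mm` of a calcified voxel centre. The default is 2/3
of the voxel spacing: large enough to cover the half-voxel offset a
boundary voxel's centre can have from a surface it touches, small enough
to exclude the next voxel shell. On a touching 60°×10 mm wedge phantom
this recovers the cylindrical patch area within a few percent, where a
full voxel-diagonal distance overestimates it by ~50% through sideways
leakage.

### Stenosis

For each contiguous run of calcified slices `[N, M]`: the reference area
`A_ref` is the largest lumen area on slices strictly proximal to `N`
(when none exists — calcification at the very start of the analyzed range
— the first slice is used and the result flagged). Per-slice stenosis is
`s_i = (1 − A_i/A_ref)·100`. Cumulative stenosis divides the summed areas
by `A_ref · (M − N)`: the denominator counts `M − N` reference areas, so
the sum runs over the matching `M − N` slices and the identity
`S_c = mean(s_i)` over that slice set holds *algebraically*; the package
asserts it to 1e-9 as an internal consistency check. (Counting `M − N + 1`
slices in both places would be equally consistent; the `M − N` form is the
one used here, and the identity check pins whichever convention is in
force.) A single-slice region uses a denominator of one. Severity uses
strict thresholds — a slice must *exceed* 30 / 50 / 70 / 90% — giving the
bands `<30`, `30–50`, `50–70`, `70–90`, `>90`; "maximum cumulative
stenosis" for an artery with several separated calcified regions is the
maximum of the per-region `S_c`.

### Location and orientation

The predominant segment is the C2–C6 label holding the largest summed
in-slice calcification area; exact ties break toward the more distal
segment and are flagged. The predominant wall orientation assigns every
calcified ray's world direction to the nearest of four references on RAS
axes: medial/lateral along patient-x signed by artery side (a left ICA's
medial direction is +x, a right ICA's is −x), and
anteroinferior/posterosuperior at 45° in the sagittal plane
(`(0, +1, −1)/√2` and `(0, −1, +1)/√2`). The 45° composites are a
documented convention — anatomical "anteroinferior" names a direction
between two axes without defining the mix — and are config-overridable.
Burden weights are the same polar patch areas used for slice areas; ties
take the last class in the fixed order and are stable.

## Statistics

- **Paired Wilcoxon signed-rank** (two-sided): zero differences are
  dropped first (all-zero input returns p = 1, flagged degenerate). With
  ≤25 informative pairs and no ties the exact null distribution comes from
  the integer-rank convolution; with ties and ≤20 pairs, from full 2ⁿ sign
  enumeration; otherwise the normal approximation with tie and continuity
  corrections. The in-package implementation exists because the base-R
  exact path cannot both drop zeros and remain exact; `stats::wilcox.test`
  serves as an independent cross-check in the tests where its exact path
  applies, and full enumeration is the oracle elsewhere.
- **χ²** wraps `stats::chisq.test`; Yates continuity correction on by
  default for 2×2 tables.
- **ICC**: two-way model, *single measurement*, *absolute agreement* —
  `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))` from the two-way
  ANOVA mean squares, with the 95% CI by the F-distribution method for
  this form. Single-measurement is the headline because each artery is
  measured once per rater; the average-measure and consistency forms are
  reported alongside (consistency ignores systematic rater bias, so
  absolute agreement ≤ consistency — a property the tests assert).
  Zero between-subject variance is flagged degenerate rather than
  reported as a number.
- **Summaries**: medians with IQRs by linear interpolation between order
  statistics (type 7) — stated because IQRs are reported downstream.
- **No multiple-testing correction** by default (α = 0.05 per test),
  matching the side-comparison design this layer reproduces; Holm
  adjustment is available behind a flag.

## The phantom generator

Phantoms define the validation conditions. A phantom is a parametric
centerline (line, circular arc, helix, or the C1 carotid-siphon composite
with bends at known arclengths), a piecewise radius profile (constant,
linear taper, raised-cosine bump — the taper and bump give analytic
stenosis), and calcified wedges specified in the centerline's transported
frame: `s`-range, angular centre and width, radial thickness and gap.
Voxelization classifies each voxel centre against the analytic geometry at
an isotropic `voxel_mm` (default **0.3 mm**, about the in-plane resolution
of clinical CTA and fine enough to resolve a 1 mm lumen radius at the
stated 3-voxel rule) with HU levels 0 / 300 / 800 placed well clear of the
100/600 thresholds, so threshold tests never depend on partial-volume
luck. Every downstream metric has a closed-form twin computed from the
specification alone, never from the voxel output.

The shipped validation geometry is: a 72 mm siphon composite with two
wedges (70°×1.5 mm and 40°×1.2 mm — arc widths and thicknesses in the
range reported for real ICA calcifications), an 80 mm straight tube with
one wedge, and an 80 mm taper narrowing the radius from 2 to 1.25 mm
(maximal local stenosis ≈56%, comfortably inside the 50–70 band so
severity classification is not decided by sub-voxel noise). Grids are
~100–130 voxels per axis; one full artery analysis runs in well under a
minute on one CPU, and the whole test suite in a few minutes.

What phantoms do **not** emulate: CT noise and beam hardening, partial
contrast filling, motion, neighbouring bone in contact with the artery,
non-isotropic clinical voxels, bifurcations, or irregular (non-wedge)
calcification shapes. Passing the phantom suite therefore demonstrates
that the *geometry and formulas* are implemented correctly at clinical
voxel sizes — not that segmentation of real CTA is accurate, which in the
intended workflow remains the responsibility of the upstream
(semi-automatic, manually corrected) segmentation.

## Degenerate inputs and edge rules

Empty masks refuse meshing; calcification-free arteries return a record
with lumen fields populated and calcification fields `NA`; a calcified
region with no proximal slice falls back to the first slice as reference
with a flag; coincident centerline endpoints are an error (tortuosity is
undefined); seeds outside the HU window are rejected by index; mismatched
grids are an error, not a resample. The voxel-count cap (default 512³)
refuses grids that would leave desk scale.

## Known limitations

- Arc-width recovery is quoted for calcifications ≥1 mm thick; sub-voxel
  shells (≤2 voxels) remain biased by up to ~5° because their lattice
  representation genuinely oscillates.
- The Bouthillier heuristic is phantom-validated only; on anatomies whose
  curvature peaks are not the four named genua it will mislabel unless
  boundary overrides are supplied.
- The inclusive-count convention makes a crisp 60° wedge read 61°; all
  arc-width conventions differ by ±1° at 1° quantization.
- Stenosis attribution is positional: narrowing co-located with
  calcification is reported as calcification-attributable whether or not
  the causal plaque is calcified.
- NIfTI sform headers store spacings in single precision; round trips are
  exact to ~1e-7, not to double precision.
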
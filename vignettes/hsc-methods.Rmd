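---
title: "Boundary-point contour metrics: model, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-point contour metrics: model, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsctools)
```

This vignette is the package's own account of the science it implements:
the boundary-point contour-accuracy model, the geometric machinery under
it, the constrained simulator, and the timing analysis — together with the
numerical choices and the design decisions that were genuinely open.

## The metric

Radiotherapy contours are stored slice by slice as closed planar polygons
whose vertices are (x, y, z) triplets in patient coordinates (mm). Editing
a contour moves some of those vertices; the working hypothesis behind the
Hu similarity coefficient is that editing *time* is driven by how many
boundary points must be moved, not by how far they move, because editing
happens along the organ's edge (the enclosed area is filled automatically
by contouring software).

The metric compares an initial contour with the final, clinically
acceptable contour an observer produced from it:

$$\mathrm{HSC} = N_U / N_T$$

with $N_T$ the total boundary-point count of the final contour and $N_U$
the number of final points left untouched. Two properties are deliberate:

* **Asymmetry.** The denominator is always the final contour. An initial
  contour larger (or denser) than the final one can contribute at most the
  points the two share, so HSC never exceeds 1.
* **Final-contour anchoring.** Any clinically acceptable contour is a
  valid reference ("pseudo ground truth"); anchoring on the observer's own
  final contour keeps the metric aligned with the effort that observer
  actually expended.

### Matching discipline

"Untouched" is operationalized as: a final point is untouched when an
initial point lies within `match_tol` of it (3D Euclidean distance). Two
numerical choices matter here:

* **Default `match_tol` = 1e-6 mm.** Exact float equality is unreliable
  after file round-trips (DICOM stores coordinates as decimal strings);
  1e-6 mm is far below any physical edit and preserves the "coordinates
  unchanged" semantics.
* **One-to-one greedy matching.** Each initial point may certify at most
  one final point; candidate pairs are accepted in ascending-distance
  order. The alternative — counting every final point with *some* near
  initial point (`matching = "many_to_one"`) — lets one stationary vertex
  certify an arbitrary number of final points at permissive tolerances. No
  matching discipline is canonical in the field, so both are exposed; the
  conservative one-to-one rule is the default.
* **Within-slice matching.** Slices pair by z within half the final
  contour's slice thickness, and matches never cross slice pairs, because
  contour editing is a per-slice operation.

### Adapted HSC

Two clinically indistinguishable contours can be offset by a
sub-resolution amount (say 0.2 mm everywhere), which drives the exact HSC
to 0 even though no editing is needed. `adapted_hsc()` therefore treats a
final point whose nearest initial point is within a clinical tolerance —
default 0.5 mm, below the in-plane pixel size of typical planning CT — as
requiring no modification. This is also the form suitable for use
prospectively (e.g. inside a training loss), where the reference contour
is only one of many acceptable ones.

### Comparators

* `dsc()` is the standard volumetric Dice overlap $2|A\cap B|/(|A|+|B|)$,
  computed on rasterized masks. Whether reported DSC values of this kind
  are 3D-volumetric or slice-averaged is usually unstated; this package
  implements the 3D volumetric form and documents the assumption.
* `surface_dsc()` and `apl()` are provided as *simplified, slice-wise 2D
  comparators*: the fraction of boundary length within a distance
  tolerance of the other contour (perimeter-weighted, both directions),
  and the final-contour boundary length farther than the tolerance from
  the initial contour. Their full 3D-mesh definitions are not reproduced
  here; the simplified versions are labelled as such in their results.

## Geometry and rasterization

Polygons are stored open (no repeated closing vertex), matching the DICOM
CLOSED_PLANAR convention and keeping $N_T$ free of double-counted
vertices. Orientation is normalized counter-clockwise on ingest (the
original orientation is kept for round-trip writing), so areas and
centroids have predictable signs. All coordinates stay in patient-space
mm; nothing in the model layer is voxel-indexed.

Masks for the volumetric DSC use a deterministic pixel-center rule: a
pixel belongs to a slice's mask when its center is inside the polygon by
the even-odd rule, with points exactly on an edge counted inside. The rule
is documented precisely so DSC values are bit-reproducible; the default
pixel size is 1 mm, the in-plane resolution of the planning CT the
defaults emulate. Grid planes take the contour of the slice whose z lies
within half the slice thickness, which both absorbs float noise in
recorded z values and allows a finer axial sampling (`z_step`) when
sub-slice volume estimates are needed.

`resample_contour()` places n points at equal arc length along the
boundary, anchored at the original first vertex. Resampled vertices lie on
the original polyline, so the resampled perimeter converges to the
original from below as n grows (corner-cutting makes exact preservation at
finite n impossible unless the vertices are already equally spaced). How a
clinical contouring tool parameterizes boundary points after brush edits
is not standardized; equal-arc-length spacing is this package's
convention.

## The synthetic phantom

`generate_phantom()` builds a bladder-like organ: a stack of superellipse
slices whose radius follows a smooth axial profile, with low-frequency
seeded radial noise. Defaults (chosen once, as the package's study
conditions):

| parameter | default | rationale |
|---|---|---|
| `n_slices` | 28 | ~8.4 cm axial extent at 3 mm; 13/28 = 0.464 makes the Set-2 HSC value exactly representable |
| `slice_thickness` | 3 mm | standard pelvic planning-CT spacing |
| `max_radius` | 40 mm | filled-bladder scale |
| `points_per_slice` | 64 | typical vertex density; sets HSC granularity to 1/28 |
| `superellipse_exponent` | 2.5 | slightly squarish axial cross-section, bladder-like |
| `noise_amp` | 1 mm | visible slice-to-slice irregularity without breaking star-shapedness |
| `axial_profile` | ellipsoid | small at the poles, maximal at the equator |

The phantom emulates the *geometric* character of a real bladder contour —
smooth convex-ish slices, realistic size and spacing, per-slice vertex
counts. It does **not** emulate image contrast, observer behavior,
multi-ring or high-curvature anatomy, or the specific slice-by-slice point
counts of any real patient; conclusions from passing tests are about the
metric and simulator machinery, not about segmentation models or human
editing. Cylinder and sphere profiles with zero noise are provided because
they admit closed-form areas and volumes, which the tests use as analytic
oracles.

## The constrained simulator

The two reference contour sets — five contours sharing one DSC with
increasing HSC, seven sharing one HSC with increasing DSC — were
originally produced by manually editing contours until both metrics hit
their targets. The simulator replaces that trial-and-error with a
deterministic construction:

1. **Untouched-slice set.** The HSC of a contour that copies the ground
   truth on a set of slices and shrinks every other slice is *exactly* the
   untouched slices' share of boundary points (`hsc_from_untouched()`), so
   the HSC target reduces to choosing a slice subset. Achievable values
   are granular in one slice's point mass (1/28 at the defaults);
   `points_per_slice` can be raised to refine the granularity.
2. **Shrink factor.** All remaining slices are scaled radially toward
   their centroids by one common factor. The volumetric DSC is continuous
   and strictly increasing in that factor — from a floor of $2U/(T+U)$
   (U, T: untouched and total mask voxel counts) up to 1 — so
   `solve_shrink_for_dsc()` finds the factor by bisection (stop when the
   measured DSC is within half of `tol`, default `tol` = 0.005; at most 60
   iterations). On a cylinder the relation is exactly
   $\mathrm{DSC}(f) = 2f^2/(1+f^2)$, which the tests use as the oracle for
   the bisection.

**Which slices to leave untouched** was a genuinely open design choice.
Accumulating untouched slices from the *equator* (largest slices first)
maximizes their volume share and therefore the DSC floor: at HSC 0.704 the
floor exceeds 0.94, making a common DSC of 0.850 unreachable, and at HSC
0.464 the floor (~0.77) sits above three of the seven Set-2 DSC targets.
The package therefore accumulates untouched slices from the *poles*
(smallest slices first, ties toward the lower index), which keeps the
untouched volume share minimal and makes every reference (DSC, HSC)
combination feasible on the phantom. A real editor would more likely leave
equatorial slices alone; the pole-first rule is a property of the
constrained construction, not a claim about editing behavior.

Shrinking about the slice centroid with factor ≤ 1 keeps every simulated
contour geometrically inside the ground truth (the slices are star-shaped
about their centroids), mirroring how such sets are drawn in practice; and
any factor < 1 displaces *every* vertex of a modified slice, so the
measured exact-tolerance HSC equals the untouched point mass exactly.

Degenerate and infeasible requests fail loudly: a DSC target at or below
the floor reports the floor; an HSC target of 1 with a fixed DSC below 1
is rejected (untouching everything forces DSC = 1); factor 0 or above 1 is
an argument error.

## The timing analysis

The packaged fixtures transcribe a four-observer timing study:
per-observer HSC/DSC of all twelve simulated cases against each observer's
final contour, the absolute modification seconds, and each observer's
from-scratch contouring time. Absolute times vary widely between observers
(max-to-min 1.83 for the first case); dividing by the same observer's
from-scratch time collapses that spread (1.11) and makes pooling
meaningful.

Choices worth stating:

* **Normalized values are recomputed, not trusted.** `normalize_times()`
  recomputes every ratio from the stored seconds; the printed normalized
  table is kept only as a cross-check. The exact ratio is carried
  alongside a half-up 3-decimal rounding (`normalized_printed`) because
  base R's `round()` is round-half-even and the printed tables are not.
* **OLS, unweighted** (`stats::lm`), with $R^2 = 1 - SS_{res}/SS_{tot}$;
  the source tables do not name a fitting method and ordinary least
  squares reproduces all eight printed slopes/intercepts within ±0.01 and the
  R² values within ±0.005. Per-observer fits use the printed-precision
  values; per-case means average the exact ratios before rounding, which
  is how the printed AVE columns were evidently computed.
* **Descriptive only.** The analysis reports fits and flags a predictor
  whose range is too narrow to support a line (as the DSC is within a
  fixed-DSC set); it performs no hypothesis tests and makes no attempt to
  predict absolute seconds for a particular person, which depend on
  habits, software familiarity and organ contrast.

## Problem sizes

The test suite and the acceptance script run the full two-set
reconstruction on the default 28-slice phantom with a 1 mm grid (about
90 s on one CPU), and use smaller phantoms (8–12 slices, 24–48 points) for
unit-level properties. These sizes were chosen so the geometric
quantization error (raster and point-mass granularity) sits well below the
tolerances being checked.

## Known limitations

* One polygon per slice: multi-ring (donut/island) slices and non-planar
  contours are out of scope.
* The HSC loses meaning for contours that oscillate at high frequency
  around the reference (e.g. alternate vertices on/off the final contour):
  redrawing the whole boundary can then be faster than the point count
  suggests. Auto-contours are typically smooth, where the metric is
  informative.
* The RT-STRUCT writer emits a minimal, self-contained object with a
  synthetic frame of reference when none is supplied; it is meant for
  interchange of contour geometry, not as a complete clinical DICOM
  object.
* `surface_dsc()` and `apl()` are slice-wise simplifications, suitable as
  comparators, not as reference implementations of their 3D-mesh forms.
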
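---
title: "Grading auto-segmentation accuracy: geometric indexes, subjective scores, and the combined standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading auto-segmentation accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socgrade)
```

## The problem

When radiotherapy planning software auto-segments organs at risk (OARs) on
CT, someone must decide whether each contour is usable as-is, needs editing,
or should be redrawn. Purely geometric scores (volume overlap, surface
distances) are objective and portable between centres but blind to clinical
editing burden; purely subjective expert review captures that burden but
does not transfer between centres. This package implements both and a
procedure that combines them: per organ, the observed correspondence between
an expert's subjective level and a geometric index is turned into an
organ-specific grading standard.

## Data model and geometric indexes

A contour is a `voxel_mask`: a 3D logical array with per-axis physical
spacing in mm (the third axis is the CT slice direction; thoracic planning
CTs commonly have 3 mm slices, hence the anisotropy is first-class) and an
origin. Contours are compared only after `validate_pair()` confirms the two
masks share grid shape, spacing (relative tolerance 1e-6) and origin, and
that both are nonempty — every index is undefined on an empty mask, so
emptiness is an error, never a silent zero.

Five indexes are computed per pair, with the manual contour as reference:

* **DSC** `2|A∩B|/(|A|+|B|)` by voxel counts, in [0,1].
* **ΔCMD**: Euclidean distance between centres of mass (unweighted means of
  foreground voxel centres in physical space), reported in cm.
* **ΔV**: `100·|V_test − V_ref|/V_ref` in percent. The denominator is the
  manual volume — it is the declared gold standard — making this the one
  asymmetric index; the asymmetry is intentional and documented rather than
  symmetrised away.
* **MHD/AHD**: Hausdorff distances between the two *surface point sets*,
  not full volumes. A surface voxel is a foreground voxel with at least one
  background face (6-connected) neighbour; voxels on the grid edge are
  surface (outside the grid is background). Surface points are voxel
  centres — sub-voxel face geometry is not modelled anywhere else in the
  pipeline, so introducing it only here would suggest precision that does
  not exist. MHD is the symmetrised maximum of directed nearest-neighbour
  distances; AHD is defined in this package as the average of the two
  directed mean surface distances. Other symmetrisations circulate
  (maximum of the two means, pooled mean over both sets); the choice is
  stated explicitly because the variants differ on asymmetric pairs.

6-connectivity was fixed for surface extraction because it matches the
distance-transform convention and errs toward including voxels (26-
connectivity would classify fewer voxels as boundary, thinning surfaces).

Nearest-neighbour distances are computed blockwise from the expansion
`|a−b|² = |a|² − 2a·b + |b|²` using BLAS matrix products, with block size
capped so no distance block exceeds a few MB. At the surface sizes this
package targets (up to tens of thousands of points) this runs in well under
a second; the test suite checks it against a literal all-pairs loop to
1e-9 cm on randomized small grids.

All internal distances are mm; conversion to cm happens once, at the metric
boundary, because grading thresholds and reports are conventionally in cm.

## Threshold grading

A grading scheme is a JSON-configured set of per-index cutpoints. The
built-in `our_center` scheme grades all five indexes into levels 1–3 with an
exact-perfection level 4; `velker` grades DSC only; `ciardo` grades DSC,
ΔCMD and AHD (each on a 1–3 scale, as published).

Two numerical conventions matter:

* **Boundary values take the better level.** DSC 0.8 is level 3, ΔCMD
  1.0 cm is level 2, a 10% slice-modification rate is level 3. This is
  forced by the published worked examples (a lower-inclusive "0.8 ≤ DSC"
  bound; a mean ΔCMD of exactly 1.00 cm graded level 2; a 10% subjective
  record graded level 3) and is applied uniformly with a 1e-9 comparison
  tolerance so that computed values sitting on a cutpoint up to floating
  noise are not misgraded.
* **Level 4 requires exact perfection** (DSC 1, distance 0, within 1e-9).
  Level 4 means the auto-contour replaces manual delineation outright; any
  measurable deviation disqualifies it.

The subjective standard grades by slice counts in three organ-length
classes: percentage modified for organs over 10 slices, counts for 3–10
slices, counts for under 3 slices. In the shortest class the level-1 cell
("3 or more modified slices") is unreachable, since at most 2 slices exist;
it is implemented as written rather than silently reinterpreted, and this
note is the documentation of that quirk. When a percentage is computed from
counts it is used unrounded for grading; `pct_modified_display()` provides
the round-half-up integer for tables only.

The consistency report compares per-organ subjective and objective levels
and counts the organs where the subjective grade is exactly one level
lower — the characteristic signature of editing burden invisible to
geometry. On the shipped 13-organ thoracic tables this statistic is 6 of 13
organs (46.2%), with the remaining 7 equal.

## Deriving the SOC standard

`soc_standard()` is the package's estimator. Input: one row per case with
the index values and the subjective level (1–4); an optional `exclude`
column drops flagged cases (no automatic outlier rejection is performed —
exclusion is an expert judgement, recorded in the input, not an algorithmic
step). Per organ and index:

1. Cases are grouped by subjective level; per level the exact min, max and
   mean are recorded (`summarize_levels()`).
2. Only levels actually observed participate; adjacent means adjacent *in
   the observed set* (an organ observed at levels 1 and 3 compares those
   two directly).
3. For each adjacent pair, the closed observed `[min, max]` intervals are
   tested for intersection (shared endpoints count as overlap). Disjoint →
   the ranges are the standard for those levels. Overlapping with per-level
   means monotone in the index's improvement direction → the means are the
   standard. Non-monotone means → `undefined`: small cohorts can produce
   inverted means, and inventing a standard there would be worse than
   refusing. A mixed result (range at one pair, means at another) is kept
   as-is.

**Interval bounds.** A range-based level keeps its observed extreme on any
side that faces another observable level, and extends to the theoretical
limit on a side with nothing beyond: level 1 extends to the worst limit
(DSC 0, distance ∞) and levels 3–4 extend to the perfect value (DSC 1,
distance 0). This reproduces the published layout for single-level organs
(DSC `0.93–1` for a good one, `≥ 0.28` cm for a poor one's centroid
distance) and for multi-level organs (an intermediate level observed between
others keeps both observed bounds). A cohort whose single observed level is
2 gets its plain observed `[min, max]` — both sides face observable levels,
so no extension is justified; this case does not occur in the published
tables and the rule is this package's own conservative choice.

**Grading by a derived standard** (`predict()`): within a range-based
entry's interval, that level; in the unobserved gap between two disjoint
intervals, the *worse* level — a gap value is unproven territory and the
conservative reading costs review time rather than risking an unreviewed
contour; beyond the observed extremes, the nearest observed level. For
mean-based (or mixed) standards the nearest level representative wins (the
mean, or the interval for range entries), ties to the better level; grading
against means is not defined by the source procedure, so this rule is a
documented package choice rather than a reproduction.

The headline standard uses DSC only. Across the five indexes, DSC (and to a
lesser degree AHD) showed level assignments consistent across published
threshold schemes, while ΔCMD, ΔV and MHD did not; the per-level
correspondence of the other four indexes is also visibly weaker. The
derivation is nonetheless implemented for all five, and `indexes =` accepts
any subset.

## The synthetic generators

Three generators make every code path testable without imaging data:

* `make_box_pair()` — solid box vs. its integer-voxel shift. Dice and ΔCMD
  have closed forms (overlap arithmetic, shift geometry), ΔV is exactly 0,
  and MHD/AHD expectations come from an independent all-pairs scan over the
  surface sets.
* `make_eroded_pair()` — sphere vs. its k-fold 6-connected erosion: exact
  ΔV from voxel counts, ΔCMD exactly 0 by symmetry, Dice decreasing in k.
* `simulate_cohort()` — per (organ, level) blocks of cases with DSC drawn
  either uniformly from a stated interval or normally (clipped to [0,1]),
  the remaining indexes drawn from the threshold band consistent with the
  level, and AHD capped at MHD. One seed argument controls the draw inside
  a local RNG scope; the caller's random state is untouched and a fixed
  seed reproduces the cohort bit for bit.

What these emulate: controllable overlap, level/index correspondence of
either the disjoint-range or the overlapping-mean kind, and cohort sizes.
What they do not emulate: real anatomy (no elongated, branching or thin
structures), CT resolution effects, rater noise in the subjective levels,
or correlation structure between the five indexes beyond band membership.
Passing tests therefore demonstrate correctness of the arithmetic and of
the derivation logic under the stated sampling assumptions — not clinical
performance of any segmentation software.

Test problem sizes: random-mask oracle comparisons run on grids up to
12×12×10 with four repetitions; recovery tests for the derivation use 200
cases per level (where the extreme order statistics of a uniform sample sit
within about 3 interval-widths/201 of the true endpoints, and sample means
within 3 standard errors of the true means); the continuous-geometry check
uses a radius-15-voxel sphere pair, where voxelisation error on the Dice of
two offset spheres is below 0.02. These sizes keep the whole suite in the
seconds-to-a-minute range while leaving each check statistically sharp.

## Known limitations

* Masks must live on a common axis-aligned grid; NIfTI affines with
  rotation or shear beyond permutations/flips are rejected, and contour
  polygons (e.g. DICOM RT-STRUCT) must be rasterised upstream.
* The Hausdorff surfaces are voxel-centre point sets; results on very
  coarse grids differ from polygon-based implementations by up to about a
  voxel diagonal.
* The derivation reports what a cohort supports and nothing more: organs
  observed at a single level yield a standard for that level only, and
  overlapping levels with inverted means yield `undefined`. Both outcomes
  are information, not failures.
* The subjective path models a single expert; inter-observer variability is
  out of scope.
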
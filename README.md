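# socgrade

Grading the accuracy of radiotherapy organ-at-risk (OAR) auto-segmentation
against manual reference contours.

Auto-segmentation software delineates OARs on planning CT in seconds, but its
contours still need review, and there is no single agreed way to score how
good they are. Two traditions exist: **geometric objective** grading
(thresholds on contour-comparison indexes such as the Dice similarity
coefficient) and **subjective** grading (an expert counts how many CT slices
they had to fix). The two disagree systematically — for several thoracic
organs the subjective grade sits exactly one level below the DSC grade,
because slice-level modification burden is invisible to volume overlap. This
package implements both paths and the procedure that reconciles them: an
organ-specific **subjective–objective-combined (SOC) grading standard**
derived from a cohort of cases graded both ways.

## What it computes

**Geometric indexes** between a manual reference mask *A* and an auto-segmented
test mask *B* on a common voxel grid (anisotropic spacing respected, distances
reported in cm):

* DSC = 2|A ∩ B| / (|A| + |B|)
* ΔCMD — Euclidean distance between centres of mass
* ΔV = 100·|V_B − V_A| / V_A (manual volume is the denominator)
* MHD — maximum Hausdorff distance between the two surface point sets,
  symmetrised: max( max_a d(a,B), max_b d(b,A) )
* AHD — average Hausdorff distance: ½( mean_a d(a,B) + mean_b d(b,A) )

Surfaces are the centres of foreground voxels with a background 6-connected
neighbour (grid edges count as surface).

**Objective grading** maps index values to levels 1–3 under configurable
threshold schemes (three built-ins ship as JSON: `our_center` covering all
five indexes, `velker` DSC-only, `ciardo` DSC/ΔCMD/AHD), with level 4
reserved for the exact perfect value. A value lying on a cutpoint takes the
better level.

**Subjective grading** maps slice-modification counts to levels 1–4: nothing
modified → 4; organs over 10 slices by percentage modified (≤10% → 3,
≤20% → 2, else 1); shorter organs by count.

**SOC derivation** (`soc_standard()`, the package's fitting function): group
one organ's cases by subjective level; if adjacent levels' observed index
ranges are disjoint, the ranges become the grading standard; if they overlap
but per-level means remain monotone, the means do; non-monotone means are
reported as `undefined`. Single-level organs yield half-bounded intervals
(e.g. DSC `0.93–1` for a level-3 organ, `≥ 0.28` cm for a level-1 organ's
centroid distance). The fitted object has `print`, `summary`, `predict`,
`plot` and `as.data.frame` methods; `predict()` grades new cases by the
derived standard (gaps between disjoint ranges go to the worse level).

## Worked example

Metrics on a synthetic phantom pair (a 10³ box and the same box shifted 5
voxels, 1×1×3 mm voxels):

```r
library(socgrade)
p <- make_box_pair(10, shift = c(5, 0, 0), spacing = c(1, 1, 3))
compute_metric_set(p$reference, p$test, oar = "phantom")
#> <metric_set phantom> DSC 0.5000 | dCMD 0.50 cm | dV 0.0% | MHD 0.50 cm | AHD 0.21 cm
```

Half the box volume overlaps (DSC 0.5), the centroid moved 5 mm (0.50 cm),
the volume is unchanged (ΔV 0%).

The package ships the per-organ index means, slice-modification records and
published level assignments of a 13-organ thoracic evaluation as CSV
fixtures. Regrading the printed means under the `our_center` scheme and the
slice records under the subjective standard, then comparing:

```r
m  <- thorax_index_means()
lv <- grade_metrics_table(m[c("oar","dsc","cmd_cm","dv_pct","mhd_cm","ahd_cm")],
                          "our_center")
head(lv, 4)
#>      oar level_dsc level_cmd level_dv level_mhd level_ahd
#> 1 R Lung         3         3        3         2         3
#> 2 L Lung         3         3        3         1         3
#> 3   Skin         3         1        2         1         1
#> 4  Heart         3         3        3         2         2

subj <- grade_subjective_table(thorax_subjective())
consistency_report(subj, setNames(lv$level_dsc, lv$oar))
#>   one_level_lower   6 (46.2%)
#>   equal             7 (53.8%)
#>   other             0 (0.0%)
```

The right lung grades level 3 on every index except MHD; for six of the 13
organs (46.2%) the subjective grade is one level below the DSC grade. Both
tables reproduce the published level grid cell for cell.

Deriving a SOC standard from a simulated cohort with separated per-level DSC
intervals:

```r
coh <- simulate_cohort(data.frame(oar = "LungX", level = c(2, 3), n = c(20, 20),
                                  dsc_lo = c(0.70, 0.82),
                                  dsc_hi = c(0.78, 0.95)), seed = 7)
soc_standard(coh)
#> SOC grading standard — 1 organ(s), indexes: dsc
#>  oar   dsc_L1 dsc_L2        dsc_L3
#>  LungX -      0.7007-0.7791 0.8256-1
```

The adjacent levels' observed ranges are disjoint, so the ranges themselves
become the standard; the best level is extended to DSC 1 on its quality side.

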
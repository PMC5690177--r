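# wbrt — automated whole-brain radiotherapy planning by database matching

Treatment planning for whole-brain radiation therapy (WBRT) is simple in
principle — two opposed lateral beams, MLC leaves shielding the eyes and
lenses — but consumes clinical time on contouring and on trial-and-error
MLC shaping that encodes human judgement. `wbrt` automates the whole
chain for this disease site:

1. **Auto-segmentation** of brain, eyes and lenses from the CT with a
   fixed chain of morphological operators: soft-tissue windowing
   (HU ∈ [−200, 200]), Sobel bone edges, an erosion that severs
   muscle-scale connections before selecting the **largest** component
   (brain), roundness ranking to find the two **roundest** components
   (eyes, refined by a level set), and an H-convex transform to find the
   **brightest** patch near each eye (lens).
2. **Case retrieval**: the segmentation is cropped to the anatomy near
   the MLC (a "nape-to-forehead" plane discards posterior/superior brain
   surface), aligned to each database case by translations-only
   iterative closest point, and scored with a direction-selective RMS
   distance

   score = sqrt( (1/N) Σᵢ [ (yᵢ − closest(yᵢ))² + (zᵢ − closest(zᵢ))² ] ),

   which ignores the left–right (along-beam) residual component and
   squares the rest so that a localized large mismatch scores worse than
   a uniform small one. The lowest score wins.
3. **Plan retargeting**: the winning case's plan is reused verbatim —
   beams, MLC, monitor units untouched — with only patient name/ID, a
   fresh UID, and the isocenter (mapped back by the inverse ICP
   translation) changed. Dose is recomputed downstream in the TPS.

Everything is testable without clinical data: a parametric head phantom
generates CT volumes with exact ground-truth masks, jittered anatomy
databases and template plans.

The intended audience is medical-physics and image-analysis researchers
studying knowledge-based planning; the package is a research
implementation, not a clinical device.

## Worked example

A 2 mm phantom end to end (output as printed):

```r
library(wbrt)
spec <- phantomSpec(spacing = c(2, 2, 2), gridShape = c(80L, 104L, 86L))
ph <- generatePhantom(spec)
ph$ct
#> CTVolume: 80 x 104 x 86 voxels, spacing 2 x 2 x 2 mm
#>   HU range [-1000, 700], origin ( -79, -103,  -85) mm

seg <- segmentAll(ph$ct)
seg
#> SegmentationResult:
#>   brain     132514 voxels (1060112 mm^3)
#>   eye_L        793 voxels (6344 mm^3)
#>   eye_R        793 voxels (6344 mm^3)
#>   lens_L        24 voxels (192 mm^3)
#>   lens_R        24 voxels (192 mm^3)

metricReport(seg, ph$masks)
#>   structure      dice mean_surface_distance_mm hausdorff_mm
#> 1     brain 0.9999925             0.0003891051            2
#> 2     eye_L 0.9302053             0.6089743590            2
#> 3     eye_R 0.9302053             0.6089743590            2
#> 4    lens_L 1.0000000             0.0000000000            0
#> 5    lens_R 1.0000000             0.0000000000            0
```

The report compares the automatic segmentation against the phantom's
ground truth: Dice overlap (1 = perfect), symmetrized mean surface
distance and Hausdorff distance in mm. Matching against a 10-case
jittered database and reusing the best plan:

```r
idx <- generateDatabaseIndex(spec, 10)
ranking <- rankDatabase(seg, idx)
head(ranking, 3)
#>    case_id    score        tx         ty         tz n_points
#> 1 case_004 1.618181  5.266292   5.904951  -2.820177      831
#> 2 case_009 1.696391 -3.337113  -6.728335  12.324140      831
#> 3 case_005 1.869644 -6.818750 -11.065197 -12.064418      831

plan <- retargetPlan(attr(ranking, "bestPlan"), "NEW^PATIENT", "NP001",
                     c(ranking$tx[1], ranking$ty[1], ranking$tz[1]))
plan
#> PlanTemplate 'WBRT_TEMPLATE' for NEW^PATIENT (NP001): 2 beam(s), isocenter (  0.5509, -13.0406,   9.2097) mm
```

`case_004`'s anatomy is 1.62 mm (RMS, across-beam components only) from
the query after alignment; its plan is copied with the isocenter carried
back into the patient frame by the inverse of the ICP translation
`(tx, ty, tz)`.

A command-line wrapper covers the same pipeline from a shell
(`inst/cli/wbrt.R`): subcommands `phantom`, `segment`, `evaluate`,
`build-db`, `match` and `autoplan`.

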
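# smfishloc

Quantification of subcellular mRNA localization from single-molecule FISH
(smFISH) images of epithelial cells, for researchers measuring how
strongly a transcript is enriched at the cell membrane or apical
junction — e.g. junctional mRNAs such as *dlg-1* and *ajm-1* in
*C. elegans* seam-cell epithelia.

## What it computes

Each diffraction-limited smFISH dot is one or more mRNAs. Per cell, on a
maximum-intensity projection, three outlines are used: the **total** cell
border (drawn on a junction marker), an **interior** outline inset
parallel to the border ("cytoplasmic + nuclear"), and a **nuclear**
outline (DAPI). With per-dot molecule counts *u<sub>i</sub>*,

- membrane mRNA: `membrane = total − interior` (never measured directly),
- standard localized fraction: `membrane / total`,
- transcription-corrected fraction: `membrane / (total − nuclear)`
  (for high transcription-site signal; overestimates in all conditions),
- apical fraction: `apical / total`.

Dots are converted to molecule counts by the intensity-**unit** method:
the unit (one mRNA) is the mean fitted Gaussian amplitude of the five
dimmest well-isolated dots, and each dot's amplitude is divided by the
unit and rounded (floor 1). Spot detection uses a Laplacian-of-Gaussian
filter with subpixel Gaussian fitting, joint refits of overlapping spot
clusters, and a residual second pass.

The package also provides apicobasal intensity-profile analysis (junction
calling from AJM-1 peaks, nuclear-signal eviction by DNA threshold),
per-condition box-plot summaries with Welch t-tests and significance
stars, and a ground-truthed synthetic-embryo simulator (4-channel 3D
stacks: smFISH, DLG-1::GFP, AJM-1, DAPI) used throughout the test suite,
so every stage can be validated against known ground truth without
external microscopy data.

## Worked example

```r
library(smfishloc)

sim <- simulate_embryo(scene_params(seed = 7))   # 5 cells, ground truth
img <- max_project(sim$stack, "mRNA")

spots <- detect_spots(img)
cal   <- calibrate_unit(spots, zstack = sim$stack$voxels[1, , , ])
cal
#> unit_calibration: 1 mRNA = 150.64 (amplitude of 5 dimmest spots)

spots  <- count_mrna(spots, cal)
counts <- assign_spots(spots, sim$rois)
data.frame(cell = counts$cell_id, total = counts$total,
           membrane = counts$membrane,
           est = round(localized_fraction(counts), 3),
           truth = round(sim$truth$cells$true_fraction, 3))
#>     cell total membrane   est truth
#> 1 cell01    33       24 0.727 0.727
#> 2 cell02    30       14 0.467 0.484
#> 3 cell03    32       17 0.531 0.515
#> 4 cell04    30       18 0.600 0.645
#> 5 cell05    32       16 0.500 0.515
```

The generator placed 60% of molecules in the membrane band; the fitted
unit is within 1% of the generator's single-mRNA amplitude (150), and the
per-cell estimated fractions track the per-cell truth to a few percent.
(Estimated totals count *molecules*, truth column shows the
multiplicity-weighted membrane share.)

Condition-level statistics:

```r
tab <- cell_fraction_table(counts)          # percent, long format
summarize_condition(tab)                    # mean, SD, median, hinges
t_test(groupA, groupB, tails = 1, direction = "greater")
significance_stars(2e-4)
#> [1] "***"
render_boxplot(tab, file = "fractions.png") # box + dots + red mean + stars
```

A command-line shell over the same functions lives at
`inst/cli/smfishloc` (subcommands `simulate`, `detect`, `quantify`,
`profile`, `stats`; each writes a `run_manifest.json`).

See the vignette (`vignettes/quantifying-mrna-localization.Rmd`) for the
model, the simulator's assumptions, parameter defaults, and numerical
choices.

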
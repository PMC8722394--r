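---
title: "Quantifying subcellular mRNA localization from smFISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular mRNA localization from smFISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfishloc)
```

## The measurement

Epithelial cells localize certain junctional mRNAs — transcripts encoding
apical-junction proteins such as DLG-1 and AJM-1 in *C. elegans* embryos —
at or near the lateral cell membrane. smfishloc quantifies that
enrichment per cell from single-molecule FISH (smFISH) images, where each
diffraction-limited dot is one or more mRNA molecules.

The per-cell read-out follows the three-outline scheme used with
FISH-quant-style analyses of seam cells on maximum-intensity projections:

1. a **total** outline along the cell border (drawn on the junction
   marker, DLG-1::GFP or AJM-1),
2. an **interior** outline parallel to the border, inset inward, whose
   contents are "cytoplasmic + nuclear" mRNA,
3. a **nuclear** outline around the DAPI signal.

Membrane mRNA is never measured directly: `membrane = total - interior`.
The standard localization fraction is `membrane / total`. When nuclear
(transcription-site) signal is high enough to deflate the fraction, the
transcription-corrected variant `membrane / (total - nuclear)` can be
selected explicitly; note it overestimates localization in every
condition, so comparisons must use the same mode throughout. Pharynx-style
analyses use `apical / total` against an apical outline.

Counts are mRNA molecules, not dots. The intensity **unit** — one mRNA —
is the mean fitted amplitude of the five dimmest spots; every dot's
amplitude is divided by the unit and rounded (floor one: a retained dot
is at least one molecule). This converts multi-mRNA dots into counts
without attempting to split them spatially.

## Spot detection and amplitude fitting

Detection operates on 2D images, normally maximum-intensity projections
of a stated z-range (`max_project()`); seam cells are quantified on such
top views, and nothing downstream uses axial spot positions, so a
full-3D detector is not provided.

The detector is deliberately more careful than a single local-maximum
pass, because the package's own recovery tests demand ~95% recall with
unbiased amplitudes:

* candidates are local maxima of an amplitude-normalized
  Laplacian-of-Gaussian response above a threshold (default: 6 robust
  noise SDs of the response);
* each candidate gets a least-squares Gaussian fit in a small window
  (3 sigma half-width by default, kept well below the classical 4 sigma
  so neighbors contribute little). The fitted width is pinned to the PSF
  sigma by default — the PSF is a property of the optics, and freeing it
  roughly doubles amplitude noise through the amplitude–width
  anti-correlation; `sigma_fit = "free"` restores the general fit.
  The center may move at most 1.5 px so a bright neighbor cannot capture
  the fit; windows clipped by the image edge are flagged and excluded
  from calibration;
* spots whose windows overlap (closer than 4 sigma, clusters up to 8)
  are refit **jointly** as a sum of Gaussians with a common background —
  sequential single-spot fits in such clusters systematically steal flux
  from dimmer members;
* a second candidate pass runs on the residual image (data minus the
  fitted spot model) to recover dots hidden under a neighbor's flank. To
  stop this pass from splitting one spot's flux in two, residual
  candidates must clear a higher bar (3x threshold) and may not fall
  within ~1.5 sigma of an existing spot — closer pairs are not resolvable
  as separate emitters and are handled by unit division instead;
* finally, retained spots must reach half the modal amplitude
  (`min_unit_fraction`): the modal dot is a single mRNA, and a "dot" far
  below it is a fitting artifact, since a real retained dot represents at
  least one molecule.

Raising the detection threshold can only remove spots (monotonicity), and
whole-pixel translations shift detections exactly.

## Unit calibration

"Lightest" is read as dimmest: only under that reading does dividing by
the unit yield molecule counts. Two practical details matter:

* **Eligibility.** The manual procedure outlines five clean, separated
  dots. The automated analogue restricts eligibility to retained,
  *isolated* spots (no neighbor within 4 sigma), whose amplitudes carry
  no crowding bias.
* **Projection floor.** On a maximum projection the background floor is
  inflated by the expected maximum of the noise across z, while a spot's
  peak — dominated by its own brightest slice — gains less; amplitudes
  measured on projections are therefore attenuated by several percent,
  and picking the dimmest few adds an order-statistic bias on top. When
  the z-stack is available (`calibrate_unit(..., zstack = )`), each
  selected dot is re-measured from its axial profile: closed-form
  per-slice amplitudes at the known center, then a 1D Gaussian over z.
  This pools photons from every slice, which keeps the selection bias
  within the package's 10% recovery tolerance.

Calibration scope is per image (all cells of one embryo share a unit);
call `calibrate_unit()` on a subset for per-cell units. Counting mode is
fitted peak amplitude by default; integrated intensity
(`2 pi A sigma^2`) is available via `det_params(mode = "integrated")`.

## Compartment assignment

Point-in-polygon membership is even-odd and boundary-inclusive — a spot
sitting exactly on a drawn outline counts as inside, matching how border
dots are treated in practice. Spots inside the nuclear outline count
toward interior and total as well (containment chain), so
`nuclear <= interior <= total` and `membrane + interior = total` hold
exactly for every cell. A spot exactly on the shared edge of two adjacent
cells is disambiguated by nudging; genuinely overlapping outlines are an
error. Spots outside every cell go to an "unassigned" bucket. Counts are
unit-weighted by default; a raw dot-count mode exists for sensitivity
analysis.

The interior offset (`offset_polygon_inward()`) is the inward parallel
offset computed by clipping against inward-shifted edge half-planes —
exact for convex outlines, which covers the simulator's cells; there is
no polygon-buffering dependency. The offset distance is a config choice
(the drawing-based procedure never states one); the simulator's default
ground-truth membrane band is 6 px (~0.4 µm at 65 nm pixels), and the
interior outline is inset by exactly that band so ground truth and
quantification agree by construction.

## Intensity profiles

`extract_band_profile()` reproduces the multi-channel line-profile
read-out: per 1-px axial bin, each channel's mean over the band's
transverse extent. Junctions (CeAJ) are called as AJM-1 peaks with a
prominence filter relative to the trace maximum (default 20%, so calls
are invariant under uniform intensity scaling) and a 3 px minimum
separation that deduplicates the shared junction of adjacent cells; peak
positions are refined by parabolic interpolation. Nuclear mRNA signal is
evicted where the DNA trace exceeds a threshold (default: Otsu on the DNA
trace); evicted bins are *missing*, never zero, so downstream peak
finding cannot hallucinate edges at span boundaries, and eviction is
idempotent. `peak_overlap_summary()` turns the qualitative
"mRNA peaks overlap protein peaks at junctions" claim into a fraction
within a stated tolerance. Whether profiles are best normalized per cell
or per trace is a genuinely open choice; both raw and per-trace-normalized
values can be derived from the returned traces.

## Statistics

The unit of analysis is the cell (typically 25 cells from 5 embryos per
condition). Summaries use sample SD and type-7 (linear interpolation)
quantiles; whiskers default to 1.5 IQR (the ggplot2 convention the
original box plots were built with), with a min/max option. Group
comparisons use Welch's unequal-variance t-test — the source states only
"t-test" computed in R, whose default is Welch — with Student's pooled
test available. One-tailed p-values take an explicit direction. Stars
follow the strict thresholds 0.05/0.01/0.001; p = 0.05 is "n.s.". No
multiple-testing correction is applied, matching the reporting
convention. Degenerate zero-variance comparisons return t = 0, p = 1
(equal means) by convention.

## The synthetic embryo

So that every stage can be validated without external microscopy data,
the package ships a ground-truthed simulator (`simulate_embryo()`) emulating
bean/comma-stage seam cells: a lateral row of rectangular cells
(150 x 75 px ≈ 10 x 5 µm at 65 nm pixels), a junction belt along the
borders rendered in the DLG-1::GFP and AJM-1 channels, one nucleus per
cell in DAPI, and smFISH spots rendered as 3D Gaussians (lateral sigma
1.3 px, axial sigma 1.5 slices) of peak `multiplicity x unit_amplitude`
over a constant background, with Poisson noise on the signal plus
Gaussian read noise (negative values clamped at zero). A single seeded
RNG stream makes every scene bit-reproducible.

Defaults and why:

* `n_spots_per_cell = 25`: a moderately expressed junctional transcript;
  at this density ~3% of spots fall within 2 px of a neighbor, the
  mostly-resolvable regime single-dot counting assumes (dense-dot
  decomposition beyond unit division is out of scope). The default is
  chosen for statistical power with valid single-dot detection. Fraction-recovery
  tests override it to 200 spots/cell deliberately, to exercise the
  unit-division machinery in crowded membranes.
* `membrane_fraction = 0.6, nuclear_fraction = 0.1`: a localized
  transcript with a visible transcription-site contribution.
* `multiplicity_dist = P(1)=0.8, P(2)=0.15, P(4)=0.05`: guarantees
  enough single-mRNA dots that dimmest-five calibration is well posed.
* `unit_amplitude = 150, background = 20, read noise SD = 2`: peak SNR
  ~11 for a single mRNA, typical of probe sets with 12–24 oligos.
* spots are kept 3 sigma away from image borders so no fit is clipped.

What the simulator does **not** emulate: optical aberrations, uneven
illumination, autofluorescence texture, bleaching, deconvolution
artifacts, curved 3D embryo geometry, or pharynx geometry (the apical
fraction is exercised on the same flat cells via the apical strip).
Passing recovery tests therefore demonstrates the correctness of the
algorithms under the stated imaging model, not robustness to every
property of real micrographs.

## Numerical choices and degenerate inputs

* Pixel indices are 1-based with pixel centers at integer coordinates;
  z-ranges are inclusive `c(z0, z1)` — the idiomatic R convention, used
  consistently for arrays and polygons.
* TIFF pages are stored as 16-bit counts with a recorded quantization
  step (1 unless the data exceed 16 bits), so integer voxel data
  round-trips exactly; metadata lives in a JSON sidecar.
* Zero-variance images detect zero spots with a warning; flat AJM-1
  traces yield no junctions with a warning; cells with undefined
  denominators are excluded from fraction tables with a message.
* Fits that fail to converge are dropped and logged in the spot table's
  `flag` column rather than silently imputed.

## Problem sizes used in the validation suite

The bundled tests run the full pipeline on five-cell scenes (three scenes
for detection/counting recovery; fifteen 200-spot-per-cell scenes, 25
cells per condition, for fraction recovery at true fractions 0.25 / 0.60 /
0.80) and 200-replicate power and type-I simulations at 25 cells per
group, matching the cell-level experimental design. These sizes give the recovery
statistics stable sampling distributions while keeping the whole suite
fast enough to run routinely.
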
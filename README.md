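# abrcsi

Adaptive Bayesian regularized cardiac strain imaging for murine
radio-frequency (RF) echocardiography, with threshold-based fibrosis
mapping and a fully synthetic validation phantom.

## The problem

After myocardial infarction, fibrotic scar stops contracting: the wall
no longer thickens radially nor shortens along its length. In mice the
heart beats above 300 bpm and deforms by 10-40% per cycle, so strain has
to be recovered from RF ultrasound data under severe inter-frame
decorrelation. This package implements an RF speckle-tracking pipeline
for that regime and quantifies fibrosis from the resulting strain
images:

1. **Displacement estimation** — multi-level 2-D normalized
   cross-correlation (NCC) block matching (three pyramid levels, kernels
   of [8, 5, 1] wavelengths by [15, 12, 10] A-lines, [50, 90]% overlaps,
   2-D sinc subsample refinement, per-level median filtering), with
   **adaptive Bayesian regularization (ABR)**: each kernel's correlation
   surface is iteratively sharpened by the product of its neighbours'
   Gaussian-blurred posteriors, with a per-kernel data-driven iteration
   count (more decorrelation, more iterations; high surface SNR, none)
   capped at 10.
2. **Lagrangian strain** — a 40 x 600 = 24,000-point material mesh
   blended between the end-diastolic endocardial and epicardial
   contours accumulates the incremental displacements over one
   ECG-gated cycle; a least-squares plane fit over a 0.06 x 0.5 mm
   window gives the strain tensor, rotated into local wall coordinates:
   radial strain `e_r = r' E r` (thickening positive) and longitudinal
   strain `e_l = l' E l` (shortening negative).
3. **Fibrosis maps and PFM** — at end-systole (smallest chamber area),
   nodes with `e_r < 4%` (radial) or `e_l > -4%` (longitudinal) are
   classified fibrotic; the myocardium splits into six AHA long-axis
   segments and each segment reports its percentage fibrotic myocardium,
   `PFM = 100 * fibrotic / total` nodes.
4. **Histology arm** — 4-class stained-slide label images (fibrotic,
   non-fibrotic, clot, background) are divided into the same six
   segments and `PFM = 100 * fibrotic / (total - background)` pixels;
   a deterministic CIELAB nearest-centroid classifier and a synthetic
   slide generator support end-to-end validation.
5. **Agreement statistics** — Spearman and Pearson correlation, OLS
   trend and Bland-Altman bias with limits of agreement for paired
   segmental PFM series.

Because no murine RF data are publicly deposited, the package ships a
speckle phantom of a contracting myocardium-like annulus with exactly
known displacement and strain fields (closed-form, differentiable, with
an optional akinetic arc emulating scar), plus a synthetic ECG — every
stage is validated against analytic ground truth.

## Worked example

Simulate a phantom whose anterior-mid segment contains a 90-degree
akinetic arc, run the full pipeline, and read off the segmental PFM:

```r
library(abrcsi)

def <- annulusDeformation(center = c(2.2e-3, 2.2e-3),
                          endoRadiusED = 1.0e-3, epiRadiusED = 1.7e-3,
                          dysfunctionAngle = pi / 2,
                          dysfunctionWidth = pi / 2)
sim  <- simulateSequence(def, noiseSNRdB = Inf,
                         scattererReplacement = 0, seed = 21)
cont <- annulusContours(def, n = 64)
res  <- runPipeline(sim$series, cont$endo, cont$epi)
res$pfmRadial
```

```
SegmentalPFM (radial source):
 segment_id   segment_name n_fibrotic n_total pfm_percent included
          1  anterior base        707    4000      17.675     TRUE
          2   anterior mid       3195    4000      79.875     TRUE
          3  anterior apex        797    4000      19.925     TRUE
          4 posterior apex        845    4000      21.125     TRUE
          5  posterior mid       1975    4000      49.375     TRUE
          6 posterior base        530    4000      13.250     TRUE
```

The akinetic arc sits in segment 2 (anterior mid), and that segment
carries by far the largest percentage fibrotic myocardium (79.9%
against a 13-49% background; segment 5's elevated value reflects the
side-wall lateral-tracking limitation discussed in the methods
vignette). The
ground truth is available through `truthStrain(sim$truth, ...)` for
node-wise comparison.

The histology arm round-trips the same statistic from a synthetic
stained slide:

```r
sl  <- synthWSI(size = 240, fibrosisFraction = c(.05, .15, .35, .55, .25, .1))
cls <- classifyPixels(sl$rgb)
pfmHistology(cls, segmentWSI(cls, sl$landmarks))$pfm_percent
#> [1]  4.715232 14.175941 33.165563 52.185430 23.688394  9.483444
```

(the values sit a little below the nominal wedge fractions because the
slide's blood-clot disc counts in the tissue denominator, exactly as the
PFM formula prescribes), and `agreementReport(histoPFM, strainPFM)`
summarizes paired series with
Spearman/Pearson r, an OLS fit and Bland-Altman limits of agreement.

A thin command-line front end over the same functions lives at
`inst/scripts/abrcsi.R` (`simulate`, `track`, `run`, `histo-pfm`,
`evaluate` subcommands).

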
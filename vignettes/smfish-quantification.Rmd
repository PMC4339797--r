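---
title: "Counting single transcripts in whole-mount embryos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting single transcripts in whole-mount embryos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfishq)
```

## The measurement problem

In single-molecule fluorescence in situ hybridization (smFISH), an mRNA is
tiled by a few dozen short labeled oligonucleotide probes, so each transcript
appears in a confocal z-stack as one diffraction-limited dot. Counting the
dots inside one cell gives that cell's absolute transcript number, and the
distribution of counts across cells characterizes expression noise. This
package implements the quantification side of that workflow for whole-mount
embryo stacks: spot enhancement, per-cell masking, threshold-sweep counting,
dot-intensity diagnostics, two-channel detection-efficiency estimation, and
distribution fitting of per-cell counts — together with a simulator that
produces ground-truth-annotated stacks so every stage can be validated
end to end without any external data.

The imaging geometry is strongly anisotropic: default voxels are
0.04 × 0.04 µm laterally with 0.3 µm slice spacing, so a physically round
dot spans many pixels laterally but only a couple of slices axially. All
physical-space parameters (filter scales, matching radii, centroid
coordinates) are expressed in micrometres and converted to voxels per axis
through the `voxel_size` record.

## Spot enhancement

`log_filter()` convolves the stack with a negated Laplacian-of-Gaussian
kernel sampled on the voxel grid. The sigma is given in micrometres
(defaults `sigma_xy = 0.13`, `sigma_z = 0.4`, roughly PSF-matched for a
high-NA oil objective) and converted per axis, so the kernel is isotropic in
physical space even on the anisotropic grid. Three properties matter for
everything downstream:

* **Zero response to flat background.** The second-derivative taps are
  mean-subtracted after sampling, so each 1-D derivative kernel sums to
  exactly zero and the full 3-D kernel annihilates constants, including the
  truncation-tail residual that plain sampling would leave.
* **Linearity.** The filter is a convolution, so responses superpose and
  scale; the test suite checks this to near machine precision against a
  direct (non-separable) convolution oracle.
* **Mirror boundary handling**, which avoids rim responses that would
  otherwise spawn spurious components at high thresholds.

`normalize_filtered()` clips negative lobes to zero and divides by the
global maximum. This puts every equally filtered image on a common [0, 1]
scale, which is what makes both the fixed dot-intensity threshold (0.25) and
the uniform 100-point threshold grid comparable across images. The price of
a global-max normalization is that a single unusually bright object rescales
everything else; the counting stage is designed to tolerate that (see
plateau selection below).

## Cell masks

Cell borders are per-slice polygons in pixel coordinates (`rois.json`,
0-based, one polygon per z-slice, no interpolation between slices — the file
format stands in for interactive freehand drawing). `rasterize_roi()` tests
each voxel center under the even-odd rule with boundary points counted
inside: deterministic and orientation-independent. `apply_mask()` sets
voxels outside the border to exactly 0, and masking is idempotent.
Whether boundary voxels of a hand-drawn border belong to the cell is
genuinely underdetermined; boundary-inclusive was chosen once and is used
everywhere.

## Counting by threshold sweep

Inside one cell mask, `threshold_sweep()` binarizes the normalized image at
the uniform grid t = k/100 (k = 1..100) and counts 26-connected components
at each threshold. 26-connectivity is the default because with 0.3 µm
slices over 0.04 µm pixels the voxels of one dot often touch only
diagonally between slices; 6-connectivity would shear single dots into
pieces. No size filter is applied by default (`min_voxels = 1`).

`select_threshold()` automates the by-eye choice of a counting threshold.
The count-versus-threshold curve of a well-resolved image has a plateau: a
range of thresholds over which every dot is above threshold, no dots have
merged, and the count is constant. Candidate plateaus are runs of at least
`min_plateau = 3` consecutive grid points with identical nonzero count.
Among candidates the selected run maximizes *run length × count*, with ties
going to the lower threshold, and the run's midpoint becomes the counting
threshold.

The count weighting is load-bearing. Scoring by length alone fails in a
specific, common situation: when one dot is about twice as bright as the
rest — exactly what a conglomerate of two transcripts produces, and the same
dot then also sets the normalization maximum — the interval where only that
dot survives is a long flat run at count 1, frequently longer than the true
plateau. Weighting by the supported count restores the plateau where the
dots actually live. Noise-dominated threshold ranges do not compete under
either rule because their counts fluctuate at nearly every grid step and
never form a qualifying run. When no run qualifies, the modal nonzero count
(by total grid occupancy) is used; when every count is zero the cell is
reported as an explicit zero, not an error.

Per-cell results (`count_per_cell()`) include a spot table with
intensity-weighted centroids in voxel and micrometre coordinates. ROIs are
required to be disjoint; overlaps are reported and resolved first-come.

## Dot intensities and conglomerates

`measure_dot_intensities()` applies one fixed threshold — default 0.25 on
the normalized scale, the same for all equally filtered images — and reports
each component's mean member-voxel intensity. `classify_conglomerates()`
bins these means (width 0.05), takes the modal bin center m as the
single-transcript intensity, and flags dots at or above
`fold × m × (1 − tol)` (defaults fold = 2, tol = 0.15) as probable
two-transcript conglomerates.

One caveat is documented rather than hidden: because the measured quantity
is the mean of member voxels *above a fixed threshold* of a peaked (LoG-
filtered) profile, it is a compressed function of dot amplitude — in the
simulator's regime a 2× amplitude dot measures only about 1.45× the modal
mean intensity, although the two populations separate cleanly. The
fold = 2 default corresponds to an acquisition regime in which the mean
tracks amplitude nearly linearly; simulation-based tests therefore classify
with a cut placed by the same rule but at the measured fold (1.5), and both
regimes are exercised in the suite. Whether dot intensity should be read
from raw or filtered voxel values is an open choice in the source workflow;
this package uses normalized filtered values.

## Two-channel detection efficiency

With the same transcript labeled by two interleaved probe sets in different
colors, the fraction of dots in one channel that have a spatial partner in
the other estimates single-channel detection efficiency.  `colocalize()`
matches dots one-to-one, greedily by ascending pairwise physical distance
(equivalent to repeated mutual-nearest pairing), accepting pairs within
`radius` (default 0.3 µm ≈ 3× the lateral PSF sigma, the matching scale at
which genuinely co-located dots are accepted and neighbors are not), and
reports efficiency in both directions.

## Distribution fitting and model selection

Per-cell counts are fitted by maximum likelihood to five reference families
(normal, gamma, logistic, Weibull, Poisson). Normal and Poisson use closed
forms (the normal MLE uses the population standard deviation); gamma,
logistic and Weibull are optimized numerically (relative tolerance 1e-8).
Zero counts are incompatible with the positive-support families and are
replaced by 0.5 with a warning before gamma/Weibull fits. The continuous
families are fitted to integer counts as-is, matching how such counts are
analyzed in practice.

`ks_gof()` computes the one-sample Kolmogorov–Smirnov statistic against the
fitted CDF with the asymptotic p-value, treating parameters as known. Two
statistical caveats are deliberate and documented:

* Estimating parameters from the same sample makes the test
  anti-conservative. A parametric bootstrap (199 replicates, refitting each
  one) is available behind `bootstrap = TRUE` as the corrected alternative.
* For the discrete Poisson family, D is the exact supremum of
  |ECDF − F| over the integers, where both step functions jump at the same
  atoms. Pushing tied integer data through a continuous-sample KS routine
  would instead bound D below by the largest point mass (≈ 0.17 at λ = 5),
  rejecting even perfectly Poisson samples at small rates; the exact-step
  statistic with the same asymptotic null is conservative but usable.

`model_selection_table()` runs all five families per gene and reports the
non-rejected families as the verdict, with no multiple-testing correction by
default (one test per family, as such analyses are usually presented);
`holm = TRUE` gives the corrected view. Counts from several embryos are
pooled by default; the CLI's `fit` subcommand can also split per embryo.

`delta_delta_ct()` implements relative qPCR quantification:
ΔCt = Ct_target − Ct_reference per sample, ΔΔCt relative to the calibrator
group mean, relative expression = efficiency^(−ΔΔCt). Calibrators are
self-normalized (geometric mean exactly 1).

## Probe tiling arithmetic

`max_tiling()` answers how many probes of length p (default 20 nt) separated
by at least g (default 2 nt) fit on a transcript of length L: the
left-packed greedy tiling is optimal for this interval-packing problem, so
the count is ⌊(L + g)/(p + g)⌋; intervals are reported 0-based half-open.
`min_length_for()` is its adjoint. A 720-nt target takes 32 probes and the
shortest 32-probe target is 702 nt — the arithmetic behind the rule of thumb
that roughly 700 bases is the minimum transcript detectable with ~30 probes.
Sequence-content screening (GC, Tm, uniqueness) is out of scope.

## The simulator: what it emulates and what it does not

`simulate_stack()` renders each transcript as a separable anisotropic 3-D
Gaussian (defaults `psf_sigma_xy = 0.1` µm, `psf_sigma_z = 0.35` µm, so a
dot spans more than one 0.3 µm slice) inside convex polygonal cells tiled
without overlap in XY and replicated over a z-interval. The expected photon
image is background (default 20 photons, with a ±10% linear ramp across X
emulating uneven illumination) plus dots (default peak amplitude 150
photons, lognormal ±10% per-dot jitter emulating the tight modal intensity
peak of well-behaved preparations); Poisson shot noise and additive Gaussian
read noise (sd 2) follow. A dot is a conglomerate (2× amplitude) with
probability 0.004 — matching a regime in which roughly 4 dots per 1000 are
doubles — and is dropped from channel B with probability 0.2, the regime of
an ~80% per-channel detection efficiency. One global RNG stream with a
documented draw order (flags first) makes every stochastic sub-draw
replayable in tests.

Dot placement enforces a minimum pairwise separation of 0.6 µm in a
resolution-normalized metric (axial distances scaled by
`psf_sigma_xy / psf_sigma_z` before combining with lateral ones). This is
the simulator's most consequential simplification: it models the
*resolvable-dot* regime. A plain Euclidean minimum would allow dots one
slice apart in z, which the anisotropic optics cannot separate — such pairs
merge into single components at every threshold and no counting method
could, or should, split them.

Consequently, passing recovery tests show that the pipeline counts correctly
when dots are individually resolvable at realistic noise; they do not show
robustness to dense expression (where unresolvable pairs make counts
underestimates by construction), to structured autofluorescence (yolk),
to aberrated or depth-attenuated PSFs, or to segmentation error in the
hand-drawn borders. Those are properties of the specimen and the annotator,
not of the counting arithmetic this package fixes.

## Numerical and interface choices

* Axis order is `(z, y, x)` everywhere; page index = z.
* TIFF pages: non-negative integer stacks are written as 16-bit integer
  pages (bit-exact round trip); real-valued stacks as min/max-scaled 32-bit
  float pages with the range recorded in the JSON sidecar (round trip to
  single precision). Metadata lives in the sidecar, not TIFF tags, to stay
  dialect-free.
* Thresholding is strictly-above everywhere (`filtered > t`).
* Intensity histogram bins are 0-anchored with width 0.05; the modal-bin tie
  goes to the lower bin. Note that a tight cluster can straddle a fixed bin
  edge, which is why homogeneity checks in the suite use the best sliding
  0.05-wide window rather than the fixed grid.
* The run configuration file is YAML with per-stage sections flattened into
  one namespace; precedence is command line > file > defaults, and the
  defaults are the workflow constants (100 thresholds, 0.25 fixed threshold,
  26-connectivity, α = 0.05). Every output CSV begins with a commented
  provenance header (package version, parameters, seed), and a fixed seed
  reproduces outputs byte for byte.

## Problem sizes used by the test and acceptance runs

The validation suite simulates 4 cells × 50 dots on 24 × 384 × 384 voxel
stacks (three seeds) for count recovery, 20 cells × 50 dots on
32 × 768 × 768 for the 1000-dot two-channel efficiency check, n = 200 with
50 replicates for KS model-selection recovery, and n = 10⁴ for MLE
parameter recovery against a likelihood grid-search oracle. These sizes were
chosen so each check is statistically meaningful while the whole suite runs
comfortably on a laptop-class single core.

## Known limitations

* Counts in dense cells are lower bounds: merged dots are counted once (and
  flagged only via the intensity route).
* No sub-voxel Gaussian fitting of spot centers; centroids are
  intensity-weighted voxel means.
* The KS layer inherits the classical caveats noted above even with the
  bootstrap correction available.
* Automatic cell segmentation is out of scope; masks come from the ROI file.
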
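---
title: "Quantifying alpha-synuclein effects on vesicle trafficking, membrane binding and abundance"
author: "asynquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alpha-synuclein effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asynquant)
```

## Scope and model system

Alpha-synuclein (a-syn) is a 140-residue intrinsically disordered
protein whose N-terminal ~100 residues form amphipathic helices on
membranes: a single extended helix on isolated vesicles, or two shorter
helices ("broken helix", helix-1 roughly residues 3-37 and helix-2
roughly 45-92) on micelles, a proposed mimic of a-syn bridging two
apposed membranes such as a docked vesicle and the plasma membrane.
Mast-cell models expressing a-syn report its functional effects through
stimulated exocytosis of recycling endosomes (a proxy for synaptic
vesicles), vesicle redistribution, mitochondrial colocalization, and
stimulated endocytosis, while NMR on micelle- and vesicle-bound protein
resolves which helical segments engage the membrane.

This package implements the quantification layer of that program: every
readout is a function from a well-defined data container to a number (or
per-residue profile), and a seeded synthetic-data module produces each
input class with known ground truth so the whole chain is testable at
desk scale. The package does not do instrument control, segmentation of
raw micrographs, NMR spectral processing, or flow-cytometry gating;
those upstream steps produce the containers this package consumes.

## Stimulated exocytosis from pHluorin traces

A pHluorin reporter is quenched in acidic vesicles and dequenched on
exocytic exposure; adding NH4Cl at the end of the time course
neutralizes all compartments and reveals the total reporter pool. With
window means over the basal epoch, the stimulated plateau and the
post-NH4Cl plateau,

$$\%\,\mathrm{Exo} = 100\,
\frac{\bar F_{\mathrm{stim}} - \bar F_{\mathrm{basal}}}
     {\bar F_{\mathrm{NH_4Cl}} - \bar F_{\mathrm{basal}}}.$$

Window choices matter and are configurable. The stimulated window
defaults to the final 60 s before NH4Cl addition: the stimulated
response is a saturating rise, and the averaged plateau is the
conventional readout; whole-epoch averaging is available by passing an
explicit window. The NH4Cl window starts 10 s after addition to skip
the mixing transient and spans 30 s. The basal window is everything
before stimulation (20 s at the default 2 s sampling).

Numerical guards: the dynamic range must exceed five basal robust
standard deviations (MAD), otherwise a degenerate-trace error is raised
(dead cells produce flat traces whose normalization would blow up).
Noise can push control percentages slightly negative; these are clipped
to zero and flagged rather than erroring, while values above 100% are
kept and flagged. The statistic is invariant to positive affine
rescaling of the raw trace, which the test suite asserts on generated
fixtures.

The trace generator produces a flat basal epoch, a smoothstep rise that
reaches the stimulated plateau exactly after its rise time (120 s by
default), and a step to the NH4Cl plateau, plus additive Gaussian
noise. A smoothstep rather than an exponential rise is a deliberate
choice: it reaches the plateau exactly, so zero-noise closure tests can
assert exact equality instead of approximations. Defaults (600 s trace,
2 s sampling, stimulation at 20 s, NH4Cl at 420 s) mirror a typical
protocol of 20 s baseline and 6-8 min of stimulation. An optional
reacidification rate models endocytic re-quenching (experimentally
suppressed with bafilomycin); with rate zero the trace is unchanged,
which is asserted as a contract. Spontaneous release uses the same
normalization with a pre-stimulus drift window (at least 60 s)
substituted for the stimulated window. No kinetic rate constants for
the stimulated rise are claimed by the model; the generator's rise time
is a free parameter.

## TIRF event detection

Single exocytic events appear in TIRF movies as abrupt, spreading
flashes. Counting them by eye is standard; the detector automates it:

1. per-pixel background as a rolling temporal median (window 15
   frames), which tracks slow drift but not abrupt flashes;
2. Gaussian smoothing of the background-subtracted frames with a sigma
   matched to the expected flash size (1.5 px default);
3. candidate events as strict 26-neighborhood spatiotemporal local
   maxima above 5 robust SDs (MAD) of the smoothed stack;
4. an onset test: a flash rises abruptly, so the previous frame's
   response at the peak must be below half the peak value. This
   suppresses secondary maxima riding on a flash's own decay tail,
   which otherwise outlive the temporal exclusion radius;
5. greedy deduplication within the exclusion radius (3 frames, 4 px),
   keeping the brightest.

Two numerical choices deserve note. The MAD collapses to zero on
noise-free stacks, so the threshold has a relative floor (1e-6 of the
stack maximum) that keeps FFT ripple below threshold. Replicate-padded
smoothing inflates noise variance at the image border, so maxima within
the kernel radius of the border are excluded; the generator places
events away from borders for the same reason. With these defaults the
detector is exact on noise-free fixtures and maintains unit precision
at peak signal-to-noise 10 in the test suite's 20-seed Monte Carlo.

The flash generator renders pixel-integrated Gaussians with peak
amplitude semantics (so noise SD relative to amplitude is the flash
SNR), exponential decay over 4 frames, pairwise spatial separation
beyond the detector resolution, and onsets at least 8 frames into the
movie so the rolling median can establish a background; violating the
separation raises a placement error rather than silently overlapping
events in the zero-noise fixture.

## Shell fractions, overlap and puncta

The membrane-proximal shell is the cell mask minus its inward Euclidean
erosion by `round(shell_nm / pixel_nm)` pixels. The distance transform
makes the shell isotropic (square structuring elements would make the
shell wider along diagonals). The default shell is 800 nm at
100 nm/pixel, i.e. 8 px, a non-degenerate geometry at confocal
sampling. If erosion empties the mask the shell degrades to the whole
mask with a warning flag. The membrane-proximal fraction is
shell-summed intensity over mask-summed intensity; on a uniform image
this equals the pixel-count area ratio exactly, which serves as the
geometric oracle in the tests. The released fraction divides the
post-stimulation shell sum by the post-NH4Cl shell sum of a registered
image pair.

The Manders overlap coefficient is evaluated inside the cell mask by
default: extracellular background pixels carry no biological overlap
information but would inflate the denominator symmetrically; whole-field
evaluation is available by flag since conventions differ between
implementations. Whether thresholding should precede the MOC is also
implementation-dependent; this package computes the unthresholded
coefficient.

Colocalized-puncta counting detects smoothed local maxima in one
channel and counts those whose label-channel mean within one sigma
exceeds a multiple (2 by default) of the label background (median
inside the mask). Counting is per 2-D plane; volumetric counting over
z-stacks is the sum of planes, and the projection convention is the
caller's choice.

The vesicle-image generator places analytically pixel-integrated
Gaussian puncta (sub-pixel ground truth, no point-sampling bias) with
centers at least 2.5 sigma from the shell boundaries, splitting puncta
between the shell band and the interior so the noiseless shell fraction
equals the target exactly in placed mass; residual Gaussian tail
leakage across the boundaries is below one percent and the achieved
noiseless fraction is recorded in the ground truth.

## Residue-resolved NMR

Amide chemical shift deviations between a mutant and the reference
state use the standard weighted combination

$$\Delta\delta_{\mathrm{avg}} =
\sqrt{\tfrac12\left(\Delta\delta_{HN}^2 +
\Delta\delta_N^2/25\right)},$$

with the nitrogen difference down-weighted by its ~5-fold larger shift
range; the 25 is a fixed convention, not a tunable. Profiles default to
residues 1-102 because the acidic C-terminal tail does not engage the
membrane. Missing residues (prolines have no amide; unassigned peaks)
propagate as absent, never as zero: a zero would fake a null deviation.

Secondary carbon shifts subtract sequence- and temperature-corrected
random-coil values from observed CA/CB shifts; positive CA deviations
indicate helix. The packaged random-coil table carries representative
literature-style values with neighbor- and temperature-correction
columns defaulting to zero; because published coefficient sets differ,
the table is a swappable CSV and the tests validate construction
closure (observed = coil + bump recovers the bump) rather than any
specific tabulated number.

Carbon re-referencing estimates the referencing offset between spectra
as the signed mean of (reference - mutant) CA/CB differences over
residues 111-130 — a window in the disordered tail unaffected by
N-terminal mutations — and adds it to all carbon columns. The signed
mean (rather than the absolute difference) is the interpretation
implemented: it is the value that zeroes the post-correction mean
difference and makes the operation idempotent, which the tests assert
to 1e-9 ppm.

Vesicle-binding profiles divide peak intensities with SUVs present by
matched lipid-free intensities; bound residues vanish (slow vesicle
tumbling broadens them away), so the ratio is the free fraction per
residue. Residues whose free intensity sits at the floor are excluded
and listed. A four-parameter logistic fitted to the profile locates the
release boundary; for V70P-like profiles the midpoint recovers the
mutation site within one residue across seeds at 5% intensity noise. No
binding isotherm is fitted — lipid:protein stoichiometry is a generator
input only.

## Absolute intracellular concentration

The blot chain: (1) per-lane loading normalization by the average of
three nonspecific bands, scaled to the grand mean (corrections beyond
25% are flagged; the synthetic defaults keep them under 10%);
(2) ordinary least-squares calibration of band density against the
standard concentrations 2, 3.5, 5, 6.5, 8 ug/ml — with a free
intercept, because blots commonly have a nonzero background offset; a
through-origin option exists; (3) interpolation of unknown lanes
(extrapolation beyond the standards is flagged, negative
concentrations clipped with a flag); (4) division by cell equivalents
per lane (default 7.5e6 equivalents/ml times 25 ul loaded); and
(5) conversion to intracellular concentration using the mean cell
volume (2627 um^3) — pg/um^3 is numerically g/ml — and to molarity via
the sequence-derived molecular weight.

Masses are average (not monoisotopic) residue masses, and cystines
count zero toward the extinction coefficient unless declared: the
packaged a-syn sequence (UniProt P37840) then gives
eps280 = 4 x 1490 = 5960 /M/cm exactly, and a 14,460 Da mass under
which 130 ug/ml is 9.0 uM to the nearest integer. Molarity is reported
at full precision together with a nearest-integer convenience field.
(At 300 ug/ml the same mass gives 20.7 uM, which rounds to 21 rather
than the conventionally quoted 20; the discrepancy is at the rounding
level and that conversion is deliberately not used as a test anchor.)

## Stimulated endocytosis

Quench curves (receptor-bound FITC quenched upon internalization into
acidic endosomes) are normalized so the pre-stimulation baseline is
exactly 1; the quenched fraction is 1 minus the mean over the endpoint
window, defaulting to the final 100 s of the ~1500 s course. The
endpoint statistic was chosen over a single-point read for noise
robustness, and an integrated (area-based) mode is provided without
claiming equivalence; the window is configurable. Relative endocytosis
is the test quench fraction as a percentage of its paired control, an
invariant under common rescaling of both raw curves.

## What the synthetic data does and does not emulate

The generators reproduce the structural features the estimators key on
— plateaus and steps, Gaussian flashes and puncta, logistic binding
transitions, linear calibrations with lane-loading variation,
exponential-to-plateau quenching — under additive Gaussian noise (with
a Poisson option for the movie generator). They deliberately omit
photobleaching, blinking, 3-D point-spread functions, detector-specific
noise, cell-to-cell variability and motion. Passing recovery tests
therefore demonstrates the correctness of the estimators under their
stated model, not their robustness to every artifact of real
microscopy; parameters tuned here (detector thresholds in particular)
should be re-examined on real data.

Problem sizes were chosen so the full suite runs in well under a
minute of compute per module: 64 x 64 x 60 movies with 12 events,
128 x 128 cell images with 20 vesicles, 140-residue tables, 5 + 2 lane
blots, and 20-50 seed Monte Carlo loops; all are generator parameters
and scale up freely.

## Known limitations

Coordinates are 0-based (row, col) pixels with distances in nm;
off-by-one conventions are pinned by the geometric oracle tests. The
shell erosion rounds the shell width to whole pixels, so sub-pixel
shell widths are not represented. The MOC is the unthresholded
coefficient; Costes thresholding and the M1/M2 split coefficients are
out of scope. The TIFF I/O stores 16-bit integer samples and carries
acquisition metadata in a text sidecar, since the available TIFF
writer does not round-trip description tags. The detector assumes
flashes are abrupt; gradual intensity ramps would be suppressed by the
onset test.
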
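# asynquant

Quantification pipeline for the cellular effects of alpha-synuclein
(a-syn), the presynaptic protein central to Parkinson's disease. The
package implements, as tested reusable R functions, the measurements used
to characterize how a-syn expression level modulates vesicle trafficking
in a mast-cell model: stimulated exocytosis of recycling endosomes read
out by pHluorin dequenching, single-event TIRF flash counting, spatial
redistribution of vesicles toward the plasma membrane, colocalization
with mitochondria, residue-resolved membrane binding by solution NMR,
stimulated endocytosis by fluorescence quenching, and absolute
intracellular a-syn concentration from calibrated western-blot
densitometry. A seeded synthetic-data module generates every input class
with known ground truth, so the full chain runs and is validated without
any raw microscopy data.

It is aimed at cell biologists and biophysicists who need these
quantifications as scriptable, testable building blocks rather than
interactive ImageJ workflows.

## The statistics at the core

- **Percent exocytosis** from a pHluorin trace with basal, stimulated and
  NH4Cl epochs:

  `% Exo = 100 * (F_stim - F_basal) / (F_NH4Cl - F_basal)`

  where each term is a window mean; NH4Cl neutralizes all compartments
  and reveals the total dequenchable pool (the denominator).
- **TIRF event detection**: exocytic fusions appear as abrupt Gaussian
  flashes; events are strict spatiotemporal local maxima of the
  rolling-median-subtracted, Gaussian-smoothed stack above a robust
  (MAD-based) threshold, deduplicated within an exclusion radius.
- **Membrane-proximal fraction**: an ~800 nm shell is obtained by
  Euclidean erosion of the cell mask; the shell-summed marker intensity
  over the mask-summed intensity is the % membrane-proximal vesicles.
- **Manders overlap coefficient** between channels R and G:

  `MOC = sum(R_i * G_i) / sqrt(sum(R_i^2) * sum(G_i^2))`

- **Amide chemical shift deviation** between two protein states:

  `dd_avg = sqrt(0.5 * (dd_HN^2 + dd_N^2 / 25))`

  plus secondary carbon shifts (observed minus random coil; positive CA
  means helix), carbon re-referencing against a reference spectrum over
  residues 111-130, and lipid/free peak-intensity-ratio profiles whose
  logistic transition midpoint locates the membrane-release boundary.
- **Absolute quantification**: loading-normalized band densities are
  interpolated on a linear calibration (standards at 2, 3.5, 5, 6.5,
  8 ug/ml), divided by cell equivalents per lane, and converted to uM
  via the mean cell volume (2627 um^3) and the sequence-derived
  molecular weight of a-syn (UniProt P37840, packaged).
- **Relative endocytosis**: fluorescence-quench curves normalized to a
  unit pre-stimulation baseline; the endpoint quench fraction of a test
  sample as a percentage of its paired control.

## Worked example

```r
library(asynquant)

# a noisy synthetic pHluorin trace with a known 25% stimulated rise
g <- genExoTrace(stimRiseFraction = 0.25, cfg = genConfig(seed = 1, noiseSd = 4))
percentExocytosis(g$trace)
#> ExoResult: 25.03% exocytosis (basal 101, stim 150, NH4Cl 299)

# vesicle image with 40% of fluorescence in the 800 nm membrane shell
gs <- genCellImage(trueShellFraction = 0.40, cfg = genConfig(seed = 1))
membraneProximalFraction(gs$image)
#> ShellResult: fraction 0.3971 (shell 800 nm, 2472/9264 px)

# the measured low-expression level, 130 ug/ml, in molar units
cellularConcentration(130e-6 * 2627)$uM
#> [1] 8.99  # reported as 9 uM at integer rounding

# V70P-like membrane-release boundary from an intensity-ratio profile
b <- genBindingProfile(boundaryResidue = 70, cfg = genConfig(1, noiseSd = 0.05))
fitBindingBoundary(intensityRatioProfile(b$lipid, b$free))$midpoint
#> [1] 69.9
```

The first number is the stimulated rise recovered from the trace (the
injected truth is 25%), the second is the recovered membrane-proximal
fraction (truth 0.40), the third converts a mass concentration to
molarity with the sequence-derived 14,460 Da mass, and the fourth
recovers the residue at which a proline mutant releases from the vesicle
surface.

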
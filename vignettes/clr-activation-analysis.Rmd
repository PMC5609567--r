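---
title: "Pharmacology and activation-transition analysis of CLR-RAMP receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacology and activation-transition analysis of CLR-RAMP receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampkit)
```

## The system and the two analyses

The calcitonin receptor-like receptor (CLR) is a class B GPCR that only
reaches the cell surface and signals when paired with a receptor
activity-modifying protein: CLR/RAMP1 is the CGRP receptor, CLR/RAMP2 and
CLR/RAMP3 are the adrenomedullin (AM) receptors. Alanine scanning of the
transmembrane bundle, read out as cAMP production, is the standard way to
map which residues drive Gs-linked activation — but raw potency shifts are
confounded by differences in cell-surface expression and by efficacy
changes, so the field summarises each mutant with a single
expression-corrected statistic, and interprets it against a structural
model of the inactive-to-active transition.

rampkit implements both halves of that workflow on synthetic and tabulated
data:

1. **Pharmacology** — concentration-response fitting, the
   expression-corrected difference in log relative activity
   $\Delta\log(RA)$ with full error propagation, ELISA expression
   normalisation and competition-binding span ratios, plus a simulator
   with known ground truth.
2. **Transition modelling** — positional-fluctuation PCA of Cα ensembles,
   fixed-increment essential-dynamics (ED) driving of the transition on a
   toy elastic network, and the trajectory metrics used to interpret
   mutants: interhelical distances, persistent contacts,
   contact-rearrangement tables, helix bend angles and representative
   frames. A parameterised seven-helix bundle generator supplies ground
   truth.

## The relative-activity statistic

Each concentration-response experiment is fitted with a three-parameter
logistic (Hill slope fixed at 1):

$$y = \mathrm{basal} + \frac{E_{max} - \mathrm{basal}}
      {1 + 10^{-(x + pEC_{50})}}, \qquad x = \log_{10}[\mathrm{agonist}]$$

`fitLogistic()` solves this by exact profiled least squares: at fixed
$pEC_{50}$ the model is linear in (basal, $E_{max}$) and is solved
directly; the residual sum of squares is then minimised over
$pEC_{50} \in [4, 14]$ (a coarse grid plus golden-section refinement).
This is equivalent to a general nonlinear optimiser (the test suite
cross-checks against one) but has no convergence failures and is fast
enough for Monte-Carlo calibration. Degenerate inputs — flat responses, a
midpoint outside the concentration window — return `converged = FALSE`
rather than an error, and a converged fit whose span is below three
residual standard deviations is flagged `noCurve` ("N.C.") and excluded
from downstream comparisons, mirroring responses too weak to fit.

Per receptor the log relative activity is
$\log RA = \log_{10}(E_{max}) + pEC_{50}$, with $E_{max}$ in nM and EC50
in M. Only *differences* of $\log RA$ are ever reported, so the unit
constant cancels (a property asserted in the tests). The mutant value is
corrected for cell-surface expression, and

$$\Delta\log RA = \log RA_{WT} - \left(\log RA_{mut} -
   \log_{10} f_{expr}\right)$$

where $f_{expr}$ is the mutant's expression as a fraction of wild type.
**Sign convention:** positive values mean an impaired mutant; a
gain-of-function combination (e.g. a mutant that turns a weak AM response
into a potent one) is negative. $E_{max}$ enters as the fitted upper
asymptote, not the span above basal — basal is reported separately and
not subtracted.

Errors from curve fitting and expression are propagated in quadrature,
with the $E_{max}$ and expression terms converted to the log scale by the
delta method:

$$SE_\Delta^2 = SE_{p,WT}^2 + SE_{p,mut}^2
  + \left(\frac{SE_{E,WT}}{E_{WT}\ln 10}\right)^2
  + \left(\frac{SE_{E,mut}}{E_{mut}\ln 10}\right)^2
  + \left(\frac{SE_f / f}{\ln 10}\right)^2$$

The 95% CI is $\Delta \pm 1.96\,SE_\Delta$ by default and a mutant is
called significant when the CI excludes zero.

```{r}
d <- deltaLogRAFromSummary(10.08, 31.16, 7.60, 19.35, 95.5,
                           wtPec50SE = 0.06, wtEmaxSE = 8.65,
                           mutPec50SE = 0.12, mutEmaxSE = 5.94,
                           expressionSE = 4.42)
d
```

### Two computation modes, and the choices behind them

`deltaLogRAFromSummary()` operates on printed summary statistics (means
and SEMs) — the form in which alanine-scan tables are published, and the
mode used to reproduce tabulated values. `deltaLogRAFromFits()` pairs
wild-type and mutant fits experiment by experiment (the paired plate
design), averages the per-experiment deltas and reports their
across-experiment SEM; the propagated SE is carried alongside on the same
object. The two modes can differ by Jensen-type effects but agree to a
few percent at assay-like noise (tested). Published tables are ambiguous
about whether the printed ± column is the propagated SE or the
across-experiment SEM; the object exposes both (`sePropagated`,
`seAcross`) so either convention can be read off. Expression correction
uses the pooled ELISA percentage; a per-experiment correction is not
supported because expression and cAMP experiments are generally not
paired.

When all five SE components are themselves SEMs over a handful of
experiments, the fixed 1.96 multiplier undercovers. For that case
`deltaLogRAFromSummary(componentDf = ...)` switches to a t multiplier at
the Welch-Satterthwaite effective degrees of freedom of the combined
variance; the simulation pipeline (`analysePharmDataset()`) uses this
calibrated interval, and the Monte-Carlo tests verify 92-98% coverage and
a 3-8% false-positive rate under the null.

### ELISA and binding normalisations

`normalizeElisa()` forms the per-well ratio $(A_{490} - A_{650})/A_{595}$
(peroxidase signal over cell density), subtracts the per-experiment mean
background (vector-only wells) from the wild-type and mutant means, and
expresses the mutant as a percentage of the same experiment's wild type —
transient transfection varies day to day, so only within-experiment
percentages are comparable. Negative corrected signals are allowed and
flagged. `relativeBinding()` fits one-site competition curves to the
wild-type and mutant displacement data and reports the mutant span
(top − bottom, proportional to specific binding) as a percentage of the
wild-type span with a ratio-delta-method 95% CI; with the radioligand
below its $K_d$, a loss of specific binding is a more sensitive readout
of affinity change than a pIC50 shift.

## The synthetic pharmacology generator

`pharmTruth()` fixes the study conditions the simulator emulates:
triplicate wells over eight log-spaced concentrations from 1 pM to 1 µM,
five independent experiments, wild-type pEC50 near 10 with Emax near
32 nM (typical of the CGRP receptor), expression near 100% of WT.
Noise is multiplicative lognormal on responses (σ = 0.15, mean-one, so
variability grows with signal as SEM patterns in such assays show),
Gaussian on ELISA ratios (σ = 0.04 on a corrected-ratio scale of ~0.4),
and each experiment's true pEC50 is jittered by a Gaussian of σ = 0.1 log
units to emulate day-to-day transfection variation. Binding curves get
triplicate wells and Gaussian counting noise at 5% of the wild-type span.
These defaults were chosen once to make the simulated SEMs match the
magnitudes seen in published alanine-scan tables (pEC50 SEM ≈ 0.05-0.2,
Emax SEM ≈ 20-30%); they are not adjusted per analysis.

What the generator does *not* emulate: plate-edge and carryover effects,
correlated well noise, cAMP standard-curve interpolation error, receptor
reserve/amplification differences between RAMP partners, and radioligand
counting statistics beyond Gaussian noise. Passing recovery tests
therefore demonstrate that the estimator and its intervals are correct
under a well-specified noise model, not that real plates are this tame.

`recoveryReport()` wraps the simulate-analyse loop and reports bias,
RMSE, CI coverage and significance rate against the plug-in truth
`trueDeltaLogRA()`.

## The conformational-transition toolkit

### Superposition and the essential subspace

`superpose()` is a standard SVD (Kabsch) least-squares superposition with
the reflection corrected to a proper rotation. `essentialSubspace()`
aligns every frame onto the iteratively converged ensemble mean (mean
shift < 1e-6 Å), forms the covariance of Cα coordinates about the mean
(divisor $n_{frames}$, non-mass-weighted) and diagonalises it. The PCA is
Cα-only: atom selection for positional-fluctuation covariance is a free
choice, and Cα keeps toy systems tractable while capturing the collective
motion. For a concatenated ensemble of two distinct conformations the
covariance has rank one — a single eigenvector with a non-zero eigenvalue
(threshold: 1e-8 of the largest) — and that eigenvector is the
inactive→active reaction coordinate. The sign of PC1 is fixed so that
frames labelled "active" project positively; with no labels, the first
component of magnitude above 1e-12 is made positive.

### Essential-dynamics driving on a toy engine

`edDrive()` implements fixed-increment ED biased sampling: at each step
an overdamped Langevin update
($x \leftarrow x - \frac{dt}{\gamma}\nabla U + \sqrt{2 k_B T\, dt/\gamma}\,\eta$)
is applied, then the projection of the coordinates onto the driving
eigenvector is reset to `start + step × increment` by a correction along
the eigenvector only. The projection series is therefore exactly affine
in the step index, and reverse driving (negative increment) retraces the
coordinate. A stiff harmonic restraint on the projection is available as
an alternative constraint (`constraint = "restraint"`). Increments are in
Å per step; nm inputs are converted (1 nm = 10 Å). `edDriveReplicates()`
runs the drive several times (default 10) from consecutive seeds and
`combineBestScore()` assembles a consensus trajectory by taking, at every
time step, the replicate frame with the best (lowest) score — ties to the
lowest replicate index; the default scorer is the toy potential energy
via `energyScorer()`.

The engine underneath is deliberately simple: `buildToyPotential()` is a
distance-based elastic network (harmonic springs on all Cα pairs within a
cutoff, rotation- and translation-invariant, zero energy at its
reference). It exists to exercise the ED constraint algorithm at toy
scale, not to model a force field. When both endpoint structures are
supplied, the network keeps only the conserved scaffold — pairs whose
distance changes by less than 0.5 Å between the endpoints, with rest
lengths at the mean — so both endpoints are near-minima and the
transition mode is soft, emulating a two-state system. Engine defaults
(dt = 0.01, γ = 1, k = 0.02 energy/Å², kT = 0.002) keep the integrator
stable and thermal blur small against the ~1.6 Å endpoint separation of
the default fixture; with these settings a 2000-step drive ends within
25% of the initial inactive→active RMSD of the target endpoint across
seeds.

### Trajectory metrics

* `distanceSeries()` — per-frame Cα-Cα distance for a residue pair, the
  generic form of TM2-TM3 (V190-I218) and TM1-TM7 (G148-H374) monitors.
* `persistentContacts()` — residue pairs within 5 Å in strictly more than
  80% of frames in *every* supplied simulation (both thresholds
  configurable; "more than" is read as a strict inequality, and the
  all-simulations rule is applied per simulation, not on pooled frames).
  Pairs within two sequence positions are excluded as trivial backbone
  contacts. Contacts are Cα-Cα for determinism at toy scale.
* `rearrangementTable()` — persistent contacts classified as
  Inactive-only, Active-only or Shared, ordered by helix then residue:
  the table of residue rearrangements upon activation.
* `helixBendAngle()` — least-squares axes fitted to the two halves of a
  helix about a split residue; the angle between them per frame, reported
  as mean ± SD and maximum (the convention for TM6 bending estimates such
  as 43° ± 9°, max 75°). Helix boundaries come from the annotation table,
  never recomputed.
* `representativeFrame()` — the frame with the lowest RMSD to the
  iteratively aligned ensemble mean (1-based; ties to the lowest index),
  the standard choice of a display structure.

### The toy bundle

`buildBundle()` generates an idealised seven-helix Cα bundle: ideal
helices (rise 1.5 Å/residue, radius 2.3 Å, 100°/residue twist), 36
residues each, axes on a 9 Å circle. Each helix spans ten exact turns, so
each 18-residue half spans five — eliminating axis-fit truncation bias in
bend-angle tests. Residue numbering follows CLR-like ranges so that the
residues named in the wet-lab analysis (V190, I218, Y227, N305, L345,
H374, ...) fall on their native helices and carry their class-B labels
(e.g. 345/6.49b); outputs therefore read like the published tables. The
fixture is Cα-only and membrane-free: it encodes only the geometry the
analyses need (packing, pivot, kink), not the receptor's actual fold.

`applyActivationPivot()` rotates TM5 and TM6 rigidly about the TM3 axis,
in the direction that separates TM6 from TM7 and brings TM5 toward TM4 —
the sense that opens the cytoplasmic G-protein face — and optionally
kinks the cytoplasmic half of TM6 outward about the hinge residue. The
ground-truth broken/formed contact lists are recorded by direct distance
counting on the two noiseless structures, giving the oracle that
`rearrangementTable()` must reproduce exactly.

```{r}
inactive <- buildBundle()
act <- applyActivationPivot(inactive, pivotAngle = 15, kinkAngle = 43)
head(rearrangementTable(inactive, act$structure)[, c(1, 2, 7)])
helixBendAngle(act$structure, "TM6", 336)$mean
```

## Numerical choices and degenerate inputs

* Logarithms are base 10 throughout, following the pEC50/pIC50
  convention.
* pEC50 search bounds [4, 14]; a fit pinned at a bound is reported
  unconverged (midpoint outside the measurable window).
* Logistic fits are unweighted least squares; SEs come from the
  Gauss-Newton covariance at the optimum.
* PCA eigenvalue "non-zero" threshold: 1e-8 of the largest eigenvalue;
  iterative-mean alignment tolerance 1e-6 Å.
* ED projection constraint is exact to floating-point precision; frame
  recording stride is configurable (initial frame always kept).
* Coordinates are Å, right-handed; residue numbers are 1-based primary
  sequence; class-B labels are carried as opaque strings, never parsed.
* Ties: best-score combination and representative-frame selection break
  ties toward the lowest index (R is 1-based, so "the first frame" is
  index 1).

## Problem sizes used by the test suite

The shipped tests run the Monte-Carlo calibrations at 1000 repeats for CI
coverage and null false-positive rate, 500 repeats for binding-ratio
coverage and logistic recovery, 10,000 frames for the RMSF closed-form
check, and 2000-step ED drives at three seeds on the 252-atom bundle.
These sizes give rate estimates with Monte-Carlo SE well inside the
asserted bands while keeping the suite to a few minutes on one core.

## Known limitations

* The elastic-network engine has no excluded volume, membrane or
  side-chain degrees of freedom; ED results on it validate the algorithm,
  not receptor energetics.
* Contact analysis is Cα-based; side-chain-centroid contacts would need
  full coordinates, which the toy bundle does not carry.
* The operational model of agonism (τ/K_A) is out of scope; relative
  activity is the Emax/EC50 form only.
* Structure I/O covers Cα-only multi-MODEL PDB and a plain XYZ dialect;
  mmCIF and binary trajectory formats are not supported.
* Hypothesis-test machinery beyond the CI-excludes-zero rule (ANOVA,
  multiple-comparison corrections) is deliberately left to standard
  tools.
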
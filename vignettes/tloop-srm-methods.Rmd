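---
title: "Methods: designing and quantifying T-loop phosphorylation SRM assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and quantifying T-loop phosphorylation SRM assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tloopr)
library(dplyr)
```

## The measurement problem

Most protein kinases are switched on by phosphorylation of their
activation loop (T-loop), the segment of the kinase domain running from
the DFG motif to the APE motif. Measuring T-loop phosphorylation therefore
reads out kinase *activation* directly, rather than inferring it from
substrate phosphorylation or protein abundance. Because T-loop
phosphopeptides are low-abundance and often poorly behaved in shotgun
proteomics, the practical readout is selected reaction monitoring (SRM) on
a triple quadrupole: predefined precursor/fragment ion pairs (transitions)
are monitored for the endogenous ("light") peptide and a spiked
heavy-isotope-labelled synthetic standard, and the analyte/standard area
ratio is the quantity carried into statistics.

`tloopr` implements the computational side of this workflow end to end:
target design from kinase sequences, transition-list construction and
scheduling, chromatographic peak quantification with acceptance rules,
detection-limit calibration, kinase-group inference for shared peptides,
and condition comparison — plus synthetic-data generators so that every
step can be exercised and validated without instrument data.

## Target design

`design_targets()` proceeds in three steps.

**Activation-segment location.** The activation segment is taken as the
interval from the first residue of the DFG motif to the last residue of
the APE motif, requiring 15–40 intervening residues (both motifs and the
bounds are configurable; relaxed patterns `D[FWL]G` / `AP[ED]` are tried
when the exact motifs fail). This DFG..APE convention is the standard
operational definition of the kinase activation segment; when curated
segment coordinates are available they can be supplied as a sidecar
annotation table and are used unchanged. Scanning is left-to-right, and
for a given DFG the nearest in-bounds APE is chosen, which makes the
location deterministic and position-equivariant. Sequences without a
valid motif pair are skipped with a log entry, never an error.

**Digestion and accessibility.** Proteins are digested in silico with
trypsin (cleavage after K/R, suppressed before proline) and optionally
Lys-C (after K regardless), with up to 2 missed cleavages by default.
A T-loop peptide is considered *accessible* when it covers at least one
S/T/Y of the activation segment and is 6–30 residues long — the range in
which tryptic peptides are routinely measurable by SRM. Both bounds are
parameters; neither is claimed to be a biochemical constant.

**Phosphoform enumeration.** Every S/T/Y inside the segment is a candidate
site. One target is emitted per distinct (peptide backbone, phosphosite
set); singly and doubly phosphorylated forms are generated by default
because several kinase T-loops carry two sites on one tryptic peptide.
Identical backbones arising from different kinases are merged, pooling
their kinase identifiers — this conservation-driven ambiguity is what
later forces kinase grouping. Peptides lacking a C-terminal K/R (protein
C-terminus) are retained in the target table but flagged, since the heavy
label sits on the C-terminal K/R.

## Transition lists, collision energy and scheduling

Masses are monoisotopic throughout (proton 1.007276, water 18.010565,
phosphate +79.966331, phosphoric-acid neutral loss 97.976896). The heavy
internal standard is modelled as the SILAC-style C-terminal label
(+8.014199 on K, +10.008269 on R), so heavy shifts apply to precursors and
y ions only.

Candidate transitions are all theoretical y/b ions of index ≥ 2, plus
neutral-loss variants for fragments retaining a phosphate, with 2+
products allowed for fragments of ≥ 6 residues. Without a spectral
library, ions are ranked y before b and longer before shorter — the
pattern that dominates tryptic CID spectra; a library table of relative
intensities overrides this ranking when supplied. The two acquisition
modes mirror SRM practice:

* **survey** — 3 transitions per precursor, 4 min scheduling windows,
  4 s cycle time: broad screening of the whole target list in one run;
* **quantification** — up to 7 transitions per precursor with all
  applicable *site-determining ions* force-included, 6–10 min windows,
  2.5–3 s cycles: accurate quantification with phosphosite localization.

A site-determining ion is a fragment whose residue span contains some but
not all candidate phosphosites, so its mass differs between positional
isomers; `site_determining_ions()` enumerates them exhaustively.

Collision energy follows the charge-dependent instrument ramp
`CE = 0.03 m/z + 2.905` (2+) and `CE = 0.038 m/z + 2.281` (3+ and
higher), with an additive per-transition offset available for empirical
optimisation.

`schedule_method()` maps expected retention times (optionally through an
iRT-style linear calibration from `calibrate_rt()`) to windows and checks
feasibility: transition concurrency is evaluated at all window endpoints
(the count is piecewise constant between them, so this is exact), dwell
time is the cycle time divided by the worst-case concurrency, and the
method is feasible when dwell stays above a 10 ms floor. Infeasibility is
a reported state, not an exception, because the remedy (narrower windows,
fewer targets, longer cycles) is an experimental decision.

## Peak quantification and acceptance

Chromatograms enter as tidy tables (peptide, channel, ion, time,
intensity). For each peptide the heavy standard channel — which is always
present — fixes the peak: the apex is the maximum of the transition-summed
trace in the search window and the boundaries are the nearest flanking
local minima, or the points where the trace falls below 1% of the apex,
whichever comes first. Apex and boundary detection run on a lightly
smoothed trace (9-point moving average) with a noise tolerance estimated
from the raw-minus-smoothed residuals, so baseline noise does not truncate
peaks at spurious micro-minima; integration itself is trapezoidal on the
raw trace with a linear baseline through the boundary points. The light
channel is integrated on the standard's boundaries (shared peak model),
with its own apex located independently for the co-elution check.

A light signal is **accepted** when three conditions hold: the
light/heavy transition patterns agree (normalized dot product
`rdotp > 0.9`), the apexes co-elute (|ΔRT| ≤ 0.2 min by default — a
quantitative stand-in for what an analyst judges visually), and the light
summed area exceeds the local noise floor (median summed intensity
outside the boundaries times the peak width). Failing signals are
**rejected** — except when the same peptide is cleanly accepted in another
condition of the experiment and absent here, which is an **on/off**
state: the noise area is then reported as a censored quantitative
readout, so a complete activation switch is not discarded as missing
data. "Absent" is operationalised as a light area at or below the noise
floor, since with additive noise a literally zero area never occurs.
Accepted peptides report the light/heavy area ratio; integration is
linear, so the ratio is invariant to common intensity scaling.

## Calibration: LOD and LOQ

For a dilution series of spiked standard amounts, the sensitivity *b* is
the slope of the ordinary least-squares fit pooled over replicates, and
*S~a~* — the standard deviation of the intercept — is estimated from the
spread of the per-replicate regression intercepts. Detection limits
follow

$$\mathrm{LOD} = \frac{3\,S_a}{b}, \qquad \mathrm{LOQ} = \frac{10\,S_a}{b},$$

so LOQ/LOD = 10/3 identically. Two estimator choices are worth making
explicit:

* With triplicate regressions the sample SD of three intercepts
  underestimates the intercept σ by the normal-consistency factor
  c₄(3) ≈ 0.886 (about 11%). The default therefore divides by c₄(n),
  giving an unbiased estimate; `sa_correct = FALSE` restores the raw SD
  and `sa_method = "fit_se"` selects the alternative reading of *S~a~*
  as the pooled fit's intercept standard error.
* Responses below the detection limit sit on the noise floor and would
  flatten the regression, so sub-LOD levels are excluded iteratively:
  all but the highest level below the current LOD are dropped, the model
  is refit, and the loop stops when the excluded set is stable (bounded
  by the number of levels). The highest sub-LOD level is deliberately
  retained to anchor the low end of the curve.

The default simulated design matches the calibration experiment the
package targets: seven levels from 10 amol to 100 fmol in triplicate.

```{r calibration-example}
series <- simulate_dilution_series(
  b_true = 2, intercept_sd = 0.5, noise_sd = 0.05, seed = 11
)
fit <- fit_calibration(series)
glance(fit)
```

## Normalization and differential testing

Ratios are normalized per peptide to the mean of a reference (control)
condition, making the control mean 1; the operation is idempotent and
peptides without a usable reference value are flagged rather than
silently dropped. `differential_test()` log2-transforms ratios, averages
technical replicates within each biological replicate, and fits a
fixed-effect condition model per peptide on the biological-replicate
means, contrasting each condition against the reference. For two
conditions this is exactly the pooled-variance two-sample t-test. For
balanced designs with technical replicates averaged first, this
fixed-effect reduction coincides with the mixed-model treatment of
technical replicates as repeated measures, while remaining deterministic
and dependency-light; repeated-measures modelling beyond this is out of
scope. Significance is called at p ≤ 0.05 by default — deliberately an
unadjusted screening cutoff — with optional Benjamini–Hochberg adjustment.
Conditions with a single biological replicate report a fold change but no
p-value.

## What the synthetic generators emulate — and what they do not

The generators exist so that every module has inputs with known ground
truth:

* `generate_kinome()` embeds one DFG..APE segment per protein with a
  designed tryptic target peptide (C-terminal K preceded by an R cleavage
  point) carrying 1–3 S/T/Y sites. Loop residues outside the designed
  peptide avoid S/T/Y (so the truth enumerates sites exactly), proline
  (so cleavage is never suppressed) and aspartate (so no spurious DFG
  arises); chance DFG occurrences elsewhere are mutated away. Subsets of
  kinases can share identical segments to create known kinase groups.
* `simulate_chromatograms()` produces Gaussian peaks (SD 3–8 s) on a
  shared grid, per-transition amplitudes decaying geometrically with
  rank, light = heavy × true ratio, and additive Gaussian baseline noise;
  ratio 0 encodes an off state.
* `simulate_dilution_series()` draws one intercept per replicate plus
  per-point noise around a true line, with optional noise-floor
  substitution for sub-floor responses.

All generators are seed-deterministic and attach their truth as an
attribute. They emulate the *structure* of the real data, not its full
physics: no chromatographic tailing or drift, no interference peptides
unless constructed, no intensity-dependent (Poisson-like) noise by
default, uniform amino-acid composition, and no retention-time
prediction. Passing closed-loop tests therefore demonstrates that the
algorithms are correct and internally consistent under the stated model —
not that real instrument data will behave this benignly.

## Numerical choices and problem sizes

Declared defaults, all configurable: loop bounds 15–40 residues; peptide
length 6–30; missed cleavages 2; multiplicities {1, 2}; minimum fragment
index 2; 2+ products from 6 residues; 3+ precursors for backbones longer
than 14 residues or with internal H/K/R; rdotp threshold 0.9 (strict
inequality); RT tolerance 0.2 min; 1%-of-apex boundary fraction; dwell
floor 10 ms. Note that the 1% boundary rule plus linear baseline
subtraction trims about 2.7% of an ideal Gaussian's analytic area; this
cancels in light/heavy ratios, which is what the pipeline quantifies.
Zero-variance inputs (degenerate dilution amounts, identical RT
references) raise errors; non-positive calibration slopes flag the fit
invalid rather than producing negative limits; a zero transition-pattern
vector defines rdotp = 0.

The validation suites use problem sizes chosen to give stable Monte-Carlo
estimates at interactive runtimes: 500 simulated dilution series for
slope/LOD recovery, 1000 null simulations for test size, 200 for power,
1000 random peptides/sequences for the mass and digestion identities, and
a 8-kinase closed-loop pipeline.

## Known limitations

Kinase-group identity is the exact kinase set of a peptide; overlapping
but unequal sets are kept distinct rather than collapsed by parsimony,
matching how ambiguity classes such as EphA3-4-5 or HCK-Lyn are reported.
Spectral-library construction from discovery data, vendor raw-file
decoding, retention-time prediction and full REML mixed models are out of
scope. The homology step that defines which kinases carry annotatable
T-loops is reduced to the motif convention above; for diverged kinases an
external segment annotation is the supported route.
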
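# tloopr

Kinome-wide kinase-activation profiling by targeted mass spectrometry:
design, schedule and quantify SRM assays for activation-loop (T-loop)
phosphorylation.

## The problem

Phosphorylation of the activation loop — the kinase-domain segment
between the DFG and APE motifs — switches most protein kinases into
their active state, so measuring T-loop phosphosites reads out kinase
*activation* directly instead of inferring it from substrates or
expression. These phosphopeptides are low-abundance and awkward in
shotgun proteomics; the practical assay is selected reaction monitoring
(SRM) on a triple quadrupole, monitoring a few precursor→fragment
transitions per peptide against a spiked heavy-isotope-labelled internal
standard and reading out the light/heavy area ratio.

`tloopr` is the computational backbone of that workflow, for proteomics
scientists building or validating such assays:

* **Target design** — locate DFG..APE activation segments in kinase
  sequences, digest in silico (trypsin/Lys-C, missed cleavages), and emit
  the accessible T-loop phosphopeptide list, merging peptides conserved
  across kinases.
* **Assay building** — monoisotopic precursor/fragment m/z for light and
  heavy channels (phospho +79.966331; neutral loss −97.976896;
  C-terminal K/R labels +8.014199/+10.008269), site-determining ions for
  phosphosite localization, collision energies
  (CE = 0.03 m/z + 2.905 for 2+, CE = 0.038 m/z + 2.281 for ≥3+), survey
  mode (3 transitions/precursor) and quantification mode (≤7 including
  site-determining ions).
* **Scheduling** — RT windows via an iRT-style linear calibration, with
  an exact concurrency sweep giving worst-case dwell time against a
  10 ms floor.
* **Quantification** — peak integration on the internal-standard
  boundaries, light/heavy pattern similarity (rdotp > 0.9), co-elution
  and noise-floor checks, and on/off noise substitution for clean
  activation switches.
* **Calibration & statistics** — dilution-series fits with
  LOD = 3·S<sub>a</sub>/b and LOQ = 10·S<sub>a</sub>/b, iterative
  sub-LOD exclusion, control normalization, and per-peptide differential
  testing of log2 ratios (p ≤ 0.05).
* **Kinase grouping** — shared T-loop peptides resolved into kinase
  groups by the protein-grouping principle (e.g. an `EPHA3-EPHA4-EPHA5`
  group from one shared peptide).
* **Synthetic data** — seed-deterministic generators for kinomes,
  chromatograms and dilution series with attached ground truth, so the
  whole pipeline is testable offline.

All user-facing functions take data frames and return tibbles, so steps
chain with the pipe; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

A six-kinase synthetic kinome in which two kinases share an identical
activation segment, carried through design → assays → simulated
chromatograms → quantification:

```r
library(tloopr)
library(dplyr)

kinome  <- generate_kinome(6, seed = 42, shared_groups = c(2))
targets <- design_targets(kinome, max_missed = 0, multiplicities = 1)
select(targets, backbone, phospho_positions, kinase_ids, site_labels)
#> # A tibble: 9 × 4
#>   backbone     phospho_positions kinase_ids      site_labels
#> 1 GQATHQNSK    4                 SYNK003         SYNK3_T462
#> 2 GQATHQNSK    8                 SYNK003         SYNK3_S466
#> 3 HTSHIYFK     2                 SYNK006         SYNK6_T105
#> ...
#> 6 MCASGQNK     4                 SYNK001;SYNK002 SYNK1_S32;SYNK2_S60
```

Nine single-site targets; the `MCASGQNK` row is shared by the two
kinases with the common segment — it can only ever report the group.
Build quantification-mode transitions and simulate one condition at a
true light/heavy ratio of 2.5:

```r
assays <- build_assays(targets, mode = "quantification")
peps   <- unique(paste0(assays$backbone, "[", assays$phospho_positions, "]"))
chrom  <- simulate_chromatograms(
  assays, tibble(peptide = peps, condition = "stim", ratio = 2.5),
  seed = 7, noise_sd = 100
)
rt    <- distinct(attr(chrom, "truth"), peptide, expected_rt = rt)
quant <- quantify_peptides(chrom, expected_rt = rt)
select(quant, peptide, rdotp, status, ratio)
#> # A tibble: 9 × 4
#>   peptide          rdotp status   ratio
#> 1 GQATHQNSK[4]     1.000 accepted  2.49
#> 2 GQATHQNSK[8]     1.000 accepted  2.50
#> 3 HTSHIYFK[2]      1.000 accepted  2.50
#> ...
```

Every peptide passes the rdotp/co-elution/noise acceptance rule and the
recovered ratios sit within 1% of the true 2.5. A dilution-series
calibration at the 7-level triplicate design:

```r
fit_calibration(simulate_dilution_series(2, 0.5, 0.05, seed = 11))
#> Calibration fit: b = 2, S_a = 0.4386
#>   LOD = 0.658 fmol, LOQ = 2.193 fmol (7 levels, 3 replicates; excluded: 0.01)
```

The slope is recovered exactly, LOQ/LOD = 10/3 by construction, and the
lowest spike-in (10 amol) is excluded as sub-LOD — all but the highest
below-LOD level are dropped from the fit. Finally, kinase grouping:

```r
m <- build_peptide_kinase_map(targets)
glance(resolve_groups(distinct(targets, backbone, phospho_positions), m))
#> # A tibble: 1 × 3
#>   n_sites n_groups n_kinases
#> 1       9        5         6
```

Nine detected sites collapse to five kinase groups covering all six
kinases: the shared peptide merges its two kinases into one group.

A thin command-line wrapper over the same functions is included at
`inst/cli/tloopr.R` (subcommands `design`, `assay`, `schedule`,
`quantify`, `group`, `calibrate`, `compare`, `simulate`).

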
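---
title: "Quantifying in-vivo lysine solvent accessibility by covalent protein painting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in-vivo lysine solvent accessibility by covalent protein painting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cppaint)
```

## The measurement model

Covalent protein painting (CPP) reads out, per lysine, the fraction of
protein molecules in which that lysine's ε-amine was solvent accessible in
the living cell. Exposed amines are reductively dimethylated in vivo with a
light label (CH₃, +28.0313 Da per amine); after lysis and chymotryptic
digestion, lysines that had been shielded — buried in the fold, or covered by
an interaction — become exposed and are labeled with the heavy isotopologue
(¹³CD₃, +36.0757 Da). Each peptide therefore appears in MS1 as a pair of
precursors spaced by 8.0444 Da per lysine (divided by charge), and the
light share of the pair's integrated areas,

$$x = 100 \cdot \frac{L}{L + H},$$

is the percent solvent accessibility of that lysine in the sampled molecule
population. In a label-swap control the isotope order is reversed and the
numerator inverts: `measurementAccessibility()` implements both
orientations, treats orientation as a property of the whole run, and clips
the result to [0, 100]. Two identities make this estimator convenient and
are enforced by the test suite on randomized inputs: forward and swap
readings of the same pair sum to 100, and scaling both areas by any
positive constant leaves the value unchanged — so absolute ionization
efficiency never matters, only the within-pair ratio.

All label masses are derived from monoisotopic atomic masses rather than
stored as magic numbers (`lightLabelDelta()`, `heavyLabelDelta()`), and the
derived values agree with the conventional constants 28.0313 / 36.0757 /
8.0444 to four decimals. Peptide masses come from a standard residue-mass
table; the tests check them against an independent elemental-composition
summation. For site bookkeeping, `chymotrypticDigest()` applies the
broad-specificity chymotrypsin rule (cleave after F, Y, W, L, M; suppressed
before proline). Because identification in this kind of experiment is done
with open (no-enzyme) search anyway, the digest here serves site-to-peptide
mapping and synthetic-data generation, not identification filtering.

## From measurements to site summaries

One quantified peptide × charge × replicate × condition row is one
measurement. Rows are admitted only if `light + heavy > 0`, then pass the
peak-quality filters of `applyQCFilters()`: determinant factor ≥ 0.5,
profile score ≥ 0.5 (both inclusive), and no retention-time shift. These
are the standard acceptance settings for dimethyl ratio quantification and
are configuration values, not constants; missing QC columns pass with a
warning by default so minimal tables remain usable, with a strict mode
available.

`aggregateSites()` pools all retained measurements of a site × condition
cell with equal weights — each peptide and charge state is an independent
observation of the same lysine — and reports the mean, the standard error
of measurement (sample SD of the pooled values over √n; defined as 0 and
flagged when n = 1), the number of measurements, and the number of distinct
biological replicates. An alternative replicate-means mode is available
behind an argument for sensitivity analysis; the pooled mode is the default
because each plotted point in this kind of experiment is a measurement, not
a replicate mean. `mergeLabelSwap()` joins forward and swap site tables and
calls a site concordant when the two means differ by at most 10 percentage
points (configurable); some swap variation is expected from label-induced
retention shifts and separately prepared samples.

## Cross-condition statistics

`compareConditions()` runs a classical one-way ANOVA per site on
measurement-level accessibilities grouped by condition (equal-variance F on
(k−1, N−k) degrees of freedom; Welch correction is deliberately not
applied, but a group-variance ratio above 4 is noted). Sites with fewer
than two conditions or fewer than two measurements in a group are skipped
with an explicit reason; zero within-group variance with unequal means
yields an infinite F and the smallest representable p, flagged as
degenerate rather than silently significant.

Raw p-values are corrected across all testable sites of a run with either
the Benjamini–Hochberg step-up or the two-stage
Benjamini–Krieger–Yekutieli procedure (`adjustPValues()`). The BKY
implementation runs stage one at α/(1+α) to estimate the number of true
nulls m₀ and reports per-entry q = BH(p) · (1+α) · m₀/m, clipped at 1 —
the sharpened q can legitimately undercut the plain BH q when many sites
are non-null. Both methods are exposed because both are in routine use for
this assay (BKY for the primary wt/ΔF508 comparison, BH for multi-treatment
panels); the BH path is additionally verified against `stats::p.adjust` to
1e−12 and the BKY path against an independently computed reference vector.
Significance tiers default to "****" at q ≤ 1e−4 and "***" at q ≤ 2e−4 —
an unusual pair of cutoffs, kept as configurable values because they are
the reporting convention of this assay. `conditionMatrix()` emits the long
site × condition table for heatmap rendering, flagging missing cells
explicitly instead of imputing.

## Structure mapping

`lysineAmineSasa()` computes the solvent-accessible surface area of a
lysine's ε-amine in a PDB model by Shrake–Rupley sampling: the NZ heavy
atom's sphere is expanded by the probe radius (1.2 Å by default, matching
the rolling-probe convention for this assay), sampled with a deterministic
Fibonacci lattice (960 points by default), and each sample point is tested
against all probe-expanded neighbor atoms. Cryo-EM depositions generally do
not model amine hydrogens, so NZ represents the ε-amino group; resolved HZ
atoms are included when present. Alternate locations resolve to the highest
occupancy (ties by label order), the first chain containing the residue is
used unless one is specified, and a lysine modeled without its amine is
reported "unresolved" rather than 0 Å².

Areas classify as inaccessible (≤ 1.0 Å²), partially accessible
(≤ 7.5 Å²) or accessible. These thresholds were chosen once from the
published per-site isosurface values for the two CFTR cryo-EM structures
(5UAK and the phosphorylated, ATP-bound 6MSM), whose printed areas they
separate cleanly — the largest printed partially-accessible area is
6.92 Å² and the smallest accessible one 8.91 Å²; with them every one of
the 42 printed area/class pairs is reproduced (`cftrReferenceAreas()`).
Exact areas from any sphere-sampling implementation differ from isosurface
areas computed by molecular-graphics software, so the contract of this
module is class-level agreement; numeric areas are reported but not
asserted against published numbers.

`concordance()` compares CPP percentages, binned with the same vocabulary
(accessible ≥ 90%, partially accessible 50–90%, inaccessible < 50%;
configurable — the 90% bound reflects that fully exposed lysines measure
">98%"), against each structure's class. A site whose CPP value is
intermediate while the structure is at an extreme is flagged as
conformational heterogeneity rather than disagreement: the chemistry
averages over the molecule population, the static model shows one
conformer. K273 of CFTR is the canonical case — about 60% accessible by
CPP in wt cells, yet solvent-excluded in every published cryo-EM model.
Sites in regions absent from a model (e.g. the disordered R-region) are
reported unmapped.

## The synthetic-data generator

`generateExperiment()` emulates the data structure behind a CPP experiment
so that every pipeline stage can be verified against known truth. For each
site × condition × replicate × peptide × charge cell it draws a total
precursor intensity T ~ LogNormal(location, scale) and a labeled fraction
f ~ Beta(aκ/100, (1−a/100)κ), then emits light = T·f, heavy = T·(1−f)
(areas exchanged for swap rows). Design choices, made once:

* **Beta noise on the fraction**, not Gaussian noise on the percentage:
  values stay in [0, 100] and variance shrinks toward the boundaries, which
  is how ratio estimates actually behave. The default precision κ = 200
  gives a ≈3.5-point spread at 50% accessibility, matching the visible
  point scatter of replicate-level CPP data; there is no published noise
  model, so κ stays configurable.
* **Log-normal total intensity** (meanlog log(1e6), sdlog 0.8) decouples
  abundance from accessibility and exercises the estimator's scale
  invariance.
* **QC failures injected independently of accessibility** (5% of rows by
  default, one random violated rule each), so filters can be shown to be
  neutral.
* **Paired swap mode** reuses the forward draws with areas exchanged, so
  forward and swap tables are exactly complementary before any re-draw;
  an unpaired mode re-draws both.
* Default design sizes mirror the published experiment: 4 biological
  replicates per condition (2 for the label swap), 2 peptides per site in
  2 charge states, i.e. 16 measurements per site × condition.

`cftrStudyDesign()` instantiates the full study emulation: 26 wt-quantified
lysine sites over eight conditions with the published replicate counts, and
published per-site accessibilities as ground truth (K273 at 61.8/95.0/
0.66/81.5/89 across conditions; K1218 dropping 35 points under VX-809,
representing the reported >30-point reduction). Two R-region sites of the
published count are unnamed in print and are included as synthetic
stand-ins (K698, K710, flagged in the design's `region` field). Sites not
determined in one published condition reuse the paired condition's value.

What passing tests on these data do show: unbiased recovery of site means
within sampling error, correct QC accounting, FDR control, and detection of
effect sizes like K273's at the study's replication level (≥ 90% power in
200 seeded repetitions, typically ≈100%). What they cannot show: behavior
under real chromatographic interference, peptide-specific labeling
efficiency differences, identification error, or replicate batch effects —
none of which the generator models.

## Numerical and degenerate-input conventions

Accessibilities are clipped to [0, 100] after the ratio; truths of exactly
0 or 100 generate point-mass Beta draws rather than NaN. Filter thresholds
are inclusive. SASA is deterministic for a fixed configuration (no random
sphere points); doubling the point count moves areas by well under 2% of an
atom's full expanded sphere. The generator restores the caller's RNG state,
and all workflows require an explicit seed — identical seeds give
byte-identical outputs, recorded with MD5 digests in each run's manifest.
Percentages are written at four decimals in machine outputs; human-readable
reports round to one decimal.

## Problem sizes used in the checks

The bundled verification suite runs entirely on synthetic or closed-form
inputs: 200-repetition Monte-Carlo runs for recovery and power at the K273
effect size, 2000-repetition null/alternative mixtures (m = 100) for FDR
control, 1000 random vectors for the BH oracle comparison, and toy atom
systems (isolated, buried, half-shell, 60-atom clouds) for the SASA engine.
These sizes give Monte-Carlo errors comfortably below the asserted margins
while keeping a full run to well under a minute per module.

## Known limitations

* Site ratios are defined by this package's pooled aggregation; quantification
  software that computes per-site ratios from clustered peptide graphs may
  weight peptides differently.
* The SASA engine targets ε-amine atoms against a static model; it does not
  model conformational ensembles, and area-level agreement with
  isosurface-based tools is out of scope by design.
* Real acquisitions can violate the equal-variance ANOVA assumption; the
  package notes heteroscedasticity but intentionally keeps the classical
  test used for this assay.
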
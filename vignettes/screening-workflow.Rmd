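---
title: "Non-targeted screening by tandem mass spectral library search: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-targeted screening by tandem mass spectral library search: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectraScreen)
```

## The screening problem

Qualitative drug screening in oral fluid (and other biological specimens)
by non-targeted LC-MS/MS records product-ion spectra of whatever elutes and
is abundant enough to trigger fragmentation, then identifies compounds by
searching those spectra against a curated reference library. The acquisition
is data-dependent (DDA): each duty cycle is one survey MS scan followed by
MS/MS of the top-N most intense precursors above an intensity threshold,
with dynamic exclusion of recently fragmented ions. Identification is
therefore limited by three distinct mechanisms — chemistry (compounds
outside the reversed-phase applicability window), acquisition (ions never
selected for MS/MS), and library coverage — and the package models all
three so that each can be validated separately.

`SpectraScreen` implements the whole chain on S4 containers:
`MassSpectrum` (a centroided peak list with precursor m/z, retention time
and collision energy), `MsRun` (a time-ordered acquisition),
`CompoundRecord`/`LibraryEntry`/`SpectralLibrary` (the reference library),
plus `SearchParams` and `DdaParams` for the two parameter blocks.

## The scoring model

For a query spectrum the engine first filters candidates on the precursor:
an entry is a candidate iff its \[M+H\]+ m/z is within the absolute
tolerance (default ±0.01 Th) of the query precursor. Both query and
reference spectra are filtered by a relative intensity cutoff (default 0.01
of the base peak; ties at the boundary are kept, so the base peak always
survives and the operation is idempotent).

The per-spectrum kernel pairs peaks one-to-one, greedily by smallest
absolute m/z difference within the match tolerance (default ±0.01 Th), and
scores

$$ s(Q, R) \;=\; 100 \cdot
   \frac{\sum_{(q,r)\ \mathrm{matched}} \sqrt{I_q I_r}}
        {\sqrt{\big(\sum_q I_q\big)\big(\sum_r I_r\big)}} \in [0, 100], $$

which is symmetric, invariant under uniform intensity scaling of either
spectrum, and (by Cauchy–Schwarz) reaches 100 exactly for spectra identical
up to such a scaling. Greedy nearest-Δm/z matching was chosen because it is
deterministic and directly checkable against an exhaustive one-to-one
assignment oracle; ties are broken by lower query m/z then lower reference
m/z.

Compound-level scores aggregate over the entry's multi-collision-energy
reference set:

* **amp** (average match probability) is the arithmetic mean of the kernel
  over *all* reference spectra of the entry. Averaging over the whole
  breakdown-curve set (rather than taking the best collision energy)
  rewards candidates whose entire fragmentation behaviour matches the
  query. A consequence worth stating explicitly: searching one reference
  spectrum of a multi-CE entry against its own library gives amp < 100,
  because the set average includes the dissimilar far-CE spectra; amp = 100
  self-identification holds exactly for single-spectrum entries.
* **ramp** (relative average match probability) is
  $100 \cdot \mathrm{amp}_i / \sum_j \mathrm{amp}_j$ over the candidate
  set, i.e. how strongly the candidate dominates its precursor-matched
  competitors: 100 for a sole positive candidate, summing to 100 whenever
  any candidate is positive, 0 when all are 0.

A tentative positive identification requires, with strict inequalities,
amp > 5.0 and ramp > 40.0 and a precursor error within ±0.01 Th. Ranking
ties are resolved by higher ramp, then smaller absolute precursor error,
then lexicographic compound id — invented, deterministic tie-breaks.
Tentative hits are per-spectrum; `screenRun()` deduplicates them into one
identification per compound (keeping the highest-amp spectrum) and exposes
both tallies, since spectrum-level and compound-level counts answer
different validation questions. `reviewHits()` models the expert-review
stage as an explicit oracle mapping compounds to verdicts.

## The validation layer

* **Specificity** of the automated search on blank samples is
  `100 · (n_spectra − n_false_positive) / n_spectra`: the denominator is
  every product-ion spectrum searched, the numerator removes the tentative
  hits an expert rejected. Reported to one decimal.
* **False-negative rate** is the share of *identifiable* spectra (true
  compound covered by the library) that the search missed; 0/0 is flagged
  undefined rather than silently 0.
* **Limit of identification (LOI)** from a dilution series
  (1.0, 2.5, 5.0, 10, 25, 50, 100 ng/mL) is the minimum level identified;
  a series identified at a low level but missed at a higher one keeps the
  same minimum but is flagged inconsistent.
* **logP applicability window**: compounds with logP < 0.5 are classed too
  polar, > 5.5 too apolar; the boundaries themselves count as in-window,
  since only values strictly beyond them are problematic.
* **Two-method agreement** is plain Venn arithmetic on (sample, compound)
  pairs, percentages relative to the union, one decimal.
* **Miss explanation** partitions reference-method-only identifications by
  a fixed priority — missing reference spectrum first, then logP outside
  the window, then concentration below 5 ng/mL, then other — mirroring an
  analysis that removes library-coverage cases before investigating the
  rest. The priority order makes the partition well defined when several
  explanations apply.
* **Neat concentration**: the collection device dilutes the specimen with
  extraction solution, so concentrations measured in the mixture are
  rescaled by `(V_fluid + V_extraction) / V_fluid`.

## What the synthetic data emulate

The generator stands in for all wet-lab data and defines the study
conditions of every test.

**Breakdown curves.** Each fragment's yield is a unimodal
log-normal-shaped function of collision energy: zero before an appearance
CE, maximal at `ceOpt = appearanceCe + 10` eV, decaying at high CE with a
log-sigma of 0.45; the surviving precursor decays as `exp(−(CE − 5)/12)`.
Reference spectra are rendered noiselessly on the ten-step 5–50 eV grid and
curated with the same 0.01 cutoff used at search time. Acquisition-time
(query) spectra model the 35 eV ± 10 eV collision-energy spread by
averaging the template over 30–40 eV, then apply multiplicative log-normal
intensity noise (sigma 0.2, a ~20 % CV typical of replicate QqTOF product
ion intensities), Gaussian m/z jitter of 0.002 Th on fragments and
precursor (a third of the match tolerance, consistent with a
well-calibrated ~30k-resolution instrument), clipped to the m/z 50–700
MS/MS scan range.

**Library population.** Precursors are drawn uniformly on m/z 120–650 with
pairwise spacing > 0.02 Th unless isobars are requested explicitly
(`isobarFraction` shares a precursor within 0.01 Th to stress ramp
discrimination); 6–12 fragments per compound, at least three of them with
appearance CE ≤ 18 eV so acquisition-time spectra are never empty; logP
drawn N(2.8, 1.7²) so a realistic minority of compounds falls outside the
0.5–5.5 window; MS1 response factors log-uniform on 1–250 counts per
ng/mL, which spreads the generated LOIs across the whole seven-level
dilution series against the 100-count trigger.

**DDA duty cycle.** One survey scan plus up to eight dependent MS/MS scans
(100 ms accumulation each, 50 ms overhead, 0.95 s cycle); precursors must
exceed 100 counts, the top 8 by intensity are selected, and a precursor is
excluded for 30 s after 2 selections (the counter resets when the window
expires; re-selection requires strictly exceeding the window). Every
selection is logged, so tests assert the duty-cycle contract on the event
log rather than on downstream artifacts.

**Dilution series.** Sample preparation processes a fixed
neat-oral-fluid-equivalent volume, so the MS1 response scales with the
concentration in neat fluid and the extraction dilution factor (400 µL vs
4 mL of extraction solution on 500 µL of fluid) cancels by construction;
the manifest still records in-vial concentrations and the dilution factor,
and per-level seeds are derived independently of the volume. The manifest's
`expected_detectable` ground truth is computed from the generating model
(response × concentration × Gaussian peak sampled on the cycle grid vs the
trigger), not by running the search, which keeps the LOI-recovery check
non-circular. Analyte apexes are re-spaced 40 s apart in dilution
experiments so top-N competition does not confound the series.

**Matrix background.** Background ions elute broadly (baseline fraction
0.15 plus a wide Gaussian bump, so matrix-loaded blanks have strictly
positive TIC everywhere), a configurable fraction is multiply charged and
appears in survey scans as isotope clusters with 1/z spacing (emulating
salivary peptides competing for DDA slots), and background m/z values avoid
the library precursors by > 0.011 Th unless overlap is requested.

What the generator does **not** emulate: ionization suppression beyond a
scalar, chimeric MS/MS from co-isolation, retention-time drift, isotope
patterns beyond charge-state spacing, in-source fragmentation, and real
fragmentation chemistry. Passing tests therefore demonstrate the
correctness of the data-mining chain (export → search → decision →
validation arithmetic) under controlled conditions, not the detection
performance of any real assay; specimen-dependent figures (population LOI
distributions, patient-sample compound counts) are out of reach of desk
simulation and are deliberately not asserted.

## Numerical choices and degenerate inputs

Empty spectra pass through I/O and the cutoff unchanged; the similarity of
an empty spectrum is 0 with a warning, not an error. Duplicate m/z
centroids are merged by intensity summation at construction. The score
kernel and both I/O round trips are exercised to 1e-6; amp/ramp identities
(ramp summing to 100, scale invariance) hold to machine precision by
construction. Problem sizes in the test suite — a 50-compound library with
500 noisy queries for the sensitivity property, an 8-compound seven-level
dilution grid in two extraction-volume variants, constructed 1–9-analyte
duty-cycle scenarios — were chosen as the smallest instances that exercise
every mechanism (isobar competition, top-N clipping, exclusion, threshold
boundaries) with comfortable determinism.

## Worked example

```{r example}
gl <- generateLibrary(20, seed = 1)
libraryStats(gl$library)$nSpectra

q <- generateQuerySpectra(gl$profiles[["CMP0005"]], n = 1, seed = 9)[[1]]
identifySpectrum(q, gl$library)$matches[1, c("compound_id", "amp", "ramp")]

computeSelectivity(11437, 230, 83)
```

## Known limitations

The amp/ramp pair implemented here honours the documented constraints of
match-probability scoring (0–100 range, averaging over the compound's
reference set, relative normalisation over candidates, the 5.0/40.0
thresholds) but is this package's own kernel; absolute score values from
other engines in the same lineage are not comparable number-for-number.
The mzML-lite reader handles the package's documented centroided dialect,
not vendor mzML (conversion is upstream tooling's job). Negative-mode ESI,
multiply charged *candidates*, retention-time scoring and quantification
are out of scope.
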
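---
title: "Fragmentation-guided PRM quantification of PFAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentation-guided PRM quantification of PFAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasprm)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) are monitored in drinking and
source waters at sub-ng/L levels. Targeted high-resolution parallel
reaction monitoring (PRM) isolates each compound's deprotonated molecular
anion `[M-H]-` in a scheduled retention-time window and records full
high-resolution fragment spectra, so that quantification (one extracted
fragment trace) and structural confirmation (additional diagnostic
fragments at exact mass) come from the same acquisition. `pfasprm`
implements the desk-side half of such a method for a 26-compound panel of
legacy PFAS and their replacement chemistries: exact-mass arithmetic,
rule-based fragment prediction, chromatogram extraction and annotation,
internal-standard calibration with formal linearity testing, and a
synthetic PRM generator that makes the whole pipeline testable with known
ground truth.

## The mass scale

All m/z values derive from one table of monoisotopic atomic masses
(`mass_constants()`), with the electron-inclusive anion convention:

* `[M-H]-`: neutral monoisotopic mass − proton mass (1.00727646 Da);
* a fragment composition stated directly as an anion (e.g. `C3F7-`):
  composition mass + electron mass (0.00054858 Da).

Including the electron mass matters at the 4th decimal: PFBA computes to
212.9792 Th rather than 212.9787. Registry formulas are stored as free
acids (the printed salt forms of the fluorotelomer sulfonate and the
chlorinated polyfluoroether sulfonates are converted; one obvious formula
typo is corrected), because the printed precursor m/z correspond to the
free-acid `[M-H]-`. Display rounding is half-up at 4 decimals; full
precision is kept internally.

## Fragmentation rules

Each registry compound belongs to one of six structural classes, each with
a fixed rule set:

| class | emitted ions |
|---|---|
| PFCA | `[M-H]-`, `[M-H-CO2]-` (= CnF2n+1-), CkF2k+1- for k = 1..n |
| PFSA | `[M-H]-`, `SO3-`, rearranged `FSO3-`, CkF2k+1- series |
| ether carboxylic acids | PFCA ions plus acid-distal `[R]-` / `[R-O]-` per ether oxygen |
| Cl-PFESA | `SO3-`, `FSO3-`, plus `[R]-` / `[R-O]-` (no CkF2k+1 series: the chain carries Cl) |
| fluorotelomer sulfonate | `[M-H]-`, `[M-H-HF]-`, `SO3-`, `FSO3-` |
| perfluoroalkane sulfonamide | `[M-H]-`, `[SO2N]-` |

Design choices made where the chemistry left room:

* **Ether arms are registry metadata**, not inferred from structures: each
  ether oxygen's acid-distal composition R is stored (e.g. `C3F7` for
  HFPO-DA; `CF3` and `C4F9O` for the dioxa acid DONA), avoiding any
  structure-drawing dependency. Only acid-distal anionic products are
  emitted.
* **The CkF2k+1 series is emitted in full** (k = 1..n). Published spectra
  show a subset for long chains; which members are observed is left to
  matching, not prediction.
* **Deduplication with merged pathway labels**: when decarboxylation and
  the C–C series give the same composition (always, for a PFCA's k = n
  member), one ion is kept carrying both pathway labels.
* **The fluorotelomer HF-loss rule is an extension**: the registry
  transition (426.9674 → 406.9615) is an HF loss, but no prose pathway
  accompanies it, so the rule is labeled `HF_loss` and documented as such.
* **No intensity prediction.** The engine emits compositions and masses;
  relative intensities are a synthetic-generator convention only.

Every non-root fragment records its parent and the neutral/radical loss
connecting them; the test suite checks mass conservation on every edge to
1e-4 Th, and `pathway_tree()` reassembles the rooted tree.

Eleven registry rows print a product m/z more than ~2 ppm from theory
(the sulfonate `SO3-` rows print 79.9558 vs 79.9574 theoretical, `C3F7-`
prints 168.9883 vs 168.9894, and so on). These carry `mz_flag = TRUE`;
matching and synthesis use theoretical values for them, and the transition
lookup tolerates 25 ppm for flagged rows versus 5 ppm otherwise.

## Spectra, XICs and identification

The canonical run format is a small JSON dialect (`pfasprm-run/1`) written
and read losslessly; mzML is read through an mzR adapter into the same
structure. Extraction and integration choices:

* **ppm tolerance defaults to 5 ppm**, consistent with an Orbitrap at
  resolution 35,000; it is a configurable parameter everywhere, since the
  published method does not state its confirmation window.
* **RT windows are half-open** `[RT − 0.5, RT + 0.5)` min; overlapping
  windows are allowed (co-eluting compounds).
* **Peak boundaries** scan outward from the apex until the trace falls
  below `max(baseline + 3 × noise SD, 1% of apex)` — reproducible and
  parameter-light. The baseline and noise SD are the median and scaled MAD
  of the trace outside a provisional (1%-of-apex) peak region, so the peak
  itself cannot inflate the noise estimate. Areas are trapezoidal
  integrals of the baseline-subtracted trace (intensity × minutes); the
  1%-of-apex cut discards about 0.3% of a true Gaussian's area, which is
  why area tests use a 1% tolerance.
* **Ties** between equally tall peaks resolve to the earlier retention
  time.
* **Identification** requires the quantifier peak (apex inside the
  scheduled window) *and* at least one additional predicted fragment
  annotated in the apex spectrum; a quantifier-only signal is flagged, not
  identified. Annotation assigns peaks in decreasing intensity order, each
  taking the unused prediction with the smallest |Δppm|, making the result
  independent of input order.

## Calibration and validation statistics

The calibration response is `y = (analyte area / IS area) × C_IS` with the
internal standards at 5.0 µg/L, regressed on the nominal concentration
over the five-point series 0.2–20 µg/L in triplicate. Choices:

* **Unweighted OLS** is the default (a 1/x-weighted fit is available but
  off): the published regression equations are reproducible as plain OLS
  and no weighting is mentioned. R² is the squared Pearson correlation of
  fitted versus observed response.
* **Lack-of-fit test**: SS_r about the line decomposes into pure error
  SS_ε (within levels) and lack of fit SS_lof (level means about the
  line); `F = (SS_lof/(I−2)) / (SS_ε/(IJ−I))` against the 95% F quantile.
  The denominator degrees of freedom are IJ−I, which uniquely reproduces
  the tabulated F(3,10) = 3.71 for the I = 5, J = 3 design (the
  alternative IJ−J reading would give F(3,12) = 3.49). Numerically exact
  data (both sums of squares below 1e-12 of the response scale) report
  F = 0, verdict linear.
* **LOD/LOQ** use the signal-to-noise mechanism with multipliers 3 and 10
  (configurable): `LOD = 3 × spike / (S/N)` from a spiked blank's XIC,
  S/N = peak height / baseline noise SD. A trace whose noise estimate is
  below 1e-8 of the apex is reported as "below the simulation noise
  floor" rather than LOD = 0. Published LODs are instrument-noise
  dependent and are *not* reproduced here — only the mechanism and its
  magnitude plausibility are tested.
* **Recovery** is `(mean − background)/spike × 100` with a non-detect
  background counted as 0 (the published table's arithmetic confirms
  this: 4.66/5.0 = 93.2%); RSD is `100 × SD/mean`.
* **Units**: calibration in µg/L (standard solutions), sample results in
  ng/L. With the method's 1000-fold SPE preconcentration (200 mL water to
  200 µL extract) the two are numerically equal; the conversion is an
  explicit `preconcentration` parameter, not an assumption.

## The synthetic generator

`generate_run()` emulates the acquisition the method describes, not an
instrument simulator:

* Gaussian chromatographic peaks (σ = 3 s by default; no tailing — an
  exponential tail is outside scope and would only stress the boundary
  scan) at the registry retention times, sampled every 1.5 s so that a
  peak spans ≥ 12 points, honouring the method's "more than eight points
  per peak" acquisition claim by construction (the real cycle time is not
  published).
* Spectra contain the rule-engine's predicted fragments with a fixed
  relative intensity profile (quantifier 1.0, precursor 0.45, remaining
  fragments 0.3 × 0.6^rank). This is a recorded convention with no
  physical claim.
* The planted quantifier area follows the registry calibration line:
  `area = (slope·x + intercept)/C_IS × IS area`, so the full pipeline
  (extraction → IS normalization → inverse prediction) recovers the
  planted concentration exactly at zero noise.
* Internal standards are co-generated on mass-shifted channels
  (+1.003355 Da per 13C label; product ions shifted by the labels the
  fragment can retain, so sulfonate products are unshifted). Published IS
  transitions are not given; this is generator plumbing.
* Noise model: additive truncated-Gaussian baseline per trace point,
  multiplicative Gaussian area error per injection, optional Gaussian
  m/z jitter in ppm. All randomness flows from one seed; planted areas,
  multipliers and IS areas are returned as machine-readable ground truth.

What passing tests on this generator do **not** show: behaviour under
matrix interference, ion suppression, peak tailing or asymmetry, retention
drift, or the SPE step — real-data validation still requires real data.
Likewise the published water-survey concentrations and the experimental
R²/F values of the original calibration replicates are not reproducible
from the printed material and are out of scope.

## Problem sizes and runtimes

The test suite exercises the full 26-compound registry for all rule-based
checks, 1,000 random datasets for the ANOVA identity, 2,000 seeded
replicates for the type-I calibration of the lack-of-fit test, and
synthetic runs of 2–6 channels (≈ 40 spectra per channel) for the
round-trip pipeline — sizes chosen so the whole suite runs in well under a
minute while keeping Monte-Carlo standard errors a few times smaller than
the tolerances being asserted.

## A worked example

```{r example, eval = FALSE}
reg <- pfas_registry()

# predict and inspect fragments
predict_fragments("PFDA")[, c("label", "mz", "pathway")]
pathway_tree("HFPO-DA")

# synthesize a run, calibrate, quantify
cal <- generate_calibration_set(c("PFOS", "PFOA"), area_cv = 0.02, seed = 1)
report <- validate_method(cal$data)
report$linearity

g <- generate_run(synth_config(conc_ugl = c(PFOS = 5, PFOA = 2),
                               area_cv = 0.02, baseline_mean = 100,
                               baseline_sd = 25, mz_jitter_ppm = 0.5,
                               seed = 7))
quantify_sample(g$run, report$curves)
```

## Known limitations

* Monoisotopic masses only: no isotope patterns, average masses, or
  positive-ion adducts.
* Fragment prediction is rule-based per class; branched-isomer intensity
  ratios and novel classes need new rules.
* `quantify_sample()` assumes one quantifier transition per compound and
  does not model cross-channel interference.
* The lack-of-fit test requires a balanced replicated design, as the
  underlying decomposition does.
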
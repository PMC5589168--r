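---
title: "Methods: glycosylation metrics and parallel-line potency for r-hFSH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycosylation metrics and parallel-line potency for r-hFSH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopotency)
```

# Scope and model

Recombinant human follicle-stimulating hormone (r-hFSH, follitropin alfa) is
a heterodimeric glycoprotein with four N-glycosylation sites: Asn52 and
Asn78 on the alpha chain, Asn7 and Asn24 on the beta chain. Comparability
between a biosimilar and its reference product rests on two measurable
surfaces that this package implements end to end:

1. **Site-specific glycosylation**: chymotryptic glycopeptides are resolved
   by HILIC and quantified by extracted-ion-chromatogram (XIC) ion counts;
   each site's glycan species are expressed as a relative percentage
   distribution, which is then condensed into the hypothetical charge number
   (Z-number) and antennarity index (A-index).
2. **In-vivo bioactivity**: the Steelman–Pohley ovarian-weight-gain assay in
   immature rats, analysed as a compendial 3×3 parallel-line design with
   Fieller fiducial limits, followed by group statistics over batches.

# Glycan model

Species are compositional shorthand `[F][Ax][Gy][Sz][LacN]`: core fucose
(0/1), antennae (1–4), galactoses, sialic acids, N-acetyllactosamine
repeats. Linkage isomery (for example alpha-2,3 versus alpha-2,6
sialylation) is deliberately out of scope; ion-count quantitation cannot see
it. Residue counts follow from the composition (`HexNAc = 2 + A + Lac`,
`Hex = 3 + G + Lac`, `dHex = F`, `NeuAc = S`), and residue masses use
monoisotopic tables by default — appropriate for Q-TOF acquisition; average
masses are selectable via `monosaccharide_masses("average")`.

Two conventions were genuinely open and are fixed here:

* **`F2A2G2S2`** appears in published species lists although the shorthand
  defines only a single core fucose. It is treated as an alias of
  `FA2G2S2`; the substitution is logged at parse time and the alias table is
  extensible through `options(glycopotency.glycan_aliases = ...)`.
* **Lac repeats** extend an antenna rather than adding one, so they
  contribute mass and residue counts but neither antennarity nor (by
  themselves) sialylation capacity beyond the extra galactose. Naming uses
  an explicit `LacN` suffix because the structures are described but not
  named in the source nomenclature.

# MS mapping

In-silico chymotryptic digestion cleaves C-terminal to F/Y/W/L/M except
before proline. The four FSH glycosite peptides bundled by
`fsh_site_peptides()` are the lowest-missed-cleavage peptides that contain
exactly one sequon; backbone masses include fixed carbamidomethylation of
cysteines (iodoacetamide alkylation).

Matching is monoisotopic-peak only (no isotope-envelope deconvolution), at a
default tolerance of **10 ppm**, over charges **1–4** filtered to the
instrument scan range 100–2000 m/z. Neither tolerance nor charge set is
stated by the source acquisition method, so both are recorded as assumptions
in every assignment report header. Each peak is assigned to the nearest
candidate in ppm; exact ties go to the lower theoretical m/z and are logged.

Relative quantitation normalizes pooled-over-charge ion counts within a
site. Pooling across *different* backbone peptides is off by default:
ionization bias cancels only within a family sharing one backbone. The
retention-time window defaults to the full run, since total ion counts do
not require modelling the HILIC gradient.

# Z-number and A-index

For a percentage distribution $\{p_i\}$ over species with sialic-acid
counts $s_i$ and antenna counts $a_i$:

$$Z = \operatorname{round}\Big(\sum_i p_i\, s_i\Big), \qquad
  A = \operatorname{round}\Big(\sum_i p_i\, a_i\Big),$$

both on a 0–400 scale (100% tetra-sialylated or tetra-antennary gives 400).
Rounding is **half away from zero**: this is the only convention that
reproduces every checkable published cell (209.5 → 210, 252.5 → 253,
286.5 → 287). Both metrics are linear in the distribution before rounding,
and $Z \le A$ whenever no species carries more sialic acids than antennae —
both properties are enforced by randomized tests.

Class-based values (computed from antennarity/sialylation class
percentages) can differ from species-based values by 1–2 units because the
class table is itself rounded. Recomputing the Bemfola Asn52 Z-number from
the published class table gives 218/219 against printed 216/217 — consistent
with species-level rounding upstream, and left as is. The acceptance surface
uses only cells that reproduce exactly from the class table (all GONAL-f
Z-numbers and all five A-indices at Asn52).

The published class blocks themselves sum to up to 101.0 after rounding, so
the `class_summary` container admits a ±1.0 deviation from 100; the
species-level `glycan_distribution` keeps the stricter ±0.5 band.

The **glycan-release simulation** is the arithmetic mean of the four site
Z-numbers (and A-indices), rounded the same way — the value a released-glycan
analysis of the whole molecule would see. Compendial expectation ranges for
the Z-number (177–233 for 2AB detection, 178–274 for pulsed amperometric
detection) are treated as inclusive on both ends.

# Parallel-line potency

Responses are modelled linearly in natural-log dose with a slope common to
the standard and test preparations. The validity ANOVA partitions the
treatment variation into *preparations*, *common regression*, *deviation
from parallelism* and *deviation from linearity*, each tested against the
within-cell residual. Validity follows the compendial convention (the source
names the method but not thresholds): regression significant at p < 0.05;
parallelism and linearity deviations non-significant at p > 0.05.

The log relative potency is $M = (\bar y_T - \bar y_S)/b$ (corrected for
any difference in mean log dose), $\rho = e^M$, and 95% limits come from
Fieller's theorem with $g = t^2 s^2 / (b^2 S_{xx})$; when $g \ge 1$ the
limits are undefined and flagged. At zero residual variance the limits
collapse to the point estimate exactly — a property test guards the
degenerate branch. The residual variance is the within-cell mean square
when it has degrees of freedom; in noiseless synthetic designs with one
animal per cell the common-slope residual (zero) is used instead.

Replicate assays are combined as a weighted mean of log potencies with
compendial weights $W = 4t^2/L^2$ ($L$ the log fiducial width, i.e.
inverse squared half-width), with a homogeneity chi-square on $k-1$ df;
heterogeneous sets are flagged but still combined, and an unweighted
geometric mean is available for comparison. Specific activity is
`IU / (µg/1000)` and batch potencies are normalized to percent of the
nominal label claim for all cross-product statistics.

# Batch comparison

`compare_groups()` is a one-way ANOVA with Fisher-LSD pairwise verdicts at
the 95% confidence level (for two groups, F equals the square of the pooled
two-sample t statistic — checked against `stats::t.test` as an independent
oracle). Variance homogeneity uses Bartlett's test (delegated to
`stats::bartlett.test`). The cross-validation analysis partitions the larger
group at random (seeded, reproducible; the seed is part of the result) into
subgroups of stated sizes and compares every subgroup pair and every
subgroup against the comparator. A descriptive two-sample power estimate is
provided but is not an acceptance surface: the published power figure's
assumptions are not stated.

# Synthetic data: the stated world

`simulate_peaklist()` emits, per (site, species, in-range charge, scan), a
peak at the theoretical m/z with intensity proportional to the target
percentage. Noise is **multiplicative log-normal** (ion counts are positive
and right-skewed), default sigma 0.1; m/z jitter is Gaussian in ppm; decoy
peaks are placed at least 30 ppm (3 matching tolerances) from every
candidate so they can never match. Ground truth is emitted alongside, so
assignment recall, distribution error and downstream metric error are all
scorable.

`simulate_assay()` uses the published design verbatim: doses 2/4/8 IU per
rat, five rats per dose and preparation, standard assigned 147.5
IU/ampoule. Response parameters (intercept 30 mg, slope 35 mg per ln-dose,
residual SD 6 mg) were chosen once so that ovary weights span a realistic
50–105 mg range and single-assay potency CVs land in the published 5–9%
batch-variability band; they were not revisited afterwards. A test
preparation of relative potency $\rho$ responds as the standard given at a
$\rho$-fold dose.

What a green synthetic test establishes: the estimator chain is unbiased
(< 1% at $\rho = 1.056$ over 1000 assays) with nominal Fieller coverage
(95% ± 2%), and the MS chain is exact in the noiseless limit. What it does
not establish: behaviour under chromatographic co-elution, isotope-envelope
interference, real ionization bias across backbones, or animal-level
covariates — none of which the generators model.

# Replacement of the raw-bioactivity criterion

The per-batch bioactivity values behind the published group summaries live
in supplementary files that are not part of the text this package was built
against, so the printed summaries (105.6%/97.3% means, 8.3%/5.8% CVs,
p = 0.0048, subgroup means 97.6/98.4/96.1%) cannot be recomputed from real
data here. Following the stated fallback, that criterion is replaced by the
property suite, plus a clearly-labelled *synthetic* stand-in: groups drawn
at the published summary parameters are pushed through the comparison layer
and checked within sampling tolerances. Single-draw significance is
deliberately not asserted — the published design itself has only ~75%
power, so demanding p < 0.05 of one simulated dataset would test luck, not
correctness.

# Numerical choices and degenerate inputs

* Half-away-from-zero rounding everywhere a published integer is
  reproduced; documented above.
* ANOVA sums of squares are clamped at zero against floating-point
  negatives in noiseless designs.
* `quantify_site()` errors on all-zero ion counts ("no quantifiable
  species") rather than returning NaN percentages.
* Empty peak lists warn and report all candidates absent.
* `assay_data()` warns when doses are not geometrically spaced, errors on
  non-positive doses/responses, and `fit_parallel_line()` refuses
  zero-variance response vectors.
* All generators save and restore the caller's RNG state; results are
  bit-reproducible given (config, seed).

# Known limitations

* Only compositional glycan shorthand; no topology or linkage.
* No MS2 scoring, no retention-time alignment, no isotope deconvolution.
* mzML input is not implemented (no suitable reader among the package's
  allowed dependencies); the peak-list CSV contract is the supported path.
* The slope-ratio and probit bioassay families are out of scope; only the
  parallel-line model is provided.
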
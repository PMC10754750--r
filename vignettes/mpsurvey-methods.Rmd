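---
title: "Models and methods behind mpsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsurvey)
```

## The survey this package models

mpsurvey analyses two-site, four-season microplastic (MP) surveys of
wastewater sediment and of *Chironomus* midge larvae and their tubes — the
tube-building, deposit-feeding benthic larvae widely used as freshwater
pollution bioindicators. One row of data is either a detected particle
(site, season, compartment, shape, length and width in µm, colour, polymer)
or a replicate's normalised count (items per kg dry sediment, particles per
individual, per tube, or per g wet tube). The package's defaults are
calibrated to a reference field survey of two wastewater disposal sites
("S1", "S2") sampled in winter, spring, summer and autumn, with fifteen
sediment replicates, five ten-larva subsamples and five ten-tube samples
per site and season; `survey_reference()` collects the reference values the
calibration targets.

Every analysis stage is driven by a seeded synthetic-survey generator, so
the full pipeline — summaries, risk indices, statistics — is testable at
desk scale without any external data.

## The risk-index stack

The core computation is the five-equation sediment risk stack:

* contamination factor **CF = Ci / Co**, with `Ci` the site concentration
  (items/kg dry weight) and `Co` a literature background concentration
  (default 1.79 items/kg DW; a benchmark, not a constant of nature, hence
  overridable);
* pollution load index **PLI = √CF**;
* polymer hazard index **H = Σₙ Pn·Sn**, with `Sn` the per-polymer hazard
  (Lithner) scores — PES = 4, PP = 4, PE = 11 by default — and `Pn` the
  polymer shares **on the percent scale (0–100)**. The percent scale is a
  deliberate, documented choice: it is the only reading that produces the
  reference survey's index values of roughly 400–520 (e.g.
  `{PES: 93, PP: 7} → 400`); the fraction scale common elsewhere in the
  literature gives values 100× smaller. Polymers missing from the score
  table raise an error rather than contributing silent zeros.
* toxicity coefficient **Tj = H / Ci**. The defining equation is garbled in
  the reference table's source typography; this reading was adopted after
  verifying it reproduces more than five independent cells of the published
  index table (400/380 = 1.05, 519/312 ≈ 1.66, 449/470 ≈ 0.96,
  460/379.05 ≈ 1.21, …).
* potential ecological risk index **RI = Tj × CF**, which algebraically
  equals **H / Co** and is therefore independent of `Ci`. The implementation
  computes `Tj × CF` and the test suite asserts the identity to 1e-9 — a
  strong internal consistency check on the whole stack.

Annual (1-year) rows use the unweighted mean of the four seasonal means as
`Ci`; cross-site seasonal pooling likewise averages the two site means
(345.8 and 380 pool to 362.9, reported 363).

### Hazard categories

H levels are I < 10, II \[10, 100), III \[100, 1000), IV ≥ 1000; RI levels
are I < 150, II \[150, 300), III \[300, 600), IV \[600, 1200), V ≥ 1200 —
all half-open, with each printed boundary assigned upward. The PLI category
table is not printed alongside the index definition in the calibration
source, so the defaults (I < 10, II \[10, 20), III \[20, 30), IV ≥ 30) were
chosen to place the reference values 12–16.5 in category II ("medium"), and
are overridable.

### Report rounding

Internal arithmetic is always full precision. The reporting layer
(`report_cf()`, `report_pli()`, `report_tj()`, `report_ri()`,
`render_table1()`) reproduces the reference table's evident conventions: CF
to the nearest integer; the displayed PLI recomputed from the displayed CF
(√181 = 13.45 → 13.5, while √180.5 would print 13.4) and shown to one
decimal below CF 200, as an integer above; Tj to two decimals; RI rounded
last from full-precision intermediates.

A handful of reference-table cells are internally inconsistent with their
own inputs (a spring CF printed 141 where Ci/Co gives 140.4; a summer PLI
printed 16.5 where √263 = 16.2; one Tj printed 1.04 where H/Ci gives 1.09;
three S1 RI cells printing a repeated 223 where recomputation gives
225/235/229 — S2's winter RI is the arithmetically consistent 223). The
package reproduces every arithmetically consistent cell exactly under the
rounding ledger; the inconsistent cells are asserted against the
recomputation and the RI = H/Co identity instead of the print.

## The synthetic-survey generator

### Abundances

Replicate sediment abundances are drawn from a normal distribution
truncated at zero with the calibrated cell mean and sd (the reference
survey reports means ± sd only; the family is our choice, and at these
means truncation is negligible). Counts are integers over a basis mass
(default 1 kg dry sediment per replicate), and the stored abundance is
`count / basis` exactly — so abundances are quantised to one particle per
basis mass, and a zero-sd calibration reproduces its mean exactly only when
`mean × basis` is an integer.

### Particle attributes

Shape, colour and polymer are independent categorical draws from the
compartment's (and, where reported, site's) composition vectors. Lengths
and widths are truncated normals parameterised by the reported mean/sd and
truncated at the reported min/max — the one family that matches all four
reported statistics at once. Generated sizes can therefore never violate
the reported ranges, which the tests assert.

Two reference compositions required judgement calls: the seasonal spring
polymer percentages print as 86 + 14 + 2 > 100 and are renormalised (that
cell is excluded from calibration checks), and colours beyond the four
quantified ones (blue 35 %, red 23 %, black 22 %, green 13 %) share the
remaining 7 % across violet/orange/yellow in roughly even steps.

### Sediment → biota coupling

Each site × season cell's mean larval burden is
`intercept + slope × (cell sediment abundance)`, with individual burdens
Poisson around the cell mean; burdens are small counts (0–2) with near-
Poisson dispersion in the reference data. The default slope/intercept
(0.00243422, −0.0287776) are the least-squares fit through the six cells
with reported (sediment mean, larval burden mean) pairs; the two cells
whose burdens are only shown graphically are interpolated from that line
(0.73 at both) and excluded from calibration checks. Negative implied means
are clipped to zero with a warning. Tubes use the analogous fit
(0.00215631, −0.2022368) through the four reported tube cells, and each
ten-tube sample draws a wet weight (mean 0.8535 g, chosen so the grand
mean burden per gram reproduces the reported 6.5 particles/g; sd 0.10 g).

One reference feature the Poisson model deliberately does **not**
reproduce: reported larval detection rates of 95–100 % alongside mean
burdens near 0.8/individual. A Poisson burden with mean 0.8 yields ~55 %
detection; matching both simultaneously would need a strongly
under-dispersed count model for which the reference data offer no
parameters. Detection-rate computation is tested on explicit counts
instead.

### Ingestion selectivity

Biota particle lengths are drawn from the *sediment* length distribution
reweighted by a monotone non-increasing selectivity curve — weight 1 up to
1000 µm, decaying linearly to a floor of 0.05 at 1500 µm — implemented by
rejection sampling. The curve models the larval mouthpart gape limit and is
a configuration knob; the default plateau/cutoff/floor were chosen, before
any acceptance run, so that larvae reproduce the reference survey's two
robust qualitative findings: concentrations decreasing with particle
length, and strong enrichment of the 501–1000 µm class relative to host
sediment (61 % vs 20 %). A gentler decay (e.g. to 0.2 at 2500 µm) provably
cannot produce that enrichment, because it leaves the reweighted
distribution nearly proportional to the sediment's.

A related tension in the reference data is left as-is: larvae carry fibers
down to 522 µm while sediment fibers start at 684 µm (plausibly digestive
fragmentation). Since generated biota lengths are resampled sediment
lengths, synthetic larval fibers are bounded below by 684 µm and their mean
exceeds the reported 840 µm; the reported biota length statistics are
reference data, not generator targets — only the size-class *enrichment* is
a tested property.

Second-instar (L2) larvae ingest fibers only, with lengths from a
calibrated short distribution (mean 422 µm, capped at 600 µm to respect the
reported 397–581 µm range).

### The instar experiment

`gen_instar_experiment()` emulates the summer collection of 100 L2 and 100
L4 larvae (10 replicates × 10): the five morphometrics are per-instar
truncated normals at the reported means/sds, and each individual's burden
is Poisson with mean proportional to its head-capsule width, scaled so the
instar mean matches the reported 0.52 (L2) / 0.91 (L4). This yields the
reported qualitative structure — a significant L4 > L2 burden difference
and a positive head-width/burden association — though the pooled
individual-level correlation (~0.3) is smaller than the reported 0.85,
which Poisson noise at burdens below 1 makes unattainable at the individual
level.

### Seeding

A single integer master seed drives everything. Each generator stream
(sediment/larvae/tubes/instar) and each of the eight site × season cells
gets its own substream via a fixed counter scheme
(`(seed mod 1e6) × 1000 + stream offset + cell index`), so adding a cell or
drawing more attributes in one cell never perturbs another, and identical
seeds give byte-identical tables.

## Statistics

Season and site contrasts use classical one-way ANOVA (`stats::aov`
machinery; equal-variance F). Group-variance diagnostics are not applied
automatically, matching the survey design. Size-class contrasts use the
Pearson chi-square without continuity correction; classes with expected
counts below 1 are merged into their right-hand neighbour (last class
leftward) deterministically. Correlation defaults to Pearson with a
`rank = TRUE` Spearman option — the reference analysis names "Pearson rank
correlation", a self-contradiction resolved in favour of Pearson because
the reported coefficients accompany linear regression fits. No
multiple-testing correction is applied anywhere (none was in the reference
analysis); reports should state how many tests they ran.

## Problem sizes and stochastic checks

The test suite's stochastic checks use problem sizes chosen by power
analysis at design time:

* generator mean recovery: 400 replicates per cell, within 2 standard
  errors per cell; compositions at the full default particle yield
  (~40 000), within 3 binomial standard errors;
* sediment → larva coupling: 200 runs at 500 larvae per cell, requiring
  r ≥ 0.9 in ≥ 80 % of runs. At the field design (50 larvae per cell)
  the expected correlation is ~0.83 — Poisson noise, not the coupling,
  binds — so the inflated design measures the property the field statistic
  (r = 0.96 over cell means) reflects;
* sediment → tube coupling: 200 runs at the field design, median r within
  0.15 of the reported 0.87 (design-time estimate ~0.83);
* enrichment chi-square: 200 runs; the calibrated null uses identity
  selectivity *and* the sediment shape mixture, because the larval
  compartment's own fiber/fragment mix shifts the length distribution even
  without selectivity;
* type-I calibration: 400 ANOVA runs under a no-season-effect calibration,
  rejection rate within 3 binomial standard errors of 0.05.

## Known limitations

* The generator emulates the reference survey's marginal structure
  (abundance cells, compositions, couplings), not hydrology, temporal
  autocorrelation beyond season cells, laboratory contamination, or
  spectral polymer identification (polymers enter as labels).
* Passing calibration checks shows the generator reproduces the reference
  survey's reported statistics, not that real surveys look like either.
* Burden models are Poisson; surveys with strongly under- or
  over-dispersed burdens need a different count family.
* The PLI category thresholds are a package default where the calibration
  source prints none; users comparing against other index literature
  should check both the thresholds and the percent-vs-fraction `Pn`
  convention.
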
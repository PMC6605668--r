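---
title: "Tetrad analysis of meiotic crossovers: models, estimators and the meiosis simulator"
author: "tetramap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad analysis of meiotic crossovers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

## The problem

In *Saccharomyces cerevisiae*, one meiosis yields four haploid spores
that can be dissected and genotyped as a unit (a tetrad).  For two
linked heterozygous markers the tetrad adopts one of three
configurations: **PD** (parental ditype, no recombinant spores),
**TT** (tetratype, two recombinants, produced by a single crossover)
and **NPD** (non-parental ditype, four recombinants, requiring a
four-strand double crossover).  From the counts (PD, TT, NPD) of many
tetrads one estimates genetic map distance and the strength of
crossover interference, the phenomenon by which one crossover
suppresses others nearby.  `tetramap` implements this analysis —
classification, estimation, conversion tallies, viability summaries,
companion exact tests — together with a generative meiosis simulator
so every estimator can be validated by parameter recovery.

Tetrad genotypes live in a `TetradExperiment`, a
`SummarizedExperiment` whose rows are markers (with chromosome,
order and phase metadata), whose columns are spores (with tetrad id
and viability), and whose single assay holds `"P1"`/`"P2"`/`NA`
calls.  Mapping raw phenotypes (drug resistance, auxotrophy) onto
P1/P2 is the caller's responsibility, recorded via the map's `phase`
column; the package never re-infers parental phase from data.

## Estimators

**Perkins map distance.**  For an interval with counts
$(PD, TT, NPD)$ and $n = PD + TT + NPD$,

$$\mathrm{cM} \;=\; 100\,\frac{TT/2 + 3\,NPD}{n},$$

which corrects the single-crossover distance $TT/2n$ for the double
crossovers revealed by NPDs.  Because the estimator is linear in the
class counts, its multinomial sampling variance is exact, giving

$$SE \;=\; \frac{100}{\sqrt n}
  \sqrt{\tfrac{f_T}{4} + 9 f_N - \left(\tfrac{f_T}{2} + 3 f_N\right)^2},
  \qquad f_T = TT/n,\; f_N = NPD/n .$$

A $10^5$-replicate multinomial bootstrap agrees with this formula
within Monte-Carlo error on every row of the shipped reference
tables (that agreement is asserted in the test suite).

**Interference via the NPD ratio.**  Under no interference (and no
chromatid interference) the NPD frequency expected from the observed
tetratype frequency is Papazian's

$$f_{NPD}^{exp} = \tfrac12\!\left[1 - f_T - (1 - 3 f_T/2)^{2/3}\right],$$

and the statistic $NPD_{obs}/NPD_{exp}$ is below 1 when interference
suppresses double crossovers.  The ratio is reported as undefined
("n.d.") when no NPD was observed or when $f_T \ge 2/3$, where the
formula's base becomes non-positive.  Note that strong interference
itself can push $f_T$ above $2/3$ (the tetratype probability is
maximal, 1, for exactly one crossover), so "n.d." is a legitimate
outcome on strongly interfering data, not only a small-sample one.
The ratio's standard error treats the observed NPD count as Poisson:
$\sqrt{NPD_{obs}}/NPD_{exp}$.  The reference tables shipped with the
package print SEs that mostly (72 of 91 defined cells) agree with
this convention at display precision; the remainder follow a
convention of the original analysis software that is not recoverable
from the printed counts, which is why the package states its own
convention explicitly.

**Random spores.**  Pooled single-spore platings give the percent
recombinant $100\,r/t$ with binomial standard error
$100\sqrt{(r/t)(1-r/t)/t}$.

**Display conventions.**  The reference tables this package
reproduces come from a legacy spreadsheet/online-tool pipeline with
two idiosyncrasies that `tetramap` deliberately mirrors in its
report functions (raw estimator functions always return full
precision): (i) cM and SE values are rounded at the second decimal
before the first (`displayRound()`), so 50.947 displays as 51.0;
(ii) per-chromosome totals of tetrad-based cM are sums of the
*displayed* interval values, while random-spore per-chromosome
totals are sums of *unrounded* percents; percent-of-control columns
are integer-rounded ratios of displayed values.  One cell of the
reference tables sits exactly on the double-rounding boundary
(counts 21/2/0, cM $= 4.3478 \to 4.35$) and is printed 4.3; it is
kept verbatim and excluded from the reproduction tests, as are a
handful of cells that are internally inconsistent with their own
printed counts (a ratio printed 1.70 whose counts and printed SE
both give 1.07, one mislabelled "n.d.", one percent cell, and one
random-spore count with a dropped digit).

## Gene conversion and viability summaries

A locus segregating 3:1, 1:3, 4:0 or 0:4 instead of 2:2 reflects
heteroduplex repair (gene conversion).  `detectConversions()`
computes per-locus segregation in 4-spore-viable tetrads and merges
runs of *adjacent* non-2:2 loci (consecutive in marker order on the
same chromosome, irrespective of physical distance) into single
events, since one conversion tract can span nearby markers.
`filterForConversionAnalysis()` keeps 4-spore-viable tetrads with at
most two merged events — tetrads beyond that more likely reflect
dissection or genotyping artefacts.  Tetrads with a conversion at an
interval-defining marker are excluded from that interval's PD/TT/NPD
tally (as "unscorable") rather than repaired; conversions are
tallied separately.  `viabilityDistribution()` and
`sporulationEfficiency()` provide the standard strain-health
summaries.

## Exact tests

`fisherExactTwoTailed()` implements the probability-mass two-sided
convention (sum the hypergeometric probabilities of all tables, with
margins fixed, no more probable than the observed one); it is checked
exhaustively against direct enumeration for small margins and against
`stats::fisher.test` on random tables.  `mannWhitneyTwoTailed()` uses
the exact U distribution (Gaussian-binomial recurrence) for combined
$n \le 20$ without ties and the tie-corrected,
continuity-corrected normal approximation otherwise, matching
`stats::wilcox.test` in both regimes.  These are companions for
cytological count and length comparisons (e.g. centromere-associated
synaptonemal-complex assemblies) rather than part of the map
pipeline.

## The meiosis simulator

`simulateTetrads()` draws crossovers on each bivalent (four-chromatid
bundle) from a **stationary gamma-renewal (counting) process** on the
genetic scale: inter-crossover distances are Gamma with integer shape
$m + 1$ and mean $1/(2(m+1))$ Morgans, so the bivalent receives on
average 2 crossovers per Morgan and each chromatid 1 — the definition
of the Morgan.  $m = 0$ reduces exactly to a homogeneous Poisson
process (no interference); larger $m$ under-disperses counts and
suppresses nearby doubles, the counting model of interference.  By
default the first inter-arrival is drawn from the equilibrium
residual distribution (for integer shape, a Gamma whose shape is
uniform on $1..m+1$), making the process stationary and free of
chromosome-end artefacts; an `"anchored"` origin that starts the
renewal at the left end is available for comparison.

Each crossover involves one chromatid of each homolog, chosen
uniformly and independently (**no chromatid interference**).  The
four meiotic products are built by the strand-path construction: a
product starts on one strand at the left telomere and switches to the
partner strand at every crossover involving the strand it currently
follows.  This guarantees every exchange joins a P1- and a
P2-carrying molecule at the exchange point — a single crossover in an
interval always yields a tetratype — and reproduces the classical
closed forms: at $m = 0$ the tetratype frequency is
$\tfrac23\left(1 - e^{-3\lambda/2}\right)$ for bivalent mean
$\lambda = 2d$, and two crossovers resolve 2-, 3- and 4-strand
doubles in the 1:2:1 ratio.  Chromatids are dealt to spores with an
independent random assortment per chromosome.

Gene conversion is overlaid marker-locally: each locus converts
independently with the configured rate, drawing its class from the
configured 3:1/1:3/4:0/0:4 mix and overwriting one (3:1, 1:3) or two
(4:0, 0:4) spore calls.  This is a deliberate simplification — real
conversions co-occur with crossover intermediates and cluster at
hotspots — but it is sufficient to exercise the segregation tallies
and the adjacent-locus merge rule.  Spore death is independent
Bernoulli per spore; an inviable spore has all calls blanked.  The
simulator therefore emulates dissected-tetrad datasets (configurable
true lengths, interference, viability, conversion), not features such
as obligate crossovers, centromere-proximal interference gradients or
meiosis-I nondisjunction, so passing recovery tests demonstrate
estimator correctness under the stated model, not the full complexity
of real meioses.

## Validation choices and problem sizes

The test suite validates each estimator two ways: frozen values
recomputed from the reference count tables, and parameter recovery on
simulated data.  Recovery replicates simulate each of the seven
reference intervals at its wild-type map length with the
wild-type sample sizes (about 670 tetrads), 100 replicates, and
require the Perkins estimate within 3 printed SEs of truth in at
least 95% of interval-replicates.  These replicates run at $m = 4$,
an interference strength consistent with the wild-type tables' NPD
ratios (0.11–0.54): under no interference the Perkins estimator has a
well-known downward truncation bias for intervals beyond roughly
35 cM (it ignores triple and higher crossovers; at a true 39.2 cM the
expectation is about 35.4 cM), which is a property of the estimator,
not of the simulator.  The interference checks themselves run at both
$m = 0$ (pooled NPD ratio centred on 1) and $m = 4$ (pooled ratio
well below 1; undefined Papazian expectations excluded from the
pool).  Closed-form checks use $10^5$ meioses for the tetratype
frequency and $10^5$ bootstrap resamples per table row for the SE
formula; these sizes keep Monte-Carlo error a few-fold below the
asserted tolerances while the whole suite runs in minutes on one
core.

Numerical conventions worth knowing: ties in display rounding go
half-away-from-zero with a $10^{-9}$ guard against binary
representation of decimals; a crossover falling exactly on a marker
position (measure zero in the continuous model) recombines markers
strictly to its right; `chromosomeSum()` takes `rounded = TRUE` for
the tetrad-table convention and `rounded = FALSE` for the
random-spore one; all RNG flows from a single seed, and simulated
datasets are byte-identical across reruns at a fixed seed.

## Worked example

```{r example, eval = FALSE}
cfg <- SimulationConfig(referenceMarkerMap(),
  lengths_cM = c(26.7, 20.1, 36.3, 22.9, 39.2, 7.6, 29.5),
  interference_m = 4L, n_tetrads = 600, seed = 1)
te <- simulateTetrads(cfg)
tal <- tallyIntervals(te)
crossoverReport(cbind(strain = "sim", tal))
```

## Limitations

Map distances beyond Perkins (Haldane or Kosambi transforms) and
fitting the interference parameter to data are out of scope: the
gamma model lives only in the generator, with $m$ a free simulation
parameter.  The conversion overlay ignores co-conversion with
crossovers.  The NPD-ratio SE follows the Poisson convention stated
above; alternative conventions exist in legacy tools and are not
reconstructable from published counts alone.
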
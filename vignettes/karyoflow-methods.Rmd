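---
title: "Karyotype reconstruction and flow-cytometric genome size estimation with karyoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype reconstruction and flow-cytometric genome size estimation with karyoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoflow)
```

karyoflow implements the two standard desk analyses of a basic cytogenetic
characterization: reconstructing a karyotype from chromosome arm-length
measurements, and estimating nuclear DNA content (and hence genome size) from
flow-cytometry fluorescence histograms acquired with an internal reference
standard. Both analyses ship with seeded synthetic-data generators so that
every stage can be validated without any external dataset. The bundled
fixtures are the published measurement tables for the echiuran worm
*Urechis unicinctus* (2n = 30) and a compilation of karyotype summaries for
related echiurans, sipunculids and annelids.

## Karyotype model

The measurement unit is one chromosome of one metaphase cell, described by
its short-arm length $p$ and long-arm length $q$ (µm), oriented so that
$q \ge p \ge 0$ and $q > 0$. From these the package derives

* total length $T = p + q$ and relative length $RL = 100\,T / \sum T$,
* arm ratio $AR = q/p$ (infinite for telocentrics, $p = 0$), and
  centromeric index $CI = p/T$,
* the Levan centromere class from $AR$: metacentric $[1, 1.7)$,
  submetacentric $[1.7, 3)$, subtelocentric $[3, 7)$, telocentric
  $[7, \infty]$.

The interval bounds are the conventional ones; they are taken half-open on
the right so that every ratio maps to exactly one class, and Levan's point
classes M ($AR = 1$) and T are folded into m and t as virtually all applied
karyotype work does. Measurements with $p > q$ are treated as an upstream
labelling slip and swapped with a warning rather than rejected.

Whole-karyotype statistics follow the field's standard definitions: the
fundamental number FN counts two arms per biarmed chromosome and one per
telocentric; AsK is the long-arm percentage of total complement length
($100\sum q / \sum(p+q)$, between 50 and 100); L/S is the
longest-to-shortest total-length ratio; and the Stebbins class combines the
proportion of chromosomes with $AR > 2$ (rows 1–4) with L/S (columns A–C).
Exact boundary values ($AR$ proportion of 50%, L/S of exactly 2 or 4) are
assigned to row 2 and column B; published karyotypes essentially never sit
on these boundaries, so the choice only affects synthetic edge cases. L/S is
evaluated on the diploid complement (each pair mean twice), which is
identical to the haploid value whenever there are at least two pairs and
stays defined (1.0) for a one-pair karyotype.

Relative lengths are always reported over the haploid complement (the pair
means), matching how published karyotype tables are printed; classifying a
full 2n spread still normalizes RL within that spread.

## Homolog pairing

Homologs are assigned "by similarity in length and centromere position":
within a cell, the chromosomes are split into pairs by a minimum-weight
perfect matching under

$$d(a, b) = w_{len}\,\frac{|T_a - T_b|}{\bar T} + w_{cen}\,|CI_a - CI_b|,
\qquad w_{len} = w_{cen} = 1.$$

Both coordinates are dimensionless and of comparable scale, so equal weights
are a sensible default; they are configurable. This is a matching on a
general graph (not a bipartite assignment), and no installed R package
offers weighted general matching, so `pair_homologs()` solves it exactly
with a branch-and-bound search: vertices are matched in index order,
partners are tried in ascending distance, and branches are pruned with the
admissible bound of half the sum of each unmatched vertex's cheapest
remaining edge, seeded by a greedy matching. The search is exact for any
input; on realistic karyotypes (clearly separated pair morphologies) it
visits only a few hundred nodes even at 2n = 30. The test suite verifies
optimality against full enumeration of all $(n-1)!!$ matchings for spreads
of up to 12 chromosomes.

## Aggregation across cells

Published karyotype tables report mean ± SEM over a few cells (classically
$n = 5$). `aggregate_cells()` aligns the pairs of the $k$ cells by rank and
averages rank-wise, with SEM = sample SD$/\sqrt k$. The alignment key is the
*continuous* centromeric index (descending; ties broken by descending total
length), which induces the canonical m → sm → st → t order without a hard
class boundary. Sorting on the discrete Levan class first — a seemingly
natural alternative — is subtly biased: when a pair lies near a class
boundary (the bundled karyotype has a pair at $AR = 1.68$, 1.2% below the
m/sm cut), measurement noise flips its per-cell class in a fraction of
cells, the ranks shift across the class boundary, and the rank-wise averages
blend different chromosomes; at 2% noise this reliably distorts the
recovered type counts. Ranking on the continuous index confines occasional
rank swaps to pairs with nearly identical morphology, whose values are
interchangeable. The aggregated Levan class is then re-derived from the mean
arm ratio; ranks containing any telocentric report $AR = \infty$ with an
undefined (NA) SEM.

## Genome size model

A mixed acquisition contains the reference population of known DNA content
(default: chicken erythrocytes) and the sample. With $M$ and $N$ the 2C peak
mean fluorescences of standard and sample, the sample's 2C content is
$Y = (N/M)\,X$ and its genome size is $0.978 \times 10^9$ bp per pg applied
to the 1C value $Y/2$. Two conventions deserve note, both configurable:

* **Reference constant.** The chicken-erythrocyte standard is taken as
  $X = 2.5$ pg. Sources citing this standard sometimes print "25 pg", but
  every published table we reproduce back-calculates row by row to 2.5 pg;
  the constant lives in `reference_standard()` and can be replaced.
* **1C conversion.** The bp-per-pg equation is applied to the 1C content
  (half the 2C estimate); this is what reproduces the published per-replicate
  genome sizes exactly (e.g. $M = 14.9$, $N = 10.6$ gives
  $(N/M) \cdot 2.5/2 \cdot 978 = 869.70$ Mb).
* **Peak identity.** In a mixed run the lower-mean 2C peak is assigned to
  the sample by default (`sample_is_lower = TRUE`), appropriate for a
  species smaller than its standard; the flag flips the assignment.

## Peak detection

The interactive gating of flow-cytometry practice is reimplemented as a
deterministic procedure in `detect_2c_peaks()`:

1. bin the events (default 1024 bins over $[0, \max]$) and smooth the counts
   with a Gaussian kernel (bandwidth 3 bins);
2. take local maxima of the smoothed histogram with topographic prominence
   of at least 5% of the tallest count, ignoring maxima in the lowest 10% of
   the range (debris);
3. discard a candidate as a G2/doublet population if its mode lies within 5%
   of twice another candidate's mode *and* its nearby event count is below
   half the other's. The area margin matters: a true doublet population is a
   small fraction of its parent peak, whereas two genuine 2C peaks can sit
   at an exact 2:1 ratio (a sample at half the standard's fluorescence), and
   an unqualified "smaller area" rule would discard one of them;
4. for each retained peak, estimate the peak SD from the full width at half
   maximum of the smoothed histogram (flank descent stops at a valley so an
   overlapping neighbour is never climbed through), and derive two windows:
   a narrow mean window of ±3 smoothing bandwidths around the mode, and a
   wide QC window of ±4 estimated SDs capped at the midpoint towards any
   neighbouring peak.

The reported peak mean is the event mean inside the narrow window — robust
to debris tails and to overlap from a neighbouring peak, and unbiased for a
symmetric peak — while the CV and event count use the wide window, which
covers essentially the whole peak. CVs above 5% (the conventional
reliability limit for DNA content work) set a QC flag; estimates are flagged
rather than suppressed, since acquisitions are adjusted, not discarded, in
practice. Simulation places the recovered ratio within 1% bias and 2% SD
across ratios 0.5–0.9, CVs 2–4%, debris up to 20% and doublets up to 5%.

## Synthetic data

`simulate_arm_measurements()` emulates measured metaphase spreads: every arm
of every chromosome carries independent lognormal noise of a configurable CV
(unit mean), and all arms of a cell share a lognormal condensation factor,
since chromosome condensation rescales a whole spread multiplicatively.
Labels are shuffled within cells so pairing must be recovered. Telocentric
short arms stay exactly zero. Defaults follow the bundled study's
conditions: 5 cells, 2% measurement noise, and a 5% cell-scale SD as a
realistic between-spread condensation spread.

`simulate_flow_events()` draws the canonical components of a PI-stained DNA
histogram: two Gaussian 2C peaks (standard at 500 a.u. by default, sample at
`ratio` times that, default 0.74; CVs default 3%, within the < 5% QC
regime), doublets at twice each 2C mean with $\sqrt 2$-scaled SD, and debris
from an exponential (scale one third of the smaller 2C mean) truncated below
that mean. Debris defaults to 10% and doublets to 2% of events, typical of
a clean acquisition. Both generators are pure functions of their
configuration and seed.

What the generators deliberately do not model: optics and staining
chemistry, the S-phase continuum between 2C and 4C, spectral compensation,
and for karyotypes any non-multiplicative measurement error or segmentation
mistakes (split/merged chromosomes). Passing the recovery tests therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to every artefact of real micrographs or cytometers.

## Numerical and degenerate-input choices

* Infinite arm ratios are explicit `Inf` sentinels; every comparison
  ($AR > 2$, $AR \ge 7$) treats them as larger than any finite value.
* Report tables round to 2 decimals for lengths and ratios and 1 decimal
  for whole-karyotype percentages, matching the precision of published
  tables; all internal computation is at full precision.
* Equal-cost matchings are resolved deterministically by input order.
* `karyotype()` requires an even chromosome count per cell (spread input);
  a per-pair table may have any number of rows.
* SVG output (idiograms, asymmetry scatter) is written by a small
  deterministic generator, so re-rendering a model is byte-identical — a
  property the test suite checks — and files carry no timestamps or
  device-dependent identifiers.

## Problem sizes in the test suite

The suite validates the pipelines at deliberately modest sizes, chosen to
exercise every code path with comfortable statistical margins: flow
simulations use $10^4$ events per replicate (20 seeds per ratio for the
recovery study; one $10^5$-event run for convergence checks), karyotype
simulations use 5 cells of 30 chromosomes, and pairing optimality is
enumerated exhaustively up to 12 chromosomes (10 395 matchings) over 200
random instances.

## Known limitations

* Arm measurements must already exist; the package does not segment or
  measure chromosomes in micrographs, and finds no satellites or secondary
  constrictions.
* Event input is CSV (one intensity per event); binary cytometer formats
  are not parsed.
* The cross-taxa comparison stores published summaries as printed — two of
  the compiled literature rows are internally inconsistent (a formula that
  does not sum to its 2n; an FN irreconcilable with its biarmed count) and
  are deliberately not corrected.
* Cell-cycle modelling beyond 2C peaks (S-phase, ploidy series) is out of
  scope.

## A worked example

```{r example}
k <- karyotype(urechis_arms(), input = "pairs")
k

gs <- genome_size(peak_means = urechis_flow_peaks())
gs
```
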
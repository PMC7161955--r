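---
title: "Scoring IES retention from junction-spanning reads: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring IES retention from junction-spanning reads: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological setting

In *Paramecium tetraurelia*, a new somatic macronucleus (MAC) develops from
the germline micronucleus at every sexual cycle. During that development,
tens of thousands of short, single-copy, non-coding Internal Eliminated
Sequences (IESs) are excised precisely from the genome. Every IES is bounded
by a TA dinucleotide at each end and excision leaves exactly one TA behind,
so the germline and somatic genomes differ by the presence or absence of the
IES at each locus. When the excision machinery is depleted (an RNAi
knockdown of one of its subunits), IESs stay in the new MAC genome, and the
failure can be read out genome-wide by sequencing whole-cell DNA at the end
of development.

`iesret` implements that readout as a self-contained, testable pipeline:

1. a **synthetic-data module** that generates MAC/germline genome pairs,
   per-IES retention truths and paired-end reads;
2. a **retention-scoring module** that classifies junction-spanning read
   pairs as IES+ (retention) or IES- (excision), computes per-IES apparent
   retention scores, and calls significantly retained IESs against a control
   condition;
3. a **feature-enrichment module** that characterizes a retained set against
   the IES universe (length peaks, neighbor-density enrichment, matched
   random-sampling nulls, replicate overlap and correlation);
4. **IO and orchestration**: FASTA/GFF3/FASTQ/TSV/YAML readers and writers,
   an end-to-end scenario runner, and a thin command-line wrapper
   (`inst/scripts/iesret`).

## The genome model

An IES inserted at MAC offset `p` (0-based) is stored as a germline sequence
that itself starts with `TA`, while the MAC carries its own `TA` at
`[p, p + 2)`:

```
germline = MAC[0:p] + IES + MAC[p:]        with  MAC[p:p+2] == "TA"
```

This makes both halves of the biology unambiguous: the IES is flanked by a
TA at each end (its own leading TA, and the MAC TA that follows it), and
excision - deletion of the IES sequence - leaves exactly one TA at the
junction. It also gives an exact round trip, which the test suite exercises
over a hundred random genomes: removing every annotated IES from the
germline reproduces the MAC byte for byte.

Internally all coordinates are 0-based half-open; GFF3 output converts to
1-based inclusive. Annotations are written in germline coordinates (the IES
is an interval there); the MAC insertion point is recovered on read as the
germline start minus the cumulative length of the preceding IESs on the
replicon.

## What the generator emulates, and what it does not

Defaults of `simulation_config()` are a scaled-down *P. tetraurelia*-like
genome, fixed once:

* **Scale**: 2 replicons of 250 kb carrying 500 IESs. The real genome has
  ~45,000 IESs across ~72 Mb; we keep the IES count per scenario in the
  hundreds so that every stage (including the brute-force test oracles) runs
  in seconds to minutes on a laptop, and accept a ~3x higher background IES
  density than the real genome.
* **Composition**: GC content 0.28 - the genome is strongly AT-rich.
* **IES lengths**: drawn from a mixture over periodic size-peak bins; the
  first peak spans 26-30 bp and later bins advance by 10 bp. Outside dense
  regions the peak weights are (0.25, 0.30, 0.25, 0.20). Only the first peak
  and its dominance are well constrained by observation; the weights beyond
  it are placeholders and configurable.
* **Spatial clustering**: a quarter of IESs (`cluster_fraction = 0.25`) are
  placed inside 8 designated dense regions of 3 kb, producing neighbor
  densities of roughly 5-12 within the 1-kb window against a background of
  0-4. Dense-region IESs draw their lengths from a mildly short-biased
  weight vector (0.50, 0.25, 0.15, 0.10). With these two vectors the
  universe first-peak fraction lands near 0.31 - matching the ~30% reported
  for the full IES complement - while dense regions are visibly enriched for
  short IESs. The bias is deliberately mild: dense regions contribute only a
  minority of all short IESs, so a *length*-matched random sample is only
  weakly density-enriched, whereas a *density*-matched sample is clearly
  shorter than the universe. Both directions are asserted in the acceptance
  tests.
* **Sequencing**: error-free 2x100 nt read pairs with a fixed 300 bp insert.
  Real libraries were 2x75-100 nt at 76-160X with variable inserts; a
  constant insert changes nothing for a count-based analysis and makes the
  fragment-position enumeration oracle exact. Sequencing error, base
  qualities, duplicates and mapping ambiguity are out of scope - errors
  would only thin the counts.
* **The old/new MAC mixture**: whole-cell DNA at late development contains
  the new developing MAC together with fragments of the maternal (old) MAC,
  which never contain IESs. A fraction `rho` of fragments is drawn from
  new-MAC molecules (each IES locus independently retained with its own
  probability `r_i`); the rest from the old MAC. The default `rho = 0.5`
  represents a roughly balanced whole-cell extract; smaller values emulate
  stronger old-MAC dominance (with complete retention and `rho = 0.15`, the
  expected apparent score is 0.15, the regime in which a fully retained
  genome still shows a low mean score).

Not modelled: transposon/minisatellite elimination, imprecise elimination
and chromosome fragmentation, excised-IES circles and concatemers,
polyploidy-resolved copy numbers, correlated excision of neighboring IESs
(excision states are independent per fragment and per locus), and
sequencing error. Consequently, passing tests demonstrate the correctness
and calibration of the counting and statistics on this idealized mixture -
not robustness to mapping artifacts or library chemistry.

## Read classification

Classification is by exact junction-probe matching rather than external
alignment, so the contract is deterministic and self-contained. For each IES
the library holds one excised-junction probe (MAC window centered on the
junction TA) and two germline boundary probes. A read pair votes:

* **IES-** for IES *i* if either mate (or its reverse complement) contains a
  contiguous exact match spanning the junction TA with at least `m` bases on
  each side (`m = min_overlap`, default 10 bp);
* **IES+** if a mate similarly spans either germline boundary.

Votes are resolved per pair: at most one vote per pair per IES; the two
IES+ boundaries pool into a single vote; a sign conflict at the same IES
(both IES+ and IES- evidence, impossible for error-free reads from a single
template) discards that IES's votes and is logged as ambiguous. Votes for
*different* IESs from the same pair all count: in IES-dense regions a
sizeable share of pairs legitimately spans two junctions (one per mate,
~300 bp apart), and discarding such pairs would systematically under-cover
exactly the dense subset that the feature analysis studies.

The default `m = 10` makes the matched cores 20-22 nt, long enough that a
chance match in a random genome of the simulated sizes is vanishingly rare;
`flank_k` defaults to one read length so the stored probes cover everything
a read could span. Probe cores truncated by a replicon end are flagged
unusable; identical cores between IESs are flagged as collisions.

The implementation matches reads against the probe cores with
`Biostrings::PDict`; the test suite pins it, instance by instance, to a
brute-force substring-scan oracle written independently with `grepl`.

## Scores, the dilution model, and the estimator

The apparent retention score of an IES is

```
IRS_app = ies_plus / (ies_plus + ies_minus)
```

undefined (`NA`) when no junction-spanning pair was seen. Because old-MAC
material is always IES-, the score is a *diluted* readout of retention: in
the limit where IES+ and IES- molecules are equally likely to yield a
classifiable pair, `E[IRS_app] = rho * r`, inverted by
`r_hat = min(1, irs / rho)`.

That limit is not exact here. A retained molecule exposes two boundary
windows while an excised molecule exposes one junction window, so the IES+
vote catchment (number of fragment positions yielding a vote) exceeds the
IES- catchment - by a factor of about 1.4 for a first-peak IES at 2x100 nt
reads, where the two boundary windows merge within a single read.
`vote_catchment()` enumerates both catchments exactly for any geometry, and
`estimate_retention()` inverts the exact expectation

```
E[IRS_app] = k * rho * r / (k * rho * r + 1 - rho * r),   k = c_plus / c_minus
```

per IES length. The tests verify the enumeration against an independent
template-based oracle and the estimator against planted truths; with the
naive `irs / rho` inversion the catchment bias alone would exceed the
accepted recovery error for mid-range `r`.

## Significance calling

Per IES, a one-sided Fisher exact test asks whether the IES+ proportion in
the case exceeds the control's, on the 2x2 table of
(`ies_plus`, `ies_minus`) counts, followed by Benjamini-Hochberg correction
across all tested IESs; `significant` means `q <= alpha` (default 0.05).
IESs with fewer than `min_reads = 10` junction-spanning pairs in either
condition are left untested rather than called. The exact test was chosen
as the simplest contract for count data of this size; it is deliberately
conservative at low counts, which the null-calibration test quantifies
(case and control simulated from the identical truth: the mean
false-discovery proportion over replicate pairs stays below `alpha + 0.02`).

## Feature analysis

* **Neighbor density**: the number of other IESs whose MAC insertion point
  lies strictly within 1 kb on either side, on the same replicon. Density is
  computed on MAC coordinates between insertion points; the alternative
  (germline coordinates, or edge-to-edge distances) would shift counts
  slightly but identically for retained set and universe.
* **Enrichment index**: IESs are binned into density classes 0..7 and
  ">=8"; `EI = log2(f_retained / f_universe)` per class, undefined (not
  +/-Inf) when either fraction is zero - such classes are excluded from
  monotonicity statements.
* **Length statistics**: the first-peak fraction (share of lengths in
  [26, 30]) and the empirical cumulative distribution, optionally restricted
  to IESs shorter than 150 bp.
* **Matched random samples**: drawn without replacement from the universe,
  stratified on exact length in bp or exact neighbor-density count - IES
  lengths and densities are small integers, so exact matching is feasible
  and the strongest possible control. Per stratum the sample takes
  `min(requested, available)` members, so a sample can be slightly smaller
  than its reference when the universe runs short in a stratum - the natural
  behavior for a without-replacement null.
* **Replicates**: overlap fractions of significant sets and Spearman rank
  correlation of scores on the IESs with defined scores in both replicates
  (at least 3 required).

## Numerical and design choices

* Fragment count is `round(coverage * mac_length / (2 * read_length))`;
  replicons are chosen proportionally to MAC length; fragment starts are
  uniform on each realized molecule. The inner loop (realizing per-fragment
  retention states and splicing the molecule) is compiled C++ driven by R's
  RNG, so a single `rng_seed` reproduces FASTA/FASTQ bytes exactly.
* One master seed per pipeline run derives a named sub-seed per stage
  (`derive_seed()`), so whole runs are reproducible from one integer and
  stages can be re-run independently.
* Undefined scores are excluded from distributions, correlations and tests
  and written as `NA`.
* Every TSV/GFF3/YAML output carries `#` header comments with the tool
  version, a configuration hash and the seeds; FASTA/FASTQ have no comment
  syntax, so their provenance lives in the sidecar `run_info.txt`.
* Scenario sizes used by the tests and the acceptance script (500 IESs at
  25-100X; 20 five-kb instances for the counting oracle; 8-20 replicate
  pairs for calibration) were chosen once, by a power analysis of the
  estimator's sampling noise at those depths, to keep the whole suite at
  desk scale.

## Known limitations

* The classifier requires exact matches; real data would need the
  alignment-based front end (a SAM passthrough is sketched in the interface
  but intentionally not implemented).
* Apparent scores depend on `rho`, which in real whole-cell extracts is
  unknown and condition-dependent; `estimate_retention()` treats it as
  given.
* Partial-excision boundary heterogeneity and IES-excision by-products are
  not represented; both would add read classes the current vote rules would
  leave unassigned.
* With hundreds (not tens of thousands) of IESs per scenario, q-value
  granularity and class occupancy are coarser than in the genome-scale
  setting; the acceptance checks are therefore formulated as properties and
  directions rather than genome-scale magnitudes.
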
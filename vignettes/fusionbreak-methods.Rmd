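---
title: "Methods and modeling choices in fusionbreak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in fusionbreak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionbreak)
```

## The biological setting

The t(1;19)(q23;p13) translocation fuses *TCF3* (chromosome 19, minus
strand) to *PBX1* (chromosome 1) and defines a well-known subgroup of
B-precursor acute lymphoblastic leukemia. Because the predominant fusion
transcript joins *TCF3* exon 16 to *PBX1* exon 3, the genomic breaks must
fall in *TCF3* intron 16 (3289 bp, chr19:1,615,822-1,619,110, GRCh38) and
*PBX1* intron 2 (229,182 bp, chr1:164,563,312-164,792,493). fusionbreak
packages the computational machinery for working with a cohort of such
breakpoints: cluster statistics, annotation overlap, in silico long
range-inverse PCR (LRI PCR), junction repair characterization,
breakpoint-specific qPCR for measurable residual disease (MRD), and a
synthetic derivative-chromosome generator that ties everything together in
round-trip tests.

The packaged catalog (`load_catalog()`) holds 49 adult patients in long
format: one row per break event, 64 on the TCF3 side and 65 on the PBX1
side (one patient carries a 788 bp inversion and therefore two PBX1
breaks; 15 patients additionally have a characterized reciprocal
PBX1::TCF3 junction).

## Coordinates

All catalog coordinates are 1-based, inclusive, intron-relative, in the
orientation of the source table. The source does not state which intron
end is position 1, and TCF3 is transcribed from the chromosome 19 minus
strand, so `intron_to_genomic()` offers both a plus-anchored (position 1 =
lowest genomic coordinate; the default) and a minus-anchored mapping. Both
are bijections of the intron, the BED export records which was used, and
`genomic_to_intron()` inverts either. Nothing downstream depends on the
choice.

## Cluster statistics

The TCF3-side hotspot is found by **sliding-window maximization**
(`max_coverage_window()`), not hard-coded bounds: no window coordinates
are published, only the window width (40 bp) and its occupancy. Only
windows whose left edge coincides with an observed position need to be
scanned; ties are resolved toward the smallest such start. On the packaged
catalog the best 40 bp window holds 53 of 64 breaks (41 of them in
TCF3::PBX1 orientation).

The two PBX1 clusters are published only approximately ("~220 to 229 kb",
"~120 to ~155 kb"). The operational bounds shipped in
`pbx1_cluster_regions()` — [220000, 229182] and [119000, 155100] — are
configuration values chosen because they reproduce every published
membership count (24 = 16+8, 33 = 27+6, 8 = 7+1); they are not claimed to
be the true cluster boundaries. (The source also states the clusters
"comprised 34 kb" although the stated bounds span ~45 kb; we report the
counts, and do not use the 34 kb figure.)

Percentages use **half-away-from-zero rounding** (`percent()`), which
reproduces every published percentage (83%, 37/51/12%, 88%, 7.7%, 22.6%)
from the corresponding counts.

`max_gap_clusters()` (single-linkage clustering with a spacing threshold)
is provided as an exploratory alternative; it is not used for any
published figure.

## Annotation overlap

Breaks are classified against interval tracks (`repeat`, `cRSS`, ...) as
`inside`, `vicinity` or `outside`. The vicinity rule is ±30 bp, the
convention used for cryptic recombination-signal-sequence (cRSS) sites.
The looser repeat-side statement "in or immediately 3′ of" is expressed
with an asymmetric vicinity (`vicinity_5p = 0`, `vicinity_3p`
configurable, default 30): "immediately" is never quantified in the
source, so the 3′ allowance is an explicit parameter rather than a hidden
constant. Track files may be 1-based TSV (matching the catalog
convention) or strict BED (converted on read). `track_coverage()` merges
intervals before counting, so duplicated or overlapping annotations never
inflate coverage.

The cRSS and repeat tracks themselves come from external annotation tools
(RepeatMasker, Tandem repeats finder, RSSSite) and are consumed as files;
the package deliberately does not reimplement those tools. Published
overlap fractions whose underlying tracks are unavailable are checked as
arithmetic (count → percentage), not as end-to-end track computations.

## In silico LRI PCR

The LRI PCR workflow — digest genomic DNA, self-ligate the fragments into
circles, amplify outward across the ligation junction — is simulated
deterministically:

* `digest()` places cuts `cut_offset_top` bases into each site occurrence
  (IUPAC-aware). A linear molecule with *n* cuts yields *n*+1 fragments, a
  circle *n*; fragment lengths always sum to the parent length. Partial
  digestion, methylation sensitivity and ligation efficiency are not
  modeled.
* `inverse_pcr_product()` requires the forward primer once on the plus
  strand, the reverse primer once on the minus strand, in divergent
  orientation on the linear fragment; the product size counts the bases on
  the circular path from the forward primer's 5′ base through the ligation
  junction to the reverse primer's 5′ base, inclusive. The size is
  invariant under rotation of the circle's linearization point (tested).
  Primer annealing is exact full-length matching; the assay's primers are
  26-31-mers, and mismatch tolerance is out of scope.
* `screen_enzymes()` encodes the published enzyme-selection criteria:
  palindromic site, no degenerate bases, sticky ends, frequent cutter
  (recognition ≤ 6 bp, admitting the 4-cutter TaqI), and flanking sites
  leaving the region on a fragment within the maximum amplifiable size
  (default 10 kb; the largest validated control band is 7567 bp).
* `breakpoint_detectability()` states when a junction is invisible to an
  enzyme: the fragment carrying both primers must also carry the junction
  and circularize, and the product must stay within the size cap. This
  reproduces, e.g., why an enzyme cutting between the primer region and
  the intron end misses breakpoints near the intron end.

The shipped enzyme database writes BamHI as canonical `G|GATCC`; the
source prints "G|GACC", which is not a BamHI site and is treated as a
typographical error (noted in the database file).

### The synthetic control-band reference

The published control bands (normal-DNA inverse-PCR products) are fixed by
the local restriction map and primer positions on GRCh38. This package
cannot ship or download genomic sequence in its test environment, so
`synthetic_tcf3_region()` builds a **synthetic stand-in**: a deterministic
13.5 kb sequence with the five LRI primers planted once each and one
SphI/BamHI/TaqI site planted on each side of the primer block at distances
derived from the six published band sizes. The layout is well determined
because the three per-enzyme F2-F6 band differences are all exactly
1177 bp. All accidental site occurrences are scrubbed. Digesting,
circularizing and amplifying this sequence through the normal code path
reproduces 3308, 2131, 5026, 3849, 7567 and 6390 bp. What this does *not*
establish is agreement with the real GRCh38 restriction map; it
establishes that the simulator's geometry, size arithmetic and orientation
handling are exactly consistent with the published band sizes.

## Junction characterization

`characterize_junction()` uses the standard prefix/suffix decomposition.
With `x` the longest common prefix of (derivative, donor) and `y` the
longest common suffix of (derivative, acceptor):

* if `x + y >= L` the junction carries `mh = x + y - L` bases of
  microhomology — sequence attributable to either parent — and the
  breakpoint is reported as a coordinate **range** of width `mh`
  (downstream tables use the 5′-most donor coordinate; the tie-break is
  documented on the function);
* otherwise the intervening bases are an insertion and microhomology is 0.
  The two are mutually exclusive by construction.

Inserted sequence of at least `min_len` (default 10 bp) is classified
`inverted-segment` if its reverse complement occurs contiguously in either
parent (the observed 788 bp PBX1 inversion is this class), `foreign` if it
occurs in a supplied foreign-sequence database (the observed FGF6 capture),
and `non-template` otherwise. Below `min_len` everything is `non-template`:
short matches arise by chance (a random 8-mer hits a 229 kb intron with
probability ~1). Matching is exact; junctions in this setting are
Sanger-validated, so sequencing-error tolerance is out of scope.

## qPCR

The MRD assay uses a fixed forward primer (`TCF3-qF`) and dual-labeled
probe (`TCF3-FAM`) 5′ of the TCF3 hotspot plus a patient-specific reverse
primer 3′ of the junction. `fit_standard_curve()` is ordinary least
squares of Ct on log10 concentration; `r_squared` is the squared Pearson
correlation, and efficiency is `10^(-1/slope) - 1`. Four-point curves
(one published assay lacks its last dilution) are accepted.

The published table of 15 assays ships as a fixture with the printed
values; raw Cts were not published, so slopes are inputs and only the
slope → efficiency closed form is recomputed. Fourteen of the 15 printed
efficiencies reproduce exactly at 3 decimals; patient 7979's printed
1.035 is inconsistent with its own printed slope (−3.242 gives 1.0345 →
1.034) and is asserted as computed, with the discrepancy documented.

`design_reverse_primer()` enumerates candidates 3′ of the junction under
length 18-30, nearest-neighbor Tm 58-62 °C and amplicon ≤ 300 bp defaults
(the source gives no design constraints; these are conventional qPCR
values and fully configurable). **Specificity is enforced at assay
level**: the fixed-forward/candidate pair must predict no product within
the amplicon cap on either unrearranged reference. A literal "candidate
has no binding site in any reference" rule would reject every primer
sited 3′ of the junction — such a primer is, by construction, acceptor
intron sequence — while the biological requirement is that *normal DNA
must not amplify*, which needs both primers on one template. This is the
one place where the package's contract deliberately refines the obvious
reading of its requirements document.

Melting temperatures use unified nearest-neighbor thermodynamics
(Allawi-SantaLucia parameters) with entropic salt correction
(`0.368·(N−1)·ln[Na+]`), 250 nM primer and 50 mM monovalent salt by
default; values agree with an independent reference implementation to
<0.01 °C on frozen test oligos. The Wallace 2+4 rule is available for
rough screening.

## The synthetic cohort generator

`simulate_cohort()` emits derivative chromosomes with the statistical
structure the analysis assumes, plus a truth table. The **stated world**
is:

* TCF3-side positions: 83% uniform in a 40 bp hotspot (positions
  1163-1202, the window found on the real catalog), 17% uniform elsewhere
  in the 3289 bp intron.
* PBX1-side positions: 37% / 51% / 12% across the intron-end cluster, the
  mid-intron cluster, and the remainder — the published fractions, shipped
  as configuration.
* Junctions: microhomology length distribution P(0)=0.7, P(1)=0.15,
  P(2)=0.10, P(3)=0.05 (the source says only "mostly no microhomologies";
  this categorical is an explicit assumption), non-template insertion with
  probability 0.5 given zero microhomology ("frequent"), geometric
  insert lengths (p=0.35, mean ~2.9 bp), inversion probability 0.02 with
  the observed 788 bp length, foreign-capture probability 0.02, and a
  reciprocal derivative with probability 15/49.
* Scaled mode (default) shrinks PBX1 intron 2 to 20 kb (1:11.5, cluster
  bounds scaled proportionally) so tests run in seconds; full-length mode
  is available.

Junction flanks are constrained during construction (by resampling, or
for non-template inserts by adjusting the first inserted base) so the
planted truth is *exactly* recoverable: accidental extension of the
prefix/suffix matches past the planted break is excluded, and non-template
inserts of ≥ 10 bp are rejected if they occur (directly or
reverse-complemented) in either reference. Templated inserts are never
mutated. This is what makes the acceptance round trip — 1000 simulated
fusions, 100% exact recovery of breakpoints, microhomology, insert and
class — a sharp test of `characterize_junction()` rather than a
statistical one.

What the generator does **not** emulate: sequencing reads or errors (the
real junctions are Sanger-validated assemblies), real intron sequence
composition (references are i.i.d. with configurable GC), repeats, or any
correlation between breakpoint position and junction chemistry. A green
round trip therefore validates the calling algebra and the simulator's
bookkeeping, not performance on real chromatograms.

All randomness flows through explicit `seed` arguments; RNG state is
saved and restored, so library calls never perturb a session's stream.

## Numerical and degenerate-input choices

* Rounding of reported percentages: half away from zero, at the stated
  number of decimals.
* Median age: midpoint convention (`stats::median`). The catalog's 49 ages
  give 40; the source text prints 39.5, which no odd-count convention can
  produce — the summary reports what the table yields.
* Ambiguously printed catalog cells are transcribed with the parse that
  reproduces all published totals and flagged in the fixture's `note`
  column (sample 3951's concatenated positions admit two parses; both
  leave every published count unchanged).
* `max_coverage_window` ties → smallest position-anchored start;
  `count_in_regions` requires non-overlapping regions and validates this.
* Empty inputs fail loudly (`empty catalog`, `positions must be
  non-empty`); a digest of a site-free sequence returns the molecule
  itself; a circular digest with one site returns one full-length linear
  fragment.

## Known limitations

* The in-silico assay is deterministic and ignores PCR kinetics, partial
  digestion and ligation efficiency; per-enzyme *yield* statistics from
  the wet lab (26/12/11 breakpoints identified per enzyme) are therefore
  out of reach by design.
* Control-band agreement is demonstrated against the geometry-faithful
  synthetic region, not against GRCh38 itself (see above).
* The per-patient qPCR sensitivities are wet-lab outcomes and are not
  simulated; only the standard-curve arithmetic is reproduced.
* Annotation-overlap conclusions depend entirely on the supplied tracks;
  the package ships none beyond test fixtures.
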
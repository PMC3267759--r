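---
title: "Methods: small-RNA discovery and expression profiling with carpmiR"
author: "carpmiR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA discovery and expression profiling with carpmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpmiR)
```

# Scope

carpmiR re-implements, as a tested and reusable pipeline, the standard
bioinformatic workflow for miRNA discovery from a single small-RNA
sequencing library of common carp (*Cyprinus carpio*) skeletal muscle:
read cleaning, collapsing to unique sequences, annotation and removal of
rRNA/tRNA/snRNA/snoRNA contaminants, exact genome mapping, identification
of conserved miRNAs against a mature catalog with isomiR clustering,
hairpin-based prediction of novel miRNAs, cross-species conservation
partitioning, and 2^-ddCt qPCR expression profiling. Because the original
sequencing run was never deposited in a public archive, the package ships
a synthetic-data generator that emulates the statistical structure the
pipeline assumes, together with a ground-truth manifest, so that every
stage can be exercised end to end and recovery can be measured exactly.
The published result tables (7 novel miRNAs, 31 teleost-only miRNAs, 16
muscle-related miRNAs) are shipped verbatim as checksummed fixtures and
anchor the worked examples.

# Read cleaning and collapsing

`cleanReads()` applies six filters in a fixed order, each read stopping at
the first rule it violates: low mean Phred quality (default threshold 20),
5'-adapter pollution (the read begins with at least 10 nt of the 5'
adapter), absence of a 3' adapter, empty insert, poly(A) insert (at least
80% A or a run of 10 A), and inserts shorter than 18 nt. The source
protocol lists these discard reasons without an order; fixing the order
makes the per-reason report deterministic, which the tests rely on. The 3'
adapter is located as the leftmost ungapped match with at least 8 nt of
overlap and at most 10% mismatches in the overlap — the same convention as
common adapter trimmers. Thresholds are exposed in `cleanParams()`; none
of them is dictated by the original study, which reported only the
categories. The retained insert window is 18-30 nt, the gel-purification
window of small-RNA library preparation.

`collapseReads()` produces one record per distinct insert with its read
count, sorted by descending count with lexicographic tie-breaks, so the
operation is order-independent and idempotent. Sequences are stored as RNA
(U) internally; DNA (T) appears only at I/O boundaries.

# Annotation and mapping

Reads of 18-30 nt make alignment heuristics unnecessary, so both
annotation and mapping are exact and fully verifiable. A unique read is
annotated as ncRNA if and only if it is a sense-strand substring of a
reference record, with the class priority rRNA > tRNA > snRNA > snoRNA on
multiple hits; annotated reads leave the analysis. Mapping uses a k-mer
index (default k = 12) over the plus strand; candidate loci are verified
by direct substring comparison, minus-strand queries are resolved by
reverse complementation, and only full-length zero-mismatch matches are
reported ("perfect" matches), up to a configurable cap of 20 loci per
read. Mismatch tolerance is deliberately absent: the workflow this package
models kept only perfectly mapped reads. Whether multi-mapped reads should
enter miRNA prediction is not settled in the source narrative;
keep-with-cap is this package's documented choice.

# Conserved miRNA identification and isomiR clustering

Unannotated reads of 18-23 nt are searched against a mature catalog
(miRBase-style FASTA or TSV; the package ships the published tables as a
small fixture catalog, and users can point to a full miRBase mature file).
A read matches an entry when the seed (positions 2-8) is identical, the
end-length difference is at most 5 nt, and at most 2 substitutions
separate them over the shared prefix; the best match minimizes total
edits, with catalog order breaking ties.

"Sequence similarity" for clustering is not defined quantitatively in the
source; carpmiR operationalizes it from the reported observation that
category members differ in length by 1-5 nt: two reads are compatible when
their seeds are identical, their end-length difference is at most 5 nt,
and at most one internal substitution separates them. Equal-length
variants (0 nt difference, one substitution) are also allowed to cluster,
since identical sequences were already merged by collapsing and a
same-length single-edit variant is as much an isomiR as a 1 nt trim.
Categories are single-linkage components under this predicate — the
natural closure of "differs by a small end offset" — and are therefore
invariant to input order, which the test suite asserts by permutation. The
representative is the member with the highest read count (ties:
lexicographically smallest sequence), mirroring the published rule that
the highest-read sequence represents its category.

# Conservation partitioning

Conservation is mature-sequence presence only: a category is "present" in
a species when that species' catalog holds a mature matching the
representative under the same seed-identical predicate. Classes are:
`pan_bilaterian` (an invertebrate and a mammal), `vertebrate_conserved`
(all of frog, zebrafish, chicken, mouse, human), `teleost_only` (non-empty
presence confined to the six teleost catalogs), and `carp_specific`
(empty). These four do not exhaust all combinations — a miRNA present in,
say, zebrafish and human only is none of them — so a fifth class,
`partially_conserved`, closes the partition; the tests check mutual
exclusivity and exhaustiveness. Whether the original "conserved in all
vertebrate models" count required exact sequence identity or seed identity
is unstated; the predicate here (seed-identical, small end offsets, at
most 2 substitutions) is a documented choice.

# RNA folding and novel miRNA prediction

## Energy model

`foldMFE()` computes the minimum-free-energy nested structure (Watson-
Crick and G-U pairs, hairpin loops of at least 3 nt, no pseudoknots) by a
Zuker-style dynamic program with an interior-loop size bound of 30 nt,
implemented in C++. The energy model is intentionally simple and fully
documented in `foldParams()`: a stack of two pairs contributes minus the
sum of per-pair strengths (G-C 1.6, A-U 0.55, G-U 0.25 kcal/mol), loop
penalties are affine in loop size, and multiloops are affine in unpaired
bases and branches. The parameters were calibrated once to the Turner
kcal/mol scale by comparison with an independent thermodynamic folder on
random sequences (random 65-mers average roughly -9 kcal/mol here versus
roughly -12 by full Turner tables; strong planted hairpins agree within a
few kcal/mol), so that the Mireap-style acceptance threshold of -18
kcal/mol sits on the scale it assumes. A full Turner table can be dropped
into `foldParams()` without code changes.

Correctness is established in two independent ways: for all sequences up
to 16 nt the dynamic program is checked against exhaustive enumeration of
every nested structure, each scored by `structureEnergy()`, a direct
scorer written separately from the DP; and every emitted structure is
re-scored to match its reported energy. Tie-breaking in the traceback is
deterministic (5'-most inner pair, helix extension preferred over loop
closure), so folding is reproducible bit for bit.

## Pre-miRNA criteria

`hairpinCriteria()` reports six independent rules: a single stem-loop;
folding energy at most -18 kcal/mol; the mature entirely on one arm with
at least 14 of its bases paired and no unpaired run longer than 4 nt; a
Dicer-plausible geometry (the mature 5' end paired on the stem and the 3'
end within 2 nt of a paired position — a proxy for the 2 nt 3'-overhang
duplex); precursor length 55-120 nt; and mature length 18-23 nt with a
read count of at least 5. The count threshold leaves margin below the
smallest published novel-miRNA frequency (8). The window sizes (20 nt
upstream / 120 nt downstream and the reverse) and the energy threshold
follow common Mireap-style defaults, since the original study names the
tools but no parameters.

## Prediction

For each mapped locus of each candidate read, both windows are folded; the
stem-loop containing the read is excised by walking outward from the
hairpin loop nearest the read through stacked and interior pairs (stopping
at a multiloop or the exterior), refolded, and tested against all six
rules. Candidates with overlapping precursor loci merge into a single
precursor — ignoring strand, because a near-palindromic stem maps its
mature to both strands of the same locus and is one physical hairpin — and
the highest-count read becomes the mature. Names are assigned in
descending count order in the pattern `CM1-mNNNN_5p/_3p`. The original
study additionally screened candidates against carp ESTs; here the genomic
window search is the sole mechanism, a documented divergence since those
ESTs are not available as a reusable input.

# Expression profiling

`deltaDeltaCt()` implements pure 2^-ddCt quantification against an
endogenous reference (U6 by convention) with amplification efficiency
fixed at 2.0 — no standard-curve correction, which is a documented
limitation. Folds are invariant to constant Ct shifts, and the calibrator
group's fold is identically 1 by construction, not merely close to it.
The SEM is computed over per-replicate folds rather than on the ddCt
scale, matching a mean ± SEM bar-chart presentation; the source does not
state which scale it used. Significance across groups uses a classic
one-way ANOVA (between/within mean squares, p from the F distribution);
degenerate tables (zero within-group variance with unequal means) yield an
infinite F with p = 0 and an explicit flag. `tissueSpecificity()` makes
the semi-quantitative gel patterns quantitative: a miRNA is specific to
the tissue set within `tau` (default 0.25) of its row maximum if that set
has at most 4 tissues — the breadth of a muscle/heart/gut/eye pattern —
otherwise ubiquitous. The threshold is explicit because no numeric rule
was ever printed.

# The synthetic study

`simulationConfig()` defaults define the simulated study conditions:

* 20 planted hairpins in a 50 kb uniform-random genome (at least 200 nt of
  genome per hairpin), half on each strand, at non-overlapping loci;
* 100,000 reads of 44 nt: 80% miRNA-origin, 8% ncRNA contaminants, 12%
  junk split over adapter dimers, poly(A) inserts, short inserts,
  adapter-less reads, 5'-adapter pollution and low-quality reads;
* matures of 22 nt with 3'-end isomiR offsets drawn from a profile whose
  central mass (offsets -1..+1) is exactly 0.9349, reproducing the
  published 93.49% fraction of 21-23 nt reads; the -5 offset has
  probability 0 because a 17 nt insert would (correctly) be discarded by
  the length filter and would blur the manifest accounting;
* Illumina TruSeq small-RNA adapters as defaults (the original adapters
  were never stated) and uniform "I" qualities with a 1.2% low-quality
  ("#") class, since no quality model was published.

Precursors are built constructively — an arm carrying the mature, its
reverse complement with 0-3 mismatches, a 6-10 nt loop — and accepted only
if they pass all six criteria, so a planted hairpin is recoverable by
construction and any end-to-end miss indicates a pipeline bug. Each
simulated read's cleaning fate is likewise guaranteed: insert candidates
are rejection-resampled against the cleaner's own rules (no hidden adapter
match, no accidental poly(A), no accidental 5'-adapter prefix), which is
what makes the manifest-versus-report identity exact at any seed rather
than merely approximate. The read length is 44 nt so that even a 30 nt
insert leaves 14 nt of adapter; with a 36 nt read, long legitimate inserts
would be discarded as adapter-less and the exact accounting would be
impossible.

What the generator does *not* emulate: sequencing errors beyond the
low-quality class, 5'-end isomiR heterogeneity, expression-dependent
sequence biases, genome repeats, and real ncRNA sequence composition
(contaminant references are random). Passing the recovery suite therefore
demonstrates the pipeline's internal correctness and calibration on clean
signal, not robustness to every artifact of a real Solexa run.

Ct tables are simulated as `Ct(target) = 25 - log2(fold) + N(0, sd)` with
a constant-plus-noise reference, five animals per timepoint and the 30 dph
group as calibrator, so fold recovery within 15% at noise 0.1 is a
round-trip contract between the generator and `deltaDeltaCt()`.

# Numerical choices and problem sizes

Energies are doubles; traceback equality uses a 1e-7 tolerance, far below
the 0.05 kcal/mol granularity of the parameter tables. The enumeration
oracle is run at up to 16 nt (hundreds of sequences fold in seconds; the
structure count explodes beyond that). The mapping oracle uses a 50 kb
genome and 1,000 probes. The end-to-end recovery benchmark uses the full
default conditions above (20 hairpins, 100,000 reads) and completes in
about a minute; unit tests use a 6-hairpin, 20,000-read configuration.
All randomness flows from explicit integer seeds; identical configurations
produce byte-identical FASTQ/FASTA/TSV outputs, which the suite checks by
checksum.

# Known limitations

* The energy model is a calibrated simplification, not Turner 2004;
  absolute energies differ by a few kcal/mol from full thermodynamic
  folders, which is acceptable for hairpin screening but not for ensemble
  thermodynamics (no partition function, no suboptimal structures).
* Conservation is mature-presence only; no synteny or precursor-level
  orthology.
* No multiple-testing correction across miRNAs in the ANOVA report, and
  no efficiency correction in 2^-ddCt, matching the modelled workflow.
* The published headline counts from the original 21-million-read library
  (188 conserved categories, 96 vertebrate-conserved, 25,966 annotated
  uniques) are not reproducible because that dataset was never deposited;
  the package's acceptance surface is the printed tables plus the
  synthetic recovery benchmarks.
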
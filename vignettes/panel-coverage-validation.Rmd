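---
title: "Per-base coverage QC and mutation discoverability for amplicon panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-base coverage QC and mutation discoverability for amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcover)
```

## The problem

A negative result from a targeted resequencing panel is only meaningful if
the assay had enough sequencing data at every position where a mutation
could have been. Amplicon panels fail in two characteristic ways that
standard summaries hide:

* **Amplicon dropout.** One PCR product fails entirely, leaving zero reads
  over the bases only it covers. Mutations there are silently invisible; a
  variant caller reports nothing, which is indistinguishable from "no
  mutation" unless coverage is audited per base.
* **Central-overlap masking.** With paired reads shorter than the amplicon
  (301 bp reads on 425 bp products), forward and reverse reads pile up in
  the middle while each flank is covered by one mate only. The *mean*
  amplicon coverage can look comfortable while flanking bases sit below the
  detection threshold.

panelcover addresses both by computing read depth at every base of the
panel footprint and deriving the **discoverability** of each known
mutation: a catalogue variant is discoverable in a sample if and only if
every base of its genomic footprint lies inside the panel footprint and
carries depth at or above a minimum threshold (30x by default). The
fraction of discoverable catalogue variants — per gene, per sample, per
run — is the QC metric that separates "no mutation found" from "no data".

## Coordinate and footprint conventions

All internal coordinates are 0-based half-open. BED input is taken as-is;
catalogue and VCF positions are 1-based on disk and converted on load.
Chromosome names are matched by exact string equality — a `1` vs `chr1`
mismatch across inputs is reported, never silently aliased, because
aliasing is a clinical-safety hazard.

The panel footprint is the exact interval union of the amplicons (no
double counting). Variant footprints follow the affected-reference-base
rule:

* substitutions and deletions occupy `[pos-1, pos-1+nchar(ref))`;
* a pure insertion changes no reference base, but its junction can only be
  seen by reads spanning both sides, so its footprint is the **two**
  flanking bases `[pos-1, pos+1)`. A one-base convention would let a read
  ending exactly at the junction count as informative when it is not.

Every footprint has length at least 1 and contains the anchor base.
Catalogue variants whose footprint falls outside the panel are permanently
non-assayable; by default they are excluded from per-gene denominators and
reported separately (an `include_unassayable` switch keeps them in the
denominator for labs that prefer the pessimistic convention — the
literature does not fix this choice, so both are provided).

## The depth engine

`compute_depth()` counts, at each footprint base, the reads whose
CIGAR-aligned reference bases include it. `M`/`=`/`X` operations count;
`D`-spanned bases count only when `count_deletion_spanned_bases = TRUE`
(off by default, matching naive pileup); `N` consumes reference without
counting; insertions and clips consume none. Reads below `min_mapq` or
with the QC-fail flag are excluded; duplicates count by default because
amplicon PCR duplicates are indistinguishable from independent coverage
(the flag exists for capture-based panels). The result is
order-independent in the read stream, additive over disjoint read sets,
monotone in MAPQ filtering, and decomposes exactly into forward plus
reverse sub-profiles — each of these contracts is property-tested, and
the engine is cross-checked against both a per-(read,base) brute-force
count and an interval-library coverage oracle.

Thresholds are **inclusive**: depth exactly 30 passes. The source text for
this tool family prints both "depth >30" and "minimum coverage depth 30x";
we read "minimum 30x" as inclusive and make the threshold a parameter, so
a lab that prefers the strict reading sets 31.

## Per-gene flags and reports

A gene's discoverability fraction is `n_discoverable / n_known` over its
assayable catalogue variants (gene assignment comes from the catalogue's
gene column, never positional overlap, to avoid ambiguity at overlapping
loci). A gene is flagged when its fraction falls **strictly below 0.90**.
The sample-level overall fraction is total-discoverable over total-known,
not the mean of gene fractions, so large genes weigh more. Percentages are
rendered to one decimal, rounding half away from zero (`38.6` from
`22/57`), matching clinical reporting style rather than banker's rounding.
Run summaries use type-7 quantiles (R's default) for the per-gene
five-number distributions.

## The variant filter cascade

`filter_calls()` applies six conjunctive rules in a fixed order — quality
strictly > 100, caller PASS, total depth strictly > 30, VAF ≥ 20%
(inclusive, since germline heterozygotes expect ~50% and the floor exists
to kill noise, not borderline heterozygotes), population frequency
strictly < 5% with *unknown frequency passing* (novel variants have no
population record and must survive), and a consequence whitelist. Because
the rules are conjunctive the kept set is order-independent; only the
rejection ledger (first failing rule per call) depends on the order, and
the original pipeline did not record rejection reasons at all — the ledger
is an auditability addition.

## Tier classification

`assign_tier()` stratifies filtered calls for reporting: Tier 1 is an
exact catalogue match validated as pathogenic in a phenotype-linked gene;
Tier 2 is a mechanistic loss-of-function prediction (frameshift, novel
stop, stop loss, initiator codon, canonical GT/AG splice — a splice call
with an annotated intronic offset counts as canonical only at ±1/±2;
without the annotation the consequence alone decides, since the package
does not recompute transcript geometry); Tier 3 covers known-pathogenic
variants in wrong-phenotype genes, predicted cryptic-splice or
transcription effects, and high-score missense changes. Deleteriousness
scores are consumed as input annotations with a configurable cut-off
(default 0.95); re-implementing SIFT/PolyPhen is out of scope.

`compound_recessive_check()` encodes the reporting caveat that two lone
heterozygous hits in two *different* autosomal-recessive genes are two
carrier states, not a diagnosis: such cases stay unsolved, while
homozygous hits, compound heterozygotes within one gene, and single hits
under dominant or X-linked inheritance remain diagnosis-eligible.

## Validation statistics

`build_concordance()` keys calls by (chrom, pos, ref, alt) against an
orthogonal truth set, with truth-negative positions judged by position.
Sensitivity and specificity come with Wilson score or exact
Clopper-Pearson intervals; the exact bounds are computed from the beta
quantile form and tested against the defining tail-probability equalities
to 1e-9, against `binom.test`, and with a 2000-draw coverage simulation
(p = 0.95, n = 300, coverage ≥ 94% required). Both methods ship because
published reports rarely state which was used, and no printed interval is
ever used as a test expectation — only point estimates are asserted.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults *are* the study conditions: 33 genes, 425 bp
amplicons overlapping by 50 bp, 301 bp reads, a 1207-variant catalogue
with the 87/4/8/1 missense/insertion/deletion/complex mix, occasional
amplicon dropout, and strand-anchored reads that produce the
central-overlap geometry (with 301 bp reads on a 425 bp amplicon the
double-covered plateau is 301 + 301 − 425 = 177 bp). Gene geometry is six
300 bp exons with 400 bp introns, which makes each gene tile into exactly
ten amplicons — the topology of the canonical single-gene coverage figure.
All generators are pure functions of the seed; reruns are byte-identical,
which is what makes planted-defect tests oracle-exact rather than
approximate.

The generator does **not** emulate sequence content, base qualities,
alignment errors, GC-driven amplification bias, or loci that are
intrinsically hard to amplify. Consequently a default synthetic run
reports ~97% discoverability, higher than the ~90% (84–92%) seen on real
panels where some regions fail consistently. Passing tests therefore
demonstrate that the *accounting* is exact — dropped amplicons blind
exactly the variants whose footprints they exclusively cover, and no
others — not that real panels achieve any particular discoverability.
Counts drawn per amplicon are Poisson around the configured mean with a
Bernoulli strand split, so expectation-based assertions use 3-standard-
error bands while identity assertions use fixed seeds.

## Numerical and degenerate-input choices

* Thresholds: depth ≥ 30 inclusive; gene flag < 0.90 strict; quality > 100
  and depth > 30 strict; VAF ≥ 0.20 inclusive; population frequency < 0.05
  strict. Each boundary has a dedicated test on both sides.
* Empty inputs: an empty BED yields an empty manifest; an empty catalogue
  is an error only where a denominator is required
  (`catalogue_composition`, `sample_report`, `cohort_summary`); a gene
  absent from the catalogue is an omitted-gene marker (`NULL`), not an
  error, mirroring reports that simply leave such genes out.
* Depth tables: overlapping rows with conflicting depths are a validation
  error; agreeing overlaps are tolerated; absent bases are depth 0.
* Catalogue records with classes outside the closed vocabulary are kept
  but mapped to `other` with a warning count, so a curator typo cannot
  silently drop a known mutation.
* Unknown population frequency passes the frequency filter; unknown
  splice offsets defer to the consequence annotation.

## Problem sizes used by the test suite

The suite runs the full default scale (33 genes, 330 amplicons, 1207
variants, ~26,000 reads) once end-to-end, and smaller instances (1–5
genes, 200–500 reads or calls) for oracle and property tests, with 10–40
replicates per property under fixed seeds. These sizes give exact oracle
comparisons in seconds while still exercising every code path at the
defaults.

## Known limitations

* No realignment, BAQ, or deduplication algorithm — flags are respected,
  nothing is recomputed.
* Filtered output is TSV (plus a rejection ledger); VCF is consumed but
  not emitted.
* The tier engine is the three-tier reporting shorthand, not a full
  ACMG-2015 criteria engine, and it performs no segregation phasing.
* Truth-negative concordance is positional, so a truth-negative site with
  a test call of any allele counts as a false positive.
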
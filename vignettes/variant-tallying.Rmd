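---
title: "Counting, comparing and filtering variants: the methods behind vcftally"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting, comparing and filtering variants: the methods behind vcftally}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcftally)
```

## The counting model

A VCF data line is one *site*, not necessarily one *variant*: the ALT
column may list several comma-separated alleles, and the same allele can
be reported on more than one line (concatenated call sets, re-called
regions). vcftally therefore counts variants only after a two-step
normalization:

1. **Split.** A record with *k* ALT alleles becomes *k* records differing
   only in ALT. All other columns are copied verbatim; order is preserved.
   Sites with *k* ≥ 2 are tallied as *multiallelic sites* — a site-level
   counter reported alongside the per-variant classes, never a class of
   its own.
2. **Deduplicate.** The identity of a normalized variant is the key
   (CHROM, POS, REF, ALT), with alleles compared case-insensitively.
   ID, QUAL, FILTER and INFO never enter the key: two records that place
   the same allele at the same position are the same variant regardless of
   annotation. The first occurrence in file order wins, which keeps
   provenance deterministic.

This is set-level normalization only. Representation-level normalization —
left-aligning and trimming INDELs against a reference genome, as
`bcftools norm` does — is deliberately out of scope: it requires the
reference FASTA, and the counting semantics here are defined on the file
as given. Two files that encode the same INDEL with different anchors will
not match in comparisons; run a representation normalizer first if that
matters for your data.

Every normalized record then receives exactly one class by a fixed rule
ladder over the uppercased alleles: symbolic or non-ACGT content
(`<DEL>`, breakends, `*`, `.`, any N) is *assorted*; single-base pairs are
SNPs, split into *transition* (A↔G, C↔T) and *transversion* (the
other eight pairs); equal multi-base lengths are *MNP*; unequal lengths
are *insertion* or *deletion* by which side is longer. The ladder is total
and exclusive by construction — the property tests assert this on random
data. Length comparison does not require one allele to be a prefix of the
other: a REF/ALT pair like `GA`/`T` still counts as a deletion, because a
length-based definition keeps the classification total without a
reference.

## Parameters that matter

* `window_bp` (default 1 000 000 bp). Windows are 1-based, inclusive, and
  anchored at position 1: window *k* is \[(k−1)·W + 1, k·W\], so position
  k·W belongs to window *k* and k·W + 1 opens window *k* + 1. Anchoring at
  1 makes window labels line up with the "n–n+1 Mbp" convention used when
  reporting polymorphic loci. Zero-count windows up to the last occupied
  window are emitted explicitly, which is what makes gap detection a pure
  scan over the density table.
* `min_qual` in `filter_qual()` uses ≥ (keep-at-threshold), and missing
  QUAL (`.`) is dropped by default: quality filtering is a conservative
  operation, and a record with no quality evidence should not pass a
  quality gate unless the user opts in with `keep_missing = TRUE`.
  Missing QUAL is a genuine missing value everywhere — never coerced to 0,
  never `Inf`, and always sorted last by `sort_records()` in both
  directions.
* `harmonize_chr_prefix` in `compare_vcf()` defaults to off. Silently
  rewriting contig names risks false matches, so exact string matching is
  the default and a disjoint-vocabulary warning points at the likely
  `chr1`-vs-`1` mismatch instead.
* Region bounds in `filter_region()` are 1-based and inclusive on both
  ends, matching how genomic loci are quoted in practice (`chr6:start-end`
  includes both boundary positions).
* Keyword search is plain substring and case-insensitive by default;
  regular expressions are opt-in via `regex = TRUE`, because search-box
  semantics should not surprise users with metacharacters.

## Degenerate inputs and numerical choices

Ts/Tv is reported as `NA` when there are no transversions (never an
error, never `Inf` in an output table) and 0 when there are transversions
but no transitions. An empty dataset summarizes to an all-zero table with
missing Ts/Tv; the empty INDEL histogram reports missing maxima; comparing
against an empty set yields a missing percentage for that side. Gap
detection runs strictly between the first and last occupied windows of a
contig: without a reference genome, leading and trailing emptiness is
indistinguishable from unassembled sequence or a contig that simply ends,
so it is not counted as a gap. Percentages are kept at full precision in
all objects and rounded only when printed (Ts/Tv to two decimals). All
counts are exact integer tallies; there are no tolerances anywhere in the
computation itself.

Parsing is strict by default: a data line with fewer than eight fields or
a non-integer POS aborts with its line number, because silently corrupted
summaries are worse than a failed run. `skip_malformed = TRUE` switches to
permissive reading, which skips and counts bad lines. Compression is
detected from the gzip magic bytes (`0x1f 0x8b`, which bgzip shares), not
the file extension. Trailing FORMAT/sample columns are carried verbatim
and never interpreted — every computation in the package uses only the
first eight columns — so a read–write round trip preserves them exactly.

## What the generator emulates — and what it does not

`generate_vcf()` turns a `fixture_spec()` into a VCF whose
normalize–summarize output equals the spec exactly: per-class counts,
multiallelic sites (planted as SNP pairs at one position: one transition
plus one transversion from the same REF when both are available, else two
transversions — one REF base offers only a single transition partner),
duplicate lines (exact copies placed immediately after their originals,
drawn from single-ALT records with non-missing QUAL so every planted
counter stays exact), and missing QUALs. Positions are unique per contig
apart from the planted duplicates, records are reference-ordered, QUAL is
uniform on \[0, 100\], and the same spec and seed produce byte-identical
files with the caller's RNG stream left untouched. Specs serialize to a
small JSON config so any failing case is reproducible from the file alone.

The generator emulates the *structure* of variant data, not its biology:
no realistic mutation spectrum (real genomes favour transitions roughly
2:1; the generator plants whatever you ask), no clustering or linkage
structure along the genome (positions are uniform), no genotype columns,
no annotation-rich INFO fields. Passing tests therefore demonstrate that
the counting, windowing, comparison and filtering machinery is exact on
well-formed and adversarially planted inputs — not that any biological
claim holds on real data.

## Design choices made where the design was open

* **The variant key includes ALT.** Identity by (CHROM, POS, REF) alone
  cannot uniquely identify normalized variants — two ALT alleles at one
  position would collapse — so the key is (CHROM, POS, REF, ALT).
* **Shared records in a comparison carry file A's columns.** Intersection
  must choose one annotation source; taking the first argument's columns
  is deterministic and easy to reason about.
* **Contig order in outputs is first-appearance order.** VCFs are
  conventionally reference-ordered already; imposing a karyotype sort
  would silently reorder non-human or non-standard contigs.
* **The multiallelic counter is carried from normalization.** Summaries
  are computed post-split, so the site count must be recorded before
  splitting and transported on the normalized object.
* **The command-line interface is a thin script.** All logic lives in the
  exported `run_*()` functions; `inst/scripts/vcftally` only parses
  arguments and maps error classes to exit codes (0 success, 2 usage,
  3 parse failure), so the CLI surface is testable as ordinary R code.

## Problem sizes in the test suite

The property suites run on deliberately small inputs: 100 randomized
generator specs of up to ~80 records each for the ground-truth closure
property, a mixed ~500-record dataset for brute-force oracle equivalence
(keys, window densities, INDEL histograms, Venn counts via a double-loop
scan, and every filter), and hand-built boundary fixtures for window
edges, inclusive regions, missing QUAL, zero-transversion Ts/Tv and empty
inputs. These sizes exercise every code path; the implementation itself is
vectorised and handles millions of records.

## Known limitations

Genotype/FORMAT columns are never parsed; there is no indexed random
access (`.tbi`/`.csi`) and no bgzip writing; comparisons are pairwise
only; no allele-frequency or sample-level filtering; INFO is searched as
raw text, not decoded against its meta declarations. These are boundaries
of the package's scope, not planned gaps.
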
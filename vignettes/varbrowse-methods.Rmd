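---
title: "varbrowse: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{varbrowse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varbrowse)
```

## What the package computes

`varbrowse` is the computational backend of a population variant-frequency
browser: the layer that turns an annotated sites VCF, gene models, per-base
coverage tables and a handful of side tables into the gene-, transcript-
and variant-level summaries such a browser displays. The package covers
ingestion, variant normalization and flagging, consequence ranking,
same-codon multi-nucleotide-variant (MNV) candidate detection, coverage and
CNV aggregation, deterministic selection of carrier samples for the
read-support display, a queryable store with search and autocomplete, page
assembly with CSV export, and an HTTP-style service contract. A seeded
synthetic-data generator produces every input with machine-readable ground
truth, so the full pipeline is testable offline.

The sites-only data model is deliberate: the package stores per-site
aggregate counts (AC/AN/Hom, total and per continental group), never
per-individual genotypes.

## The data model and its conventions

Internally every interval is 0-based half-open; the 1-based inclusive
conventions of VCF and GTF are converted at the I/O boundary and converted
back on output. Chromosome names are unified by stripping any `chr` prefix
on ingest. A variant's identity is the string `chrom-pos-ref-alt` *after*
normalization, which is what makes dbSNP keys, URL keys and split
multi-allelic alleles land on the same record.

The population breakdown defaults to the seven continental groups used by
large exome-aggregation callsets — AFR, AMR, EAS, FIN, NFE, SAS, OTH — and
is configurable everywhere (`store_config(populations = ...)`), since the
set is a dataset convention rather than a fixed fact.

## Variant normalization

`minimal_representation()` trims a (pos, ref, alt) triple to its minimal
spelling: the shared suffix is removed first, then the shared prefix
(advancing the position per trimmed base), in both phases only while both
alleles stay longer than one base. This is the standard minimal
representation used by variant-browser backends; it is idempotent and the
output position never decreases. It runs once per alternate allele at
ingest and is implemented in C++ because at production scale (millions of
alleles) it sits on the hot path.

One limitation is inherent and worth understanding. For any variant whose
minimal spelling ends in two *different* bases — every SNV and MNP, and any
anchored indel that does not extend a base run — all prefix- and
suffix-padded spellings collapse to the same fixed point, so equivalent
descriptions unify exactly (this is a provable property of the trimming
order, and the test suite enumerates all paddings up to three bases to
confirm it). But an indel sitting inside a base run (minimal spelling
ending in a shared base, e.g. deleting one `T` of `TTT`) has no unique
placement without consulting the reference genome: a prefix-padded spelling
can legitimately trim to a shifted but equivalent form. Reference-aware
left-alignment is the only complete fix and is out of scope for a
string-level normalizer; the test suite pins a concrete example of the
ambiguity so the behavior is documented rather than silent.

## Multi-allelic splitting and flags

Sites with several alternate alleles are split into one record per alt,
each taking its own AC/Hom (total and per population) while sharing the
site's AN; all alleles of such a site carry the `multiallelic` flag, and
spanning-deletion `*` alleles are dropped (with a warning) without touching
AN. The `low_an` flag marks variants whose called allele number falls
strictly below 80% of the dataset's maximum AN — the conventional "low
number of individuals covered" cutoff, configurable via
`store_config(low_an_fraction = ...)`.

## Consequence severity and the "worst" annotation

Per-transcript consequences come from the VCF's pipe-delimited annotation
field (VEP-style). The sub-field order is always read from the VCF header,
never hard-coded, because annotation-tool versions differ. Ampersand-joined
terms become term lists; when an `Allele` sub-field is present, entries are
partitioned to their alternate allele, accepting both the full and the
anchor-trimmed spelling of indel alleles.

The "worst consequence across transcripts" shown in gene-page tables is the
minimum over a fixed severity ranking of Sequence Ontology terms. The
ranking ships as a plain text file (one term per line, most severe first,
the VEP ordering) so it is inspectable and overridable; an unknown term is
an error rather than a silent last place, because a silently mis-ranked
term would corrupt every table built from it.

## Codon arithmetic and MNV candidates

For each transcript with CDS features, the codon index of a genomic
position is computed from its CDS offset — the number of coding bases
strictly 5′ of the position in transcript orientation, walking from the
highest genomic coordinate on the minus strand. Two single-nucleotide
variants annotated against the same transcript whose positions share a
codon are reported as an MNV candidate pair: jointly they may change a
different amino acid than either suggests alone. Because the model is
sites-only, candidacy is positional; when a co-occurrence table
(pairs observed in one individual) is supplied, pairs are restricted to it.
Pairs are reported once, members ordered by ascending position, and both
members gain the `mnv_candidate` flag. Pairs across different alts of one
site are included — they share a position, hence a codon.

## Coverage and CNV aggregation

Exon coverage summaries are means over interval bases: mean of per-base
mean depths, mean of per-base medians (a median of medians is not
well-defined across bases, and the output metadata says which statistic is
shown), and per depth cutoff the mean of per-base covered fractions. A base
with no coverage row contributes zero to every metric — absence of data
must read as absence of depth, because displaying the absence of variation
credibly is the whole point of showing coverage. The cutoff set is taken
from the coverage file header, and per-exon `frac_over` is non-increasing
in the cutoff whenever the input rows are.

CNV calls are consumed as an input table (the calling itself is upstream
and out of scope). A call counts toward every exon interval it overlaps by
at least one base — regardless of the amount of overlap — if and only if
its quality score is strictly above the SQ 60 confidence cutoff; both the
strictness and the cutoff are pinned by tests and configurable.

## Read-support sample selection

For each variant, carrier samples back the raw-read display. Selection is
per genotype class (het / hom): keep carriers with read depth ≥ 10 and
genotype quality ≥ 20; when more than five qualify, take the five with the
highest GQ. Ties on GQ break by ascending sample id — the selection must be
deterministic for caching and testing, and no natural ordering is otherwise
defined. The display window is 125 bp centered on the variant's first
reference base (left flank `floor((w-1)/2)`, remainder right). Manifests
record the reassembly parameters (300 bp padding and related caller flags)
verbatim so an external reassembly step could reproduce the read
extraction; this package never runs a caller and never writes BAMs.
`batch_manifests()` partitions manifests into batches and assigns each
(variant, sample) pair a unique read-group label, mirroring how small
per-variant read sets are combined into larger files for compression while
read groups preserve provenance.

## Store, queries and the service contract

The store is an embedded index — in-memory tables with a directory
save/load — rather than a database server: the original deployment's
document store is an operational detail, not a method, and an embedded
index keeps the artifact self-contained and testable. All variant lists are
returned in (chrom, pos, ref, alt) order. Gene pages for genes with at
least `large_gene_threshold` variants are pre-computed into a payload
cache; a cache hit is byte-identical to a fresh computation, which the
tests assert, so caching is purely a latency optimization.

Search resolution order is: rsid (`rs\d+`), then variant key or `chrom:pos`
position, then `chrom:start-stop` region, then exact gene symbol
(case-insensitive), then alias, then Ensembl-style gene or transcript id;
anything else is a `not_found` *result* carrying autocomplete suggestions.
Symbols outrank aliases both in resolution and in autocomplete ranking, so
a symbol that happens to be another gene's alias resolves to its own gene.
Region queries are limited to 100 kb (strict on `stop − start`, 1-based
inclusive input) so results return promptly; the limit and its boundary are
pinned by tests. Looking up a well-formed variant that is not in the
dataset returns a page that still carries coverage for the surrounding
window — absence of a variant is information, not an error.

CSV export follows RFC 4180 with allele frequencies printed to 6
significant digits, switching to scientific notation below 1e-4 (the usual
display convention for rare-variant frequencies).

The HTTP contract lives in `handle_request()` — a pure function from
(method, path, query) to (status, content type, body) with 404/400/422
structured errors — so the wire behavior is testable without sockets and
byte-identical to direct calls of the page-assembly functions. `serve()`
wraps it in a minimal single-threaded HTTP server over base-R sockets for
local use; production deployments should front the router with a real
server.

## The synthetic-data generator

`generate_fixtures(seed, out_dir)` writes the complete input bundle plus a
`truth.json`. Its defaults define the study conditions of the test suite:
4 genes (recycled from a template list with both strands always present, so
minus-strand codon arithmetic is always exercised), 24 variants per gene,
and the seven-population breakdown with full-call-rate allele numbers of
~121,000 alleles in proportions typical of large exome-aggregation
callsets. Each gene contributes a
deliberate same-codon SNV pair on its canonical transcript, one
multi-allelic SNV site, one deletion written in padded (non-minimal) VCF
spelling, and a background of SNVs, ~15% of them at a reduced call rate so
the `low_an` flag is exercised. CNV qualities straddle the SQ 60 cutoff
(including one call exactly at it), and carrier GQ/DP values straddle the
20/10 selection floors with extra mass at the boundaries. Population counts
are drawn so per-population AC sums *exactly* to the total — stricter than
real released data, which uses adjusted counts, but it makes conservation
assertable. Coverage tracks have ~7% missing bases so the zero-fill rule is
always hit.

The generator aims for structural consistency, not realism: no
mutation-rate model, no site-frequency spectrum, no linkage. Passing tests
therefore demonstrate correctness of the bookkeeping — coordinate
conventions, splitting, ranking, counting, selection — on data shaped like
the real inputs, not statistical behavior on real cohorts.

Ground truth is computed by construction inside the generator (e.g. codon
assignment by a naive per-base walk over the CDS it just wrote), giving the
end-to-end tests an oracle that does not share code with the pipeline under
test.

## Problem sizes and numerical choices

The default test-suite conditions (4 genes × 24 variants, ~100-variant
stores, 100-case oracle sweeps, full padding enumeration up to 3 bases on
500 variants) were chosen so every property is exercised on both strands
and at every boundary while the whole suite stays interactive. Histograms
default to 20 equal bins over [0, 100] — the conventional precomputed-
histogram shape for phred-scaled genotype quality and depth — with values
at or above the last edge kept in the last bin so counts are conserved.
Exon coverage plots expose a configurable flank (default 0) rather than
guessing a padding. All floating-point payload serialization keeps full
precision (`digits = NA`); integer fields round-trip bit-identically.

## Known limitations

- No reference-aware left-alignment: run-context indels keep whichever
  minimal spelling their input used (see the normalization section).
- Sites-only: MNV candidacy is positional unless a co-occurrence table is
  supplied; no genotype-level phasing evidence is consulted.
- Readers materialize their tables (idiomatic for in-memory R) rather than
  streaming record-by-record; re-reading an input yields identical
  structures, and the store build is single-pass.
- The built-in HTTP server is single-threaded and blocking, suitable for
  local inspection and tests only.
- Constraint scores and CNV calls are consumed as inputs and displayed;
  computing them is explicitly out of scope.
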
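# varbrowse

A backend for browsing large population variant-frequency datasets.

Clinical geneticists and biologists use population reference callsets to
tell pathogenic mutations from benign polymorphisms: a variant's frequency
in a large cohort is among the best predictors of its deleteriousness. The
raw releases are sites VCFs with per-population allele counts, which take
bioinformatics expertise to parse. `varbrowse` is the computational layer
that turns such a release — an annotated sites VCF, gene models (GTF),
per-base coverage tables, and side tables with constraint scores, CNV calls
and rsID mappings — into the gene-, transcript- and variant-level summaries
a variant browser displays, and serves them through a queryable store with
search, autocomplete, region limits and CSV export.

What the package computes, per module:

- **Ingestion** (`read_sites_vcf`, `read_gene_models`, `read_coverage`,
  `read_side_tables`): format readers built on vcfR, rtracklayer and
  data.table, converting 1-based VCF/GTF records into the internal 0-based
  half-open model and unifying `chr` prefixes.
- **Variant algebra** (`split_multiallelic`, `minimal_representation`,
  `worst_consequence`, `codon_index`, `detect_mnv_candidates`,
  `flag_low_an`): multi-allelic sites split into per-alt records; alleles
  normalized by suffix-then-prefix trimming so equivalent spellings unify
  under the key `chrom-pos-ref-alt`; each variant annotated with its worst
  consequence across transcripts (minimum over a shipped Sequence Ontology
  severity ranking, AF = AC/AN per continental group); same-codon SNV pairs
  flagged as multi-nucleotide-variant (MNV) candidates, strand-aware.
- **Summaries** (`aggregate_coverage`, `compute_metric_histogram`,
  `cnv_counts`, `population_table`): per-exon coverage means with missing
  bases counted as zero depth; genotype-quality/depth histograms (20 bins
  over [0,100], last bin closed); exon CNV counts for calls with SQ
  strictly above 60, any overlap counting.
- **Read support** (`select_samples`, `build_manifest`,
  `batch_manifests`): per genotype class, carriers with DP ≥ 10 and
  GQ ≥ 20, the five highest-GQ kept when more qualify, over a 125 bp
  display window; batched manifests with unique read-group labels.
- **Store + queries** (`build_store`, `resolve_search`, `gene_page`,
  `transcript_page`, `variant_page`, `region_page`,
  `export_variant_table_csv`): an embedded index with key/interval/name
  lookups, pre-computed payloads for large genes, 100 kb region limit, and
  RFC 4180 CSV export.
- **Service** (`handle_request`, `serve`, `cli_main`): a framework-neutral
  HTTP contract plus a minimal socket server and a CLI
  (`build` / `serve` / `search` / `export-csv` / `readviz-manifest` /
  `simulate`).
- **Fixtures** (`generate_fixtures`): a seeded synthetic generator writing
  every input format with machine-readable ground truth.

## Worked example

Generate a synthetic bundle, build the store, and look at a gene:

```r
library(varbrowse)

dir <- tempfile()
bundle <- generate_fixtures(seed = 7, out_dir = dir)
store  <- build_store_from_bundle(bundle)

res <- resolve_search("PCSK9", store)
res$kind
#> [1] "gene"

page <- gene_page(res$target, store)
length(page$variant_table)
#> [1] 24
page$variant_table[[1]][c("pos", "ref", "alt", "worst_consequence", "ac", "an")]
#> $pos
#> [1] 1000018
#> $ref
#> [1] "T"
#> $alt
#> [1] "A"
#> $worst_consequence
#> [1] "5_prime_UTR_variant"
#> $ac
#> [1] 7
#> $an
#> [1] 121410
page$cnv_summary$total
#> $DEL
#> [1] 0
#> $DUP
#> [1] 2
```

The gene page holds 24 variants (every variant the generator placed in the
gene), each row carrying its worst consequence across transcripts and
total/per-population AC/AN/Hom with AF = AC/AN (here 7/121410 ≈ 5.8e-05);
the CNV summary counts confidently called deletions/duplications (SQ > 60)
overlapping the canonical transcript's exons. A variant page for any key,
e.g. `variant_page("1-1000018-T-A", store)`, adds quality histograms,
per-transcript consequence groups, the per-population frequency table and
the read-support manifest (the ≤5 highest-GQ carriers per genotype class).

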
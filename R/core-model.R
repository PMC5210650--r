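# Domain types shared by all stages. Plain tagged lists with strict
# constructors; no file I/O here. Internal coordinates are 0-based half-open;
# VCF/GTF 1-based coordinates are converted at the I/O boundary.

vb_stop <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

as_int1 <- function(x, what) {
  if (is.null(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    vb_stop("%s must be a single integer (got %s)", what, paste(x, collapse = ","))
  as.integer(x)
}

as_num1 <- function(x, what) {
  if (is.null(x) || length(x) != 1L || !is.finite(as.numeric(x)))
    vb_stop("%s must be a single finite number", what)
  as.numeric(x)
}

as_chr1 <- function(x, what, allow_na = FALSE) {
  if (is.null(x)) {
    if (allow_na) return(NA_character_)
    vb_stop("%s must be a single string", what)
  }
  x <- as.character(x)
  if (length(x) != 1L) vb_stop("%s must be a single string", what)
  if (is.na(x) && !allow_na) vb_stop("%s must not be NA", what)
  x
}

#' Genomic interval (0-based half-open)
#'
#' @param chrom chromosome name (non-empty, "chr" prefix already stripped)
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end; must satisfy `0 <= start < end`
#' @return a `vb_interval`
#' @export
genome_interval <- function(chrom, start, end) {
  chrom <- as_chr1(chrom, "chrom")
  if (!nzchar(chrom)) vb_stop("chrom must be non-empty")
  start <- as_int1(start, "start"); end <- as_int1(end, "end")
  if (start < 0L || start >= end)
    vb_stop("interval requires 0 <= start < end (got %d, %d)", start, end)
  structure(list(chrom = chrom, start = start, end = end),
            class = "vb_interval")
}

#' Per-transcript functional consequence of a variant
#'
#' One row of the VEP-style annotation of a variant against a transcript.
#'
#' @param transcript_id,gene_id Ensembl-style identifiers
#' @param consequence_terms non-empty character vector of Sequence Ontology
#'   terms
#' @param polyphen,sift optional `list(prediction=, score=)`
#' @param lof optional loss-of-function confidence label (e.g. "HC", "LC")
#' @param is_canonical is this the gene's canonical transcript?
#' @return a `vb_consequence`
#' @export
transcript_consequence <- function(transcript_id, gene_id, consequence_terms,
                                   polyphen = NULL, sift = NULL, lof = NULL,
                                   is_canonical = FALSE) {
  consequence_terms <- as.character(consequence_terms)
  if (length(consequence_terms) == 0L || any(!nzchar(consequence_terms)))
    vb_stop("consequence_terms must be a non-empty set of terms")
  chk_pred <- function(p, what) {
    if (is.null(p)) return(NULL)
    list(prediction = as_chr1(p$prediction, paste0(what, " prediction")),
         score = as_num1(p$score, paste0(what, " score")))
  }
  structure(list(
    transcript_id = as_chr1(transcript_id, "transcript_id"),
    gene_id = as_chr1(gene_id, "gene_id"),
    consequence_terms = consequence_terms,
    polyphen = chk_pred(polyphen, "polyphen"),
    sift = chk_pred(sift, "sift"),
    lof = if (is.null(lof)) NULL else as_chr1(lof, "lof"),
    is_canonical = isTRUE(is_canonical)
  ), class = "vb_consequence")
}

#' Pre-computed quality-metric histogram
#'
#' @param metric_name e.g. `"genotype_quality"` or `"depth"`
#' @param bin_edges strictly ascending numeric vector
#' @param counts non-negative integer vector, length `length(bin_edges) - 1`
#' @return a `vb_histogram`
#' @export
metric_histogram <- function(metric_name, bin_edges, counts) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    vb_stop("bin_edges must be strictly ascending with >= 2 edges")
  counts <- vapply(counts, as_int1, integer(1), what = "histogram count")
  if (length(counts) != length(bin_edges) - 1L)
    vb_stop("counts length must be length(bin_edges) - 1")
  if (any(counts < 0L)) vb_stop("histogram counts must be non-negative")
  structure(list(metric_name = as_chr1(metric_name, "metric_name"),
                 bin_edges = bin_edges, counts = counts),
            class = "vb_histogram")
}

VARIANT_FLAGS <- c("multiallelic", "low_an", "mnv_candidate")

#' A normalized alternate allele at a site
#'
#' One alt allele after multi-allelic splitting and minimal representation,
#' with total and per-population allele counts, quality metadata, display
#' flags and per-transcript consequences.
#'
#' @param chrom chromosome name
#' @param pos 1-based position of the first reference base (VCF convention)
#' @param ref,alt reference / alternate allele strings (`[ACGT]+`, unequal)
#' @param ac_total,an_total,hom_total site totals; `ac <= an`, `2*hom <= ac`
#' @param rsid optional dbSNP identifier
#' @param site_quality site QUAL
#' @param filter_status `"PASS"` or semicolon-joined filter names
#' @param pop_counts named list, population code -> `list(ac=, an=, hom=)`;
#'   each population's `ac <= an` and `sum(ac) <= ac_total`
#' @param quality_histograms named list of [metric_histogram()]s
#' @param flags subset of `multiallelic`, `low_an`, `mnv_candidate`
#' @param consequences list of [transcript_consequence()]s
#' @return a `vb_variant`
#' @export
variant <- function(chrom, pos, ref, alt, ac_total, an_total, hom_total,
                    rsid = NULL, site_quality = NA_real_,
                    filter_status = "PASS", pop_counts = list(),
                    quality_histograms = list(), flags = character(),
                    consequences = list()) {
  chrom <- as_chr1(chrom, "chrom"); pos <- as_int1(pos, "pos")
  ref <- as_chr1(ref, "ref"); alt <- as_chr1(alt, "alt")
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    vb_stop("ref and alt must match ^[ACGT]+$ (got %s/%s)", ref, alt)
  if (ref == alt) vb_stop("ref must differ from alt")
  ac_total <- as_int1(ac_total, "ac_total")
  an_total <- as_int1(an_total, "an_total")
  hom_total <- as_int1(hom_total, "hom_total")
  if (ac_total < 0L || an_total < 0L || hom_total < 0L)
    vb_stop("allele counts must be non-negative")
  if (ac_total > an_total) vb_stop("ac_total (%d) > an_total (%d)", ac_total, an_total)
  if (2L * hom_total > ac_total)
    vb_stop("2*hom_total (%d) > ac_total (%d)", 2L * hom_total, ac_total)
  pop_counts <- lapply(pop_counts, function(p) {
    p <- list(ac = as_int1(p$ac, "population ac"),
              an = as_int1(p$an, "population an"),
              hom = as_int1(p$hom, "population hom"))
    if (p$ac > p$an) vb_stop("population ac > an")
    p
  })
  if (length(pop_counts)) {
    if (is.null(names(pop_counts)) || any(!nzchar(names(pop_counts))))
      vb_stop("pop_counts must be named by population code")
    if (sum(vapply(pop_counts, `[[`, integer(1), "ac")) > ac_total)
      vb_stop("sum of population ac exceeds ac_total")
  }
  flags <- unique(as.character(flags))
  bad <- setdiff(flags, VARIANT_FLAGS)
  if (length(bad)) vb_stop("unknown variant flag(s): %s", paste(bad, collapse = ", "))
  stopifnot(all(vapply(consequences, inherits, logical(1), "vb_consequence")))
  stopifnot(all(vapply(quality_histograms, inherits, logical(1), "vb_histogram")))
  structure(list(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    rsid = if (is.null(rsid) || is.na(rsid)) NULL else as_chr1(rsid, "rsid"),
    site_quality = as.numeric(site_quality),
    filter_status = as_chr1(filter_status, "filter_status"),
    ac_total = ac_total, an_total = an_total, hom_total = hom_total,
    pop_counts = pop_counts, quality_histograms = quality_histograms,
    flags = flags, consequences = consequences
  ), class = "vb_variant")
}

#' Variant identity key
#'
#' The canonical string key `"chrom-pos-ref-alt"` of a normalized variant.
#' @param v a `vb_variant` (or anything with chrom/pos/ref/alt fields)
#' @return character key
#' @export
variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "-")

#' Parse a variant key
#' @param key `"chrom-pos-ref-alt"` string
#' @return list(chrom, pos, ref, alt)
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(as_chr1(key, "variant key"), "-", fixed = TRUE)[[1]]
  if (length(parts) != 4L || !grepl("^[0-9]+$", parts[2]) ||
      !grepl("^[ACGT]+$", parts[3]) || !grepl("^[ACGT]+$", parts[4]))
    vb_stop("malformed variant key '%s'; expected chrom-pos-ref-alt", key)
  list(chrom = parts[1], pos = as.integer(parts[2]), ref = parts[3], alt = parts[4])
}

#' Gene model
#'
#' @param gene_id Ensembl-style id
#' @param symbol HGNC-style symbol
#' @param aliases alternate symbols
#' @param chrom,start,end 0-based half-open genomic span containing all
#'   transcripts
#' @param strand `"+"` or `"-"`
#' @param canonical_transcript_id must be one of `transcript_ids`
#' @param transcript_ids transcripts of this gene
#' @param constraint optional [constraint_record()]
#' @return a `vb_gene`
#' @export
gene_model <- function(gene_id, symbol, chrom, start, end, strand,
                       canonical_transcript_id, transcript_ids,
                       aliases = character(), constraint = NULL) {
  strand <- as_chr1(strand, "strand")
  if (!strand %in% c("+", "-")) vb_stop("strand must be '+' or '-'")
  transcript_ids <- as.character(transcript_ids)
  canonical_transcript_id <- as_chr1(canonical_transcript_id, "canonical_transcript_id")
  if (!canonical_transcript_id %in% transcript_ids)
    vb_stop("canonical transcript %s not among transcript_ids", canonical_transcript_id)
  if (!is.null(constraint)) stopifnot(inherits(constraint, "vb_constraint"))
  structure(list(
    gene_id = as_chr1(gene_id, "gene_id"),
    symbol = as_chr1(symbol, "symbol"),
    aliases = as.character(aliases),
    chrom = as_chr1(chrom, "chrom"),
    start = as_int1(start, "start"), end = as_int1(end, "end"),
    strand = strand,
    canonical_transcript_id = canonical_transcript_id,
    transcript_ids = transcript_ids,
    constraint = constraint
  ), class = "vb_gene")
}

#' Transcript model
#'
#' Exon/CDS/UTR structure in genomic order (coordinates 0-based half-open,
#' stored in ascending genomic position regardless of strand).
#'
#' @param transcript_id,gene_id identifiers
#' @param strand `"+"` or `"-"`
#' @param features `data.frame(start, end, kind)` with
#'   `kind %in% c("exon","CDS","UTR")`; intervals of one kind must not overlap
#' @return a `vb_transcript`
#' @export
transcript_model <- function(transcript_id, gene_id, strand, features) {
  strand <- as_chr1(strand, "strand")
  if (!strand %in% c("+", "-")) vb_stop("strand must be '+' or '-'")
  features <- as.data.frame(features)
  stopifnot(all(c("start", "end", "kind") %in% names(features)))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$kind <- as.character(features$kind)
  if (any(!features$kind %in% c("exon", "CDS", "UTR")))
    vb_stop("feature kind must be exon, CDS or UTR")
  if (any(features$start >= features$end)) vb_stop("feature with start >= end")
  features <- features[order(features$kind, features$start), , drop = FALSE]
  for (k in unique(features$kind)) {
    f <- features[features$kind == k, , drop = FALSE]
    if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
      vb_stop("overlapping %s intervals in transcript %s", k, transcript_id)
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(
    transcript_id = as_chr1(transcript_id, "transcript_id"),
    gene_id = as_chr1(gene_id, "gene_id"),
    strand = strand, features = features
  ), class = "vb_transcript")
}

#' Per-transcript mutational constraint scores (consumed as input)
#'
#' Expected/observed variant counts and z-scores per functional class, plus
#' pLI. These are pre-calculated upstream and only displayed; this package
#' never computes them.
#'
#' @param transcript_id transcript the record describes
#' @param exp_syn,obs_syn,syn_z synonymous class
#' @param exp_mis,obs_mis,mis_z missense class
#' @param exp_lof,obs_lof,lof_z loss-of-function class
#' @param pli probability of loss-of-function intolerance, in `[0, 1]`
#' @return a `vb_constraint`
#' @export
constraint_record <- function(transcript_id, exp_syn, obs_syn, syn_z,
                              exp_mis, obs_mis, mis_z,
                              exp_lof, obs_lof, lof_z, pli) {
  pli <- as_num1(pli, "pli")
  if (pli < 0 || pli > 1) vb_stop("pli must be in [0, 1]")
  exp_syn <- as_num1(exp_syn, "exp_syn"); exp_mis <- as_num1(exp_mis, "exp_mis")
  exp_lof <- as_num1(exp_lof, "exp_lof")
  if (min(exp_syn, exp_mis, exp_lof) < 0) vb_stop("expected counts must be >= 0")
  structure(list(
    transcript_id = as_chr1(transcript_id, "transcript_id"),
    exp_syn = exp_syn, obs_syn = as_int1(obs_syn, "obs_syn"), syn_z = as_num1(syn_z, "syn_z"),
    exp_mis = exp_mis, obs_mis = as_int1(obs_mis, "obs_mis"), mis_z = as_num1(mis_z, "mis_z"),
    exp_lof = exp_lof, obs_lof = as_int1(obs_lof, "obs_lof"), lof_z = as_num1(lof_z, "lof_z"),
    pli = pli
  ), class = "vb_constraint")
}

#' Per-base coverage record
#'
#' @param chrom chromosome
#' @param pos 1-based base position
#' @param mean_depth,median_depth depth summaries across individuals
#' @param frac_over named numeric vector, depth cutoff -> fraction of
#'   individuals covered at or above it; must be in `[0, 1]` and
#'   non-increasing as the cutoff grows
#' @return a `vb_coverage_row`
#' @export
coverage_row <- function(chrom, pos, mean_depth, median_depth, frac_over) {
  frac_over <- unlist(frac_over)
  if (is.null(names(frac_over))) vb_stop("frac_over must be named by cutoff")
  cutoffs <- as.numeric(names(frac_over))
  frac_over <- as.numeric(frac_over)[order(cutoffs)]
  cutoffs <- sort(cutoffs)
  names(frac_over) <- as.character(cutoffs)
  if (any(frac_over < 0 | frac_over > 1)) vb_stop("frac_over outside [0, 1]")
  if (any(diff(frac_over) > 1e-12))
    vb_stop("frac_over must be non-increasing in the cutoff")
  structure(list(chrom = as_chr1(chrom, "chrom"), pos = as_int1(pos, "pos"),
                 mean_depth = as_num1(mean_depth, "mean_depth"),
                 median_depth = as_num1(median_depth, "median_depth"),
                 frac_over = frac_over),
            class = "vb_coverage_row")
}

#' Copy-number variant call (consumed as input)
#'
#' @param chrom chromosome
#' @param start,end 0-based half-open span
#' @param kind `"DEL"` or `"DUP"`
#' @param sq_score call quality (SQ) from the calling model, `>= 0`
#' @param population population code of the carrier
#' @param sample_id carrier sample
#' @return a `vb_cnv`
#' @export
cnv_call <- function(chrom, start, end, kind, sq_score, population, sample_id) {
  kind <- as_chr1(kind, "kind")
  if (!kind %in% c("DEL", "DUP")) vb_stop("CNV kind must be DEL or DUP")
  start <- as_int1(start, "start"); end <- as_int1(end, "end")
  if (start >= end) vb_stop("CNV requires start < end")
  sq_score <- as_num1(sq_score, "sq_score")
  if (sq_score < 0) vb_stop("sq_score must be >= 0")
  structure(list(chrom = as_chr1(chrom, "chrom"), start = start, end = end,
                 kind = kind, sq_score = sq_score,
                 population = as_chr1(population, "population"),
                 sample_id = as_chr1(sample_id, "sample_id")),
            class = "vb_cnv")
}

#' A carrier sample considered for the read-support display
#'
#' @param sample_id sample identifier
#' @param genotype_class `"het"` or `"hom"`
#' @param gq genotype quality (phred-scaled), `>= 0`
#' @param dp read depth, `>= 0`
#' @return a `vb_readviz_sample`
#' @export
readviz_sample <- function(sample_id, genotype_class, gq, dp) {
  genotype_class <- as_chr1(genotype_class, "genotype_class")
  if (!genotype_class %in% c("het", "hom"))
    vb_stop("genotype_class must be 'het' or 'hom'")
  gq <- as_int1(gq, "gq"); dp <- as_int1(dp, "dp")
  if (gq < 0L || dp < 0L) vb_stop("gq and dp must be >= 0")
  structure(list(sample_id = as_chr1(sample_id, "sample_id"),
                 genotype_class = genotype_class, gq = gq, dp = dp),
            class = "vb_readviz_sample")
}

#' Assembled page payload
#'
#' The serializable content of a gene/transcript/variant/region page.
#'
#' @param page_kind one of gene, transcript, variant, region, not_found
#' @param metadata named list of page metadata
#' @param variant_table list of row lists, each carrying a
#'   `worst_consequence` field
#' @param coverage_series list of per-base coverage records
#' @param cnv_summary CNV count summary (or NULL)
#' @param warnings character vector of display warnings
#' @return a `vb_payload`
#' @export
page_payload <- function(page_kind, metadata = list(), variant_table = list(),
                         coverage_series = list(), cnv_summary = NULL,
                         warnings = character()) {
  page_kind <- as_chr1(page_kind, "page_kind")
  if (!page_kind %in% c("gene", "transcript", "variant", "region", "not_found"))
    vb_stop("unknown page_kind '%s'", page_kind)
  if (length(variant_table) &&
      !all(vapply(variant_table, function(r) "worst_consequence" %in% names(r),
                  logical(1))))
    vb_stop("every variant_table row must carry worst_consequence")
  structure(list(page_kind = page_kind, metadata = metadata,
                 variant_table = variant_table,
                 coverage_series = coverage_series,
                 cnv_summary = cnv_summary,
                 warnings = as.character(warnings)),
            class = "vb_payload")
}
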
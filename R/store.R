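# The queryable index over all ingested and computed content: variant by
# key, variants by interval, gene by id/symbol/alias, transcript by id,
# rsid lookup, coverage and CNVs by interval. Backed by in-memory
# data.table indexes (interval queries via IRanges) with a directory
# save/load, so a built store is self-contained — no database server.

#' Store configuration
#'
#' @param populations population codes, display order
#' @param low_an_fraction `low_an` flag threshold fraction (default 0.8)
#' @param cnv_sq_threshold strict CNV quality cutoff (default 60)
#' @param histogram_edges bin edges for quality histograms
#' @param severity_path severity-order file for [load_severity_table()]
#' @param window_width read-support display window width in bp
#' @param region_max_span region query limit in bp (default 100000)
#' @param large_gene_threshold variant count from which gene payloads are
#'   pre-computed
#' @param csq_field_name INFO key of the consequence field
#' @return a `vb_config` list
#' @export
store_config <- function(populations = DEFAULT_POPULATIONS,
                         low_an_fraction = 0.8,
                         cnv_sq_threshold = 60,
                         histogram_edges = seq(0, 100, by = 5),
                         severity_path = NULL,
                         window_width = 125L,
                         region_max_span = 100000L,
                         large_gene_threshold = 50L,
                         csq_field_name = "CSQ") {
  structure(list(populations = populations,
                 low_an_fraction = low_an_fraction,
                 cnv_sq_threshold = cnv_sq_threshold,
                 histogram_edges = histogram_edges,
                 severity_path = severity_path,
                 window_width = as_int1(window_width, "window_width"),
                 region_max_span = as_int1(region_max_span, "region_max_span"),
                 large_gene_threshold = as_int1(large_gene_threshold,
                                                "large_gene_threshold"),
                 csq_field_name = csq_field_name),
            class = "vb_config")
}

identical_counts <- function(a, b) {
  identical(a$ac_total, b$ac_total) && identical(a$an_total, b$an_total) &&
    identical(a$hom_total, b$hom_total) && identical(a$pop_counts, b$pop_counts)
}

#' Build the browser store from input files
#'
#' Runs the full ingest-and-annotate pipeline: reads the sites VCF, gene
#' models, coverage and side tables; splits multi-allelic sites; normalizes
#' every allele to minimal representation; attaches rsids; sets the
#' `low_an`, `multiallelic` and `mnv_candidate` flags; computes per-variant
#' quality histograms from the carrier table; and indexes everything for
#' key, interval and name lookups.
#'
#' @param vcf_path sites VCF
#' @param gtf_path gene models GTF
#' @param coverage_path per-base coverage TSV
#' @param constraint_path,cnv_path,dbsnp_path,carriers_path,alias_path
#'   optional side tables (see [read_side_tables()], [read_carriers()])
#' @param cooccurrence_path optional TSV (variant_key_1, variant_key_2,
#'   n_individuals) restricting MNV candidacy to co-observed pairs
#' @param config a [store_config()]
#' @return a `vb_store`
#' @export
build_store <- function(vcf_path, gtf_path, coverage_path,
                        constraint_path = NULL, cnv_path = NULL,
                        dbsnp_path = NULL, carriers_path = NULL,
                        alias_path = NULL, cooccurrence_path = NULL,
                        config = store_config()) {
  severity <- if (is.null(config$severity_path)) load_severity_table()
              else load_severity_table(config$severity_path)
  models <- read_gene_models(gtf_path, alias_path = alias_path)
  coverage <- read_coverage(coverage_path)
  side <- read_side_tables(constraint_path, cnv_path, dbsnp_path)
  carriers <- if (is.null(carriers_path)) NULL else read_carriers(carriers_path)
  cooccurrence <- if (is.null(cooccurrence_path)) NULL else
    as.data.frame(data.table::fread(cooccurrence_path, header = TRUE, sep = "\t"))

  # attach constraint to genes (canonical transcript record shown on the page)
  for (gid in names(models$genes)) {
    ct <- side$constraint[[models$genes[[gid]]$canonical_transcript_id]]
    if (!is.null(ct)) models$genes[[gid]]$constraint <- ct
  }

  vcf <- read_sites_vcf(vcf_path, csq_field_name = config$csq_field_name)

  variants <- list()
  for (site in vcf$sites) {
    site$consequences_by_alt <- parse_consequences(site, vcf$csq_format)
    for (v in split_multiallelic(site)) {
      norm <- minimal_representation(v$pos, v$ref, v$alt)
      v$pos <- norm$pos; v$ref <- norm$ref; v$alt <- norm$alt
      key <- variant_key(v)
      if (!is.null(variants[[key]])) {
        if (identical_counts(variants[[key]], v)) {
          warning(sprintf("duplicate variant %s after normalization; merged", key),
                  call. = FALSE)
          variants[[key]]$flags <- sort(unique(c(variants[[key]]$flags, v$flags)))
          variants[[key]]$consequences <-
            c(variants[[key]]$consequences, v$consequences)
          next
        }
        vb_stop("duplicate variant %s after normalization with conflicting counts",
                key)
      }
      variants[[key]] <- v
    }
  }

  # rsids: dbSNP table wins over the VCF ID column; one rsid may attach to
  # several normalized alleles
  if (nrow(side$dbsnp)) {
    for (i in seq_len(nrow(side$dbsnp))) {
      key <- paste(side$dbsnp$chrom[i], side$dbsnp$pos[i],
                   side$dbsnp$ref[i], side$dbsnp$alt[i], sep = "-")
      if (!is.null(variants[[key]])) variants[[key]]$rsid <- side$dbsnp$rsid[i]
    }
  }

  an_max <- if (length(variants))
    max(vapply(variants, `[[`, integer(1), "an_total")) else 1L
  variants <- lapply(variants, flag_low_an, an_max = an_max,
                     threshold_fraction = config$low_an_fraction)

  if (!is.null(carriers) && nrow(carriers)) {
    split_car <- split(as.data.frame(carriers), carriers$variant_key)
    for (key in intersect(names(split_car), names(variants))) {
      cc <- split_car[[key]]
      variants[[key]]$quality_histograms <- list(
        genotype_quality = compute_metric_histogram(
          cc$gq, "genotype_quality", config$histogram_edges),
        depth = compute_metric_histogram(cc$dp, "depth",
                                         config$histogram_edges))
    }
  }

  # MNV candidates per transcript
  keys_by_tx <- list()
  for (key in names(variants))
    for (cons in variants[[key]]$consequences)
      keys_by_tx[[cons$transcript_id]] <-
        c(keys_by_tx[[cons$transcript_id]], key)
  mnv_pairs <- list()
  for (tid in sort(names(keys_by_tx))) {
    tx <- models$transcripts[[tid]]
    if (is.null(tx) || !any(tx$features$kind == "CDS")) next
    res <- detect_mnv_candidates(variants[unique(keys_by_tx[[tid]])], tx,
                                 cooccurrence = cooccurrence)
    if (length(res$pairs)) mnv_pairs[[tid]] <- res$pairs
    for (key in res$flagged_keys)
      variants[[key]]$flags <- sort(unique(c(variants[[key]]$flags,
                                             "mnv_candidate")))
  }

  # stable (chrom, pos, ref, alt) ordering everywhere
  vindex <- data.table::data.table(
    chrom = vapply(variants, `[[`, character(1), "chrom"),
    pos = vapply(variants, `[[`, integer(1), "pos"),
    ref = vapply(variants, `[[`, character(1), "ref"),
    alt = vapply(variants, `[[`, character(1), "alt"))
  vindex[, key := names(variants) %||% character()]
  if (nrow(vindex)) {
    vindex[, `:=`(start0 = pos - 1L, end0 = pos - 1L + nchar(ref))]
    data.table::setorder(vindex, chrom, pos, ref, alt)
  } else {
    vindex[, `:=`(start0 = integer(), end0 = integer())]
  }
  variants <- variants[vindex$key]

  symbol_map <- as.list(setNames(
    names(models$genes),
    toupper(vapply(models$genes, `[[`, character(1), "symbol"))))
  alias_pairs <- do.call(rbind, lapply(models$genes, function(g)
    if (length(g$aliases)) data.frame(alias = toupper(g$aliases),
                                      gene_id = g$gene_id) else NULL))
  rsid_map <- list()
  for (key in names(variants)) {
    r <- variants[[key]]$rsid
    if (!is.null(r)) rsid_map[[r]] <- c(rsid_map[[r]], key)
  }

  structure(list(
    config = config, severity = severity,
    genes = models$genes, transcripts = models$transcripts,
    variants = variants, vindex = vindex,
    symbol_map = symbol_map,
    alias_map = alias_pairs %||% data.frame(alias = character(),
                                            gene_id = character()),
    rsid_map = rsid_map,
    coverage = coverage, cnv = side$cnv,
    carriers = carriers, mnv_pairs = mnv_pairs,
    an_max = an_max,
    payload_cache = list()
  ), class = "vb_store")
}

#' Variant lookup by key
#' @param store a `vb_store`
#' @param key `chrom-pos-ref-alt` (normalized)
#' @return the `vb_variant` or NULL
#' @export
get_variant <- function(store, key) store$variants[[key]]

#' Variants overlapping an interval
#'
#' A variant overlaps when its reference span `[pos-1, pos-1+nchar(ref))`
#' intersects the query interval by at least one base.
#'
#' @param store a `vb_store`
#' @param interval a [genome_interval()]
#' @return list of `vb_variant`s in (chrom, pos, ref, alt) order
#' @export
variants_in_interval <- function(store, interval) {
  idx <- store$vindex[chrom == interval$chrom]
  if (nrow(idx) == 0L) return(list())
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = interval$start + 1L, end = interval$end),
    IRanges::IRanges(start = idx$start0 + 1L, end = idx$end0))
  keys <- idx$key[sort(unique(S4Vectors::subjectHits(hits)))]
  if (length(keys) == 0L) return(list())
  store$variants[keys]
}

#' Gene lookup by id, symbol or alias
#' @param store a `vb_store`
#' @param q gene id, symbol or alias (symbols/aliases case-insensitive)
#' @return the `vb_gene` or NULL
#' @export
get_gene <- function(store, q) {
  if (!is.null(store$genes[[q]])) return(store$genes[[q]])
  gid <- store$symbol_map[[toupper(q)]]
  if (!is.null(gid)) return(store$genes[[gid]])
  hit <- store$alias_map$gene_id[store$alias_map$alias == toupper(q)]
  if (length(hit)) return(store$genes[[hit[1]]])
  NULL
}

#' Transcript lookup by id
#' @param store a `vb_store`
#' @param transcript_id id
#' @return the `vb_transcript` or NULL
#' @export
get_transcript <- function(store, transcript_id) store$transcripts[[transcript_id]]

#' Variant keys for an rsid
#' @param store a `vb_store`
#' @param rsid dbSNP identifier
#' @return character vector of matching variant keys (possibly several)
#' @export
get_rsid <- function(store, rsid) store$rsid_map[[rsid]] %||% character()

#' Coverage rows overlapping an interval
#' @param store a `vb_store`
#' @param interval a [genome_interval()]
#' @return coverage data.table clipped to the interval
#' @export
coverage_in_interval <- function(store, interval) {
  cutoffs <- attr(store$coverage, "cutoffs")
  out <- store$coverage[chrom == interval$chrom &
                          pos - 1L >= interval$start & pos - 1L < interval$end]
  data.table::setattr(out, "cutoffs", cutoffs)
  out
}

#' CNV calls overlapping an interval
#' @param store a `vb_store`
#' @param interval a [genome_interval()]
#' @return CNV data.table
#' @export
cnv_in_interval <- function(store, interval) {
  store$cnv[chrom == interval$chrom & start < interval$end &
              end > interval$start]
}

tx_intervals <- function(store, tx, kind = "exon") {
  g <- store$genes[[tx$gene_id]]
  f <- tx$features[tx$features$kind == kind, , drop = FALSE]
  lapply(seq_len(nrow(f)), function(i)
    genome_interval(g$chrom, f$start[i], f$end[i]))
}

#' Pre-compute payloads for large genes
#'
#' Genes whose variant tables reach the threshold get their gene page
#' serialized into the store's payload cache; a cache hit returns a payload
#' byte-identical to a fresh computation, so large genes load fast without
#' changing content.
#'
#' @param store a `vb_store`
#' @param variant_count_threshold cache genes with at least this many
#'   variants (default: the store config's `large_gene_threshold`)
#' @return the store with a populated `payload_cache`
#' @export
precompute_large_gene_payloads <- function(store,
                                           variant_count_threshold =
                                             store$config$large_gene_threshold) {
  store$payload_cache <- list()
  for (gid in sort(names(store$genes))) {
    g <- store$genes[[gid]]
    n <- length(variants_in_interval(
      store, genome_interval(g$chrom, g$start, g$end)))
    if (n >= variant_count_threshold)
      store$payload_cache[[gid]] <-
        vb_to_json(gene_page(gid, store, use_cache = FALSE))
  }
  store
}

#' Save / load a built store
#'
#' The store directory holds one index file plus the pre-computed payload
#' cache; `store_save` writes it, [store_load()] reads it back.
#'
#' @param store a `vb_store`
#' @param dir destination directory (created if needed)
#' @return `dir`, invisibly
#' @export
store_save <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cache <- store$payload_cache
  store$payload_cache <- list()
  saveRDS(store, file.path(dir, "index.rds"))
  jsonlite::write_json(cache, file.path(dir, "payload_cache.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname store_save
#' @export
store_load <- function(dir) {
  idx <- file.path(dir, "index.rds")
  if (!file.exists(idx))
    vb_stop("no store at '%s' (missing %s)", dir, idx)
  store <- readRDS(idx)
  cache_path <- file.path(dir, "payload_cache.json")
  if (file.exists(cache_path)) {
    cache <- jsonlite::fromJSON(cache_path, simplifyVector = FALSE)
    store$payload_cache <- lapply(cache, as.character)
  }
  store
}
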
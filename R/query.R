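# The browser's semantics: search resolution, page assembly, region limits
# and CSV export. Every page is a serializable payload; the display layer
# (not part of this package) consumes the JSON.

variant_row <- function(v, severity, populations) {
  wc <- if (length(v$consequences))
    worst_consequence(v$consequences, severity) else NA_character_
  pops <- setNames(lapply(populations, function(p)
    v$pop_counts[[p]] %||% list(ac = 0L, an = 0L, hom = 0L)), populations)
  list(chrom = v$chrom, pos = v$pos, rsid = v$rsid, ref = v$ref, alt = v$alt,
       worst_consequence = wc, filter = v$filter_status,
       ac = v$ac_total, an = v$an_total, hom = v$hom_total,
       af = as.numeric(allele_frequency(v$ac_total, v$an_total)),
       flags = as.list(v$flags), populations = pops)
}

coverage_series_list <- function(cov_dt) {
  cutoffs <- attr(cov_dt, "cutoffs")
  df <- as.data.frame(cov_dt)
  lapply(seq_len(nrow(df)), function(i) {
    fo <- as.list(df[i, as.character(cutoffs), drop = FALSE])
    names(fo) <- as.character(cutoffs)
    list(chrom = df$chrom[i], pos = df$pos[i], mean = df$mean[i],
         median = df$median[i], frac_over = fo)
  })
}

#' Resolve a search query
#'
#' The single search bar accepts variants (rsids, `chrom-pos-ref-alt` keys
#' or `chrom:pos` positions), regions (`chrom:start-stop`), and genes or
#' transcripts (symbols, aliases or Ensembl-style identifiers). Resolution
#' precedence: rsid, then variant key/position, then region, then exact
#' symbol, then alias, then Ensembl id; anything else is `not_found` with
#' autocomplete suggestions. `not_found` is a result, never an error.
#'
#' @param q query string (non-empty after trimming)
#' @param store a `vb_store`
#' @return a `vb_search_result`: list(kind, target, suggestions)
#' @export
resolve_search <- function(q, store) {
  q <- trimws(q)
  if (!nzchar(q)) vb_stop("empty search query")
  result <- function(kind, target = "", suggestions = character())
    structure(list(kind = kind, target = target,
                   suggestions = as.character(suggestions)),
              class = "vb_search_result")

  if (grepl("^rs[0-9]+$", q, ignore.case = TRUE)) {
    keys <- get_rsid(store, tolower(q))
    if (length(keys)) return(result("variant", keys[1], keys))
    return(result("not_found"))
  }
  if (grepl("^(chr)?[0-9XYMT]+-[0-9]+-[ACGTacgt]+-[ACGTacgt]+$", q)) {
    p <- strsplit(q, "-", fixed = TRUE)[[1]]
    norm <- minimal_representation(as.integer(p[2]), toupper(p[3]), toupper(p[4]))
    key <- paste(norm_chrom(p[1]), norm$pos, norm$ref, norm$alt, sep = "-")
    return(result("variant", key))
  }
  if (grepl("^(chr)?[0-9XYMT]+:[0-9]+$", q)) {
    p <- strsplit(q, ":", fixed = TRUE)[[1]]
    chrom <- norm_chrom(p[1]); pos <- as.integer(p[2])
    hits <- variants_in_interval(store, genome_interval(chrom, pos - 1L, pos))
    if (length(hits)) {
      keys <- vapply(hits, variant_key, character(1))
      return(result("variant", keys[1], keys))
    }
    return(result("region", sprintf("%s:%d-%d", chrom, pos, pos)))
  }
  if (grepl("^(chr)?[0-9XYMT]+:[0-9]+-[0-9]+$", q)) {
    p <- strsplit(q, "[:-]")[[1]]
    return(result("region", sprintf("%s:%s-%s", norm_chrom(p[1]), p[2], p[3])))
  }
  gid <- store$symbol_map[[toupper(q)]]
  if (!is.null(gid)) return(result("gene", gid))
  hit <- store$alias_map$gene_id[store$alias_map$alias == toupper(q)]
  if (length(hit)) return(result("gene", hit[1]))
  if (!is.null(store$genes[[q]])) return(result("gene", q))
  if (!is.null(store$transcripts[[q]])) return(result("transcript", q))
  result("not_found", suggestions = autocomplete(q, store))
}

#' Autocomplete gene symbols and aliases
#'
#' Case-insensitive prefix matches over symbols and aliases, exact symbols
#' ranked before aliases, then lexicographic, capped at `limit`.
#'
#' @param prefix at least one character
#' @param store a `vb_store`
#' @param limit maximum suggestions (default 20)
#' @return character vector of suggestions
#' @export
autocomplete <- function(prefix, store, limit = 20L) {
  prefix <- toupper(trimws(prefix))
  if (!nzchar(prefix)) vb_stop("autocomplete prefix must be non-empty")
  symbols <- vapply(store$genes, `[[`, character(1), "symbol")
  sym_hits <- sort(unname(symbols[startsWith(toupper(symbols), prefix)]))
  aliases <- unique(unlist(lapply(store$genes, `[[`, "aliases")))
  ali_hits <- sort(aliases[startsWith(toupper(aliases), prefix)])
  head(unique(c(sym_hits, ali_hits)), limit)
}

gene_like_page <- function(store, kind, meta, variant_keys, cov_intervals,
                           tx_filter = NULL, warnings = character()) {
  severity <- store$severity
  pops <- store$config$populations
  vs <- store$variants[variant_keys]
  if (!is.null(tx_filter)) {
    vs <- lapply(vs, function(v) {
      v$consequences <- Filter(function(c) c$transcript_id == tx_filter,
                               v$consequences)
      v
    })
    vs <- Filter(function(v) length(v$consequences) > 0L, vs)
  }
  rows <- lapply(vs, function(v) variant_row(v, severity, pops))
  names(rows) <- NULL
  cov <- aggregate_coverage(store$coverage, cov_intervals)
  cnv <- cnv_counts(store$cnv, cov_intervals,
                    sq_threshold = store$config$cnv_sq_threshold,
                    populations = pops)
  meta$coverage_exons <- lapply(seq_len(nrow(cov$exons)), function(i)
    as.list(cov$exons[i, , drop = FALSE]))
  cov_dt <- data.table::as.data.table(cov$series)
  data.table::setattr(cov_dt, "cutoffs", attr(store$coverage, "cutoffs"))
  page_payload(kind, metadata = meta, variant_table = rows,
               coverage_series = coverage_series_list(cov_dt),
               cnv_summary = list(
                 sq_threshold = store$config$cnv_sq_threshold,
                 per_interval = lapply(seq_len(nrow(cnv$per_interval)),
                                       function(i) as.list(cnv$per_interval[i, ])),
                 per_population = lapply(seq_len(nrow(cnv$per_population)),
                                         function(i) as.list(cnv$per_population[i, ])),
                 total = as.list(cnv$total)),
               warnings = warnings)
}

gene_metadata <- function(g) {
  list(gene_id = g$gene_id, symbol = g$symbol, aliases = as.list(g$aliases),
       chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
       canonical_transcript_id = g$canonical_transcript_id,
       transcript_ids = as.list(g$transcript_ids),
       constraint = g$constraint,
       external = list(
         ucsc = sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?position=chr%s:%d-%d",
                        g$chrom, g$start + 1L, g$end)))
}

#' Assemble a gene page
#'
#' Gene metadata with constraint, coverage aggregated over the canonical
#' transcript's exons, the variant table (every variant in the gene span,
#' each annotated with its worst consequence across all transcripts, total
#' and per-population counts, frequency and flags) and exon CNV counts. A
#' gene with no variants still gets its coverage — the absence of variation
#' must be displayed. Unknown gene ids yield a `not_found` payload.
#'
#' @param gene_id gene id, symbol or alias
#' @param store a `vb_store`
#' @param use_cache serve the pre-computed payload when available
#' @return a `vb_payload`
#' @export
gene_page <- function(gene_id, store, use_cache = TRUE) {
  g <- get_gene(store, gene_id)
  if (is.null(g))
    return(page_payload("not_found",
                        metadata = list(query = gene_id, entity = "gene"),
                        warnings = sprintf("gene '%s' not found", gene_id)))
  if (use_cache && !is.null(store$payload_cache[[g$gene_id]]))
    return(vb_from_json(store$payload_cache[[g$gene_id]]))
  keys <- vapply(variants_in_interval(
    store, genome_interval(g$chrom, g$start, g$end)), variant_key, character(1))
  canon <- store$transcripts[[g$canonical_transcript_id]]
  gene_like_page(store, "gene", gene_metadata(g), keys,
                 tx_intervals(store, canon, "exon"))
}

#' Assemble a transcript page
#'
#' Like [gene_page()], but consequences are filtered to this transcript
#' (variants annotated only against other transcripts drop out) and coverage
#' is aggregated over this transcript's exons.
#'
#' @param transcript_id transcript id
#' @param store a `vb_store`
#' @return a `vb_payload`
#' @export
transcript_page <- function(transcript_id, store) {
  tx <- get_transcript(store, transcript_id)
  if (is.null(tx))
    return(page_payload("not_found",
                        metadata = list(query = transcript_id,
                                        entity = "transcript"),
                        warnings = sprintf("transcript '%s' not found",
                                           transcript_id)))
  g <- store$genes[[tx$gene_id]]
  keys <- vapply(variants_in_interval(
    store, genome_interval(g$chrom, g$start, g$end)), variant_key, character(1))
  meta <- list(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
               symbol = g$symbol, strand = tx$strand,
               is_canonical = identical(g$canonical_transcript_id,
                                        tx$transcript_id),
               constraint = NULL)
  gene_like_page(store, "transcript", meta, keys,
                 tx_intervals(store, tx, "exon"), tx_filter = transcript_id)
}

group_consequences <- function(consequences, severity) {
  if (length(consequences) == 0L) return(list())
  terms <- vapply(consequences, function(c)
    worst_consequence(list(c), severity), character(1))
  order_idx <- severity_index(terms, severity)
  groups <- split(consequences, terms)
  groups <- groups[order(vapply(names(groups), function(t)
    severity_index(t, severity), numeric(1)))]
  lapply(names(groups), function(t)
    list(consequence = t, n_transcripts = length(groups[[t]]),
         transcripts = groups[[t]]))
}

#' Assemble a variant page
#'
#' For a known variant: site metadata (rsid, quality, filter, flags, link
#' templates), pre-computed quality histograms, the per-transcript
#' consequence table grouped by identical consequence term, the
#' per-population frequency table and the read-support manifest. For an
#' absent (but well-formed) variant: a `not_found` payload that still
#' carries coverage for the surrounding region, so the absence of variation
#' is displayed with its context.
#'
#' @param key normalized `chrom-pos-ref-alt` key
#' @param store a `vb_store`
#' @return a `vb_payload`
#' @export
variant_page <- function(key, store) {
  parsed <- parse_variant_key(key)   # errors on malformed keys
  norm <- minimal_representation(parsed$pos, parsed$ref, parsed$alt)
  key <- paste(norm_chrom(parsed$chrom), norm$pos, norm$ref, norm$alt,
               sep = "-")
  v <- get_variant(store, key)
  w <- store$config$window_width
  left <- (w - 1L) %/% 2L
  ctx_start <- max(0L, norm$pos - 1L - left)
  ctx <- genome_interval(norm_chrom(parsed$chrom), ctx_start, ctx_start + w)
  if (is.null(v)) {
    cov <- coverage_in_interval(store, ctx)
    return(page_payload(
      "not_found",
      metadata = list(query = key, entity = "variant",
                      region = list(chrom = ctx$chrom, start = ctx$start,
                                    end = ctx$end)),
      coverage_series = coverage_series_list(cov),
      warnings = sprintf(
        "variant %s is not in the dataset; showing coverage for the surrounding region",
        key)))
  }
  manifest <- NULL
  if (!is.null(store$carriers)) {
    cc <- store$carriers[variant_key == key]
    samples <- lapply(seq_len(nrow(cc)), function(i)
      readviz_sample(cc$sample_id[i], cc$genotype_class[i], cc$gq[i], cc$dp[i]))
    manifest <- build_manifest(v, select_samples(samples),
                               window_width = store$config$window_width)
  }
  pop_tab <- population_table(v, store$config$populations)
  page_payload(
    "variant",
    metadata = list(
      variant_key = key, chrom = v$chrom, pos = v$pos, ref = v$ref,
      alt = v$alt, rsid = v$rsid, site_quality = v$site_quality,
      filter = v$filter_status, flags = as.list(v$flags),
      external = list(
        dbsnp = if (!is.null(v$rsid))
          sprintf("https://www.ncbi.nlm.nih.gov/snp/%s", v$rsid) else NULL,
        ucsc = sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?position=chr%s:%d-%d",
                       v$chrom, ctx$start + 1L, ctx$end),
        clinvar = sprintf(
          "https://www.ncbi.nlm.nih.gov/clinvar?term=%s[chr]+AND+%d[chrpos37]",
          v$chrom, v$pos)),
      quality_histograms = v$quality_histograms,
      consequence_groups = group_consequences(v$consequences, store$severity),
      population_table = lapply(seq_len(nrow(pop_tab)), function(i)
        as.list(pop_tab[i, ])),
      readviz = manifest),
    variant_table = list(variant_row(v, store$severity,
                                     store$config$populations)))
}

#' Assemble a region page
#'
#' Variants, genes and coverage in a 1-based inclusive interval. Queries
#' wider than the configured span limit are rejected with a payload naming
#' the limit, to ensure a timely return of results; the comparison is
#' strict on `stop - start`.
#'
#' @param chrom chromosome
#' @param start,stop 1-based inclusive bounds, `start <= stop`
#' @param store a `vb_store`
#' @param max_span region limit in bp (default: store config, 100 kb)
#' @return a `vb_payload`; rejected queries have
#'   `metadata$rejected == TRUE`
#' @export
region_page <- function(chrom, start, stop, store,
                        max_span = store$config$region_max_span) {
  start <- as_int1(start, "start"); stop <- as_int1(stop, "stop")
  if (start > stop) vb_stop("inverted region coordinates %d-%d", start, stop)
  chrom <- norm_chrom(chrom)
  if (stop - start > max_span)
    return(page_payload(
      "region",
      metadata = list(chrom = chrom, start = start, stop = stop,
                      rejected = TRUE, max_span = max_span),
      warnings = sprintf(
        "region of %d bp exceeds the %d bp query limit", stop - start,
        max_span)))
  iv <- genome_interval(chrom, start - 1L, stop)
  keys <- vapply(variants_in_interval(store, iv), variant_key, character(1))
  genes_hit <- Filter(function(g) g$chrom == chrom && g$start < iv$end &&
                        g$end > iv$start, store$genes)
  rows <- lapply(store$variants[keys], function(v)
    variant_row(v, store$severity, store$config$populations))
  names(rows) <- NULL
  cov <- coverage_in_interval(store, iv)
  page_payload(
    "region",
    metadata = list(chrom = chrom, start = start, stop = stop,
                    rejected = FALSE,
                    genes = lapply(unname(genes_hit), function(g)
                      list(gene_id = g$gene_id, symbol = g$symbol))),
    variant_table = rows,
    coverage_series = coverage_series_list(cov))
}

# 6 significant digits, scientific notation below 1e-4
format_af <- function(af) {
  vapply(af, function(x) {
    if (x == 0) return("0")
    if (x < 1e-4) sprintf("%.5e", x)
    else format(signif(x, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

csv_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl('[",\r\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Export a page's variant table as CSV
#'
#' RFC 4180 CSV: a header row plus one row per variant with chrom, pos,
#' rsid, ref, alt, worst consequence, filter, total AC/AN/Hom, allele
#' frequency (6 significant digits, scientific below 1e-4) and
#' per-population AC/AN/Hom columns.
#'
#' @param payload a `vb_payload` with a variant table
#' @param populations population codes for the per-population columns
#' @return CSV text (single string, CRLF-free \n line endings)
#' @export
export_variant_table_csv <- function(payload,
                                     populations = DEFAULT_POPULATIONS) {
  pop_cols <- unlist(lapply(populations, function(p)
    paste0(c("ac_", "an_", "hom_"), p)))
  header <- c("chrom", "pos", "rsid", "ref", "alt", "consequence", "filter",
              "ac", "an", "hom", "af", pop_cols)
  lines <- paste(csv_quote(header), collapse = ",")
  for (row in payload$variant_table) {
    pop_vals <- unlist(lapply(populations, function(p) {
      pc <- row$populations[[p]] %||% list(ac = 0L, an = 0L, hom = 0L)
      c(pc$ac, pc$an, pc$hom)
    }))
    fields <- c(row$chrom, row$pos, row$rsid %||% "", row$ref, row$alt,
                row$worst_consequence %||% "", row$filter,
                row$ac, row$an, row$hom, format_af(row$af), pop_vals)
    lines <- c(lines, paste(csv_quote(fields), collapse = ","))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
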
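test_that("search resolves rsids, keys, positions, regions, names in order", {
  st <- fixture_store()
  r <- resolve_search("rs113993960", st)
  expect_identical(r$kind, "variant")
  expect_true(nzchar(r$target))
  expect_identical(get_variant(st, r$target)$rsid, "rs113993960")

  expect_identical(resolve_search("PCSK9", st)$kind, "gene")
  expect_identical(resolve_search(" pcsk9 ", st)$kind, "gene")
  expect_identical(resolve_search("NARC1", st)$kind, "gene")

  k <- names(st$variants)[1]
  rk <- resolve_search(k, st)
  expect_identical(rk$kind, "variant")
  expect_identical(rk$target, k)
  # a padded spelling of the same variant resolves to the normalized key
  p <- parse_variant_key(k)
  padded <- paste(p$chrom, p$pos - 1L, paste0("A", p$ref), paste0("A", p$alt),
                  sep = "-")
  expect_identical(resolve_search(padded, st)$target, k)

  v <- st$variants[[k]]
  rp <- resolve_search(sprintf("%s:%d", v$chrom, v$pos), st)
  expect_identical(rp$kind, "variant")
  expect_true(k %in% rp$suggestions)

  rr <- resolve_search("1:1000000-1000500", st)
  expect_identical(rr$kind, "region")

  # unknown rsid pattern is a not_found result, not an error
  rn <- resolve_search("rs999999999", st)
  expect_identical(rn$kind, "not_found")
  expect_identical(rn$target, "")

  g <- st$genes[[1]]
  expect_identical(resolve_search(g$gene_id, st)$kind, "gene")
  expect_identical(resolve_search(g$canonical_transcript_id, st)$kind,
                   "transcript")
})

test_that("an exact symbol outranks a colliding alias of another gene", {
  st <- fixture_store()
  # make PCSK9's symbol also an alias of another gene
  other <- st$genes[[2]]
  st$alias_map <- rbind(data.frame(alias = "PCSK9", gene_id = other$gene_id),
                        st$alias_map)
  r <- resolve_search("PCSK9", st)
  expect_identical(r$kind, "gene")
  expect_identical(st$genes[[r$target]]$symbol, "PCSK9")
})

test_that("autocomplete ranks symbols before aliases, capped and ordered", {
  st <- fixture_store()
  expect_true("PCSK9" %in% autocomplete("PCS", st))
  expect_identical(autocomplete("ZZZZNOPE", st), character())
  # symbol and alias share a prefix: symbol comes first
  sug <- autocomplete("P", st)
  symbols <- toupper(vapply(st$genes, `[[`, character(1), "symbol"))
  is_sym <- sug %in% names(st$symbol_map) | toupper(sug) %in% symbols
  if (any(!is_sym)) expect_true(min(which(!is_sym)) > max(which(is_sym)))
  expect_length(autocomplete("P", st, limit = 1L), 1L)
  expect_identical(autocomplete("P", st, limit = 1L), sug[1])
})

test_that("gene pages carry the whole variant table with worst consequences", {
  b <- fixture_bundle()
  st <- fixture_store()
  for (gt in b$truth$genes) {
    page <- gene_page(gt$gene_id, st)
    expect_identical(page$page_kind, "gene")
    expect_identical(length(page$variant_table), gt$n_variants)
    posns <- vapply(page$variant_table, `[[`, integer(1), "pos")
    expect_false(is.unsorted(posns))
    # every row's worst consequence equals an oracle recompute
    for (row in page$variant_table) {
      key <- paste(row$chrom, row$pos, row$ref, row$alt, sep = "-")
      v <- get_variant(st, key)
      expect_identical(row$worst_consequence,
                       worst_consequence(v$consequences, st$severity))
    }
  }
  nf <- gene_page("ENSG99999999999", st)
  expect_identical(nf$page_kind, "not_found")
})

test_that("a gene with no variants still shows coverage", {
  st <- mini_store()
  page <- gene_page("BETA", st)
  expect_identical(page$page_kind, "gene")
  expect_length(page$variant_table, 0L)
  expect_gt(length(page$coverage_series), 0L)
})

test_that("transcript pages filter consequences and use their own exons", {
  b <- fixture_bundle()
  st <- fixture_store()
  g <- get_gene(st, "PCSK9")
  t1 <- g$canonical_transcript_id
  t2 <- setdiff(g$transcript_ids, t1)[1]
  gene_keys <- vapply(gene_page(g$gene_id, st)$variant_table, function(r)
    paste(r$chrom, r$pos, r$ref, r$alt, sep = "-"), character(1))
  p1 <- transcript_page(t1, st)
  p2 <- transcript_page(t2, st)
  keys1 <- vapply(p1$variant_table, function(r)
    paste(r$chrom, r$pos, r$ref, r$alt, sep = "-"), character(1))
  keys2 <- vapply(p2$variant_table, function(r)
    paste(r$chrom, r$pos, r$ref, r$alt, sep = "-"), character(1))
  expect_true(all(keys1 %in% gene_keys))
  expect_true(all(keys2 %in% gene_keys))
  # variants annotated only against the canonical transcript (third exon)
  # are absent from the short transcript's page
  only_t1 <- Filter(function(k) {
    v <- get_variant(st, k)
    tids <- vapply(v$consequences, `[[`, character(1), "transcript_id")
    t1 %in% tids && !(t2 %in% tids)
  }, gene_keys)
  expect_gt(length(only_t1), 0L)
  expect_false(any(only_t1 %in% keys2))
  # coverage intervals equal this transcript's exons
  tx2 <- get_transcript(st, t2)
  f <- tx2$features[tx2$features$kind == "exon", ]
  got <- do.call(rbind, lapply(p2$metadata$coverage_exons, function(e)
    data.frame(start = e$start, end = e$end)))
  expect_identical(got$start, f$start)
  expect_identical(got$end, f$end)

  expect_identical(transcript_page("ENST00", st)$page_kind, "not_found")
})

test_that("variant pages carry metadata, histograms, groups and frequencies", {
  st <- fixture_store()
  k <- names(st$variants)[1]
  page <- variant_page(k, st)
  expect_identical(page$page_kind, "variant")
  expect_length(page$metadata$population_table, 8L)
  expect_identical(page$metadata$variant_key, k)
  expect_true(!is.null(page$metadata$quality_histograms$genotype_quality))
  expect_true(!is.null(page$metadata$readviz))
  expect_identical(page$metadata$readviz$window$end -
                     page$metadata$readviz$window$start, 125L)
  expect_error(variant_page("not a key", st), "chrom-pos-ref-alt")
})

test_that("transcripts sharing a consequence term group together", {
  st <- fixture_store()
  k <- names(st$variants)[1]
  st$variants[[k]]$consequences <- list(
    transcript_consequence("TX1", "G", "missense_variant"),
    transcript_consequence("TX2", "G", "missense_variant"),
    transcript_consequence("TX3", "G", "synonymous_variant"))
  page <- variant_page(k, st)
  groups <- page$metadata$consequence_groups
  expect_length(groups, 2L)
  expect_identical(groups[[1]]$consequence, "missense_variant")  # severity order
  expect_identical(groups[[1]]$n_transcripts, 2L)
})

test_that("an absent variant at a covered position shows regional coverage", {
  st <- fixture_store()
  g <- st$genes[[1]]
  key <- sprintf("%s-%d-A-C", g$chrom, g$start + 10L)
  if (!is.null(get_variant(st, key)))
    key <- sprintf("%s-%d-A-C", g$chrom, g$start + 11L)
  page <- variant_page(key, st)
  expect_identical(page$page_kind, "not_found")
  expect_gt(length(page$coverage_series), 0L)
})

test_that("region queries enforce the span limit exactly at the boundary", {
  st <- fixture_store()
  ok <- region_page("1", 1000000L, 1100000L, st)     # span 100000
  expect_false(isTRUE(ok$metadata$rejected))
  over <- region_page("1", 1000000L, 1100001L, st)   # span 100001
  expect_true(isTRUE(over$metadata$rejected))
  expect_match(over$warnings, "100000")
  expect_error(region_page("1", 500L, 100L, st), "inverted")

  served <- region_page("1", 1000000L, 1001500L, st)
  got <- vapply(served$variant_table, function(r)
    paste(r$chrom, r$pos, r$ref, r$alt, sep = "-"), character(1))
  brute <- character()
  for (v in st$variants)
    if (v$chrom == "1" && v$pos - 1L < 1001500L &&
        v$pos - 1L + nchar(v$ref) > 999999L)
      brute <- c(brute, variant_key(v))
  expect_identical(got, brute)
  expect_true(length(served$metadata$genes) >= 1L)
})

test_that("CSV export is RFC 4180 and round-trips the table values", {
  st <- fixture_store()
  g <- st$genes[[1]]
  page <- gene_page(g$gene_id, st)
  csv <- export_variant_table_csv(page, st$config$populations)
  lines <- strsplit(csv, "\n")[[1]]
  expect_identical(length(lines), length(page$variant_table) + 1L)
  parsed <- utils::read.csv(text = csv, stringsAsFactors = FALSE,
                            colClasses = "character")
  expect_identical(nrow(parsed), length(page$variant_table))
  for (i in seq_len(nrow(parsed))) {
    row <- page$variant_table[[i]]
    expect_identical(parsed$pos[i], as.character(row$pos))
    expect_identical(parsed$ref[i], row$ref)
    expect_identical(parsed$consequence[i], row$worst_consequence)
    expect_identical(as.integer(parsed$ac[i]), row$ac)
    expect_equal(as.numeric(parsed$af[i]), row$af, tolerance = 1e-5)
    for (p in st$config$populations)
      expect_identical(as.integer(parsed[[paste0("ac_", p)]][i]),
                       row$populations[[p]]$ac)
  }
  empty <- page_payload("gene")
  expect_identical(export_variant_table_csv(empty),
                   paste0(strsplit(csv, "\n")[[1]][1], "\n"))
})

test_that("allele frequencies format with 6 significant digits", {
  v <- list(chrom = "1", pos = 1L, ref = "A", alt = "G",
            worst_consequence = "missense_variant", filter = "PASS",
            ac = 1L, an = 121412L, hom = 0L, af = 1 / 121412,
            rsid = NULL, flags = list(), populations = list())
  payload <- page_payload("gene", variant_table = list(v))
  csv <- export_variant_table_csv(payload, character())
  af_field <- strsplit(strsplit(csv, "\n")[[1]][2], ",")[[1]][11]
  expect_match(af_field, "e-06$")                  # scientific below 1e-4
  expect_equal(as.numeric(af_field), 1 / 121412, tolerance = 1e-6)
})
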
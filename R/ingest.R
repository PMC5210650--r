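# Readers for all input formats. File parsing is delegated to vcfR
# (sites VCF), rtracklayer (GTF) and data.table (TSVs); this module converts
# the external records into the package's domain types. Chromosome names are
# unified by stripping any "chr" prefix on ingest; 1-based GTF coordinates
# become 0-based half-open internally.

norm_chrom <- function(x) sub("^chr", "", as.character(x))

info_fields <- function(info) {
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1L) paste(p[-1], collapse = "=") else "")
  setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

info_ints <- function(fields, key, n, line) {
  raw <- fields[[key]]
  if (is.null(raw)) return(rep(0L, n))
  v <- suppressWarnings(as.integer(strsplit(raw, ",", fixed = TRUE)[[1]]))
  if (anyNA(v)) vb_stop("line %d: non-integer value in INFO/%s", line, key)
  v
}

#' Read a sites VCF
#'
#' Reads a sites-only VCF carrying total and per-population AC/AN/Hom INFO
#' fields plus a pipe-delimited per-transcript consequence field whose
#' sub-field order is declared in the header. Alt alleles are kept intact;
#' splitting happens downstream in [split_multiallelic()].
#'
#' @param path VCF file (optionally bgzip/gzip-compressed)
#' @param csq_field_name INFO key of the consequence field (default "CSQ")
#' @return list with `csq_format` (ordered sub-field names from the header)
#'   and `sites` (list of raw site records; see [split_multiallelic()] for
#'   the record layout)
#' @export
read_sites_vcf <- function(path, csq_field_name = "CSQ") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  csq_line <- grep(sprintf("^##INFO=<ID=%s[,>]", csq_field_name), meta, value = TRUE)
  if (length(csq_line) == 0L)
    vb_stop("VCF header is missing the consequence INFO field '%s'",
            csq_field_name)
  m <- regmatches(csq_line[1],
                  regexpr("Format: [^\"]+", csq_line[1]))
  if (length(m) == 0L)
    vb_stop("consequence INFO field '%s' declares no Format", csq_field_name)
  csq_format <- strsplit(sub("^Format: ", "", m), "|", fixed = TRUE)[[1]]

  fix <- vcf@fix
  col <- function(name) unname(fix[, name])
  chrom_c <- col("CHROM"); pos_c <- col("POS"); id_c <- col("ID")
  ref_c <- col("REF"); alt_c <- col("ALT"); qual_c <- col("QUAL")
  filt_c <- col("FILTER"); info_c <- col("INFO")
  n <- nrow(fix)
  sites <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- suppressWarnings(as.integer(pos_c[i]))
    if (is.na(pos)) vb_stop("line %d: malformed POS '%s'", i, pos_c[i])
    alts <- strsplit(alt_c[i], ",", fixed = TRUE)[[1]]
    fields <- info_fields(info_c[i])
    an <- info_ints(fields, "AN", 1L, i)
    pop_codes <- sub("^AC_", "", grep("^AC_", names(fields), value = TRUE))
    pops <- setNames(lapply(pop_codes, function(p) list(
      ac = info_ints(fields, paste0("AC_", p), length(alts), i),
      an = info_ints(fields, paste0("AN_", p), 1L, i),
      hom = info_ints(fields, paste0("Hom_", p), length(alts), i)
    )), pop_codes)
    rsid <- id_c[i]
    csq_raw <- fields[[csq_field_name]]
    sites[[i]] <- list(
      chrom = norm_chrom(chrom_c[i]), pos = pos,
      rsid = if (!is.na(rsid) && rsid != "." && nzchar(rsid)) rsid else NULL,
      ref = ref_c[i], alts = alts,
      qual = suppressWarnings(as.numeric(qual_c[i])),
      filter = if (is.na(filt_c[i]) || filt_c[i] == ".")
        "PASS" else filt_c[i],
      ac = info_ints(fields, "AC", length(alts), i), an = an,
      hom = info_ints(fields, "Hom", length(alts), i),
      pop_counts = pops,
      csq = if (is.null(csq_raw)) "" else csq_raw,
      consequences_by_alt = NULL, line = i
    )
  }
  list(csq_format = csq_format, sites = sites)
}

parse_prediction <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(NULL)
  m <- regmatches(x, regexec("^(.*)\\(([-0-9.eE]+)\\)$", x))[[1]]
  if (length(m) == 3L) list(prediction = m[2], score = as.numeric(m[3]))
  else list(prediction = x, score = NA_real_)
}

# VEP-style representation of an alt allele: when all alleles at the site
# share their first base it is stripped ("-" when nothing remains).
vep_allele <- function(ref, alt) {
  if (nchar(ref) > 0L && nchar(alt) > 0L &&
      substr(ref, 1, 1) == substr(alt, 1, 1) &&
      (nchar(ref) > 1L || nchar(alt) > 1L)) {
    out <- substr(alt, 2, nchar(alt))
    if (!nzchar(out)) "-" else out
  } else alt
}

#' Parse the consequence INFO field of one site
#'
#' Splits the comma-separated, pipe-delimited VEP-style annotation into
#' per-transcript consequence entries and partitions them to the site's alt
#' alleles. Ampersand-joined terms become a term list; `CANONICAL == "YES"`
#' marks the canonical transcript; absent PolyPhen/SIFT/LoF sub-fields stay
#' unset. Entries with fewer sub-fields than the declared format are
#' rejected with a warning. When the format carries an `Allele` sub-field,
#' each entry is attached only to the matching alt (full or VEP-trimmed
#' spelling); otherwise every entry attaches to every alt.
#'
#' @param site raw site record from [read_sites_vcf()]
#' @param csq_format ordered sub-field names; must include at least
#'   Consequence, Gene, Feature, CANONICAL
#' @return list with one element per alt allele, each a list of
#'   [transcript_consequence()]s
#' @export
parse_consequences <- function(site, csq_format) {
  required <- c("Consequence", "Gene", "Feature", "CANONICAL")
  if (!all(required %in% csq_format))
    vb_stop("consequence format must include %s", paste(required, collapse = ", "))
  per_alt <- rep(list(list()), length(site$alts))
  if (is.null(site$csq) || !nzchar(site$csq)) return(per_alt)
  entries <- strsplit(site$csq, ",", fixed = TRUE)[[1]]
  has_allele <- "Allele" %in% csq_format
  alt_spellings <- lapply(site$alts, function(a)
    unique(c(a, vep_allele(site$ref, a))))
  for (e in entries) {
    sub <- strsplit(e, "|", fixed = TRUE)[[1]]
    # trailing empty sub-fields are significant: count by delimiter
    n_fields <- nchar(gsub("[^|]", "", e)) + 1L
    if (n_fields >= length(csq_format) && length(sub) < n_fields)
      sub <- c(sub, rep("", n_fields - length(sub)))
    if (length(sub) < length(csq_format)) {
      warning(sprintf("rejecting consequence entry with %d of %d sub-fields at %s:%d",
                      length(sub), length(csq_format), site$chrom, site$pos),
              call. = FALSE)
      next
    }
    f <- setNames(as.list(sub[seq_along(csq_format)]), csq_format)
    cons <- transcript_consequence(
      transcript_id = f$Feature, gene_id = f$Gene,
      consequence_terms = strsplit(f$Consequence, "&", fixed = TRUE)[[1]],
      polyphen = parse_prediction(f$PolyPhen),
      sift = parse_prediction(f$SIFT),
      lof = if (!is.null(f$LoF) && nzchar(f$LoF)) f$LoF else NULL,
      is_canonical = identical(f$CANONICAL, "YES"))
    targets <- if (has_allele)
      which(vapply(alt_spellings, function(s) f$Allele %in% s, logical(1)))
    else seq_along(site$alts)
    for (i in targets)
      per_alt[[i]] <- c(per_alt[[i]], list(cons))
  }
  per_alt
}

#' Read gene models from a GTF file
#'
#' Expects gene/transcript/exon/CDS (optionally UTR) feature lines with
#' `gene_id`, `transcript_id` and `gene_name` attributes, Gencode-style.
#' 1-based inclusive GTF coordinates are converted to 0-based half-open;
#' exons are stored in ascending genomic order on both strands. When no
#' transcript is tagged canonical the canonical transcript is the one with
#' the longest total CDS, ties broken by lexicographically smallest
#' transcript id.
#'
#' @param path GTF file
#' @param alias_path optional TSV (gene_id, alias) attaching alternate
#'   symbols
#' @return list with `genes` (named list of `vb_gene`) and `transcripts`
#'   (named list of `vb_transcript`)
#' @export
read_gene_models <- function(path, alias_path = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$seqnames <- norm_chrom(df$seqnames)
  df$start0 <- df$start - 1L   # to 0-based half-open
  df$end0 <- df$end

  tx_rows <- df[df$type == "transcript", , drop = FALSE]
  known_tx <- tx_rows$transcript_id
  feat <- df[df$type %in% c("exon", "CDS", "UTR"), , drop = FALSE]
  unknown <- setdiff(unique(feat$transcript_id), known_tx)
  if (length(unknown))
    vb_stop("feature references unknown transcript: %s",
            paste(unknown, collapse = ", "))

  transcripts <- list()
  for (i in seq_len(nrow(tx_rows))) {
    tid <- tx_rows$transcript_id[i]
    f <- feat[feat$transcript_id == tid, , drop = FALSE]
    transcripts[[tid]] <- transcript_model(
      tid, tx_rows$gene_id[i], as.character(tx_rows$strand[i]),
      data.frame(start = f$start0, end = f$end0,
                 kind = ifelse(f$type == "CDS", "CDS",
                               ifelse(f$type == "UTR", "UTR", "exon"))))
  }

  alias_map <- list()
  if (!is.null(alias_path)) {
    al <- data.table::fread(alias_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    alias_map <- split(al$alias, al$gene_id)
  }

  cds_len <- vapply(transcripts, function(tx) {
    f <- tx$features[tx$features$kind == "CDS", , drop = FALSE]
    sum(f$end - f$start)
  }, numeric(1))

  gene_rows <- df[df$type == "gene", , drop = FALSE]
  genes <- list()
  for (i in seq_len(nrow(gene_rows))) {
    gid <- gene_rows$gene_id[i]
    tids <- sort(tx_rows$transcript_id[tx_rows$gene_id == gid])
    if (length(tids) == 0L)
      vb_stop("gene %s has no transcripts", gid)
    len <- cds_len[tids]
    canonical <- tids[order(-len, tids)][1]
    genes[[gid]] <- gene_model(
      gid, gene_rows$gene_name[i], gene_rows$seqnames[i],
      gene_rows$start0[i], gene_rows$end0[i],
      as.character(gene_rows$strand[i]),
      canonical_transcript_id = canonical, transcript_ids = tids,
      aliases = alias_map[[gid]] %||% character())
  }
  list(genes = genes, transcripts = transcripts)
}

#' Read a per-base coverage table
#'
#' Tab-separated with header `#chrom pos mean median <cutoff> <cutoff> ...`;
#' each fraction column holds the proportion of individuals covered at or
#' above that depth cutoff. The cutoff set is taken from the header.
#' Gzip-compressed files are detected by extension.
#'
#' @param path coverage TSV
#' @return a `data.table` with columns chrom, pos, mean, median and one
#'   column per cutoff (named by the cutoff); attribute `cutoffs` holds the
#'   ascending cutoff vector
#' @export
read_coverage <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  names(dt)[1] <- sub("^#", "", names(dt)[1])
  stopifnot(all(c("chrom", "pos", "mean", "median") %in% names(dt)))
  cutoff_cols <- setdiff(names(dt), c("chrom", "pos", "mean", "median"))
  cutoffs <- as.numeric(cutoff_cols)
  if (anyNA(cutoffs)) vb_stop("non-numeric depth-cutoff column in coverage header")
  for (cc in cutoff_cols) {
    v <- dt[[cc]]
    bad <- which(v < 0 | v > 1)
    if (length(bad))
      vb_stop("coverage fraction outside [0,1] at %s:%d (cutoff %s)",
              dt$chrom[bad[1]], dt$pos[bad[1]], cc)
  }
  dt[, chrom := norm_chrom(chrom)]
  data.table::setattr(dt, "cutoffs", sort(cutoffs))
  data.table::setcolorder(dt, c("chrom", "pos", "mean", "median",
                                cutoff_cols[order(cutoffs)]))
  dt[]
}

#' Read the side tables: constraint scores, CNV calls and rsID mappings
#'
#' Constraint TSV: transcript_id, exp_syn, obs_syn, syn_z, exp_mis, obs_mis,
#' mis_z, exp_lof, obs_lof, lof_z, pli. CNV TSV: chrom, start, end, kind,
#' sq, population, sample_id (0-based half-open coordinates). dbSNP TSV:
#' rsid, chrom, pos, ref, alt (1-based). Duplicate dbSNP rows for one
#' variant: the last row wins, with a warning.
#'
#' @param constraint_path,cnv_path,dbsnp_path TSV paths (any may be NULL)
#' @return list with `constraint` (named list of [constraint_record()] keyed
#'   by transcript), `cnv` (data.table of calls) and `dbsnp` (data.table
#'   rsid/chrom/pos/ref/alt, normalized via [minimal_representation()])
#' @export
read_side_tables <- function(constraint_path = NULL, cnv_path = NULL,
                             dbsnp_path = NULL) {
  constraint <- list()
  if (!is.null(constraint_path)) {
    ct <- data.table::fread(constraint_path, header = TRUE, sep = "\t")
    num_cols <- setdiff(names(ct), "transcript_id")
    for (cc in num_cols) {
      bad <- which(is.na(suppressWarnings(as.numeric(ct[[cc]]))))
      if (length(bad))
        vb_stop("unparsable numeric field '%s' in constraint table row %d",
                cc, bad[1])
    }
    for (i in seq_len(nrow(ct)))
      constraint[[ct$transcript_id[i]]] <- constraint_record(
        ct$transcript_id[i], ct$exp_syn[i], ct$obs_syn[i], ct$syn_z[i],
        ct$exp_mis[i], ct$obs_mis[i], ct$mis_z[i],
        ct$exp_lof[i], ct$obs_lof[i], ct$lof_z[i], ct$pli[i])
  }
  cnv <- data.table::data.table(chrom = character(), start = integer(),
                                end = integer(), kind = character(),
                                sq = numeric(), population = character(),
                                sample_id = character())
  if (!is.null(cnv_path)) {
    raw <- data.table::fread(cnv_path, header = TRUE, sep = "\t")
    if (nrow(raw)) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw$sq))))
      if (length(bad))
        vb_stop("unparsable numeric SQ in CNV table row %d", bad[1])
      cnv <- raw[, .(chrom = norm_chrom(chrom), start = as.integer(start),
                     end = as.integer(end), kind = as.character(kind),
                     sq = as.numeric(sq), population = as.character(population),
                     sample_id = as.character(sample_id))]
    }
  }
  dbsnp <- data.table::data.table(rsid = character(), chrom = character(),
                                  pos = integer(), ref = character(),
                                  alt = character())
  if (!is.null(dbsnp_path)) {
    raw <- data.table::fread(dbsnp_path, header = TRUE, sep = "\t")
    if (nrow(raw)) {
      bad <- which(is.na(suppressWarnings(as.integer(raw$pos))))
      if (length(bad))
        vb_stop("unparsable position in dbSNP table row %d", bad[1])
      norm <- lapply(seq_len(nrow(raw)), function(i)
        minimal_representation(as.integer(raw$pos[i]), raw$ref[i], raw$alt[i]))
      dbsnp <- data.table::data.table(
        rsid = as.character(raw$rsid), chrom = norm_chrom(raw$chrom),
        pos = vapply(norm, `[[`, integer(1), "pos"),
        ref = vapply(norm, `[[`, character(1), "ref"),
        alt = vapply(norm, `[[`, character(1), "alt"))
      key <- paste(dbsnp$chrom, dbsnp$pos, dbsnp$ref, dbsnp$alt, sep = "-")
      if (anyDuplicated(key)) {
        warning("duplicate dbSNP rows for one variant; last row wins",
                call. = FALSE)
        dbsnp <- dbsnp[!duplicated(key, fromLast = TRUE)]
      }
    }
  }
  list(constraint = constraint, cnv = cnv, dbsnp = dbsnp)
}

#' Read the carrier table backing the read-support display
#'
#' TSV with columns variant_key, sample_id, genotype_class, gq, dp — the
#' per-variant carrier candidates from which [select_samples()] draws.
#'
#' @param path carriers TSV
#' @return data.table of carriers
#' @export
read_carriers <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("variant_key", "sample_id", "genotype_class", "gq", "dp")
                %in% names(dt)))
  dt[, `:=`(variant_key = as.character(variant_key),
            sample_id = as.character(sample_id),
            genotype_class = as.character(genotype_class),
            gq = as.integer(gq), dp = as.integer(dp))][]
}
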
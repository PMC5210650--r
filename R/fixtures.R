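# Seeded synthetic-data generator: produces a structurally consistent input
# bundle (sites VCF, GTF gene models, coverage TSV, constraint/CNV/dbSNP
# side tables, read-support carriers) plus a machine-readable truth JSON, so
# every module is testable with no download. The generator aims for
# structural consistency (coordinate conventions, conserved counts, both
# strands, deliberate boundary cases), not for realistic mutation-rate or
# site-frequency-spectrum modeling.

GENE_TEMPLATES <- list(
  list(symbol = "PCSK9", aliases = c("NARC1", "FH3"), chrom = "1", strand = "+"),
  list(symbol = "BRCA1", aliases = c("RNF53", "BRCC1"), chrom = "17", strand = "-"),
  list(symbol = "CFTR",  aliases = c("ABCC7", "MRP7"), chrom = "7", strand = "+"),
  list(symbol = "TTN",   aliases = c("CMD1G", "TMD"), chrom = "2", strand = "-"),
  list(symbol = "MYH7",  aliases = c("CMH1"), chrom = "14", strand = "+"),
  list(symbol = "TP53",  aliases = c("P53", "LFS1"), chrom = "17", strand = "-"),
  list(symbol = "FBN1",  aliases = c("MFS1"), chrom = "15", strand = "+"),
  list(symbol = "SCN5A", aliases = c("LQT3"), chrom = "3", strand = "-")
)

# AN per population at full call rate (diploid allele numbers in the
# proportions typical of large exome-aggregation callsets, ~121k alleles)
FULL_AN <- c(AFR = 10406L, AMR = 11578L, EAS = 8654L, FIN = 6614L,
             NFE = 66738L, SAS = 16512L, OTH = 908L)

# naive per-base CDS walk: 1-based genomic positions in translation order
cds_walk <- function(cds_df, strand) {
  pos <- unlist(Map(function(s, e) seq.int(s + 1L, e), cds_df$start, cds_df$end))
  pos <- sort(pos)
  if (strand == "-") rev(pos) else pos
}

fx_gene_structure <- function(i, n_genes) {
  tpl <- GENE_TEMPLATES[[((i - 1L) %% length(GENE_TEMPLATES)) + 1L]]
  symbol <- if (i <= length(GENE_TEMPLATES)) tpl$symbol
            else paste0(tpl$symbol, "L", i)
  G <- 1000000L + (i - 1L) * 1000000L
  gid <- sprintf("ENSG%011d", i)
  t1 <- sprintf("ENST%011d", i * 10L + 1L)
  t2 <- sprintf("ENST%011d", i * 10L + 2L)
  exons <- data.frame(start = G + c(0L, 500L, 1000L),
                      end = G + c(300L, 800L, 1300L))
  cds1 <- data.frame(start = G + c(100L, 500L, 1000L),
                     end = G + c(300L, 800L, 1100L))      # 600 bases
  cds2 <- data.frame(start = G + c(100L, 500L),
                     end = G + c(300L, 798L))             # 498 bases
  list(i = i, gene_id = gid, symbol = symbol, aliases = tpl$aliases,
       chrom = tpl$chrom, strand = tpl$strand, start = G, end = G + 1300L,
       t1 = t1, t2 = t2, exons = exons, cds1 = cds1, cds2 = cds2,
       utr1 = data.frame(start = G + c(0L, 1100L), end = G + c(100L, 1300L)),
       utr2 = data.frame(start = G + c(0L, 798L), end = G + c(100L, 800L)))
}

fx_gtf_lines <- function(g) {
  attr1 <- function(tid) sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s";', g$gene_id, tid, g$symbol)
  line <- function(type, s0, e0, attrs) sprintf(
    "chr%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\t%s",
    g$chrom, type, s0 + 1L, e0, g$strand, attrs)
  out <- c(line("gene", g$start, g$end,
                sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol)))
  for (tx in list(list(id = g$t1, ex = g$exons, cds = g$cds1, utr = g$utr1),
                  list(id = g$t2, ex = g$exons[1:2, ], cds = g$cds2,
                       utr = g$utr2))) {
    out <- c(out, line("transcript", min(tx$ex$start), max(tx$ex$end),
                       attr1(tx$id)))
    for (k in seq_len(nrow(tx$ex)))
      out <- c(out, line("exon", tx$ex$start[k], tx$ex$end[k], attr1(tx$id)))
    for (k in seq_len(nrow(tx$cds)))
      out <- c(out, line("CDS", tx$cds$start[k], tx$cds$end[k], attr1(tx$id)))
    for (k in seq_len(nrow(tx$utr)))
      out <- c(out, line("UTR", tx$utr$start[k], tx$utr$end[k], attr1(tx$id)))
  }
  out
}

fx_draw_counts <- function(populations, low_an) {
  an_pop <- FULL_AN[populations]
  if (low_an) an_pop <- as.integer(round(an_pop * runif(1, 0.3, 0.7)))
  ac_total <- 1L + stats::rpois(1, 5)
  w <- as.numeric(an_pop) / sum(an_pop)
  ac_pop <- as.integer(stats::rmultinom(1, ac_total, w))
  names(ac_pop) <- populations
  hom_pop <- vapply(ac_pop, function(a)
    if (a >= 2L) stats::rbinom(1, a %/% 2L, 0.15) else 0L, integer(1))
  list(ac = ac_pop, an = setNames(as.integer(an_pop), populations),
       hom = setNames(as.integer(hom_pop), populations))
}

fx_severity_rank <- function(terms, severity_terms) {
  idx <- match(terms, severity_terms)
  stopifnot(!anyNA(idx))
  severity_terms[min(idx)]
}

#' Generate a synthetic input bundle with ground truth
#'
#' Writes a consistent bundle of every input the pipeline consumes — GTF
#' gene models (genes on both strands, multi-exon, CDS lengths divisible by
#' 3), a sites VCF (SNVs and indels, multi-allelic sites, per-population
#' AC/AN/Hom drawn so population counts sum exactly to the totals,
#' VEP-style consequence strings, a deliberate same-codon SNV pair per
#' gene, some indels written in padded non-minimal form), a per-base
#' coverage TSV with gaps, constraint and CNV tables (SQ values straddling
#' the confidence threshold), a dbSNP table and a read-support carrier
#' table (GQ/DP straddling the selection thresholds) — plus `truth.json`
#' recording the expected variant count per gene, per-variant worst
#' consequence and flags, MNV pairs, CNV counts and read-support
#' selections. Byte-identical output for identical seeds.
#'
#' @param seed RNG seed
#' @param out_dir destination directory (created if needed)
#' @param n_genes number of genes (>= 2 so both strands occur)
#' @param variants_per_gene variants per gene (>= 6)
#' @param populations population codes
#' @return invisibly, a list with the file `paths` and the `truth` list
#' @export
generate_fixtures <- function(seed, out_dir, n_genes = 4L,
                              variants_per_gene = 24L,
                              populations = DEFAULT_POPULATIONS) {
  stopifnot(n_genes >= 2L, variants_per_gene >= 6L)
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  severity_terms <- as.character(load_severity_table())

  genes <- lapply(seq_len(n_genes), fx_gene_structure, n_genes = n_genes)

  gtf_lines <- unlist(lapply(genes, fx_gtf_lines))

  # ---- variants ------------------------------------------------------------
  # per-gene: one deliberate same-codon SNV pair on the canonical
  # transcript, one multi-allelic SNV site, one padded indel, the rest SNVs
  all_vars <- list()     # truth-level records, keyed by normalized key
  vcf_sites <- list()    # one element per VCF line
  for (g in genes) {
    walk1 <- cds_walk(g$cds1, g$strand)
    used_pos <- integer()
    take_pos <- function(pool) {
      pool <- setdiff(pool, used_pos)
      p <- pool[sample.int(length(pool), 1L)]
      used_pos <<- c(used_pos, p)
      p
    }
    exon_pos <- unlist(Map(function(s, e) seq.int(s + 1L, e),
                           g$exons$start, g$exons$end))
    mk_var <- function(pos, ref, alt, terms_by_tx, low_an = FALSE,
                       pad = FALSE) {
      counts <- fx_draw_counts(populations, low_an)
      list(gene = g, pos = pos, ref = ref, alt = alt,
           key = paste(g$chrom, pos, ref, alt, sep = "-"),
           counts = counts, terms_by_tx = terms_by_tx, pad = pad)
    }
    tx_span <- list()
    tx_span[[g$t1]] <- c(g$start, g$end)
    tx_span[[g$t2]] <- c(min(g$exons$start[1:2]), max(g$exons$end[1:2]))
    tx_of_pos <- function(pos) {
      out <- character()
      for (tid in names(tx_span))
        if (pos - 1L >= tx_span[[tid]][1] && pos - 1L < tx_span[[tid]][2])
          out <- c(out, tid)
      out
    }
    coding_terms <- c("missense_variant", "synonymous_variant", "stop_gained",
                      "splice_region_variant&synonymous_variant")
    terms_for <- function(pos, ref, alt) {
      tids <- tx_of_pos(pos)
      setNames(lapply(tids, function(tid) {
        cds <- if (tid == g$t1) g$cds1 else g$cds2
        in_cds <- any(pos - 1L >= cds$start & pos - 1L < cds$end)
        if (!in_cds) {
          if (g$strand == "+") "5_prime_UTR_variant" else "3_prime_UTR_variant"
        } else if (nchar(ref) != nchar(alt)) {
          if ((abs(nchar(ref) - nchar(alt)) %% 3L) == 0L)
            "inframe_deletion" else "frameshift_variant"
        } else sample(coding_terms, 1L)
      }), tids)
    }
    bases <- c("A", "C", "G", "T")
    gene_vars <- list()

    # deliberate same-codon pair: CDS offsets 3k and 3k+2 of the canonical
    k <- sample.int(length(walk1) %/% 3L - 2L, 1L)
    p1 <- walk1[3L * k + 1L]; p2 <- walk1[3L * k + 3L]
    for (p in sort(c(p1, p2))) {
      used_pos <- c(used_pos, p)
      ref <- sample(bases, 1L); alt <- sample(setdiff(bases, ref), 1L)
      gene_vars <- c(gene_vars, list(mk_var(p, ref, alt, terms_for(p, ref, alt))))
    }
    # one multi-allelic SNV site (two alts, same codon by construction only
    # if both are SNVs at one position — they are)
    p <- take_pos(exon_pos)
    ref <- sample(bases, 1L); alts <- sample(setdiff(bases, ref), 2L)
    ma <- lapply(alts, function(a) mk_var(p, ref, a, terms_for(p, ref, a)))
    ma[[2]]$counts$an <- ma[[1]]$counts$an   # one shared AN per site
    gene_vars <- c(gene_vars, ma)
    # one deletion written padded in the VCF (shared suffix base appended)
    p <- take_pos(exon_pos[exon_pos < g$end - 10L])
    anchor <- sample(bases, 1L); del <- sample(bases, 1L)
    ref <- paste0(anchor, del)
    gene_vars <- c(gene_vars,
                   list(mk_var(p, ref, anchor, terms_for(p, ref, anchor),
                               pad = TRUE)))
    # remaining SNVs, ~15% at reduced call rate
    n_rest <- variants_per_gene - length(gene_vars)
    for (j in seq_len(n_rest)) {
      p <- take_pos(exon_pos)
      ref <- sample(bases, 1L); alt <- sample(setdiff(bases, ref), 1L)
      gene_vars <- c(gene_vars,
                     list(mk_var(p, ref, alt, terms_for(p, ref, alt),
                                 low_an = runif(1) < 0.15)))
    }
    for (v in gene_vars) all_vars[[v$key]] <- v

    # VCF lines: group the multi-allelic site, keep the rest single-alt
    singles <- Filter(function(v) !(v$key %in% c(ma[[1]]$key, ma[[2]]$key)),
                      gene_vars)
    vcf_sites <- c(vcf_sites,
                   lapply(singles, function(v) list(gene = g, alleles = list(v))),
                   list(list(gene = g, alleles = ma)))
  }

  # rsids: ~30% of variants; the CFTR gene (when present) carries the
  # cystic-fibrosis rsid so named-variant search is exercised
  rsid_rows <- list()
  keys <- names(all_vars)
  n_rs <- max(1L, as.integer(round(length(keys) * 0.3)))
  rs_keys <- sort(sample(keys, n_rs))
  rs_nums <- sample.int(2e8L, n_rs)
  for (j in seq_along(rs_keys))
    all_vars[[rs_keys[j]]]$rsid <- sprintf("rs%d", rs_nums[j])
  cftr <- Filter(function(g) g$symbol == "CFTR", genes)
  if (length(cftr)) {
    ck <- Filter(function(k) all_vars[[k]]$gene$gene_id == cftr[[1]]$gene_id,
                 keys)[[1]]
    all_vars[[ck]]$rsid <- "rs113993960"
  }
  for (k in keys) {
    v <- all_vars[[k]]
    if (!is.null(v$rsid))
      rsid_rows[[length(rsid_rows) + 1L]] <- sprintf(
        "%s\t%s\t%d\t%s\t%s", v$rsid, v$gene$chrom, v$pos, v$ref, v$alt)
  }

  # ---- VCF text ------------------------------------------------------------
  csq_format <- "Allele|Consequence|Gene|Feature|CANONICAL|PolyPhen|SIFT|LoF"
  fmt_csq <- function(v) {
    g <- v$gene
    entries <- vapply(names(v$terms_by_tx), function(tid) {
      term <- v$terms_by_tx[[tid]]
      canonical <- if (tid == g$t1) "YES" else ""
      poly <- sift <- lof <- ""
      if (grepl("missense_variant", term)) {
        poly <- sprintf("probably_damaging(%.2f)", runif(1, 0.85, 1))
        sift <- sprintf("deleterious(%.2f)", runif(1, 0, 0.05))
      }
      if (grepl("stop_gained|frameshift", term)) lof <- "HC"
      paste(v$alt_vcf, term, g$gene_id, tid, canonical, poly, sift, lof,
            sep = "|")
    }, character(1))
    paste(entries, collapse = ",")
  }
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "##INFO=<ID=Hom,Number=A,Type=Integer,Description=\"Homozygote count\">",
    unlist(lapply(populations, function(p) c(
      sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"AC in %s\">", p, p),
      sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"AN in %s\">", p, p),
      sprintf("##INFO=<ID=Hom_%s,Number=A,Type=Integer,Description=\"Hom in %s\">", p, p)))),
    sprintf("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations. Format: %s\">",
            csq_format),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  site_order <- order(vapply(vcf_sites, function(s) s$gene$chrom, character(1)),
                      vapply(vcf_sites, function(s) s$alleles[[1]]$pos, integer(1)))
  data_lines <- character()
  for (s in vcf_sites[site_order]) {
    alleles <- s$alleles
    v1 <- alleles[[1]]
    # padded deletions get one shared suffix base appended in the VCF only
    pad_base <- sample(c("A", "C", "G", "T"), 1L)
    write_ref <- if (v1$pad) paste0(v1$ref, pad_base) else v1$ref
    write_alts <- vapply(alleles, function(v)
      if (v$pad) paste0(v$alt, pad_base) else v$alt, character(1))
    for (j in seq_along(alleles)) {
      all_vars[[alleles[[j]]$key]]$alt_vcf <- write_alts[j]
      alleles[[j]]$alt_vcf <- write_alts[j]
    }
    ac <- vapply(alleles, function(v) sum(v$counts$ac), integer(1))
    hom <- vapply(alleles, function(v) sum(v$counts$hom), integer(1))
    an <- sum(alleles[[1]]$counts$an)
    info <- c(sprintf("AC=%s", paste(ac, collapse = ",")),
              sprintf("AN=%d", an),
              sprintf("Hom=%s", paste(hom, collapse = ",")))
    for (p in populations) {
      info <- c(info,
        sprintf("AC_%s=%s", p,
                paste(vapply(alleles, function(v) v$counts$ac[[p]], integer(1)),
                      collapse = ",")),
        sprintf("AN_%s=%d", p, alleles[[1]]$counts$an[[p]]),
        sprintf("Hom_%s=%s", p,
                paste(vapply(alleles, function(v) v$counts$hom[[p]], integer(1)),
                      collapse = ",")))
    }
    csq <- paste(vapply(alleles, fmt_csq, character(1)), collapse = ",")
    info <- c(info, sprintf("CSQ=%s", csq))
    id_field <- if (length(alleles) == 1L && !is.null(all_vars[[v1$key]]$rsid))
      all_vars[[v1$key]]$rsid else "."
    filter <- if (runif(1) < 0.08) "RF" else "PASS"
    for (j in seq_along(alleles)) all_vars[[alleles[[j]]$key]]$filter <- filter
    data_lines <- c(data_lines, sprintf(
      "%s\t%d\t%s\t%s\t%s\t%.1f\t%s\t%s",
      v1$gene$chrom, v1$pos, id_field, write_ref,
      paste(write_alts, collapse = ","), runif(1, 100, 9000), filter,
      paste(info, collapse = ";")))
  }
  vcf_lines <- c(vcf_lines, data_lines)

  # ---- coverage ------------------------------------------------------------
  cutoffs <- c(1, 5, 10, 15, 20, 25, 30, 50, 100)
  cov_lines <- paste(c("#chrom", "pos", "mean", "median", cutoffs),
                     collapse = "\t")
  for (g in genes) {
    pos <- seq.int(g$start - 49L, g$end + 50L)     # 1-based: start0+1-50 ...
    pos <- pos + 1L
    keep <- runif(length(pos)) > 0.07              # ~7% gaps
    pos <- pos[keep]
    mean_d <- round(pmax(0.5, 40 + 15 * sin(pos / 37) + stats::rnorm(length(pos), 0, 4)), 1)
    med_d <- round(mean_d * 0.95)
    for (jj in seq_along(pos)) {
      fr <- round(pmin(1, pmax(0, 1.02 - cutoffs / (1.8 * mean_d[jj] + 1))), 4)
      cov_lines <- c(cov_lines, paste(
        c(g$chrom, pos[jj], sprintf("%.1f", mean_d[jj]), med_d[jj],
          sprintf("%.4f", fr)), collapse = "\t"))
    }
  }

  # ---- constraint ----------------------------------------------------------
  con_lines <- paste(c("transcript_id", "exp_syn", "obs_syn", "syn_z",
                       "exp_mis", "obs_mis", "mis_z", "exp_lof", "obs_lof",
                       "lof_z", "pli"), collapse = "\t")
  for (g in genes) for (tid in c(g$t1, g$t2))
    con_lines <- c(con_lines, sprintf(
      "%s\t%.1f\t%d\t%.2f\t%.1f\t%d\t%.2f\t%.1f\t%d\t%.2f\t%.4f",
      tid, runif(1, 20, 80), as.integer(stats::rpois(1, 40)), stats::rnorm(1),
      runif(1, 40, 160), as.integer(stats::rpois(1, 80)), stats::rnorm(1),
      runif(1, 5, 30), as.integer(stats::rpois(1, 6)), stats::rnorm(1),
      runif(1)))

  # ---- CNVs (SQ straddling the 60 threshold, incl. one exactly at it) ------
  cnv_lines <- paste(c("chrom", "start", "end", "kind", "sq", "population",
                       "sample_id"), collapse = "\t")
  cnv_truth_rows <- list()
  for (g in genes) {
    n_cnv <- 12L
    for (j in seq_len(n_cnv)) {
      s <- g$start + sample.int(1200L, 1L) - 1L
      e <- s + sample(c(5L, 50L, 200L, 600L), 1L)
      kind <- sample(c("DEL", "DUP"), 1L)
      sq <- if (j == 1L) 60 else round(runif(1, 20, 100), 1)
      popn <- sample(populations, 1L)
      sid <- sprintf("S%05d", sample.int(60706L, 1L))
      cnv_lines <- c(cnv_lines, sprintf("%s\t%d\t%d\t%s\t%.1f\t%s\t%s",
                                        g$chrom, s, e, kind, sq, popn, sid))
      cnv_truth_rows[[length(cnv_truth_rows) + 1L]] <-
        list(chrom = g$chrom, start = s, end = e, kind = kind, sq = sq)
    }
  }

  # ---- carriers (GQ/DP straddling 20/10) -----------------------------------
  car_lines <- paste(c("variant_key", "sample_id", "genotype_class", "gq",
                       "dp"), collapse = "\t")
  readviz_truth <- list()
  for (k in sort(names(all_vars))) {
    n_het <- sample(0:9, 1L); n_hom <- sample(0:3, 1L)
    rows <- list()
    for (cls in c("het", "hom")) {
      n <- if (cls == "het") n_het else n_hom
      for (j in seq_len(n)) {
        gq <- sample(c(0:99, 19L, 20L), 1L)   # extra mass at the boundary
        dp <- sample(c(5:40, 9L, 10L), 1L)
        sid <- sprintf("S%05d", sample.int(60706L, 1L))
        rows[[length(rows) + 1L]] <- list(sample_id = sid, cls = cls,
                                          gq = gq, dp = dp)
        car_lines <- c(car_lines, sprintf("%s\t%s\t%s\t%d\t%d",
                                          k, sid, cls, gq, dp))
      }
    }
    sel <- list()
    for (cls in c("het", "hom")) {
      pool <- Filter(function(r) r$cls == cls && r$dp >= 10L && r$gq >= 20L,
                     rows)
      if (length(pool)) {
        gq <- vapply(pool, `[[`, integer(1), "gq")
        sid <- vapply(pool, `[[`, character(1), "sample_id")
        ord <- order(-gq, sid)
        sel[[cls]] <- sid[ord][seq_len(min(5L, length(pool)))]
      } else sel[[cls]] <- character()
    }
    readviz_truth[[k]] <- sel
  }

  # ---- truth ---------------------------------------------------------------
  an_max <- max(vapply(all_vars, function(v) sum(v$counts$an), integer(1)))
  truth_variants <- list()
  # multiallelic = shares its VCF site with another alt (the generator only
  # co-sites the deliberate multi-allelic pair)
  for (k in sort(names(all_vars))) {
    v <- all_vars[[k]]
    site_n <- sum(vapply(all_vars, function(w)
      w$gene$gene_id == v$gene$gene_id && w$pos == v$pos &&
        nchar(w$ref) == 1L && nchar(w$alt) == 1L, logical(1)))
    is_multi <- nchar(v$ref) == 1L && nchar(v$alt) == 1L && site_n > 1L
    truth_variants[[k]] <- list(
      gene_id = v$gene$gene_id,
      worst_consequence = fx_severity_rank(
        unlist(strsplit(unlist(v$terms_by_tx), "&", fixed = TRUE)),
        severity_terms),
      multiallelic = is_multi,
      low_an = sum(v$counts$an) < 0.8 * an_max,
      rsid = v$rsid, filter = v$filter,
      ac = sum(v$counts$ac), an = sum(v$counts$an), hom = sum(v$counts$hom))
  }

  # MNV truth: all same-codon SNV pairs per transcript, by naive walk
  mnv_truth <- list()
  for (g in genes) {
    for (tx in list(list(id = g$t1, cds = g$cds1),
                    list(id = g$t2, cds = g$cds2))) {
      walk <- cds_walk(tx$cds, g$strand)
      snvs <- Filter(function(v) v$gene$gene_id == g$gene_id &&
                       nchar(v$ref) == 1L && nchar(v$alt) == 1L &&
                       tx$id %in% names(v$terms_by_tx), all_vars)
      if (length(snvs) < 2L) next
      codon <- vapply(snvs, function(v) {
        o <- match(v$pos, walk)
        if (is.na(o)) NA_integer_ else (o - 1L) %/% 3L
      }, integer(1))
      kk <- vapply(snvs, `[[`, character(1), "key")
      pp <- vapply(snvs, `[[`, integer(1), "pos")
      ord <- order(pp, kk)
      kk <- kk[ord]; codon <- codon[ord]
      pairs <- list()
      for (a in seq_len(length(kk) - 1L)) for (b in seq.int(a + 1L, length(kk)))
        if (!is.na(codon[a]) && !is.na(codon[b]) && codon[a] == codon[b])
          pairs[[length(pairs) + 1L]] <- c(kk[a], kk[b])
      if (length(pairs)) mnv_truth[[tx$id]] <- pairs
    }
  }
  for (tid in names(mnv_truth))
    for (pr in mnv_truth[[tid]])
      for (k in pr) truth_variants[[k]]$mnv_candidate <- TRUE
  for (k in names(truth_variants))
    if (is.null(truth_variants[[k]]$mnv_candidate))
      truth_variants[[k]]$mnv_candidate <- FALSE

  # CNV truth: brute-force double loop over canonical exons, strict SQ > 60
  cnv_truth <- list()
  for (g in genes) {
    del <- 0L; dup <- 0L
    for (r in cnv_truth_rows) {
      if (r$chrom != g$chrom || r$sq <= 60) next
      hit <- FALSE
      for (k in seq_len(nrow(g$exons)))
        if (r$start < g$exons$end[k] && r$end > g$exons$start[k]) hit <- TRUE
      if (hit) {
        if (r$kind == "DEL") del <- del + 1L else dup <- dup + 1L
      }
    }
    cnv_truth[[g$gene_id]] <- list(DEL = del, DUP = dup)
  }

  gene_truth <- lapply(genes, function(g) list(
    gene_id = g$gene_id, symbol = g$symbol, chrom = g$chrom,
    strand = g$strand, canonical_transcript_id = g$t1,
    n_variants = sum(vapply(all_vars, function(v)
      v$gene$gene_id == g$gene_id, logical(1)))))

  truth <- list(seed = seed, n_genes = n_genes,
                variants_per_gene = variants_per_gene,
                populations = as.list(populations), an_max = an_max,
                genes = gene_truth, variants = truth_variants,
                mnv_pairs = mnv_truth, cnv_counts = cnv_truth,
                readviz = readviz_truth)

  # ---- aliases & dbSNP -----------------------------------------------------
  alias_lines <- "gene_id\talias"
  for (g in genes) for (a in g$aliases)
    alias_lines <- c(alias_lines, sprintf("%s\t%s", g$gene_id, a))
  dbsnp_lines <- c("rsid\tchrom\tpos\tref\talt", unlist(rsid_rows))

  paths <- list(vcf = file.path(out_dir, "sites.vcf"),
                gtf = file.path(out_dir, "genes.gtf"),
                coverage = file.path(out_dir, "coverage.tsv"),
                constraint = file.path(out_dir, "constraint.tsv"),
                cnv = file.path(out_dir, "cnv.tsv"),
                dbsnp = file.path(out_dir, "dbsnp.tsv"),
                aliases = file.path(out_dir, "aliases.tsv"),
                carriers = file.path(out_dir, "carriers.tsv"),
                truth = file.path(out_dir, "truth.json"))
  writeLines(vcf_lines, paths$vcf)
  writeLines(gtf_lines, paths$gtf)
  writeLines(cov_lines, paths$coverage)
  writeLines(con_lines, paths$constraint)
  writeLines(cnv_lines, paths$cnv)
  writeLines(dbsnp_lines, paths$dbsnp)
  writeLines(alias_lines, paths$aliases)
  writeLines(car_lines, paths$carriers)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' Build a store from a generated fixture bundle
#'
#' Convenience wrapper wiring the bundle paths of [generate_fixtures()] into
#' [build_store()].
#'
#' @param bundle result of [generate_fixtures()] (or a directory containing
#'   a bundle)
#' @param config a [store_config()]
#' @return a `vb_store`
#' @export
build_store_from_bundle <- function(bundle, config = store_config()) {
  if (is.character(bundle)) {
    d <- bundle
    bundle <- list(paths = list(
      vcf = file.path(d, "sites.vcf"), gtf = file.path(d, "genes.gtf"),
      coverage = file.path(d, "coverage.tsv"),
      constraint = file.path(d, "constraint.tsv"),
      cnv = file.path(d, "cnv.tsv"), dbsnp = file.path(d, "dbsnp.tsv"),
      aliases = file.path(d, "aliases.tsv"),
      carriers = file.path(d, "carriers.tsv")))
  }
  p <- bundle$paths
  build_store(p$vcf, p$gtf, p$coverage, constraint_path = p$constraint,
              cnv_path = p$cnv, dbsnp_path = p$dbsnp,
              carriers_path = p$carriers, alias_path = p$aliases,
              config = config)
}
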
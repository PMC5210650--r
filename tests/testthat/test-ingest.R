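write_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
  "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
  "##INFO=<ID=Hom,Number=A,Type=Integer,Description=\"Hom\">",
  "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations from VEP. Format: Allele|Consequence|Gene|Feature|CANONICAL|PolyPhen|SIFT|LoF\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

test_that("sites VCF reading keeps alts intact and captures the CSQ format", {
  path <- write_vcf(c(vcf_header,
    "1\t100\trs1\tA\tC,G\t50.0\tPASS\tAC=3,1;AN=200;Hom=0,0;CSQ=C|missense_variant|G1|T1|YES|||",
    "chr2\t200\t.\tT\tA\t60.0\tRF\tAC=5;AN=100;Hom=2;CSQ="))
  res <- read_sites_vcf(path)
  expect_identical(res$csq_format,
                   c("Allele", "Consequence", "Gene", "Feature", "CANONICAL",
                     "PolyPhen", "SIFT", "LoF"))
  expect_length(res$sites, 2L)
  s1 <- res$sites[[1]]
  expect_identical(s1$alts, c("C", "G"))          # splitting is downstream
  expect_identical(s1$ac, c(3L, 1L))
  expect_identical(s1$rsid, "rs1")
  expect_identical(res$sites[[2]]$chrom, "2")     # chr prefix stripped
  expect_identical(res$sites[[2]]$filter, "RF")
})

test_that("a VCF without data lines still yields the parsed header", {
  path <- write_vcf(vcf_header)
  res <- suppressWarnings(read_sites_vcf(path))
  expect_length(res$sites, 0L)
  expect_identical(res$csq_format[2], "Consequence")
})

test_that("a missing consequence INFO declaration is fatal and named", {
  path <- write_vcf(c(vcf_header[-5],
    "1\t100\t.\tA\tC\t50.0\tPASS\tAC=3;AN=200;Hom=0"))
  expect_error(read_sites_vcf(path), "CSQ")
  # a field that exists but declares no sub-field order is also fatal
  expect_error(read_sites_vcf(path, csq_field_name = "AC"), "Format")
})

test_that("fixture VCF record count equals a raw line scan", {
  b <- fixture_bundle()
  n_lines <- sum(!startsWith(readLines(b$paths$vcf), "#"))
  res <- read_sites_vcf(b$paths$vcf)
  expect_identical(length(res$sites), n_lines)
})

test_that("consequence entries parse terms, predictions and canonical flag", {
  site <- list(chrom = "1", pos = 100L, ref = "A", alts = "G",
               csq = "G|missense_variant&splice_region_variant|ENSG01|ENST01|YES|probably_damaging(0.98)|deleterious(0.01)|")
  fmt <- c("Allele", "Consequence", "Gene", "Feature", "CANONICAL",
           "PolyPhen", "SIFT", "LoF")
  out <- parse_consequences(site, fmt)
  expect_length(out, 1L)
  expect_length(out[[1]], 1L)
  cons <- out[[1]][[1]]
  expect_identical(cons$consequence_terms,
                   c("missense_variant", "splice_region_variant"))
  expect_true(cons$is_canonical)
  expect_identical(cons$polyphen,
                   list(prediction = "probably_damaging", score = 0.98))
  expect_identical(cons$sift, list(prediction = "deleterious", score = 0.01))
  expect_null(cons$lof)

  empty <- site; empty$csq <- ""
  expect_identical(parse_consequences(empty, fmt), list(list()))

  short <- site; short$csq <- "G|missense_variant|ENSG01"
  expect_warning(out2 <- parse_consequences(short, fmt), "rejecting")
  expect_length(out2[[1]], 0L)

  expect_error(parse_consequences(site, c("Allele", "Consequence")),
               "must include")
})

test_that("consequence entries partition to their alt allele", {
  fmt <- c("Allele", "Consequence", "Gene", "Feature", "CANONICAL")
  site <- list(chrom = "1", pos = 100L, ref = "A", alts = c("C", "G"),
               csq = paste("C|missense_variant|G1|T1|YES",
                           "G|synonymous_variant|G1|T1|YES", sep = ","))
  out <- parse_consequences(site, fmt)
  expect_identical(out[[1]][[1]]$consequence_terms, "missense_variant")
  expect_identical(out[[2]][[1]]$consequence_terms, "synonymous_variant")
  expect_length(out[[1]], 1L)
  expect_length(out[[2]], 1L)
  # VEP-trimmed indel spelling also matches (shared first base stripped)
  indel <- list(chrom = "1", pos = 100L, ref = "AT", alts = "A",
                csq = "-|frameshift_variant|G1|T1|YES")
  out2 <- parse_consequences(indel, fmt)
  expect_length(out2[[1]], 1L)
  # without an Allele sub-field every entry attaches to every alt
  fmt2 <- c("Consequence", "Gene", "Feature", "CANONICAL")
  site2 <- list(chrom = "1", pos = 100L, ref = "A", alts = c("C", "G"),
                csq = "missense_variant|G1|T1|YES")
  out3 <- parse_consequences(site2, fmt2)
  expect_length(out3[[1]], 1L)
  expect_length(out3[[2]], 1L)
})

gtf_line <- function(type, start, end, gid, tid = NULL, strand = "+",
                     name = "SYM") {
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', gid, name)
  if (!is.null(tid))
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     gid, tid, name)
  sprintf("chr1\tsrc\t%s\t%d\t%d\t.\t%s\t.\t%s", type, start, end, strand, attrs)
}

test_that("GTF coordinates convert to 0-based half-open", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("gene", 101, 200, "G1"),
               gtf_line("transcript", 101, 200, "G1", "T1"),
               gtf_line("exon", 101, 200, "G1", "T1"),
               gtf_line("CDS", 101, 199, "G1", "T1")), path)
  m <- read_gene_models(path)
  expect_identical(m$genes$G1$start, 100L)
  expect_identical(m$genes$G1$end, 200L)
  ex <- m$transcripts$T1$features
  expect_identical(ex$start[ex$kind == "exon"], 100L)
  expect_identical(ex$end[ex$kind == "exon"], 200L)
  expect_identical(m$genes$G1$chrom, "1")
})

test_that("canonical transcript is longest CDS with lexicographic ties, stably", {
  lines_for <- function(order_ids) {
    c(gtf_line("gene", 1, 1000, "G1"),
      unlist(lapply(order_ids, function(tid) c(
        gtf_line("transcript", 1, 1000, "G1", tid),
        gtf_line("exon", 1, 1000, "G1", tid),
        gtf_line("CDS", 1, 300, "G1", tid)))))
  }
  for (ids in list(c("TB", "TA"), c("TA", "TB"))) {
    path <- tempfile(fileext = ".gtf")
    writeLines(lines_for(ids), path)
    m <- read_gene_models(path)
    expect_identical(m$genes$G1$canonical_transcript_id, "TA")
  }
  # longer CDS wins regardless of id order
  path <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("gene", 1, 1000, "G1"),
               gtf_line("transcript", 1, 1000, "G1", "TA"),
               gtf_line("exon", 1, 1000, "G1", "TA"),
               gtf_line("CDS", 1, 300, "G1", "TA"),
               gtf_line("transcript", 1, 1000, "G1", "TZ"),
               gtf_line("exon", 1, 1000, "G1", "TZ"),
               gtf_line("CDS", 1, 600, "G1", "TZ")), path)
  expect_identical(read_gene_models(path)$genes$G1$canonical_transcript_id,
                   "TZ")
})

test_that("minus-strand exons are stored in ascending genomic order", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("gene", 1, 1000, "G1", strand = "-"),
               gtf_line("transcript", 1, 1000, "G1", "T1", strand = "-"),
               gtf_line("exon", 501, 600, "G1", "T1", strand = "-"),
               gtf_line("exon", 101, 200, "G1", "T1", strand = "-")), path)
  f <- read_gene_models(path)$transcripts$T1$features
  expect_identical(f$start, c(100L, 500L))
})

test_that("features referencing unknown transcripts are fatal", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("gene", 1, 1000, "G1"),
               gtf_line("transcript", 1, 1000, "G1", "T1"),
               gtf_line("exon", 1, 1000, "G1", "TMISSING")), path)
  expect_error(read_gene_models(path), "TMISSING")
})

test_that("coverage reading takes the cutoff set from the header", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tmean\tmedian\t1\t5\t10",
               "1\t1000\t34.2\t33\t1.0\t0.99\t0.97"), path)
  cov <- read_coverage(path)
  expect_identical(attr(cov, "cutoffs"), c(1, 5, 10))
  expect_identical(cov$`5`, 0.99)
  expect_identical(cov$pos, 1000L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tmean\tmedian\t1",
               "1\t1000\t34.2\t33\t1.5"), bad)
  expect_error(read_coverage(bad), "1000")

  many <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tmean\tmedian\t1\t10",
               sprintf("1\t%d\t30.0\t29\t1.0\t0.9", 1:100)), many)
  expect_identical(nrow(read_coverage(many)), 100L)
})

test_that("side tables load constraint, CNVs and normalized rsid mappings", {
  con <- tempfile(); cnv <- tempfile(); dbs <- tempfile()
  writeLines(c("transcript_id\texp_syn\tobs_syn\tsyn_z\texp_mis\tobs_mis\tmis_z\texp_lof\tobs_lof\tlof_z\tpli",
               "ENST01\t10.1\t4\t-2.1\t20.0\t10\t1.0\t5.0\t0\t2.0\t0.99"), con)
  writeLines("chrom\tstart\tend\tkind\tsq\tpopulation\tsample_id", cnv)
  writeLines(c("rsid\tchrom\tpos\tref\talt",
               "rs113993960\t7\t117199644\tCTT\tCT"), dbs)
  side <- read_side_tables(con, cnv, dbs)
  expect_identical(side$constraint$ENST01$pli, 0.99)
  expect_identical(side$constraint$ENST01$exp_syn, 10.1)
  expect_identical(nrow(side$cnv), 0L)
  # padded dbSNP row normalized on ingest
  expect_identical(side$dbsnp$ref, "CT")
  expect_identical(side$dbsnp$alt, "C")

  dup <- tempfile()
  writeLines(c("rsid\tchrom\tpos\tref\talt",
               "rs1\t1\t100\tA\tG", "rs2\t1\t100\tA\tG"), dup)
  expect_warning(side2 <- read_side_tables(dbsnp_path = dup), "last row wins")
  expect_identical(side2$dbsnp$rsid, "rs2")
})

test_that("re-reading a fixture yields identical structures", {
  b <- fixture_bundle()
  expect_identical(read_sites_vcf(b$paths$vcf), read_sites_vcf(b$paths$vcf))
  expect_identical(read_coverage(b$paths$coverage),
                   read_coverage(b$paths$coverage))
  expect_identical(read_gene_models(b$paths$gtf, b$paths$aliases),
                   read_gene_models(b$paths$gtf, b$paths$aliases))
})
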
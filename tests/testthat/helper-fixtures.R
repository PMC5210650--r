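# Shared fixtures: one generated bundle + built store per seed, memoised
# across test files so the pipeline runs once.

.fx_env <- new.env(parent = emptyenv())

fixture_bundle <- function(seed = 7) {
  key <- paste0("bundle", seed)
  if (is.null(.fx_env[[key]])) {
    dir <- file.path(tempdir(), paste0("vb_fixture_", seed))
    .fx_env[[key]] <- generate_fixtures(seed, dir)
  }
  .fx_env[[key]]
}

fixture_store <- function(seed = 7) {
  key <- paste0("store", seed)
  if (is.null(.fx_env[[key]]))
    .fx_env[[key]] <- build_store_from_bundle(fixture_bundle(seed))
  .fx_env[[key]]
}

# random ACGT string of length n
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# all ACGT padding strings of length 0..max_len
all_pads <- function(max_len = 3) {
  unlist(lapply(0:max_len, function(L) {
    if (L == 0) return("")
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)), 1,
          paste, collapse = "")
  }))
}

# independent naive codon oracle: walk the CDS base by base in translation
# order and look the position up
naive_codon <- function(tx, genomic_pos) {
  cds <- tx$features[tx$features$kind == "CDS", , drop = FALSE]
  walk <- unlist(Map(function(s, e) seq.int(s + 1L, e), cds$start, cds$end))
  walk <- sort(walk)
  if (tx$strand == "-") walk <- rev(walk)
  o <- match(genomic_pos, walk)
  if (is.na(o)) return(NULL)
  list(codon_number = (o - 1L) %/% 3L, offset_in_codon = (o - 1L) %% 3L)
}

# a tiny hand-written bundle: gene A (one variant), gene B (no variants),
# coverage over both. Used for edge-case pages.
mini_bundle <- function(dir = tempfile("mini")) {
  dir.create(dir, showWarnings = FALSE)
  gtf <- c(
    "chr1\tsynth\tgene\t101\t400\t.\t+\t.\tgene_id \"GA\"; gene_name \"ALPHA\";",
    "chr1\tsynth\ttranscript\t101\t400\t.\t+\t.\tgene_id \"GA\"; transcript_id \"TA1\"; gene_name \"ALPHA\";",
    "chr1\tsynth\texon\t101\t400\t.\t+\t.\tgene_id \"GA\"; transcript_id \"TA1\"; gene_name \"ALPHA\";",
    "chr1\tsynth\tCDS\t101\t400\t.\t+\t.\tgene_id \"GA\"; transcript_id \"TA1\"; gene_name \"ALPHA\";",
    "chr1\tsynth\tgene\t1001\t1300\t.\t-\t.\tgene_id \"GB\"; gene_name \"BETA\";",
    "chr1\tsynth\ttranscript\t1001\t1300\t.\t-\t.\tgene_id \"GB\"; transcript_id \"TB1\"; gene_name \"BETA\";",
    "chr1\tsynth\texon\t1001\t1300\t.\t-\t.\tgene_id \"GB\"; transcript_id \"TB1\"; gene_name \"BETA\";",
    "chr1\tsynth\tCDS\t1001\t1300\t.\t-\t.\tgene_id \"GB\"; transcript_id \"TB1\"; gene_name \"BETA\";")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
    "##INFO=<ID=Hom,Number=A,Type=Integer,Description=\"Hom\">",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Format: Allele|Consequence|Gene|Feature|CANONICAL|PolyPhen|SIFT|LoF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("1\t150\t.\tA\tG\t100.0\tPASS\t",
           "AC=3;AN=1000;Hom=1;CSQ=G|missense_variant|GA|TA1|YES|||"))
  cov <- c(paste(c("#chrom", "pos", "mean", "median", "1", "10"),
                 collapse = "\t"),
           vapply(c(101:400, 1001:1300), function(p)
             paste(c("1", p, "30.0", "29", "1.0000", "0.9000"),
                   collapse = "\t"), character(1)))
  paths <- list(vcf = file.path(dir, "sites.vcf"),
                gtf = file.path(dir, "genes.gtf"),
                coverage = file.path(dir, "coverage.tsv"))
  writeLines(vcf, paths$vcf)
  writeLines(gtf, paths$gtf)
  writeLines(cov, paths$coverage)
  paths
}

mini_store <- function() {
  if (is.null(.fx_env$mini)) {
    p <- mini_bundle()
    .fx_env$mini <- build_store(p$vcf, p$gtf, p$coverage)
  }
  .fx_env$mini
}
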
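test_that("minimal representation trims padded alleles to a unique fixed point", {
  expect_identical(minimal_representation(1001, "CTCC", "CCC"),
                   list(pos = 1001L, ref = "CT", alt = "C"))
  expect_identical(minimal_representation(500, "A", "G"),
                   list(pos = 500L, ref = "A", alt = "G"))
  # suffix first: TAA/TA -> TA/T, then the prefix trim stops because the
  # alt is already a single base
  expect_identical(minimal_representation(100, "TAA", "TA"),
                   list(pos = 100L, ref = "TA", alt = "T"))
  expect_error(minimal_representation(5, "AC", "AC"), "not a variant")

  set.seed(11)
  pads <- all_pads(2)
  for (i in 1:60) {
    ref <- rand_seq(sample(1:3, 1)); alt <- rand_seq(sample(1:3, 1))
    if (ref == alt) next
    base <- minimal_representation(1000L, ref, alt)
    # idempotent and position-monotone
    expect_identical(minimal_representation(base$pos, base$ref, base$alt),
                     base)
    expect_gte(base$pos, 1000L)
    # suffix paddings always collapse back; prefix paddings do too unless
    # the minimal form ends in a shared base (an indel inside a base run,
    # where placement is inherently ambiguous without a reference genome)
    run_ambiguous <- substr(base$ref, nchar(base$ref), nchar(base$ref)) ==
      substr(base$alt, nchar(base$alt), nchar(base$alt))
    ok <- TRUE
    for (p in pads) for (s in pads) {
      if (nzchar(p) && run_ambiguous) next
      padded <- minimal_representation(1000L - nchar(p),
                                       paste0(p, ref, s), paste0(p, alt, s))
      if (!identical(padded, base)) ok <- FALSE
    }
    expect_true(ok, info = sprintf("%s/%s", ref, alt))
  }
})

test_that("indels inside base runs keep an equivalent shifted spelling", {
  # deleting one T of the run GTG written two ways: the two spellings denote
  # the same edit, and each is a stable fixed point
  a <- minimal_representation(1000L, "TG", "G")
  b <- minimal_representation(999L, "GTG", "GG")   # prefix-padded form
  expect_identical(a, list(pos = 1000L, ref = "TG", alt = "G"))
  expect_identical(b, list(pos = 999L, ref = "GT", alt = "G"))
  expect_identical(minimal_representation(b$pos, b$ref, b$alt), b)
  # both spellings delete one base and net the same sequence change
  expect_identical(nchar(a$ref) - nchar(a$alt), nchar(b$ref) - nchar(b$alt))
})

test_that("worst consequence picks the most severe term, order-independently", {
  sev <- load_severity_table()
  mk <- function(terms) transcript_consequence("T1", "G1", terms)
  expect_identical(worst_consequence(list(mk("synonymous_variant"),
                                          mk("missense_variant"),
                                          mk("stop_gained")), sev),
                   "stop_gained")
  expect_identical(worst_consequence(list(mk("intron_variant")), sev),
                   "intron_variant")
  expect_error(worst_consequence(list(), sev), "empty")
  expect_error(worst_consequence(list(mk("made_up_term")), sev), "made_up_term")

  set.seed(12)
  terms_pool <- as.character(sev)
  for (i in 1:100) {
    terms <- sample(terms_pool, sample(1:6, 1))
    entries <- lapply(terms, mk)
    # brute-force oracle: minimum severity rank over the raw term list
    oracle <- terms_pool[min(match(terms, terms_pool))]
    expect_identical(worst_consequence(entries, sev), oracle)
    expect_identical(worst_consequence(sample(entries), sev), oracle)
  }
})

test_that("codon arithmetic matches a naive per-base walk on both strands", {
  plus <- transcript_model("TP", "G", "+",
                           data.frame(start = 100L, end = 130L, kind = "CDS"))
  expect_identical(codon_index(plus, 104L),
                   list(codon_number = 1L, offset_in_codon = 0L))
  minus <- transcript_model("TM", "G", "-",
                            data.frame(start = 100L, end = 200L, kind = "CDS"))
  expect_identical(codon_index(minus, 200L),
                   list(codon_number = 0L, offset_in_codon = 0L))
  expect_identical(codon_index(minus, 198L),
                   list(codon_number = 0L, offset_in_codon = 2L))
  utr <- transcript_model("TU", "G", "+",
                          data.frame(start = c(50L, 100L), end = c(100L, 130L),
                                     kind = c("UTR", "CDS")))
  expect_null(codon_index(utr, 60L))

  set.seed(13)
  for (i in 1:40) {
    strand <- sample(c("+", "-"), 1)
    s1 <- sample(100:200, 1); e1 <- s1 + 3 * sample(2:6, 1)
    s2 <- e1 + sample(10:50, 1); e2 <- s2 + 3 * sample(2:6, 1)
    tx <- transcript_model("T", "G", strand,
                           data.frame(start = c(s1, s2), end = c(e1, e2),
                                      kind = "CDS"))
    for (pos in sample(s1:(e2 + 5), 12))
      expect_identical(codon_index(tx, pos), naive_codon(tx, pos),
                       info = sprintf("strand %s pos %d", strand, pos))
  }
})

test_that("same-codon MNV candidates equal the brute-force all-pairs scan", {
  tx <- transcript_model("T1", "G1", "+",
                         data.frame(start = 100L, end = 160L, kind = "CDS"))
  mkv <- function(pos, ref = "A", alt = "G")
    variant("1", pos, ref, alt, 1L, 100L, 0L)
  # two SNVs in codon 1 (cds offsets 3,5 -> positions 104,106)
  res <- detect_mnv_candidates(list(mkv(104L), mkv(106L, alt = "C")), tx)
  expect_length(res$pairs, 1L)
  expect_identical(res$pairs[[1]], c("1-104-A-G", "1-106-A-C"))
  # adjacent positions straddling a codon boundary: offsets 2 and 0 of
  # consecutive codons -> no pair (confirmed by the naive walk)
  expect_identical(naive_codon(tx, 103L)$codon_number, 0L)
  expect_identical(naive_codon(tx, 104L)$codon_number, 1L)
  expect_length(detect_mnv_candidates(list(mkv(103L), mkv(104L)), tx)$pairs, 0L)
  # n SNVs in one codon -> choose(n, 2) pairs
  vs <- list(mkv(104L, alt = "G"), mkv(105L, alt = "C"), mkv(106L, alt = "T"))
  expect_length(detect_mnv_candidates(vs, tx)$pairs, choose(3, 2))
  # indels never participate
  expect_length(detect_mnv_candidates(list(mkv(104L), mkv(105L, "AT", "A")),
                                      tx)$pairs, 0L)

  set.seed(14)
  for (i in 1:30) {
    strand <- sample(c("+", "-"), 1)
    tx2 <- transcript_model("T2", "G1", strand,
                            data.frame(start = c(100L, 200L),
                                       end = c(130L, 230L), kind = "CDS"))
    posns <- sample(95:235, sample(3:8, 1))
    vs <- lapply(posns, function(p)
      mkv(p, alt = sample(c("C", "G", "T"), 1)))
    got <- detect_mnv_candidates(vs, tx2)
    # brute force with the naive walk oracle
    keys <- vapply(vs, variant_key, character(1))
    ord <- order(posns, keys)
    keys <- keys[ord]; posns_o <- posns[ord]
    codons <- vapply(posns_o, function(p) {
      ci <- naive_codon(tx2, p)
      if (is.null(ci)) NA_integer_ else ci$codon_number
    }, integer(1))
    exp_pairs <- list()
    n <- length(keys)
    for (a in seq_len(n - 1)) for (b in seq.int(a + 1, n))
      if (!is.na(codons[a]) && !is.na(codons[b]) &&
          codons[a] == codons[b] && keys[a] != keys[b])
        exp_pairs[[length(exp_pairs) + 1]] <- c(keys[a], keys[b])
    expect_identical(got$pairs, exp_pairs)
    # symmetric in input order
    expect_identical(detect_mnv_candidates(sample(vs), tx2)$pairs, exp_pairs)
  }
})

test_that("co-occurrence table restricts MNV pairs to co-observed ones", {
  tx <- transcript_model("T1", "G1", "+",
                         data.frame(start = 100L, end = 160L, kind = "CDS"))
  vs <- list(variant("1", 104L, "A", "G", 1L, 100L, 0L),
             variant("1", 105L, "A", "C", 1L, 100L, 0L),
             variant("1", 106L, "A", "T", 1L, 100L, 0L))
  cc <- data.frame(variant_key_1 = "1-104-A-G", variant_key_2 = "1-105-A-C",
                   n_individuals = 2L)
  res <- detect_mnv_candidates(vs, tx, cooccurrence = cc)
  expect_identical(res$pairs, list(c("1-104-A-G", "1-105-A-C")))
})

test_that("multi-allelic splitting assigns per-alt counts and flags", {
  site <- list(chrom = "1", pos = 5000L, ref = "A", alts = c("C", "G", "T"),
               qual = 900, filter = "PASS", ac = c(5L, 2L, 1L), an = 1000L,
               hom = c(1L, 0L, 0L),
               pop_counts = list(NFE = list(ac = c(5L, 2L, 1L), an = 1000L,
                                            hom = c(1L, 0L, 0L))),
               consequences_by_alt = NULL, rsid = NULL)
  out <- split_multiallelic(site)
  expect_length(out, 3L)
  expect_identical(vapply(out, `[[`, integer(1), "ac_total"), c(5L, 2L, 1L))
  expect_true(all(vapply(out, function(v) "multiallelic" %in% v$flags,
                         logical(1))))
  expect_true(all(vapply(out, function(v) v$an_total == 1000L, logical(1))))

  single <- site; single$alts <- "C"; single$ac <- 5L; single$hom <- 1L
  single$pop_counts <- list(NFE = list(ac = 5L, an = 1000L, hom = 1L))
  out1 <- split_multiallelic(single)
  expect_length(out1, 1L)
  expect_length(out1[[1]]$flags, 0L)

  star <- site; star$alts <- c("C", "*"); star$ac <- c(5L, 2L)
  star$hom <- c(1L, 0L)
  star$pop_counts <- list(NFE = list(ac = c(5L, 2L), an = 1000L,
                                     hom = c(1L, 0L)))
  expect_warning(out2 <- split_multiallelic(star), "star allele")
  expect_length(out2, 1L)
  expect_identical(out2[[1]]$an_total, 1000L)   # AN untouched by the drop

  bad <- site; bad$ac <- c(5L, 2L)
  expect_error(split_multiallelic(bad), "does not match alt count")
})

test_that("low-AN flagging uses a strict fraction-of-maximum threshold", {
  mkv <- function(an) variant("1", 1L, "A", "G", 0L, an, 0L)
  expect_false("low_an" %in% flag_low_an(mkv(1000L), 1000L)$flags)
  expect_true("low_an" %in% flag_low_an(mkv(500L), 1000L)$flags)
  expect_false("low_an" %in% flag_low_an(mkv(800L), 1000L)$flags)  # boundary
  expect_true("low_an" %in% flag_low_an(mkv(799L), 1000L)$flags)
  expect_false("low_an" %in%
                 flag_low_an(mkv(500L), 1000L, threshold_fraction = 0.4)$flags)
  expect_error(flag_low_an(mkv(10L), 0L), "an_max")
})
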
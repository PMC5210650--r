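# Variant-level algorithms: multi-allelic splitting, minimal representation,
# consequence severity ranking, codon arithmetic and same-codon MNV-candidate
# detection.

#' Load a consequence severity table
#'
#' An ordered ranking of Sequence Ontology consequence terms, most severe
#' first, used to pick the "worst" annotation of a variant across
#' transcripts. The default table ships with the package (the VEP ranking)
#' and can be overridden with any file holding one term per line.
#'
#' @param path file with one term per line, most severe first; `#` comments
#'   allowed. Default: the packaged VEP ordering.
#' @return a `vb_severity_table`: character vector of terms with an index
#'   lookup attribute (1 = most severe)
#' @export
load_severity_table <- function(path = system.file("extdata",
                                                   "consequence_severity.txt",
                                                   package = "varbrowse")) {
  terms <- readLines(path, warn = FALSE)
  terms <- trimws(terms)
  terms <- terms[nzchar(terms) & !startsWith(terms, "#")]
  if (anyDuplicated(terms))
    vb_stop("severity table contains duplicate terms: %s",
            paste(unique(terms[duplicated(terms)]), collapse = ", "))
  structure(terms, index = setNames(seq_along(terms), terms),
            class = "vb_severity_table")
}

severity_index <- function(terms, table) {
  idx <- attr(table, "index")[terms]
  if (anyNA(idx)) {
    missing <- terms[is.na(idx)]
    vb_stop("consequence term(s) not in severity table: %s",
            paste(unique(missing), collapse = ", "))
  }
  unname(idx)
}

#' Worst consequence across transcripts
#'
#' The most severe Sequence Ontology term over all terms of all
#' per-transcript consequence entries; invariant under input order.
#'
#' @param consequences non-empty list of [transcript_consequence()]s
#' @param table severity table from [load_severity_table()]
#' @return the single most severe term
#' @export
worst_consequence <- function(consequences, table = load_severity_table()) {
  if (length(consequences) == 0L) vb_stop("worst_consequence of an empty list")
  terms <- unique(unlist(lapply(consequences, `[[`, "consequence_terms")))
  table[min(severity_index(terms, table))]
}

#' Minimal representation of a variant
#'
#' Normalizes (pos, ref, alt) so equivalent padded descriptions unify: the
#' shared suffix is trimmed first, then the shared prefix (advancing `pos`
#' per trimmed base), in both cases only while both alleles remain longer
#' than one base. Idempotent; output position >= input position.
#'
#' @param pos 1-based position of the first ref base
#' @param ref,alt allele strings, `ref != alt`
#' @return `list(pos, ref, alt)`
#' @export
minimal_representation <- function(pos, ref, alt) {
  if (ref == alt) vb_stop("ref == alt ('%s'): not a variant", ref)
  .minrep_cpp(as.integer(pos), ref, alt)
}

#' Split a multi-allelic site into per-alt records
#'
#' Each alt allele receives its own AC/Hom (total and per population) while
#' AN is shared; when the site had more than one alt, every split record is
#' flagged `multiallelic`. Star alleles (`*`, spanning deletions) are
#' dropped with a warning without touching AN. Consequence entries are
#' partitioned to their alt by the annotation's allele field.
#'
#' @param site a raw site record from [read_sites_vcf()]: list with chrom,
#'   pos, ref, alts (character vector), qual, filter, ac (per alt), an,
#'   hom (per alt), pop_counts (list per population of list(ac per alt, an,
#'   hom per alt)), consequences_by_alt (list per alt index), rsid
#' @return list of `vb_variant`s, one per retained alt (not yet normalized)
#' @export
split_multiallelic <- function(site) {
  n_alt <- length(site$alts)
  if (n_alt < 1L) vb_stop("site with no alt alleles")
  if (length(site$ac) != n_alt || length(site$hom) != n_alt)
    vb_stop("per-alt AC/Hom length (%d/%d) does not match alt count (%d) at %s:%d",
            length(site$ac), length(site$hom), n_alt, site$chrom, site$pos)
  keep <- which(site$alts != "*")
  if (length(keep) < n_alt)
    warning(sprintf("dropping star allele at %s:%d", site$chrom, site$pos),
            call. = FALSE)
  flags <- if (n_alt > 1L) "multiallelic" else character()
  lapply(keep, function(i) {
    pops <- lapply(site$pop_counts, function(p)
      list(ac = p$ac[i], an = p$an, hom = p$hom[i]))
    variant(site$chrom, site$pos, site$ref, site$alts[i],
            ac_total = site$ac[i], an_total = site$an, hom_total = site$hom[i],
            rsid = site$rsid, site_quality = site$qual,
            filter_status = site$filter, pop_counts = pops,
            flags = flags,
            consequences = site$consequences_by_alt[[i]] %||% list())
  })
}

#' Codon index of a genomic position within a transcript's CDS
#'
#' Computes which codon (0-based) and which position within the codon a
#' genomic base falls on, in transcript orientation: the CDS offset is the
#' number of coding bases strictly 5' of the position (for minus-strand
#' transcripts the walk starts from the highest genomic coordinate).
#'
#' @param transcript a `vb_transcript` with CDS features
#' @param genomic_pos 1-based genomic position
#' @return `list(codon_number, offset_in_codon)` or `NULL` when the position
#'   is outside the CDS
#' @export
codon_index <- function(transcript, genomic_pos) {
  pos0 <- as_int1(genomic_pos, "genomic_pos") - 1L
  cds <- transcript$features[transcript$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) vb_stop("transcript %s has no CDS", transcript$transcript_id)
  inside <- any(pos0 >= cds$start & pos0 < cds$end)
  if (!inside) return(NULL)
  if (transcript$strand == "+") {
    cds_offset <- sum(pmax(0L, pmin(pos0, cds$end) - cds$start))
  } else {
    cds_offset <- sum(pmax(0L, cds$end - pmax(pos0 + 1L, cds$start)))
  }
  list(codon_number = cds_offset %/% 3L, offset_in_codon = cds_offset %% 3L)
}

#' Detect same-codon MNV candidate pairs
#'
#' Finds all unordered pairs of single-nucleotide variants that fall in the
#' same codon of one transcript — nearby substitutions that, when carried by
#' one individual, jointly change the encoded amino acid and make
#' single-variant annotations misleading. With the sites-only model the
#' candidacy is positional; an optional co-occurrence table restricts pairs
#' to those observed together in at least one individual.
#'
#' @param variants list of normalized `vb_variant`s annotated against the
#'   transcript
#' @param transcript the `vb_transcript`
#' @param cooccurrence optional data.frame (variant_key_1, variant_key_2,
#'   n_individuals); when given, only pairs present with n_individuals >= 1
#'   are reported
#' @return list with `pairs` (list of 2-element key vectors, keys in
#'   ascending position order, each pair once) and `flagged_keys` (keys of
#'   variants in at least one pair)
#' @export
detect_mnv_candidates <- function(variants, transcript, cooccurrence = NULL) {
  snv <- Filter(function(v) nchar(v$ref) == 1L && nchar(v$alt) == 1L, variants)
  if (length(snv) < 2L) return(list(pairs = list(), flagged_keys = character()))
  codons <- vapply(snv, function(v) {
    ci <- codon_index(transcript, v$pos)
    if (is.null(ci)) NA_integer_ else ci$codon_number
  }, integer(1))
  keys <- vapply(snv, variant_key, character(1))
  posns <- vapply(snv, `[[`, integer(1), "pos")
  ord <- order(posns, keys)
  keys <- keys[ord]; codons <- codons[ord]; posns <- posns[ord]
  allowed <- NULL
  if (!is.null(cooccurrence) && nrow(cooccurrence) > 0L) {
    cc <- cooccurrence[cooccurrence$n_individuals >= 1L, , drop = FALSE]
    allowed <- unique(c(paste(cc$variant_key_1, cc$variant_key_2, sep = "|"),
                        paste(cc$variant_key_2, cc$variant_key_1, sep = "|")))
  }
  pairs <- list()
  flagged <- character()
  n <- length(keys)
  for (i in seq_len(n - 1L)) {
    if (is.na(codons[i])) next
    for (j in seq.int(i + 1L, n)) {
      if (is.na(codons[j]) || codons[i] != codons[j] || keys[i] == keys[j]) next
      if (!is.null(allowed) &&
          !(paste(keys[i], keys[j], sep = "|") %in% allowed)) next
      pairs[[length(pairs) + 1L]] <- c(keys[i], keys[j])
      flagged <- c(flagged, keys[i], keys[j])
    }
  }
  list(pairs = pairs, flagged_keys = sort(unique(flagged)))
}

#' Flag a variant genotyped in few individuals
#'
#' Sets the `low_an` flag when the variant's called allele number falls
#' strictly below a fraction of the maximum AN observed in the dataset —
#' i.e. when a low number of individuals is covered at the locus.
#'
#' @param v a `vb_variant`
#' @param an_max maximum AN across the dataset (> 0)
#' @param threshold_fraction flag when `an_total < threshold_fraction * an_max`;
#'   default 0.8
#' @return the variant, with `low_an` added to or removed from its flags
#' @export
flag_low_an <- function(v, an_max, threshold_fraction = 0.8) {
  an_max <- as_int1(an_max, "an_max")
  if (an_max <= 0L) vb_stop("an_max must be > 0")
  low <- v$an_total < threshold_fraction * an_max
  v$flags <- setdiff(v$flags, "low_an")
  if (low) v$flags <- c(v$flags, "low_an")
  v
}
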
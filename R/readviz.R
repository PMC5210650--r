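# Deterministic selection of carrier samples backing the read-support
# display, and the processing manifest an external reassembly step would
# consume. No BAMs are produced here; the manifest records everything needed
# to reproduce the read extraction.

# Reassembly parameters recorded verbatim in every manifest so a downstream
# caller run can reproduce the original read extraction.
REASSEMBLY_PARAMS <- list(
  padding_around_snps = 300L,
  padding_around_indels = 300L,
  max_alternate_alleles = 3L,
  max_num_haplotypes_in_population = 200L,
  stand_call_conf = 30.0,
  stand_emit_conf = 30.0,
  min_pruning = 3L
)

#' Select carrier samples for the read-support display
#'
#' Within each genotype class (het / hom), keeps only samples with read
#' depth and genotype quality at or above the thresholds; when more than
#' `max_per_class` qualify, the `max_per_class` with the highest genotype
#' quality are kept (ties broken by ascending sample id, so selection is
#' deterministic). Output is sorted by descending GQ within each class.
#'
#' @param carriers list of [readviz_sample()]s
#' @param min_dp minimum read depth (default 10)
#' @param min_gq minimum genotype quality (default 20)
#' @param max_per_class cap per genotype class (default 5)
#' @return named list (`het`, `hom`) of selected [readviz_sample()]s
#' @export
select_samples <- function(carriers, min_dp = 10L, min_gq = 20L,
                           max_per_class = 5L) {
  sel <- list(het = list(), hom = list())
  for (cls in c("het", "hom")) {
    pool <- Filter(function(s) s$genotype_class == cls &&
                     s$dp >= min_dp && s$gq >= min_gq, carriers)
    if (length(pool) == 0L) next
    gq <- vapply(pool, `[[`, integer(1), "gq")
    sid <- vapply(pool, `[[`, character(1), "sample_id")
    ord <- order(-gq, sid)
    sel[[cls]] <- pool[ord][seq_len(min(length(pool), max_per_class))]
  }
  sel
}

#' Read-support manifest of one variant
#'
#' @param variant_key normalized `chrom-pos-ref-alt` key
#' @param selected named list (`het`, `hom`) from [select_samples()]
#' @param window display [genome_interval()]
#' @param reassembly_padding recorded padding parameter (default 300)
#' @param max_per_class per-class cap the selection was made under
#' @return a `vb_readviz_manifest`
#' @export
readviz_manifest <- function(variant_key, selected, window,
                             reassembly_padding = 300L, max_per_class = 5L) {
  stopifnot(inherits(window, "vb_interval"))
  for (cls in c("het", "hom")) {
    samples <- selected[[cls]] %||% list()
    if (length(samples) > max_per_class)
      vb_stop("more than %d %s samples in manifest", max_per_class, cls)
    stopifnot(all(vapply(samples, inherits, logical(1), "vb_readviz_sample")))
  }
  structure(list(variant_key = as_chr1(variant_key, "variant_key"),
                 selected = list(het = selected$het %||% list(),
                                 hom = selected$hom %||% list()),
                 window = window,
                 reassembly_padding = as_int1(reassembly_padding,
                                              "reassembly_padding")),
            class = "vb_readviz_manifest")
}

#' Build the read-support manifest for a variant
#'
#' The display window is centered on the position of the variant's first
#' reference base with total width `window_width`: the left flank is
#' `floor((window_width - 1) / 2)` bases, the right flank the remainder.
#' The default width is the 125 bp pileup window of the browser display.
#'
#' @param v a normalized `vb_variant` (or a list with chrom/pos/ref/alt)
#' @param selection output of [select_samples()]
#' @param window_width total window width in bp (default 125)
#' @return a [readviz_manifest()]
#' @export
build_manifest <- function(v, selection, window_width = 125L) {
  window_width <- as_int1(window_width, "window_width")
  if (window_width < 1L) vb_stop("window_width must be >= 1")
  center0 <- as_int1(v$pos, "pos") - 1L
  left <- (window_width - 1L) %/% 2L
  start <- max(0L, center0 - left)
  window <- genome_interval(v$chrom, start, start + window_width)
  readviz_manifest(variant_key(v), selection, window)
}

#' Batch manifests for combined storage
#'
#' Partitions manifests in input order into batches and assigns each
#' (variant, sample) pair a unique read-group label
#' `"<variant_key>_<sample_id>_<class>"`, mirroring how small per-variant
#' read sets are combined into larger files while read groups keep track of
#' the original source of each read.
#'
#' @param manifests list of [readviz_manifest()]s
#' @param batch_size manifests per batch, `>= 1`
#' @return list of batches; each batch is a list with `batch_id` and
#'   `entries` (data.frame: variant_key, sample_id, genotype_class, gq, dp,
#'   window_chrom, window_start, window_end, read_group, batch_id)
#' @export
batch_manifests <- function(manifests, batch_size) {
  batch_size <- as_int1(batch_size, "batch_size")
  if (batch_size < 1L) vb_stop("batch_size must be >= 1")
  if (length(manifests) == 0L) return(list())
  idx <- split(seq_along(manifests),
               ceiling(seq_along(manifests) / batch_size))
  lapply(seq_along(idx), function(b) {
    entries <- do.call(rbind, lapply(manifests[idx[[b]]], function(m) {
      rows <- do.call(rbind, lapply(c("het", "hom"), function(cls) {
        samples <- m$selected[[cls]]
        if (length(samples) == 0L) return(NULL)
        do.call(rbind, lapply(samples, function(s) data.frame(
          variant_key = m$variant_key, sample_id = s$sample_id,
          genotype_class = cls, gq = s$gq, dp = s$dp,
          window_chrom = m$window$chrom, window_start = m$window$start,
          window_end = m$window$end,
          read_group = paste(m$variant_key, s$sample_id, cls, sep = "_"))))
      }))
      if (is.null(rows))
        rows <- data.frame(variant_key = m$variant_key, sample_id = NA_character_,
                           genotype_class = NA_character_, gq = NA_integer_,
                           dp = NA_integer_, window_chrom = m$window$chrom,
                           window_start = m$window$start,
                           window_end = m$window$end,
                           read_group = NA_character_)
      rows
    }))
    entries$batch_id <- b
    rownames(entries) <- NULL
    list(batch_id = b, entries = entries)
  })
}

#' Write a read-support manifest file
#'
#' @param batches output of [batch_manifests()]
#' @param path TSV destination
#' @return the combined data.frame, invisibly
#' @export
write_manifest_tsv <- function(batches, path) {
  combined <- do.call(rbind, lapply(batches, `[[`, "entries")) %||%
    data.frame(variant_key = character(), sample_id = character(),
               genotype_class = character(), gq = integer(), dp = integer(),
               window_chrom = character(), window_start = integer(),
               window_end = integer(), read_group = character(),
               batch_id = integer())
  utils::write.table(combined, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(combined)
}
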
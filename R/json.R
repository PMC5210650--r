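# Lossless JSON round-trip for every domain type. Each tagged list is
# serialized with a "_type" discriminator; deserialization re-applies the
# strict constructor, so integer fields come back as integers bit-identically
# and invariants are re-checked on the way in.

vb_class_tags <- c(
  vb_interval = "interval", vb_consequence = "consequence",
  vb_histogram = "histogram", vb_variant = "variant", vb_gene = "gene",
  vb_transcript = "transcript", vb_constraint = "constraint",
  vb_coverage_row = "coverage_row", vb_cnv = "cnv",
  vb_readviz_sample = "readviz_sample", vb_readviz_manifest = "readviz_manifest",
  vb_payload = "page_payload"
)

vb_as_list <- function(x) {
  if (inherits(x, names(vb_class_tags))) {
    tag <- vb_class_tags[[class(x)[1]]]
    body <- lapply(unclass(x), vb_as_list)
    if (identical(tag, "transcript")) {
      f <- x$features
      body$features <- lapply(seq_len(nrow(f)), function(i)
        list(start = f$start[i], end = f$end[i], kind = f$kind[i]))
    }
    if (identical(tag, "coverage_row"))
      body$frac_over <- as.list(x$frac_over)
    c(list(`_type` = tag), body)
  } else if (is.list(x)) {
    lapply(x, vb_as_list)
  } else x
}

#' Serialize a domain object to JSON
#'
#' Every core type (and nested structures of them) round-trips through
#' [vb_from_json()] bit-identically for integer fields and without precision
#' loss for floats.
#'
#' @param x a domain object or list of them
#' @return a JSON string
#' @export
vb_to_json <- function(x) {
  as.character(jsonlite::toJSON(vb_as_list(x), auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

vb_from_list <- function(x) {
  if (is.list(x) && !is.null(x[["_type"]])) {
    tag <- x[["_type"]]
    x[["_type"]] <- NULL
    x <- lapply(x, vb_from_list)
    switch(tag,
      interval = genome_interval(x$chrom, x$start, x$end),
      consequence = transcript_consequence(
        x$transcript_id, x$gene_id, unlist(x$consequence_terms),
        polyphen = x$polyphen, sift = x$sift, lof = x$lof,
        is_canonical = x$is_canonical),
      histogram = metric_histogram(x$metric_name, unlist(x$bin_edges),
                                   unlist(x$counts)),
      variant = variant(x$chrom, x$pos, x$ref, x$alt, x$ac_total, x$an_total,
                        x$hom_total, rsid = x$rsid,
                        site_quality = x$site_quality %||% NA_real_,
                        filter_status = x$filter_status,
                        pop_counts = x$pop_counts,
                        quality_histograms = x$quality_histograms,
                        flags = unlist(x$flags) %||% character(),
                        consequences = x$consequences),
      gene = gene_model(x$gene_id, x$symbol, x$chrom, x$start, x$end,
                        x$strand, x$canonical_transcript_id,
                        unlist(x$transcript_ids),
                        aliases = unlist(x$aliases) %||% character(),
                        constraint = x$constraint),
      transcript = transcript_model(
        x$transcript_id, x$gene_id, x$strand,
        data.frame(start = vapply(x$features, `[[`, numeric(1), "start"),
                   end = vapply(x$features, `[[`, numeric(1), "end"),
                   kind = vapply(x$features, `[[`, character(1), "kind"))),
      constraint = constraint_record(x$transcript_id, x$exp_syn, x$obs_syn,
                                     x$syn_z, x$exp_mis, x$obs_mis, x$mis_z,
                                     x$exp_lof, x$obs_lof, x$lof_z, x$pli),
      coverage_row = coverage_row(x$chrom, x$pos, x$mean_depth,
                                  x$median_depth, x$frac_over),
      cnv = cnv_call(x$chrom, x$start, x$end, x$kind, x$sq_score,
                     x$population, x$sample_id),
      readviz_sample = readviz_sample(x$sample_id, x$genotype_class, x$gq, x$dp),
      readviz_manifest = readviz_manifest(x$variant_key, x$selected, x$window,
                                          reassembly_padding = x$reassembly_padding),
      page_payload = page_payload(x$page_kind, metadata = x$metadata,
                                  variant_table = x$variant_table,
                                  coverage_series = x$coverage_series,
                                  cnv_summary = x$cnv_summary,
                                  warnings = unlist(x$warnings) %||% character()),
      vb_stop("unknown serialized type '%s'", tag))
  } else if (is.list(x)) {
    lapply(x, vb_from_list)
  } else x
}

#' Deserialize a domain object from JSON
#'
#' @param txt JSON produced by [vb_to_json()]
#' @return the reconstructed object
#' @export
vb_from_json <- function(txt) {
  vb_from_list(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}
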
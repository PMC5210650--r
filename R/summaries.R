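# Quantitative page content: allele frequencies, per-population tables,
# exon coverage aggregation, quality-metric histograms and CNV counts.

#' Allele frequency
#'
#' `ac / an`, defined as 0 when `an` is 0 (with a warning attribute on the
#' result so callers can surface it).
#'
#' @param ac alternate allele count
#' @param an total called allele number, `an >= ac >= 0`
#' @return frequency in `[0, 1]`; attribute `warning` set when `an == 0`
#' @export
allele_frequency <- function(ac, an) {
  ac <- as_int1(ac, "ac"); an <- as_int1(an, "an")
  if (ac < 0L) vb_stop("ac must be >= 0")
  if (an == 0L)
    return(structure(0, warning = "allele number is zero at this site"))
  if (ac > an) vb_stop("ac (%d) > an (%d)", ac, an)
  ac / an
}

#' Per-population frequency table of a variant
#'
#' One row per configured population, in fixed order, plus a Total row.
#' Populations absent from the variant's counts get zero rows.
#'
#' @param v a `vb_variant`
#' @param populations population codes, in display order
#' @return data.frame(population, ac, an, hom, af)
#' @export
population_table <- function(v, populations = DEFAULT_POPULATIONS) {
  rows <- lapply(populations, function(p) {
    pc <- v$pop_counts[[p]] %||% list(ac = 0L, an = 0L, hom = 0L)
    data.frame(population = p, ac = pc$ac, an = pc$an, hom = pc$hom,
               af = as.numeric(allele_frequency(pc$ac, pc$an)))
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    population = "Total", ac = v$ac_total, an = v$an_total, hom = v$hom_total,
    af = as.numeric(allele_frequency(v$ac_total, v$an_total))))))
  rownames(out) <- NULL
  out
}

merge_intervals <- function(intervals) {
  if (length(intervals) == 0L) return(intervals)
  df <- data.frame(start = vapply(intervals, `[[`, integer(1), "start"),
                   end = vapply(intervals, `[[`, integer(1), "end"))
  chrom <- vapply(intervals, `[[`, character(1), "chrom")
  stopifnot(length(unique(chrom)) == 1L)
  df <- df[order(df$start, df$end), , drop = FALSE]
  merged <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(merged)
    if (df$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], df$end[i])
    } else merged <- rbind(merged, df[i, ])
  }
  lapply(seq_len(nrow(merged)), function(i)
    genome_interval(chrom[1], merged$start[i], merged$end[i]))
}

#' Aggregate per-base coverage over exon intervals
#'
#' Restricts the per-base series to the given intervals and summarizes each
#' interval: mean of per-base mean depths, mean of per-base median depths,
#' and per depth cutoff the mean of the per-base covered fractions. A base
#' with no coverage row contributes zero to every metric — absent data reads
#' as absent depth, never as missing.
#'
#' @param rows coverage `data.table` from [read_coverage()] (or a
#'   data.frame with the same columns), one chromosome
#' @param intervals list of [genome_interval()]s (merged if overlapping)
#' @return list with `exons` (data.frame: chrom, start, end, n_bases,
#'   mean_depth, median_depth and one `over_<cutoff>` column per cutoff) and
#'   `series` (data.frame of the clipped per-base rows, 1-based pos)
#' @export
aggregate_coverage <- function(rows, intervals) {
  cutoffs <- attr(rows, "cutoffs")
  if (is.null(cutoffs))
    cutoffs <- as.numeric(setdiff(names(rows), c("chrom", "pos", "mean", "median")))
  cutoffs <- sort(cutoffs)
  over_cols <- as.character(cutoffs)
  if (length(intervals) == 0L) {
    empty <- stats::setNames(
      data.frame(matrix(numeric(0), ncol = 6 + length(cutoffs))),
      c("chrom", "start", "end", "n_bases", "mean_depth", "median_depth",
        paste0("over_", over_cols)))
    return(list(exons = empty, series = rows[0, ]))
  }
  intervals <- merge_intervals(intervals)
  chrom <- intervals[[1]]$chrom
  rows <- as.data.frame(rows)
  rows <- rows[rows$chrom == chrom, , drop = FALSE]
  in_any <- rep(FALSE, nrow(rows))
  pos0 <- rows$pos - 1L
  for (iv in intervals) in_any <- in_any | (pos0 >= iv$start & pos0 < iv$end)
  series <- rows[in_any, , drop = FALSE]
  rownames(series) <- NULL

  exons <- do.call(rbind, lapply(intervals, function(iv) {
    n <- iv$end - iv$start
    sel <- series[series$pos - 1L >= iv$start & series$pos - 1L < iv$end, ,
                  drop = FALSE]
    # missing bases contribute 0: divide sums by the interval width
    out <- data.frame(chrom = chrom, start = iv$start, end = iv$end,
                      n_bases = n,
                      mean_depth = sum(sel$mean) / n,
                      median_depth = sum(sel$median) / n)
    for (cc in over_cols) out[[paste0("over_", cc)]] <- sum(sel[[cc]]) / n
    out
  }))
  rownames(exons) <- NULL
  list(exons = exons, series = series)
}

#' Histogram of a quality metric
#'
#' `counts[i]` is the number of values `v` with
#' `bin_edges[i] <= v < bin_edges[i+1]`; values at or above the last edge
#' fall into the last bin, so inputs at the metric ceiling are conserved.
#' Values below the first edge are outside the histogram.
#'
#' @param values numeric vector (order-invariant)
#' @param metric_name name recorded on the histogram
#' @param bin_edges strictly ascending edges; default 20 equal bins over
#'   `[0, 100]`, the convention for phred-scaled genotype quality and depth
#' @return a [metric_histogram()]
#' @export
compute_metric_histogram <- function(values, metric_name = "metric",
                                     bin_edges = seq(0, 100, by = 5)) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    vb_stop("bin_edges must be strictly ascending")
  n_bins <- length(bin_edges) - 1L
  values <- as.numeric(values)
  values <- values[values >= bin_edges[1]]
  idx <- findInterval(values, bin_edges)     # last-bin rule: clamp overflow
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  metric_histogram(metric_name, bin_edges, counts)
}

#' Count CNVs over exon intervals
#'
#' A confidently called CNV (quality strictly above `sq_threshold`) counts
#' toward every interval it overlaps by at least one base, regardless of the
#' amount of overlap. Counts are broken down by call kind (DEL/DUP) and by
#' population.
#'
#' @param calls CNV `data.table` from [read_side_tables()] (chrom, start,
#'   end, kind, sq, population, sample_id)
#' @param intervals list of [genome_interval()]s (merged if overlapping)
#' @param sq_threshold strict quality cutoff (default 60)
#' @param populations population codes for the breakdown
#' @return list with `per_interval` (data.frame: chrom, start, end, DEL,
#'   DUP), `per_population` (data.frame: population, DEL, DUP over all
#'   intervals), `total` (named DEL/DUP counts)
#' @export
cnv_counts <- function(calls, intervals, sq_threshold = 60,
                       populations = DEFAULT_POPULATIONS) {
  if (length(intervals)) intervals <- merge_intervals(intervals)
  calls <- as.data.frame(calls)
  conf <- calls[calls$sq > sq_threshold, , drop = FALSE]
  per_interval <- do.call(rbind, lapply(intervals, function(iv) {
    hit <- conf$chrom == iv$chrom & conf$start < iv$end & conf$end > iv$start
    data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
               DEL = sum(hit & conf$kind == "DEL"),
               DUP = sum(hit & conf$kind == "DUP"))
  })) %||% data.frame(chrom = character(), start = integer(), end = integer(),
                      DEL = integer(), DUP = integer())
  # per-population: calls overlapping any interval, counted once per call
  hit_any <- rep(FALSE, nrow(conf))
  for (iv in intervals)
    hit_any <- hit_any |
      (conf$chrom == iv$chrom & conf$start < iv$end & conf$end > iv$start)
  overl <- conf[hit_any, , drop = FALSE]
  per_population <- do.call(rbind, lapply(populations, function(p)
    data.frame(population = p,
               DEL = sum(overl$population == p & overl$kind == "DEL"),
               DUP = sum(overl$population == p & overl$kind == "DUP"))))
  rownames(per_population) <- NULL
  list(per_interval = per_interval, per_population = per_population,
       total = c(DEL = sum(overl$kind == "DEL"),
                 DUP = sum(overl$kind == "DUP")))
}

#' Export a per-base coverage series as a BED-graph-like table
#'
#' @param series per-base coverage data.frame (1-based pos)
#' @param metric column to export (default "mean")
#' @return data.frame(chrom, start, end, value) with 0-based half-open rows
#' @export
coverage_bedgraph <- function(series, metric = "mean") {
  data.frame(chrom = series$chrom, start = series$pos - 1L, end = series$pos,
             value = series[[metric]])
}
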
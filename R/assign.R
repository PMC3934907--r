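#' Assign ChIP-seq peaks to genes
#'
#' Implements the study's assignment rule. A peak that overlaps one or
#' more gene spans (any partial overlap of the half-open intervals,
#' strand ignored) is intragenic: it yields one `GENE_OVERLAP`
#' assignment per overlapped gene, with `gene_distance = 0`. A peak
#' overlapping no gene is intergenic (`GENE_CLOSE`) and is assigned to
#' the nearest gene in either direction, measured as the gap in bp
#' between the peak edge and the gene edge; on an exact distance tie
#' all tied genes are assigned. Every assignment also carries the
#' nearest-TSS gene and distance, which are computed independently of
#' the assigned gene and may name a different gene.
#'
#' Peaks on chromosomes absent from the annotation cannot be assigned;
#' they are dropped with a warning.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble.
#' @return A tibble with one row per peak-gene link: `peak_id`,
#'   `gene_id`, `status` (`"GENE_OVERLAP"`/`"GENE_CLOSE"`),
#'   `gene_distance`, `tss_gene_id`, `tss_distance`, ordered by
#'   `(peak_id, gene_id)`.
#' @export
assign_peaks_to_genes <- function(peaks, genes) {
  validate_peaks(peaks)
  validate_genes(genes)
  known <- peaks$chrom %in% unique(genes$chrom)
  if (any(!known)) {
    warn(sprintf(
      "%d peak(s) lie on chromosomes absent from the annotation and were excluded: %s",
      sum(!known),
      paste(head(peaks$peak_id[!known], 5), collapse = ", ")
    ))
    peaks <- peaks[known, , drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    return(tibble(peak_id = character(), gene_id = character(),
                  status = character(), gene_distance = integer(),
                  tss_gene_id = character(), tss_distance = integer()))
  }

  pk <- peaks_to_granges(peaks)
  gn <- genes_to_granges(genes)

  ov <- GenomicRanges::findOverlaps(pk, gn, ignore.strand = TRUE)
  overlap_links <- tibble(
    peak_id = peaks$peak_id[S4Vectors::queryHits(ov)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    status = "GENE_OVERLAP",
    gene_distance = 0L
  )

  no_ov <- setdiff(seq_len(nrow(peaks)), unique(S4Vectors::queryHits(ov)))
  close_links <- NULL
  if (length(no_ov) > 0) {
    # nearest() drops cross-side distance ties, and the contract is to
    # assign every tied gene, so the gap minimization is done directly.
    close_links <- nearest_gene_all_ties(peaks[no_ov, , drop = FALSE], genes)
  }

  tss <- peak_tss_distance(peaks, build_tss_index(genes))

  dplyr::bind_rows(overlap_links, close_links) |>
    dplyr::left_join(tss, by = "peak_id") |>
    dplyr::arrange(.data$peak_id, .data$gene_id)
}

# Nearest gene(s) for peaks known to overlap no gene. Every gene on
# the peak's chromosome lies entirely left (gene end <= peak start) or
# right (gene start >= peak end) of the peak; the gap is minimized
# over both sides and all genes achieving the minimum are returned.
nearest_gene_all_ties <- function(peaks, genes) {
  by_chrom <- split(genes, genes$chrom)
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- by_chrom[[peaks$chrom[i]]]
    s <- peaks$start[i]; e <- peaks$end[i]
    gap_left <- ifelse(g$end <= s, s - g$end, NA_integer_)
    gap_right <- ifelse(g$start >= e, g$start - e, NA_integer_)
    gap <- pmin(gap_left, gap_right, na.rm = TRUE)
    best <- min(gap)
    out[[i]] <- tibble(
      peak_id = peaks$peak_id[i],
      gene_id = sort(g$gene_id[gap == best]),
      status = "GENE_CLOSE",
      gene_distance = as.integer(best)
    )
  }
  dplyr::bind_rows(out)
}

#' Nearest-TSS distance for each peak
#'
#' Distance is 0 when any TSS falls inside the half-open peak interval;
#' otherwise it is the position difference between the TSS and the
#' nearer peak edge (`start` or `end - 1`), minimized over all TSSs on
#' the peak's chromosome. Ties (including several genes sharing the
#' nearest TSS position) are resolved deterministically by taking the
#' smallest `gene_id`.
#'
#' @param peaks Peak tibble.
#' @param tss_index Index from [build_tss_index()].
#' @return A tibble `peak_id`, `tss_gene_id`, `tss_distance`, one row
#'   per peak; peaks on chromosomes absent from the index are omitted.
#' @export
peak_tss_distance <- function(peaks, tss_index) {
  validate_peaks(peaks)
  assert_columns(tss_index, c("chrom", "pos", "gene_id"), "tss_index")
  if (nrow(tss_index) == 0) abort("Empty TSS index.")
  by_chrom <- split(tss_index, tss_index$chrom)
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    idx <- by_chrom[[peaks$chrom[i]]]
    if (is.null(idx)) next
    hit <- .tss_query_one(idx$pos, idx$gene_id, peaks$start[i], peaks$end[i])
    out[[i]] <- tibble(peak_id = peaks$peak_id[i],
                       tss_gene_id = hit$gene_id[1],
                       tss_distance = hit$distance)
  }
  dplyr::bind_rows(out)
}

#' Nearest-TSS distance profile of a peak set
#'
#' Bins each peak's (deduplicated) nearest-TSS distance into half-open
#' distance classes, by default `[0, 1 kb)`, `[1, 5 kb)`, `[5, 10 kb)`,
#' `[10, 20 kb)`, `[20 kb, Inf)` — the binning behind statements such
#' as "52.4% of peaks are <1 kb from the nearest TSS". A distance of
#' exactly 1,000 bp falls in the second bin.
#'
#' @param assignments Assignment tibble (or any tibble with `peak_id`
#'   and `tss_distance`).
#' @param bin_edges Increasing numeric vector of lower edges plus a
#'   final upper edge, default `c(0, 1e3, 5e3, 1e4, 2e4, Inf)`.
#' @return A tibble with one row per bin: `bin_low`, `bin_high`,
#'   `label`, `count`, `fraction`, `pct` (fraction rounded to 0.1% for
#'   display). Counts sum to the number of distinct peaks.
#' @export
distance_profile <- function(assignments,
                             bin_edges = c(0, 1e3, 5e3, 1e4, 2e4, Inf)) {
  assert_columns(assignments, c("peak_id", "tss_distance"), "assignments")
  if (length(bin_edges) < 2 || is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing with >= 2 values.")
  }
  per_peak <- dplyr::distinct(as_tibble(assignments),
                              .data$peak_id, .data$tss_distance)
  if (anyDuplicated(per_peak$peak_id)) {
    abort("Conflicting `tss_distance` values for the same peak_id.")
  }
  nbin <- length(bin_edges) - 1
  bin <- findInterval(per_peak$tss_distance, bin_edges,
                      rightmost.closed = FALSE)  # half-open [low, high)
  counts <- tabulate(bin, nbins = nbin)
  lows <- bin_edges[-length(bin_edges)]
  highs <- bin_edges[-1]
  frac <- if (nrow(per_peak) > 0) counts / nrow(per_peak) else rep(NA_real_, nbin)
  tibble(
    bin_low = lows,
    bin_high = highs,
    label = ifelse(is.finite(highs),
                   sprintf("[%s, %s)", format(lows, big.mark = ",", trim = TRUE,
                                              scientific = FALSE),
                           format(highs, big.mark = ",", trim = TRUE,
                                  scientific = FALSE)),
                   sprintf(">= %s", format(lows, big.mark = ",", trim = TRUE,
                                           scientific = FALSE))),
    count = counts,
    fraction = frac,
    pct = round_half_up(100 * frac, 1)
  )
}

#' Intragenic/intergenic summary of an assignment set
#'
#' The fraction of peaks with at least one `GENE_OVERLAP` assignment
#' (intragenic), its complement (intergenic), and the number of
#' distinct genes linked to any peak. A peak overlapping two genes
#' counts once in the overlap fraction but contributes both genes to
#' the distinct-gene count.
#'
#' @param assignments Assignment tibble.
#' @return One-row tibble: `n_peaks`, `fraction_overlap`,
#'   `fraction_close`, `distinct_genes`.
#' @export
summarize_gene_status <- function(assignments) {
  assert_columns(assignments, c("peak_id", "gene_id", "status"), "assignments")
  per_peak <- assignments |>
    as_tibble() |>
    dplyr::group_by(.data$peak_id) |>
    dplyr::summarise(overlap = any(.data$status == "GENE_OVERLAP"),
                     .groups = "drop")
  n <- nrow(per_peak)
  tibble(
    n_peaks = n,
    fraction_overlap = if (n > 0) mean(per_peak$overlap) else NA_real_,
    fraction_close = if (n > 0) mean(!per_peak$overlap) else NA_real_,
    distinct_genes = dplyr::n_distinct(assignments$gene_id)
  )
}
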
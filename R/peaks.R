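#' Convert between peak-call P-values and the -10*log10(P) score
#'
#' ChIP-seq peaks are scored on the MACS convention
#' `score = -10 * log10(P)`, so a score of 50 corresponds to
#' `P = 1e-5` and a score of 640 to `P = 1e-64`. `p_from_score()` is
#' the exact inverse.
#'
#' @param p P-value(s) in `(0, 1]`.
#' @param score Score(s) `>= 0` on the `-10*log10(P)` scale.
#' @return Numeric vector of scores (`score_from_p`) or P-values
#'   (`p_from_score`).
#' @examples
#' score_from_p(1e-5)  # 50
#' p_from_score(50)    # 1e-5
#' @export
score_from_p <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  -10 * log10(p)
}

#' @rdname score_from_p
#' @export
p_from_score <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0)) {
    abort("`score` must be >= 0.")
  }
  10^(-score / 10)
}

#' Filter peaks on significance and fold enrichment
#'
#' Keeps peaks with `score >= min_score` and `fold >= min_fold`.
#' Defaults implement the study's filter: peaks with P larger than
#' 1e-5 (score below 50) or fold change below 3 are removed; boundary
#' values pass. Row order is preserved.
#'
#' @param peaks Peak tibble with columns `peak_id`, `chrom`, `start`,
#'   `end`, `score`, `fold`.
#' @param min_score Minimum score kept (default 50, i.e. P <= 1e-5).
#' @param min_fold Minimum fold enrichment kept (default 3).
#' @return The filtered peak tibble.
#' @export
filter_peaks <- function(peaks, min_score = 50, min_fold = 3) {
  validate_peaks(peaks)
  dplyr::filter(as_tibble(peaks),
                .data$score >= min_score, .data$fold >= min_fold)
}

#' Rank peaks by significance and assign index numbers
#'
#' Sorts peaks by score descending (most significant first) and assigns
#' `index = 1..N`; a lower index means a smaller P-value. Equal scores
#' are broken deterministically by chromosome (lexicographic), start
#' (ascending), then peak id. Idempotent.
#'
#' @param peaks Peak tibble.
#' @return The tibble sorted with an `index` column, 1 = most
#'   significant.
#' @export
rank_peaks <- function(peaks) {
  validate_peaks(peaks)
  if (nrow(peaks) == 0) abort("Cannot rank an empty peak set.")
  peaks |>
    as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$score), .data$chrom, .data$start,
                   .data$peak_id) |>
    dplyr::mutate(index = dplyr::row_number())
}

#' Select the top fraction of indexed peaks
#'
#' Returns the `k = ceiling(fraction * N)` most significant peaks
#' (smallest index). The ceiling rule means the top 10% of 7,566 peaks
#' is 757 peaks.
#'
#' @param peaks Indexed peak tibble from [rank_peaks()].
#' @param fraction Fraction in `(0, 1]`.
#' @return The selected peak tibble, index order.
#' @export
select_top_fraction <- function(peaks, fraction = 0.10) {
  validate_peaks(peaks)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1].")
  }
  if (!"index" %in% names(peaks) || anyNA(peaks$index)) {
    abort("Peaks must be indexed first; see `rank_peaks()`.")
  }
  k <- ceiling(fraction * nrow(peaks))
  peaks |>
    as_tibble() |>
    dplyr::arrange(.data$index) |>
    dplyr::slice_head(n = k)
}

#' Read called peaks from a MACS-style table or narrowPeak file
#'
#' `macs_tab` is a tab table with header columns `chrom`, `start`,
#' `end`, `score`, `fold`, where `start` is 1-based inclusive (converted
#' on read) and `score` is already -10*log10(P). ENCODE `narrowpeak`
#' is headerless BED6+4; column 7 (signalValue) supplies the fold
#' enrichment and column 8 (pValue, -log10 P) is multiplied by 10 to
#' reach the score scale. A narrowPeak file with missing fold
#' enrichment (column 7 = -1) is an error unless `default_fold` is
#' given.
#'
#' @param path Input path.
#' @param dialect `"macs_tab"` or `"narrowpeak"`.
#' @param default_fold Fold enrichment to substitute when narrowPeak
#'   column 7 is `-1` (default: none, error).
#' @return A peak tibble: `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `score`, `fold`.
#' @export
read_peaks <- function(path, dialect = c("macs_tab", "narrowpeak"),
                       default_fold = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("Peak file not found: %s", path))
  if (dialect == "macs_tab") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    assert_columns(tab, c("chrom", "start", "end", "score", "fold"), path)
    check_peak_numbers(tab, path, one_based_start = TRUE)
    out <- tibble(
      peak_id = if ("peak_id" %in% names(tab)) as.character(tab$peak_id) else
        sprintf("peak_%05d", seq_len(nrow(tab))),
      chrom = as.character(tab$chrom),
      start = as.integer(tab$start) - 1L,  # 1-based inclusive -> 0-based
      end = as.integer(tab$end),
      score = as.numeric(tab$score),
      fold = as.numeric(tab$fold)
    )
  } else {
    cols <- c("chrom", "start", "end", "name", "bed_score", "strand",
              "signal", "pvalue", "qvalue", "summit")
    tab <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
    check_peak_numbers(tab, path, one_based_start = FALSE)
    fold <- as.numeric(tab$signal)
    if (any(fold < 0)) {
      if (is.null(default_fold)) {
        abort(sprintf(
          "%s: narrowPeak signalValue (fold enrichment) is missing (-1) for %d record(s); supply `default_fold`.",
          path, sum(fold < 0)
        ))
      }
      fold[fold < 0] <- default_fold
    }
    if (any(tab$pvalue < 0)) {
      abort(sprintf("%s: narrowPeak pValue column is missing (-1).", path))
    }
    nm <- as.character(tab$name)
    nm[is.na(nm) | nm == "."] <- sprintf("peak_%05d", which(is.na(nm) | nm == "."))
    out <- tibble(
      peak_id = nm,
      chrom = as.character(tab$chrom),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      score = 10 * as.numeric(tab$pvalue),  # -log10 -> -10*log10
      fold = fold
    )
  }
  validate_peaks(out, what = path)
  out
}

check_peak_numbers <- function(tab, path, one_based_start) {
  start_num <- suppressWarnings(as.numeric(tab$start))
  end_num <- suppressWarnings(as.numeric(tab$end))
  bad <- which(is.na(start_num) | is.na(end_num))
  if (length(bad) > 0) {
    parse_fail(path, bad[1] + 1L, "non-numeric start/end")
  }
  min_start <- if (one_based_start) 1 else 0
  bad <- which(start_num < min_start)
  if (length(bad) > 0) {
    parse_fail(path, bad[1] + as.integer(one_based_start),
               "negative coordinate")
  }
  score_col <- if ("score" %in% names(tab)) tab$score else tab$pvalue
  bad <- which(is.na(suppressWarnings(as.numeric(score_col))))
  if (length(bad) > 0) {
    parse_fail(path, bad[1] + as.integer(one_based_start),
               "non-numeric score")
  }
  invisible(tab)
}

#' Write peaks back to a MACS-style table or narrowPeak file
#'
#' Inverse of [read_peaks()] for both dialects (`macs_tab` start is
#' written 1-based; narrowPeak score is written back on the -log10
#' scale), so write/read round-trips preserve every field.
#'
#' @inheritParams read_peaks
#' @param peaks Peak tibble.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("macs_tab", "narrowpeak")) {
  dialect <- match.arg(dialect)
  validate_peaks(peaks)
  if (dialect == "macs_tab") {
    tibble(peak_id = peaks$peak_id, chrom = peaks$chrom,
           start = peaks$start + 1L, end = peaks$end,
           score = peaks$score, fold = peaks$fold) |>
      readr::write_tsv(path, progress = FALSE)
  } else {
    readr::write_lines(sprintf(
      "%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t-1\t-1",
      peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
      pmin(1000L, as.integer(round(peaks$score))),
      format(peaks$fold, trim = TRUE, scientific = FALSE),
      format(peaks$score / 10, trim = TRUE, scientific = FALSE)
    ), path)
  }
  invisible(path)
}

#' Write the annotated peak table
#'
#' Emits the per-link peak/gene table in the supplementary-dataset
#' dialect: tab-separated with header `INDEX, PVALUE, CHR, START, END,
#' GENE, GENE_STATUS, GENE_DIS, TSS_GENE, TSS_DIS`. The `PVALUE`
#' column holds the -10*log10(P) score (so 50 means P = 1e-5);
#' `START`/`END` are 1-based inclusive; `GENE_DIS` is 0 for intragenic
#' (`GENE_OVERLAP`) rows and the peak-to-gene gap for intergenic
#' (`GENE_CLOSE`) rows; the nearest-TSS gene (`TSS_GENE`) may differ
#' from the assigned `GENE`. One row per peak-gene link, ordered by
#' `INDEX` then `GENE`.
#'
#' @param peaks Indexed peak tibble from [rank_peaks()].
#' @param assignments Assignment tibble from [assign_peaks_to_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, assignments, path) {
  validate_peaks(peaks)
  if (!"index" %in% names(peaks) || anyNA(peaks$index)) {
    abort("Peaks must be indexed first; see `rank_peaks()`.")
  }
  assert_columns(assignments,
                 c("peak_id", "gene_id", "status", "gene_distance",
                   "tss_gene_id", "tss_distance"), "assignments")
  peaks |>
    dplyr::inner_join(assignments, by = "peak_id") |>
    dplyr::transmute(
      INDEX = .data$index,
      PVALUE = .data$score,
      CHR = .data$chrom,
      START = .data$start + 1L,
      END = .data$end,
      GENE = .data$gene_id,
      GENE_STATUS = .data$status,
      GENE_DIS = .data$gene_distance,
      TSS_GENE = .data$tss_gene_id,
      TSS_DIS = .data$tss_distance
    ) |>
    dplyr::arrange(.data$INDEX, .data$GENE) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
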
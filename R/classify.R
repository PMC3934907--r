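# Classification of peak-bearing genes as positively, negatively or
# ambiguously regulated, from two expression contrasts:
#   loss contrast (ectopic-ey discs with vs without functional so):
#     a gene DOWN in the mutant implies So activates it (positive);
#     UP implies repression (negative).
#   gain contrast (wild type vs so+eya co-overexpression):
#     UP under overexpression implies activation; DOWN repression.
# A gene whose inferred directions conflict across (or within)
# contrasts is AMB.

#' Collapse probe-level responses to gene-level sign sets
#'
#' Per gene and contrast, takes the union of directions over all
#' significant probes; a gene with distinct probes up- and
#' down-regulated in one contrast gets both signs. Genes with no
#' significant probe in either contrast are dropped.
#'
#' @param probes Tibble with columns `probe_id`, `gene_id`, `contrast`
#'   (`"loss"`/`"gain"`), `direction` (`"up"`/`"down"`), `significant`
#'   (logical or 0/1).
#' @return A tibble with one row per responding gene: `gene_id` and
#'   logical columns `loss_up`, `loss_down`, `gain_up`, `gain_down`.
#' @export
collapse_probes <- function(probes) {
  assert_columns(probes, c("probe_id", "gene_id", "contrast", "direction",
                           "significant"), "probes")
  if (!all(probes$contrast %in% c("loss", "gain"))) {
    abort("`contrast` must be 'loss' or 'gain'.")
  }
  if (!all(probes$direction %in% c("up", "down"))) {
    abort("`direction` must be 'up' or 'down'.")
  }
  sig <- dplyr::filter(as_tibble(probes), as.logical(.data$significant))
  if (any(is.na(sig$gene_id) | sig$gene_id == "")) {
    abort("Every significant probe must carry a gene_id.")
  }
  sig |>
    dplyr::distinct(.data$gene_id, .data$contrast, .data$direction) |>
    dplyr::mutate(flag = TRUE,
                  key = paste(.data$contrast, .data$direction, sep = "_")) |>
    dplyr::select("gene_id", "key", "flag") |>
    tidyr::pivot_wider(names_from = "key", values_from = "flag",
                       values_fill = FALSE) |>
    add_missing_sign_cols() |>
    dplyr::select("gene_id", "loss_up", "loss_down", "gain_up", "gain_down") |>
    dplyr::arrange(.data$gene_id)
}

add_missing_sign_cols <- function(x) {
  for (col in c("loss_up", "loss_down", "gain_up", "gain_down")) {
    if (!col %in% names(x)) x[[col]] <- rep(FALSE, nrow(x))
  }
  x
}

#' Classify gene-level sign sets as POS, NEG or AMB
#'
#' Maps each observed sign to an inferred regulatory direction
#' (loss-down and gain-up imply activation; loss-up and gain-down
#' imply repression) and takes the union over both contrasts:
#' only-activation is `POS`, only-repression `NEG`, both `AMB`.
#'
#' @param records Tibble from [collapse_probes()].
#' @return The input with a `category` column
#'   (`"POS"`/`"NEG"`/`"AMB"`).
#' @export
classify_responses <- function(records) {
  assert_columns(records, c("gene_id", "loss_up", "loss_down", "gain_up",
                            "gain_down"), "records")
  any_sign <- records$loss_up | records$loss_down |
    records$gain_up | records$gain_down
  if (any(!any_sign)) {
    abort(sprintf(
      "%d record(s) have empty sign sets in both contrasts and cannot be classified.",
      sum(!any_sign)
    ))
  }
  inferred_pos <- records$loss_down | records$gain_up
  inferred_neg <- records$loss_up | records$gain_down
  dplyr::mutate(as_tibble(records), category = dplyr::case_when(
    inferred_pos & inferred_neg ~ "AMB",
    inferred_pos ~ "POS",
    TRUE ~ "NEG"
  ))
}

#' Flag classified genes that carry a ChIP-seq peak
#'
#' `has_peak` is `TRUE` when the gene appears in any peak assignment —
#' intragenic (`GENE_OVERLAP`) or nearest-gene (`GENE_CLOSE`) links
#' both count. Downstream summaries use only peak-bearing genes, i.e.
#' putative *direct* targets.
#'
#' @param calls Tibble from [classify_responses()].
#' @param assignments Assignment tibble from
#'   [assign_peaks_to_genes()].
#' @return `calls` with a logical `has_peak` column.
#' @export
intersect_with_peaks <- function(calls, assignments) {
  assert_columns(calls, "gene_id", "calls")
  assert_columns(assignments, "gene_id", "assignments")
  dplyr::mutate(as_tibble(calls),
                has_peak = .data$gene_id %in% unique(assignments$gene_id))
}

#' Summarize the regulatory classification of peak-bearing genes
#'
#' Reproduces the study's summary arithmetic over genes that both
#' respond in at least one contrast and carry a peak: POS/NEG/AMB
#' counts and percentages of the total; per-contrast marginals
#' (`n_loss`, `n_gain`, their overlap `n_both` and its percentage of
#' the total); and within-category breakdowns for POS and NEG (genes
#' responding in the loss contrast, the gain contrast, and both, with
#' the both-contrast percentage of that category). All percentages are
#' rounded half-away-from-zero to one decimal.
#'
#' @param calls Classified calls carrying `has_peak` (from
#'   [intersect_with_peaks()]); rows with `has_peak = FALSE` are
#'   excluded. A `has_peak` column is optional — absent means all
#'   genes count.
#' @return An object of class `so_reg_summary`; see also
#'   [tidy.so_reg_summary()] and [glance.so_reg_summary()].
#' @export
summarize_calls <- function(calls) {
  assert_columns(calls, c("gene_id", "category", "loss_up", "loss_down",
                          "gain_up", "gain_down"), "calls")
  x <- as_tibble(calls)
  if ("has_peak" %in% names(x)) x <- dplyr::filter(x, .data$has_peak)
  total <- nrow(x)
  if (total == 0) abort("No peak-bearing classified genes to summarize.")
  in_loss <- x$loss_up | x$loss_down
  in_gain <- x$gain_up | x$gain_down
  pct <- function(k, d) round_half_up(100 * k / d, 1)
  counts_in <- function(keep) {
    c(loss = sum(in_loss & keep), gain = sum(in_gain & keep),
      both = sum(in_loss & in_gain & keep))
  }
  n_pos <- sum(x$category == "POS")
  n_neg <- sum(x$category == "NEG")
  n_amb <- sum(x$category == "AMB")
  pos_bd <- counts_in(x$category == "POS")
  neg_bd <- counts_in(x$category == "NEG")
  structure(list(
    total = total,
    n_pos = n_pos, n_neg = n_neg, n_amb = n_amb,
    pct_pos = pct(n_pos, total), pct_neg = pct(n_neg, total),
    pct_amb = pct(n_amb, total),
    n_loss = sum(in_loss), n_gain = sum(in_gain),
    n_both = sum(in_loss & in_gain),
    pct_both = pct(sum(in_loss & in_gain), total),
    n_loss_pos = unname(pos_bd["loss"]), n_gain_pos = unname(pos_bd["gain"]),
    n_both_pos = unname(pos_bd["both"]),
    pct_both_pos = unname(pct(pos_bd["both"], n_pos)),
    n_loss_neg = unname(neg_bd["loss"]), n_gain_neg = unname(neg_bd["gain"]),
    n_both_neg = unname(neg_bd["both"]),
    pct_both_neg = unname(pct(neg_bd["both"], n_neg))
  ), class = "so_reg_summary")
}

#' @export
print.so_reg_summary <- function(x, ...) {
  cat(sprintf("Putative direct targets: %d peak-bearing responsive genes\n",
              x$total))
  cat(sprintf("  POS (activated): %d (%.1f%%)\n", x$n_pos, x$pct_pos))
  cat(sprintf("  NEG (repressed): %d (%.1f%%)\n", x$n_neg, x$pct_neg))
  cat(sprintf("  AMB (conflicting): %d (%.1f%%)\n", x$n_amb, x$pct_amb))
  cat(sprintf("  Contrasts: %d loss, %d gain, %d both (%.1f%%)\n",
              x$n_loss, x$n_gain, x$n_both, x$pct_both))
  cat(sprintf("  POS breakdown: %d loss / %d gain / %d both (%.1f%% of POS)\n",
              x$n_loss_pos, x$n_gain_pos, x$n_both_pos, x$pct_both_pos))
  cat(sprintf("  NEG breakdown: %d loss / %d gain / %d both (%.1f%% of NEG)\n",
              x$n_loss_neg, x$n_gain_neg, x$n_both_neg, x$pct_both_neg))
  invisible(x)
}

#' Tidy a regulatory classification summary
#'
#' @param x A `so_reg_summary` object.
#' @param ... Unused.
#' @return A tibble with one row per reported statistic: `metric`,
#'   `count`, `percent` (NA where no percentage is defined).
#' @method tidy so_reg_summary
#' @export
tidy.so_reg_summary <- function(x, ...) {
  tibble(
    metric = c("total", "pos", "neg", "amb", "loss", "gain", "both",
               "pos_loss", "pos_gain", "pos_both",
               "neg_loss", "neg_gain", "neg_both"),
    count = c(x$total, x$n_pos, x$n_neg, x$n_amb, x$n_loss, x$n_gain,
              x$n_both, x$n_loss_pos, x$n_gain_pos, x$n_both_pos,
              x$n_loss_neg, x$n_gain_neg, x$n_both_neg),
    percent = c(NA, x$pct_pos, x$pct_neg, x$pct_amb, NA, NA, x$pct_both,
                NA, NA, x$pct_both_pos, NA, NA, x$pct_both_neg)
  )
}

#' Glance at a regulatory classification summary
#'
#' @inheritParams tidy.so_reg_summary
#' @return A one-row tibble of the headline numbers.
#' @method glance so_reg_summary
#' @export
glance.so_reg_summary <- function(x, ...) {
  tibble(total = x$total, n_pos = x$n_pos, n_neg = x$n_neg, n_amb = x$n_amb,
         pct_pos = x$pct_pos, pct_neg = x$pct_neg, pct_amb = x$pct_amb,
         n_both = x$n_both, pct_both = x$pct_both)
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric probability of observing at least `k`
#' foreground genes annotated to a term, given `K` background genes in
#' the term, a foreground of size `n` and a background universe of
#' size `N`. Term gene sets are intersected with the background first;
#' Benjamini-Hochberg adjusted P-values are reported alongside the raw
#' ones.
#'
#' @param foreground Character vector of foreground gene ids (must be
#'   a subset of `background`).
#' @param background Character vector of background (universe) gene
#'   ids.
#' @param term_map Tibble with columns `term`, `gene_id`.
#' @return A tibble: `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adjust`, sorted by `p_value`.
#' @export
hypergeom_enrichment <- function(foreground, background, term_map) {
  assert_columns(term_map, c("term", "gene_id"), "term_map")
  foreground <- unique(foreground)
  background <- unique(background)
  extra <- setdiff(foreground, background)
  if (length(extra) > 0) {
    abort(sprintf(
      "Foreground must be a subset of the background; %d gene(s) are not (e.g. %s).",
      length(extra), extra[1]
    ))
  }
  n <- length(foreground)
  N <- length(background)
  term_map |>
    as_tibble() |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::distinct(.data$term, .data$gene_id) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      k = sum(.data$gene_id %in% foreground),
      K = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::arrange(.data$p_value, .data$term)
}

#' Cluster enrichment score from member-term P-values
#'
#' Minus log10 of the geometric mean of the P-values; a score above
#' 1.3 corresponds to a geometric-mean P below 0.05.
#'
#' @param p Numeric vector of P-values in `(0, 1]`.
#' @return A single score.
#' @examples
#' cluster_enrichment_score(c(0.1, 0.001))  # 2
#' @export
cluster_enrichment_score <- function(p) {
  if (length(p) == 0) abort("`p` must be non-empty.")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("All P-values must lie in (0, 1].")
  }
  mean(-log10(p))
}

#' Select candidate genes for a phenotypic screen
#'
#' The three selection criteria: (1) the gene is flagged novel (no
#' previously reported role in the eye); (2) at least one assigned
#' peak has `score > min_peak_score` — strictly, since the default 200
#' encodes P < 1e-20; and (3) the gene's expression is at least
#' `min_expression` (boundary kept). Genes absent from the expression
#' table are treated as not expressed and reported in a message.
#'
#' @param assignments Assignment tibble from
#'   [assign_peaks_to_genes()].
#' @param peaks Peak tibble (source of peak scores).
#' @param expression Tibble with columns `gene_id`, `expression`.
#' @param novel Character vector of novel gene ids, or a tibble with
#'   columns `gene_id`, `novel` (logical).
#' @param min_peak_score Strict lower bound on the best assigned peak
#'   score (default 200, i.e. P < 1e-20).
#' @param min_expression Inclusive expression threshold (default 10).
#' @return A tibble of selected genes: `gene_id`, `best_peak_score`,
#'   `expression`, sorted by `best_peak_score` descending.
#' @export
select_screen_candidates <- function(assignments, peaks, expression, novel,
                                     min_peak_score = 200,
                                     min_expression = 10) {
  assert_columns(assignments, c("peak_id", "gene_id"), "assignments")
  validate_peaks(peaks)
  assert_columns(expression, c("gene_id", "expression"), "expression")
  if (is.data.frame(novel)) {
    assert_columns(novel, c("gene_id", "novel"), "novel")
    novel <- novel$gene_id[as.logical(novel$novel)]
  }
  per_gene <- assignments |>
    as_tibble() |>
    dplyr::inner_join(peaks[c("peak_id", "score")], by = "peak_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(best_peak_score = max(.data$score), .groups = "drop")
  missing <- setdiff(intersect(per_gene$gene_id, novel), expression$gene_id)
  if (length(missing) > 0) {
    inform(sprintf(
      "%d candidate gene(s) missing from the expression table were treated as not expressed (e.g. %s).",
      length(missing), missing[1]
    ))
  }
  per_gene |>
    dplyr::left_join(dplyr::distinct(as_tibble(expression), .data$gene_id,
                                     .keep_all = TRUE),
                     by = "gene_id") |>
    dplyr::filter(
      .data$gene_id %in% novel,
      .data$best_peak_score > min_peak_score,
      !is.na(.data$expression) & .data$expression >= min_expression
    ) |>
    dplyr::arrange(dplyr::desc(.data$best_peak_score), .data$gene_id) |>
    dplyr::select("gene_id", "best_peak_score", "expression")
}

#' Read a probe-level response table
#'
#' Tab-separated with header `PROBE, GENE, CONTRAST, DIRECTION, SIG`
#' (`CONTRAST` in loss/gain, `DIRECTION` in up/down, `SIG` 0/1).
#'
#' @param path Input path.
#' @return A probe tibble for [collapse_probes()].
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Probe table not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tab, c("PROBE", "GENE", "CONTRAST", "DIRECTION", "SIG"), path)
  tibble(probe_id = as.character(tab$PROBE),
         gene_id = as.character(tab$GENE),
         contrast = tolower(tab$CONTRAST),
         direction = tolower(tab$DIRECTION),
         significant = as.logical(as.integer(tab$SIG)))
}

#' Write probe-level responses
#'
#' @param probes Probe tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  assert_columns(probes, c("probe_id", "gene_id", "contrast", "direction",
                           "significant"), "probes")
  tibble(PROBE = probes$probe_id, GENE = probes$gene_id,
         CONTRAST = probes$contrast, DIRECTION = probes$direction,
         SIG = as.integer(probes$significant)) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write gene-level regulatory calls
#'
#' Tab-separated mirror of the per-gene call table: `GENE, CATEGORY,
#' LOSS_SIGNS, GAIN_SIGNS, HAS_PEAK`, with sign sets rendered as
#' `up`, `down`, `up,down` or empty.
#'
#' @param calls Tibble from [intersect_with_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulatory_calls <- function(calls, path) {
  assert_columns(calls, c("gene_id", "category", "loss_up", "loss_down",
                          "gain_up", "gain_down", "has_peak"), "calls")
  signs <- function(up, down) {
    dplyr::case_when(up & down ~ "up,down", up ~ "up", down ~ "down",
                     TRUE ~ "")
  }
  tibble(GENE = calls$gene_id, CATEGORY = calls$category,
         LOSS_SIGNS = signs(calls$loss_up, calls$loss_down),
         GAIN_SIGNS = signs(calls$gain_up, calls$gain_down),
         HAS_PEAK = as.integer(calls$has_peak)) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
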
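#' Run the full target-inference pipeline on a synthetic study
#'
#' Chains every stage on generated data: simulate, filter peaks
#' (score >= `min_score`, fold >= `min_fold`), rank and index, assign
#' peaks to genes, nearest-TSS distance profile, motif occurrence and
#' shuffled-background enrichment, probe collapse and POS/NEG/AMB
#' classification restricted to peak-bearing genes, hypergeometric
#' term enrichment of the top-decile peak genes, and three-criterion
#' screen-candidate selection. Writes standard-format outputs plus a
#' JSON run manifest when `out_dir` is given; identical config and
#' seed give identical manifests and files.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @param min_score,min_fold Peak filter thresholds (defaults 50 and
#'   3).
#' @param top_fraction Fraction of most significant peaks used for
#'   term enrichment (default 0.10).
#' @param candidate_min_score,candidate_min_expression Screen-candidate
#'   thresholds (defaults 200 and 10).
#' @param n_shuffles Shuffle rounds for the motif background; 0 skips
#'   the background and reports observed fractions only.
#' @param motifs Motif tibble to scan (default [builtin_motifs()]).
#' @param quiet Suppress progress messages.
#' @return A list with the study, every stage result and the
#'   `manifest` list, invisibly.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         min_score = 50, min_fold = 3, top_fraction = 0.10,
                         candidate_min_score = 200,
                         candidate_min_expression = 10,
                         n_shuffles = 19, motifs = builtin_motifs(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))

  say("Simulating study (seed %d): %d genes, %d peaks ...",
      config$seed, config$n_genes, config$n_peaks)
  study <- simulate_study(config, out_dir = out_dir)

  peaks <- filter_peaks(study$peaks, min_score = min_score,
                        min_fold = min_fold) |>
    rank_peaks()
  say("Peaks after filter: %d of %d", nrow(peaks), nrow(study$peaks))

  assignments <- assign_peaks_to_genes(peaks, study$genes)
  status <- summarize_gene_status(assignments)
  profile <- distance_profile(assignments)
  say("Assigned peaks: %.1f%% intragenic, %d distinct genes",
      100 * status$fraction_overlap, status$distinct_genes)

  seqs <- study$sequences[peaks$peak_id]
  motif_summary <- if (n_shuffles > 0) {
    shuffle_enrichment(seqs, motifs, n_shuffles = n_shuffles,
                       seed = config$seed + 7L)
  } else {
    peak_hit_fraction(seqs, motifs)
  }

  calls <- collapse_probes(study$probes) |>
    classify_responses() |>
    intersect_with_peaks(assignments)
  summary <- summarize_calls(calls)
  say("Classified %d peak-bearing genes: %d POS / %d NEG / %d AMB",
      summary$total, summary$n_pos, summary$n_neg, summary$n_amb)

  top <- select_top_fraction(peaks, top_fraction)
  foreground <- unique(assignments$gene_id[assignments$peak_id %in%
                                             top$peak_id])
  enrichment <- hypergeom_enrichment(foreground, study$genes$gene_id,
                                     study$term_map)

  candidates <- select_screen_candidates(
    assignments, peaks,
    expression = study$expression[c("gene_id", "expression")],
    novel = study$expression[c("gene_id", "novel")],
    min_peak_score = candidate_min_score,
    min_expression = candidate_min_expression
  )
  say("Screen candidates: %d", nrow(candidates))

  manifest <- list(
    version = as.character(packageVersion("sotargets")),
    seed = config$seed,
    parameters = list(
      min_score = min_score, min_fold = min_fold,
      top_fraction = top_fraction,
      candidate_min_score = candidate_min_score,
      candidate_min_expression = candidate_min_expression,
      n_shuffles = n_shuffles,
      n_genes = config$n_genes, n_peaks = config$n_peaks
    ),
    counts = list(
      peaks_input = nrow(study$peaks),
      peaks_kept = nrow(peaks),
      peaks_top = nrow(top),
      assignments = nrow(assignments),
      distinct_genes = status$distinct_genes,
      fraction_overlap = status$fraction_overlap,
      classified_total = summary$total,
      n_pos = summary$n_pos, n_neg = summary$n_neg, n_amb = summary$n_amb,
      candidates = nrow(candidates)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peak_table(peaks, assignments,
                     file.path(out_dir, "peak_gene_table.tsv"))
    readr::write_tsv(profile, file.path(out_dir, "tss_profile.tsv"),
                     progress = FALSE)
    write_motif_summary(motif_summary,
                        file.path(out_dir, "motif_summary.tsv"))
    write_regulatory_calls(calls,
                           file.path(out_dir, "regulatory_calls.tsv"))
    readr::write_tsv(enrichment, file.path(out_dir, "term_enrichment.tsv"),
                     progress = FALSE)
    readr::write_tsv(candidates, file.path(out_dir, "screen_candidates.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(summary),
                     file.path(out_dir, "classification_summary.tsv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(
    study = study, peaks = peaks, assignments = assignments,
    status = status, profile = profile, motif_summary = motif_summary,
    calls = calls, summary = summary, top_peaks = top,
    enrichment = enrichment, candidates = candidates, manifest = manifest
  ))
}
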
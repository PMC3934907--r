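# Synthetic-data generator. Emulates the study conditions with known
# ground truth: ~7,566 peaks of ~1 kb mean width whose nearest-TSS
# distances follow the observed bin fractions, an 84.7% intragenic
# placement rate, peak scores spanning 50-650 on the -10*log10(P)
# scale, sequences with planted IUPAC motifs, and two expression
# contrasts reproducing the printed response marginals and category
# breakdowns by construction.
#
# Geometry: each gene owns a fixed 250-kb territory on its chromosome
# and every peak is placed relative to its chosen gene's TSS with a
# drawn distance capped well below half the territory, so the planted
# gene is provably the nearest gene AND the nearest TSS. That makes
# every drawn bin and intragenic flag exact, which is what lets the
# parameter-recovery tests assert closed-form expectations.

#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the study conditions; every generator is a pure
#' function of this object, so a fixed seed gives byte-identical
#' output files.
#'
#' @param seed Integer master seed; each generator derives its own
#'   sub-seed so the call order does not matter.
#' @param n_genes,n_chroms Genome shape: genes are spread round-robin
#'   over the chromosomes, one per 250-kb territory.
#' @param gene_length_range Min/max gene length in bp (log-uniform).
#' @param gene_spacing,chrom_margin Territory width and chromosome-end
#'   margin, bp.
#' @param overlap_fraction Fraction of genes nested inside their
#'   predecessor's span, to exercise multi-gene overlap assignment
#'   (default 0; peak simulation requires 0).
#' @param n_peaks Number of peaks.
#' @param peak_width_mean,peak_width_sd Peak width draw,
#'   `Normal(mean, sd)` truncated to `[100, 5000]` bp.
#' @param tss_bin_targets Target fractions for the five nearest-TSS
#'   distance bins `[0,1k), [1,5k), [5,10k), [10,20k), >=20k`; must sum
#'   to 1.
#' @param max_tss_distance Upper cap on drawn TSS distances in the
#'   open last bin, bp.
#' @param frac_intragenic Probability that a peak is placed overlapping
#'   its gene.
#' @param score_range,fold_range Log-uniform ranges for the
#'   -10*log10(P) score and the fold enrichment.
#' @param planted_motifs Tibble `name`, `consensus`, `fraction`: each
#'   motif gets one exact planted instance in that fraction of peak
#'   sequences.
#' @param n_loss,n_gain,n_both Response marginals: genes responding in
#'   the loss contrast, the gain contrast, and both.
#' @param pos_breakdown,neg_breakdown Named vectors `c(loss=, gain=,
#'   both=)` giving, within the POS and NEG categories, how many genes
#'   respond in each contrast (inclusive of the both-contrast genes).
#'   The AMB cells and the category totals are derived from these and
#'   the marginals; inconsistent values raise a feasibility error.
#' @param allow_dual_direction Whether AMB genes confined to a single
#'   contrast may be realized through dual-direction (up+down) probes;
#'   with `FALSE`, such cells are a feasibility error.
#' @param n_nonpeak_responders Responding genes with no peak, used to
#'   test the peak intersection.
#' @param decoy_probe_rate Fraction of additional non-significant
#'   probes added as noise.
#' @param n_terms,term_size_range,planted_term_frac Term-map shape:
#'   random terms plus one planted term drawing this fraction of its
#'   genes from the enrichment foreground.
#' @param novel_fraction Fraction of genes flagged as having no
#'   reported eye role.
#' @param expression_range Log-uniform range of gene expression values.
#' @return A validated list of class `so_synth_config`; `$cells` holds
#'   the derived per-(contrast-cell, category) gene counts.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 3000,
                             n_chroms = 5,
                             gene_length_range = c(1e3, 8e4),
                             gene_spacing = 250000,
                             chrom_margin = 150000,
                             overlap_fraction = 0,
                             n_peaks = 7566,
                             peak_width_mean = 1000,
                             peak_width_sd = 250,
                             tss_bin_targets = c(0.524, 0.167, 0.098, 0.103, 0.108),
                             max_tss_distance = 50000,
                             frac_intragenic = 0.847,
                             score_range = c(50, 650),
                             fold_range = c(3, 64),
                             planted_motifs = tibble(name = "So",
                                                     consensus = "AGATAC",
                                                     fraction = 0.4),
                             n_loss = 460, n_gain = 444, n_both = 94,
                             pos_breakdown = c(loss = 257, gain = 244, both = 33),
                             neg_breakdown = c(loss = 151, gain = 149, both = 10),
                             allow_dual_direction = TRUE,
                             n_nonpeak_responders = 90,
                             decoy_probe_rate = 0.1,
                             n_terms = 30,
                             term_size_range = c(10, 60),
                             planted_term_frac = 0.7,
                             novel_fraction = 0.5,
                             expression_range = c(1, 1000)) {
  if (abs(sum(tss_bin_targets) - 1) > 1e-9) {
    abort("`tss_bin_targets` must sum to 1.")
  }
  if (length(tss_bin_targets) != 5) {
    abort("`tss_bin_targets` must have 5 bins.")
  }
  if (n_both > min(n_loss, n_gain)) {
    abort("`n_both` cannot exceed either marginal.")
  }
  assert_columns(planted_motifs, c("name", "consensus", "fraction"),
                 "planted_motifs")
  cells <- derive_response_cells(n_loss, n_gain, n_both,
                                 pos_breakdown, neg_breakdown,
                                 allow_dual_direction)
  structure(list(
    seed = as.integer(seed), n_genes = n_genes, n_chroms = n_chroms,
    gene_length_range = gene_length_range, gene_spacing = gene_spacing,
    chrom_margin = chrom_margin, overlap_fraction = overlap_fraction,
    n_peaks = n_peaks, peak_width_mean = peak_width_mean,
    peak_width_sd = peak_width_sd, tss_bin_targets = tss_bin_targets,
    bin_edges = c(0, 1e3, 5e3, 1e4, 2e4, Inf),
    max_tss_distance = max_tss_distance, frac_intragenic = frac_intragenic,
    score_range = score_range, fold_range = fold_range,
    planted_motifs = planted_motifs,
    n_loss = n_loss, n_gain = n_gain, n_both = n_both,
    cells = cells, allow_dual_direction = allow_dual_direction,
    n_nonpeak_responders = n_nonpeak_responders,
    decoy_probe_rate = decoy_probe_rate,
    n_terms = n_terms, term_size_range = term_size_range,
    planted_term_frac = planted_term_frac,
    novel_fraction = novel_fraction, expression_range = expression_range
  ), class = "so_synth_config")
}

# Solve the per-cell gene counts implied by the marginals and the
# POS/NEG breakdowns. Inclusion-exclusion fixes every AMB cell; any
# negative cell means the configuration is infeasible.
derive_response_cells <- function(n_loss, n_gain, n_both,
                                  pos_breakdown, neg_breakdown,
                                  allow_dual_direction) {
  need <- function(v) {
    if (!all(c("loss", "gain", "both") %in% names(v))) {
      abort("Breakdowns must be named vectors with loss, gain, both.")
    }
    v[c("loss", "gain", "both")]
  }
  pb <- need(pos_breakdown); nb <- need(neg_breakdown)
  amb_loss <- n_loss - pb[["loss"]] - nb[["loss"]]
  amb_gain <- n_gain - pb[["gain"]] - nb[["gain"]]
  amb_both <- n_both - pb[["both"]] - nb[["both"]]
  cells <- c(
    pos_loss_only = pb[["loss"]] - pb[["both"]],
    pos_gain_only = pb[["gain"]] - pb[["both"]],
    pos_both = pb[["both"]],
    neg_loss_only = nb[["loss"]] - nb[["both"]],
    neg_gain_only = nb[["gain"]] - nb[["both"]],
    neg_both = nb[["both"]],
    amb_loss_only = amb_loss - amb_both,
    amb_gain_only = amb_gain - amb_both,
    amb_both = amb_both
  )
  if (any(cells < 0)) {
    bad <- names(cells)[cells < 0][1]
    abort(sprintf(
      "Infeasible response targets: derived cell `%s` is negative (%d). Check the marginals against the breakdowns.",
      bad, cells[[bad]]
    ))
  }
  if (!allow_dual_direction &&
      (cells[["amb_loss_only"]] > 0 || cells[["amb_gain_only"]] > 0)) {
    abort(paste(
      "Infeasible response targets: AMB genes restricted to a single",
      "contrast require dual-direction probes",
      "(set `allow_dual_direction = TRUE`)."
    ))
  }
  cells
}

chrom_names <- function(n) {
  base <- c("chr2L", "chr2R", "chr3L", "chr3R", "chrX")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("chr%d", seq_len(n - length(base)) + 3))
}

#' Simulate a gene annotation with territory layout
#'
#' Genes are placed one per fixed territory (non-overlapping by
#' default), with log-uniform lengths and 50/50 strands. With
#' `overlap_fraction > 0`, that fraction of genes is instead nested
#' inside the previous gene's span, to exercise multi-gene overlap
#' assignment; the exact overlapping pairs are recorded in the ground
#' truth.
#'
#' @param config A [synthetic_config()].
#' @return A list: `genes` (tibble), `chrom_sizes` (named integer),
#'   `ground_truth` (list with `overlap_pairs`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "so_synth_config"))
  with_local_seed(config$seed + 1L, {
    n <- config$n_genes
    chroms <- chrom_names(config$n_chroms)
    chrom_of <- rep(chroms, length.out = n)
    slot <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
    center <- config$chrom_margin + (slot - 1) * config$gene_spacing
    lr <- log10(config$gene_length_range)
    len <- as.integer(round(10^runif(n, lr[1], lr[2])))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      name = sprintf("g%04d", seq_len(n)),
      chrom = chrom_of,
      start = as.integer(center),
      end = as.integer(center + len),
      strand = strand
    )
    overlap_pairs <- tibble(gene_id = character(), host_gene_id = character())
    if (config$overlap_fraction > 0) {
      ord <- order(match(genes$chrom, chroms), genes$start)
      eligible <- which(duplicated(genes$chrom[ord]))  # has a predecessor
      pick <- eligible[runif(length(eligible)) < config$overlap_fraction]
      for (j in pick) {
        i <- ord[j]; h <- ord[j - 1]
        host_len <- genes$end[h] - genes$start[h]
        nest_len <- max(200L, as.integer(host_len %/% 2))
        genes$start[i] <- genes$start[h] + as.integer(host_len %/% 4)
        genes$end[i] <- genes$start[i] + nest_len
      }
      overlap_pairs <- tibble(gene_id = genes$gene_id[ord[pick]],
                              host_gene_id = genes$gene_id[ord[pick - 1]])
    }
    per_chrom <- table(chrom_of)[chroms]
    chrom_sizes <- setNames(
      as.integer(as.integer(per_chrom) * config$gene_spacing +
                   2L * config$chrom_margin),
      chroms
    )
    validate_genes(genes)
    list(genes = genes, chrom_sizes = chrom_sizes,
         ground_truth = list(overlap_pairs = overlap_pairs))
  })
}

#' Simulate scored peaks with planted TSS-distance bins
#'
#' Each peak draws a distance bin from `tss_bin_targets`, an exact
#' distance inside the bin, an intragenic/intergenic flag
#' (`frac_intragenic`), and a uniformly chosen gene (restricted to
#' genes long enough when the peak must sit inside the gene body at
#' that distance), then a position realizing exactly that nearest-TSS
#' distance relative to the gene's strand-aware TSS. Widths are
#' truncated normal; scores and fold enrichments log-uniform and
#' independent of placement. The territory layout guarantees the
#' chosen gene is both the nearest gene and the nearest TSS, so the
#' ground truth (bin, flag, distance, gene) is exact.
#'
#' @param annotation Result of [simulate_annotation()].
#' @param config A [synthetic_config()] (with `overlap_fraction = 0`).
#' @return A list: `peaks` (tibble), `ground_truth` (tibble `peak_id`,
#'   `gene_id`, `bin`, `intragenic`, `tss_distance`).
#' @export
simulate_peaks <- function(annotation, config) {
  stopifnot(inherits(config, "so_synth_config"))
  if (config$overlap_fraction > 0) {
    abort("Exact peak placement requires `overlap_fraction = 0`.")
  }
  genes <- annotation$genes
  with_local_seed(config$seed + 2L, {
    n <- config$n_peaks
    len <- genes$end - genes$start
    tss <- as.integer(ifelse(genes$strand == "+", genes$start,
                             genes$end - 1L))
    edges <- config$bin_edges
    bin_lo <- edges[-length(edges)]
    bin_hi <- pmin(edges[-1] - 1, config$max_tss_distance)

    bin <- sample.int(5L, n, replace = TRUE, prob = config$tss_bin_targets)
    intragenic <- runif(n) < config$frac_intragenic
    lo <- ifelse(intragenic, bin_lo[bin], pmax(1, bin_lo[bin]))
    d <- as.integer(floor(runif(n, lo, bin_hi[bin] + 1)))
    w <- as.integer(pmin(5000, pmax(
      100, round(rnorm(n, config$peak_width_mean, config$peak_width_sd))
    )))

    gi <- sample.int(nrow(genes), n, replace = TRUE)
    need_long <- intragenic & (d >= len[gi])
    for (k in which(need_long)) {
      ok <- which(len > d[k])
      if (length(ok) == 0) {
        abort(sprintf(
          "No gene is long enough to host an intragenic peak at TSS distance %d bp.",
          d[k]
        ))
      }
      gi[k] <- ok[sample.int(length(ok), 1L)]
    }

    t <- tss[gi]
    plus <- genes$strand[gi] == "+"
    start <- integer(n); end <- integer(n)
    into <- intragenic   # peak placed into the gene body
    # + strand: body extends rightwards from the TSS; - strand leftwards.
    body_right <- (plus & into) | (!plus & !into)
    start[body_right] <- t[body_right] + d[body_right]
    end[body_right] <- start[body_right] + w[body_right]
    end[!body_right] <- t[!body_right] - d[!body_right] + 1L
    start[!body_right] <- end[!body_right] - w[!body_right]
    if (any(start < 0)) abort("Peak placement escaped the chromosome margin.")

    sr <- log10(config$score_range); fr <- log10(config$fold_range)
    peaks <- tibble(
      peak_id = sprintf("peak_%05d", seq_len(n)),
      chrom = genes$chrom[gi],
      start = start, end = end,
      score = round(10^runif(n, sr[1], sr[2]), 2),
      fold = round(10^runif(n, fr[1], fr[2]), 2)
    )
    validate_peaks(peaks)
    list(
      peaks = peaks,
      ground_truth = tibble(
        peak_id = peaks$peak_id, gene_id = genes$gene_id[gi],
        bin = bin, intragenic = intragenic, tss_distance = d
      )
    )
  })
}

#' Simulate peak sequences with planted motif instances
#'
#' Uniform-random DNA at each peak's width; for each configured motif,
#' a random subset of the target fraction of peaks receives one exact
#' planted instance (a uniformly drawn concretization of the IUPAC
#' consensus) at a random offset on a random strand. A motif longer
#' than a sequence skips planting for that peak with a message.
#'
#' @param peaks Peak tibble from [simulate_peaks()].
#' @param config A [synthetic_config()].
#' @return A list: `sequences` (named character vector), `ground_truth`
#'   (list per motif of planted peak ids).
#' @export
simulate_sequences <- function(peaks, config) {
  stopifnot(inherits(config, "so_synth_config"))
  with_local_seed(config$seed + 3L, {
    n <- nrow(peaks)
    widths <- peaks$end - peaks$start
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(widths, function(w) {
      paste(sample(bases, w, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- peaks$peak_id
    planted <- list()
    for (r in seq_len(nrow(config$planted_motifs))) {
      cons <- validate_consensus(config$planted_motifs$consensus[r])
      frac <- config$planted_motifs$fraction[r]
      k <- nchar(cons)
      n_plant <- round(frac * n)
      idx <- sort(sample.int(n, n_plant))
      ok <- widths[idx] >= k
      if (any(!ok)) {
        inform(sprintf(
          "Motif %s is longer than %d sequence(s); planting skipped there.",
          cons, sum(!ok)
        ))
        idx <- idx[ok]
      }
      for (i in idx) {
        inst <- paste(vapply(strsplit(cons, "")[[1]], function(ch) {
          set <- expand_iupac(ch)
          set[sample.int(length(set), 1L)]
        }, character(1)), collapse = "")
        if (runif(1) < 0.5) inst <- revcomp_iupac(inst)
        off <- sample.int(widths[i] - k + 1L, 1L)
        substr(seqs[i], off, off + k - 1L) <- inst
      }
      planted[[config$planted_motifs$name[r]]] <- peaks$peak_id[idx]
    }
    list(sequences = seqs, ground_truth = list(planted = planted))
  })
}

#' Simulate a probe-level response table with planted categories
#'
#' Assigns planted POS/NEG/AMB categories and contrast cells to genes
#' so the emitted table reproduces exactly the configured marginals
#' and breakdowns: each responding gene-contrast gets one significant
#' probe whose direction encodes the planted category (AMB genes in
#' both contrasts get conflicting inferred directions; AMB genes in a
#' single contrast get dual-direction probes). Optionally adds
#' responding genes without peaks and non-significant decoy probes.
#'
#' @param config A [synthetic_config()].
#' @param peak_genes Character vector of genes that carry peaks.
#' @param nonpeak_genes Character vector of genes without peaks, drawn
#'   on for the `n_nonpeak_responders`.
#' @return A list: `probes` (tibble), `ground_truth` (tibble
#'   `gene_id`, `category`, `cell`, `has_peak`, plus
#'   `expected_summary`, the closed-form counts).
#' @export
simulate_response_table <- function(config, peak_genes,
                                    nonpeak_genes = character()) {
  stopifnot(inherits(config, "so_synth_config"))
  cells <- config$cells
  total <- config$n_loss + config$n_gain - config$n_both
  stopifnot(sum(cells) == total)
  if (length(peak_genes) < total) {
    abort(sprintf(
      "Need at least %d peak-bearing genes for the response targets; only %d available.",
      total, length(peak_genes)
    ))
  }
  if (config$n_nonpeak_responders > length(nonpeak_genes)) {
    abort(sprintf(
      "Need %d genes without peaks for non-peak responders; only %d available.",
      config$n_nonpeak_responders, length(nonpeak_genes)
    ))
  }
  with_local_seed(config$seed + 4L, {
    chosen <- sample(peak_genes, total)
    cell_of <- rep(names(cells), times = cells)
    plan <- tibble(gene_id = chosen, cell = cell_of, has_peak = TRUE)
    if (config$n_nonpeak_responders > 0) {
      extra <- sample(nonpeak_genes, config$n_nonpeak_responders)
      extra_cell <- sample(c("pos_loss_only", "pos_gain_only",
                             "neg_loss_only", "neg_gain_only"),
                           config$n_nonpeak_responders, replace = TRUE)
      plan <- dplyr::bind_rows(plan, tibble(gene_id = extra,
                                            cell = extra_cell,
                                            has_peak = FALSE))
    }
    plan$category <- toupper(sub("_.*$", "", plan$cell))

    rows <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      g <- plan$gene_id[i]; cell <- plan$cell[i]
      cat <- plan$category[i]
      in_loss <- grepl("loss_only|both", cell)
      in_gain <- grepl("gain_only|both", cell)
      recs <- list()
      if (cat == "POS") {
        if (in_loss) recs <- c(recs, list(c(g, "loss", "down")))
        if (in_gain) recs <- c(recs, list(c(g, "gain", "up")))
      } else if (cat == "NEG") {
        if (in_loss) recs <- c(recs, list(c(g, "loss", "up")))
        if (in_gain) recs <- c(recs, list(c(g, "gain", "down")))
      } else {
        if (in_loss && in_gain) {
          # conflicting inferred directions across contrasts
          if (runif(1) < 0.5) {
            recs <- list(c(g, "loss", "down"), c(g, "gain", "down"))
          } else {
            recs <- list(c(g, "loss", "up"), c(g, "gain", "up"))
          }
        } else {
          ctr <- if (in_loss) "loss" else "gain"
          recs <- list(c(g, ctr, "up"), c(g, ctr, "down"))
        }
      }
      rows[[i]] <- do.call(rbind, recs)
    }
    sig <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(sig) <- c("gene_id", "contrast", "direction")
    sig$significant <- TRUE

    n_decoy <- round(config$decoy_probe_rate * nrow(sig))
    if (n_decoy > 0) {
      decoy <- tibble(
        gene_id = sample(plan$gene_id, n_decoy, replace = TRUE),
        contrast = sample(c("loss", "gain"), n_decoy, replace = TRUE),
        direction = sample(c("up", "down"), n_decoy, replace = TRUE),
        significant = FALSE
      )
      sig <- dplyr::bind_rows(as_tibble(sig), decoy)
    }
    probes <- as_tibble(sig) |>
      dplyr::mutate(probe_id = sprintf("pr%06d", dplyr::row_number())) |>
      dplyr::select("probe_id", "gene_id", "contrast", "direction",
                    "significant")

    expected <- expected_summary_from_cells(cells)
    list(
      probes = probes,
      ground_truth = list(
        plan = plan,
        expected_summary = expected
      )
    )
  })
}

# Closed-form summary counts implied by the planted cells; the
# pipeline's summarize_calls() must reproduce these exactly.
expected_summary_from_cells <- function(cells) {
  g <- function(nm) unname(cells[nm])
  list(
    total = sum(cells),
    n_pos = g("pos_loss_only") + g("pos_gain_only") + g("pos_both"),
    n_neg = g("neg_loss_only") + g("neg_gain_only") + g("neg_both"),
    n_amb = g("amb_loss_only") + g("amb_gain_only") + g("amb_both"),
    n_loss = g("pos_loss_only") + g("neg_loss_only") + g("amb_loss_only") +
      g("pos_both") + g("neg_both") + g("amb_both"),
    n_gain = g("pos_gain_only") + g("neg_gain_only") + g("amb_gain_only") +
      g("pos_both") + g("neg_both") + g("amb_both"),
    n_both = g("pos_both") + g("neg_both") + g("amb_both"),
    n_loss_pos = g("pos_loss_only") + g("pos_both"),
    n_gain_pos = g("pos_gain_only") + g("pos_both"),
    n_both_pos = g("pos_both"),
    n_loss_neg = g("neg_loss_only") + g("neg_both"),
    n_gain_neg = g("neg_gain_only") + g("neg_both"),
    n_both_neg = g("neg_both")
  )
}

#' Simulate gene expression levels and novelty flags
#'
#' Log-uniform expression values plus a random subset flagged as
#' "novel" (no previously reported eye role), inputs to the
#' screen-candidate selection.
#'
#' @param config A [synthetic_config()].
#' @param genes Gene tibble.
#' @return A tibble: `gene_id`, `expression`, `novel`.
#' @export
simulate_expression <- function(config, genes) {
  stopifnot(inherits(config, "so_synth_config"))
  with_local_seed(config$seed + 5L, {
    er <- log10(config$expression_range)
    tibble(
      gene_id = genes$gene_id,
      expression = round(10^runif(nrow(genes), er[1], er[2]), 1),
      novel = runif(nrow(genes)) < config$novel_fraction
    )
  })
}

#' Simulate a term-to-gene annotation map
#'
#' Random terms of random sizes, plus one planted term
#' (`planted_eye_term`) drawing most of its genes from a supplied
#' foreground so enrichment tests have a known positive.
#'
#' @param config A [synthetic_config()].
#' @param genes Gene tibble (the background universe).
#' @param foreground Character vector of genes the planted term should
#'   favor.
#' @return A list: `term_map` (tibble `term`, `gene_id`),
#'   `ground_truth` (list with `planted_term`).
#' @export
simulate_term_map <- function(config, genes, foreground = character()) {
  stopifnot(inherits(config, "so_synth_config"))
  with_local_seed(config$seed + 6L, {
    universe <- genes$gene_id
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    config$n_terms, replace = TRUE)
    rows <- purrr::map2_dfr(sprintf("T%03d", seq_len(config$n_terms)), sizes,
                            function(term, size) {
      tibble(term = term, gene_id = sample(universe, size))
    })
    planted <- NULL
    if (length(foreground) > 0) {
      size <- min(40L, length(foreground))
      n_fg <- round(config$planted_term_frac * size)
      members <- c(sample(foreground, n_fg),
                   sample(setdiff(universe, foreground), size - n_fg))
      planted <- tibble(term = "planted_eye_term", gene_id = members)
      rows <- dplyr::bind_rows(rows, planted)
    }
    list(term_map = rows,
         ground_truth = list(planted_term = if (is.null(planted)) NA_character_
                             else "planted_eye_term"))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator under the shared config: annotation, peaks,
#' peak sequences, expression, response probes (with planted
#' categories over the peak-bearing genes) and a term map whose
#' planted term favors the genes of the top-decile peaks. Optionally
#' writes all standard-format files plus a ground-truth JSON into
#' `out_dir`; repeated runs under the same config are byte-identical.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list with elements `config`, `genes`, `chrom_sizes`,
#'   `peaks`, `sequences`, `probes`, `expression`, `term_map`,
#'   `ground_truth` and, when written, `paths`.
#' @export
simulate_study <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "so_synth_config"))
  ann <- simulate_annotation(config)
  pk <- simulate_peaks(ann, config)
  sq <- simulate_sequences(pk$peaks, config)
  peak_genes <- unique(pk$ground_truth$gene_id)
  nonpeak_genes <- setdiff(ann$genes$gene_id, peak_genes)
  resp <- simulate_response_table(config, peak_genes, nonpeak_genes)
  expr <- simulate_expression(config, ann$genes)
  top_genes <- pk$ground_truth$gene_id[
    order(-pk$peaks$score)[seq_len(ceiling(0.10 * nrow(pk$peaks)))]
  ]
  tm <- simulate_term_map(config, ann$genes, unique(top_genes))

  ground_truth <- list(
    annotation = ann$ground_truth,
    peaks = pk$ground_truth,
    motifs = sq$ground_truth,
    response = resp$ground_truth,
    term_map = tm$ground_truth
  )
  out <- list(config = config, genes = ann$genes,
              chrom_sizes = ann$chrom_sizes, peaks = pk$peaks,
              sequences = sq$sequences, probes = resp$probes,
              expression = expr, term_map = tm$term_map,
              ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      annotation = file.path(out_dir, "genes.gff3"),
      peaks = file.path(out_dir, "peaks.tsv"),
      sequences = file.path(out_dir, "peak_sequences.fasta"),
      probes = file.path(out_dir, "probes.tsv"),
      expression = file.path(out_dir, "expression.tsv"),
      term_map = file.path(out_dir, "term_map.tsv"),
      ground_truth = file.path(out_dir, "ground_truth.json")
    )
    write_gene_annotation(ann$genes, paths$annotation, format = "gff3",
                          chrom_sizes = ann$chrom_sizes)
    write_peaks(pk$peaks, paths$peaks, dialect = "macs_tab")
    write_peak_sequences(sq$sequences, paths$sequences)
    write_probe_table(resp$probes, paths$probes)
    readr::write_tsv(
      tibble(GENE = expr$gene_id, EXPRESSION = expr$expression,
             NOVEL = as.integer(expr$novel)),
      paths$expression, progress = FALSE
    )
    readr::write_tsv(tibble(TERM = tm$term_map$term,
                            GENE = tm$term_map$gene_id),
                     paths$term_map, progress = FALSE)
    gt_json <- list(
      peaks = ground_truth$peaks,
      planted_motifs = ground_truth$motifs$planted,
      response_plan = ground_truth$response$plan,
      expected_summary = ground_truth$response$expected_summary,
      planted_term = ground_truth$term_map$planted_term,
      overlap_pairs = ground_truth$annotation$overlap_pairs
    )
    jsonlite::write_json(gt_json, paths$ground_truth, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    out$paths <- paths
  }
  out
}
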
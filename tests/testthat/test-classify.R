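test_that("probe collapse unions directions per gene and contrast", {
  probes <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6),
    gene_id = c("geneA", "geneA", "nonA", "nonA", "quiet", "geneB"),
    contrast = c("loss", "loss", "loss", "loss", "gain", "gain"),
    direction = c("down", "down", "up", "down", "up", "up"),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  rec <- collapse_probes(probes)
  # duplicate significant probes collapse to one sign
  a <- rec[rec$gene_id == "geneA", ]
  expect_true(a$loss_down && !a$loss_up && !a$gain_up && !a$gain_down)
  # dual-direction probes give both signs in one contrast
  n <- rec[rec$gene_id == "nonA", ]
  expect_true(n$loss_up && n$loss_down)
  # genes with no significant probe are dropped
  expect_false("quiet" %in% rec$gene_id)
})

test_that("classification maps every sign combination to its category", {
  # enumerate all 15 non-empty sign combinations against the rule
  # applied by hand: loss-down/gain-up infer activation,
  # loss-up/gain-down infer repression; mixtures are AMB
  combos <- tidyr::expand_grid(loss_up = c(FALSE, TRUE),
                               loss_down = c(FALSE, TRUE),
                               gain_up = c(FALSE, TRUE),
                               gain_down = c(FALSE, TRUE)) |>
    dplyr::filter(loss_up | loss_down | gain_up | gain_down) |>
    dplyr::mutate(gene_id = sprintf("g%02d", dplyr::row_number()))
  got <- classify_responses(combos)
  want <- with(combos, {
    pos <- loss_down | gain_up
    neg <- loss_up | gain_down
    dplyr::case_when(pos & neg ~ "AMB", pos ~ "POS", TRUE ~ "NEG")
  })
  expect_equal(got$category, want)
  # spot checks pinned to the published definitions
  pick <- function(lu, ld, gu, gd) {
    got$category[combos$loss_up == lu & combos$loss_down == ld &
                   combos$gain_up == gu & combos$gain_down == gd]
  }
  expect_equal(pick(FALSE, TRUE, FALSE, FALSE), "POS")  # loss-down only
  expect_equal(pick(TRUE, FALSE, TRUE, FALSE), "AMB")   # up in both assays
  expect_equal(pick(TRUE, TRUE, FALSE, FALSE), "AMB")   # dual-direction
  expect_equal(pick(TRUE, FALSE, FALSE, TRUE), "NEG")
})

test_that("classification is symmetric under the direction-preserving contrast swap", {
  withr::with_seed(41, {
    records <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:100),
      loss_up = sample(c(TRUE, FALSE), 100, replace = TRUE),
      loss_down = sample(c(TRUE, FALSE), 100, replace = TRUE),
      gain_up = sample(c(TRUE, FALSE), 100, replace = TRUE),
      gain_down = sample(c(TRUE, FALSE), 100, replace = TRUE)
    ) |>
      dplyr::filter(loss_up | loss_down | gain_up | gain_down)
  })
  # loss-down behaves as gain-up and loss-up as gain-down
  swapped <- tibble::tibble(gene_id = records$gene_id,
                            loss_up = records$gain_down,
                            loss_down = records$gain_up,
                            gain_up = records$loss_down,
                            gain_down = records$loss_up)
  expect_equal(classify_responses(records)$category,
               classify_responses(swapped)$category)
})

test_that("empty sign sets are rejected", {
  bad <- tibble::tibble(gene_id = "g", loss_up = FALSE, loss_down = FALSE,
                        gain_up = FALSE, gain_down = FALSE)
  expect_error(classify_responses(bad), "empty sign sets")
})

test_that("peak intersection keeps GENE_CLOSE links and drops peakless genes", {
  calls <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    loss_up = FALSE, loss_down = TRUE, gain_up = FALSE, gain_down = FALSE
  ) |> classify_responses()
  asg <- tibble::tibble(peak_id = c("p1", "p2"),
                        gene_id = c("gA", "gB"),
                        status = c("GENE_OVERLAP", "GENE_CLOSE"))
  flagged <- intersect_with_peaks(calls, asg)
  expect_equal(flagged$has_peak, c(TRUE, TRUE, FALSE))
  summ <- summarize_calls(flagged)
  expect_equal(summ$total, 2L)
})

test_that("summary arithmetic reproduces the published percentages", {
  # construct calls with the printed cell counts:
  # POS 224 loss-only / 211 gain-only / 33 both;
  # NEG 141 / 139 / 10; AMB 1 dual-direction loss-only / 51 both
  mk <- function(n, prefix, lu, ld, gu, gd) {
    if (n == 0) return(NULL)
    tibble::tibble(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
                   loss_up = lu, loss_down = ld,
                   gain_up = gu, gain_down = gd)
  }
  calls <- dplyr::bind_rows(
    mk(224, "pl", FALSE, TRUE, FALSE, FALSE),
    mk(211, "pg", FALSE, FALSE, TRUE, FALSE),
    mk(33, "pb", FALSE, TRUE, TRUE, FALSE),
    mk(141, "nl", TRUE, FALSE, FALSE, FALSE),
    mk(139, "ng", FALSE, FALSE, FALSE, TRUE),
    mk(10, "nb", TRUE, FALSE, FALSE, TRUE),
    mk(1, "ad", TRUE, TRUE, FALSE, FALSE),
    mk(51, "ab", FALSE, TRUE, FALSE, TRUE)
  ) |> classify_responses()
  summ <- summarize_calls(calls)
  expect_equal(summ$total, 810L)
  expect_equal(c(summ$n_pos, summ$n_neg, summ$n_amb), c(468L, 290L, 52L))
  expect_equal(c(summ$pct_pos, summ$pct_neg, summ$pct_amb),
               c(57.8, 35.8, 6.4))
  expect_equal(c(summ$n_loss, summ$n_gain, summ$n_both), c(460L, 444L, 94L))
  expect_equal(summ$pct_both, 11.6)
  expect_equal(summ$n_both_pos, 33L)
  expect_equal(summ$pct_both_pos, 7.1)
  expect_equal(summ$n_both_neg, 10L)
  expect_equal(summ$pct_both_neg, 3.4)
})

test_that("POS/NEG/AMB partition and inclusion-exclusion hold on random tables", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      records <- tibble::tibble(
        gene_id = sprintf("g%03d", 1:200),
        loss_up = sample(c(TRUE, FALSE), 200, replace = TRUE),
        loss_down = sample(c(TRUE, FALSE), 200, replace = TRUE),
        gain_up = sample(c(TRUE, FALSE), 200, replace = TRUE),
        gain_down = sample(c(TRUE, FALSE), 200, replace = TRUE)
      ) |>
        dplyr::filter(loss_up | loss_down | gain_up | gain_down)
      summ <- summarize_calls(classify_responses(records))
      expect_equal(summ$n_pos + summ$n_neg + summ$n_amb, summ$total)
      expect_equal(summ$n_loss + summ$n_gain - summ$n_both, summ$total)
      expect_equal(summ$n_loss_pos + summ$n_gain_pos - summ$n_both_pos,
                   summ$n_pos)
      expect_equal(summ$n_loss_neg + summ$n_gain_neg - summ$n_both_neg,
                   summ$n_neg)
    }
  })
})

test_that("tidy and glance expose the summary as tibbles", {
  calls <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    loss_up = c(FALSE, TRUE, FALSE), loss_down = c(TRUE, FALSE, TRUE),
    gain_up = c(FALSE, FALSE, FALSE), gain_down = c(FALSE, FALSE, TRUE)
  ) |> classify_responses()
  summ <- summarize_calls(calls)
  td <- generics::tidy(summ)
  expect_true(all(c("metric", "count", "percent") %in% names(td)))
  expect_equal(td$count[td$metric == "total"], 3)
  gl <- generics::glance(summ)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$total, 3)
})

test_that("hypergeometric enrichment equals exhaustive enumeration for N <= 12", {
  withr::with_seed(43, {
    for (rep in 1:30) {
      N <- sample(4:12, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      background <- sprintf("g%02d", seq_len(N))
      term_genes <- background[seq_len(K)]
      foreground <- sample(background, n)
      res <- hypergeom_enrichment(
        foreground, background,
        tibble::tibble(term = "t1", gene_id = term_genes)
      )
      k <- sum(foreground %in% term_genes)
      expect_equal(res$k, k)
      expect_equal(res$p_value, oracle_hypergeom_upper(k, K, n, N),
                   tolerance = 1e-12)
    }
  })
})

test_that("hypergeometric edge cases: full-universe term and k = 0 give p = 1", {
  bg <- sprintf("g%d", 1:10)
  fg <- bg[1:4]
  all_term <- hypergeom_enrichment(fg, bg, tibble::tibble(term = "all",
                                                          gene_id = bg))
  expect_equal(all_term$p_value, 1)
  # C(5,4)/C(10,4) worked example
  half <- hypergeom_enrichment(bg[1:4], bg,
                               tibble::tibble(term = "t", gene_id = bg[1:5]))
  expect_equal(half$p_value, 5 / 210)
  none <- hypergeom_enrichment(fg, bg, tibble::tibble(term = "t",
                                                      gene_id = bg[5:10]))
  expect_equal(none$k, 0L)
  expect_equal(none$p_value, 1)
  expect_error(hypergeom_enrichment(c("zz", bg[1]), bg,
                                    tibble::tibble(term = "t", gene_id = bg)),
               "subset")
})

test_that("cluster enrichment score is -log10 of the geometric mean", {
  expect_equal(cluster_enrichment_score(rep(0.05, 4)), -log10(0.05))
  expect_gt(cluster_enrichment_score(rep(0.05, 4)), 1.3)
  expect_equal(cluster_enrichment_score(c(1, 1, 1)), 0)
  expect_equal(cluster_enrichment_score(c(0.1, 0.001)), 2)
  expect_error(cluster_enrichment_score(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(cluster_enrichment_score(numeric(0)), "non-empty")
})

test_that("screen candidates need novelty, a strong peak and expression", {
  asg <- tibble::tibble(peak_id = c("p1", "p2", "p3", "p4"),
                        gene_id = c("gA", "gB", "gC", "gD"))
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2", "p3", "p4"), chrom = "chr1",
    start = c(0L, 100L, 200L, 300L), end = c(50L, 150L, 250L, 350L),
    score = c(250, 200, 300, 400), fold = 5
  )
  expression <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                               expression = c(12, 50, 10))
  novel <- c("gA", "gB", "gC", "gD")
  expect_message(
    got <- select_screen_candidates(asg, peaks, expression, novel),
    "not expressed"
  )
  # gA passes; gB fails the strict score bound (exactly 200);
  # gC passes with expression exactly 10; gD has no expression record
  expect_equal(got$gene_id, c("gC", "gA"))

  known <- select_screen_candidates(asg, peaks, expression, c("gA"))
  expect_equal(known$gene_id, "gA")
})

test_that("probe and call tables round-trip through their TSV dialects", {
  probes <- tibble::tibble(
    probe_id = c("p1", "p2"), gene_id = c("gA", "gB"),
    contrast = c("loss", "gain"), direction = c("down", "up"),
    significant = c(TRUE, FALSE)
  )
  f <- tempfile(fileext = ".tsv")
  write_probe_table(probes, f)
  expect_equal(as.data.frame(read_probe_table(f)), as.data.frame(probes))

  calls <- tibble::tibble(
    gene_id = "gA", loss_up = TRUE, loss_down = TRUE,
    gain_up = FALSE, gain_down = FALSE
  ) |> classify_responses() |>
    intersect_with_peaks(tibble::tibble(gene_id = "gA"))
  g <- tempfile(fileext = ".tsv")
  write_regulatory_calls(calls, g)
  tab <- readr::read_tsv(g, show_col_types = FALSE)
  expect_equal(tab$LOSS_SIGNS, "up,down")
  expect_equal(tab$CATEGORY, "AMB")
  expect_equal(tab$HAS_PEAK, 1)
})
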
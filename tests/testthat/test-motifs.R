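test_that("IUPAC codes expand to their standard base sets", {
  expect_setequal(expand_iupac("Y"), c("C", "T"))
  expect_setequal(expand_iupac("M"), c("A", "C"))
  expect_setequal(expand_iupac("K"), c("G", "T"))
  expect_setequal(expand_iupac("S"), c("C", "G"))
  expect_setequal(expand_iupac("W"), c("A", "T"))
  expect_setequal(expand_iupac("N"), c("A", "C", "G", "T"))
  expect_error(expand_iupac("X"), "Invalid IUPAC")
})

test_that("the built-in motif set carries the eight reported consensi", {
  motifs <- builtin_motifs()
  expect_equal(nrow(motifs), 8)
  lookup <- setNames(motifs$consensus, motifs$name)
  expect_equal(lookup[["So"]], "AGATAC")
  expect_equal(lookup[["So-consensus"]], "YGATAY")
  expect_equal(lookup[["Optix"]], "STTWTCA")
  expect_equal(lookup[["Iro-C"]], "AACAYAA")
  expect_equal(lookup[["DRE"]], "TATCGATA")
  expect_equal(lookup[["Trl"]], "AGAGMGMG")
  expect_equal(lookup[["Hr78/Usp"]], "CGGTCACACTG")
  expect_equal(lookup[["Abd-B/Cad/Hb-class"]], "ATTTKTA")
})

test_that("scanning finds forward, reverse and degenerate matches", {
  fwd <- scan_sequence("TTAGATACTT", "AGATAC")
  expect_equal(fwd$start, 3L)
  expect_equal(fwd$strand, "+")

  rev <- scan_sequence("TTGTATCTTT", "AGATAC")
  expect_equal(rev$strand, "-")
  expect_equal(rev$start, 3L)  # GTATCT at offset 3

  deg <- scan_sequence("CGATAC", "YGATAY")
  expect_equal(deg$start, 1L)

  # overlapping occurrences are all reported
  ov <- scan_sequence("AAAAA", "AAAA")
  expect_equal(ov$start[ov$strand == "+"], c(1L, 2L))

  # N in the sequence matches nothing
  expect_equal(nrow(scan_sequence("AGNTAC", "AGATAC")), 0L)
  expect_equal(nrow(scan_sequence("AGANAC", "AGANAC")), 0L)

  # motif longer than the sequence: empty result, not an error
  expect_equal(nrow(scan_sequence("ACg", "AGATAC")), 0L)
})

test_that("palindromic motifs report one hit per offset", {
  expect_equal(revcomp_iupac("TATCGATA"), "TATCGATA")
  hits <- scan_sequence("GGTATCGATAGG", "TATCGATA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
})

test_that("reverse-complementing the sequence mirrors the hit list", {
  withr::with_seed(31, {
    seqs <- random_dna(20, 200)
  })
  rc_seq <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  for (cons in c("AGATAC", "YGATAY", "STTWTCA")) {
    k <- nchar(cons)
    for (s in seqs) {
      h <- scan_sequence(s, cons)
      hr <- scan_sequence(rc_seq(s), cons)
      mirrored <- tibble::tibble(
        start = nchar(s) - h$start - k + 2L,
        strand = as.character(ifelse(h$strand == "+", "-", "+"))
      ) |> dplyr::arrange(start, strand)
      expect_equal(as.data.frame(hr), as.data.frame(mirrored))
    }
  }
})

test_that("regex scanning agrees with the position-by-position oracle", {
  withr::with_seed(32, {
    seqs <- random_dna(30, 150)
  })
  for (cons in builtin_motifs()$consensus[c(1, 2, 3, 8)]) {
    rc <- revcomp_iupac(cons)
    for (s in seqs) {
      got <- scan_sequence(s, cons)
      expect_equal(got$start[got$strand == "+"], oracle_scan_forward(s, cons))
      if (rc != cons) {
        expect_equal(got$start[got$strand == "-"], oracle_scan_forward(s, rc))
      }
    }
  }
})

test_that("scanning agrees with Biostrings on random sequences", {
  withr::with_seed(33, {
    seqs <- random_dna(25, 300)
  })
  for (cons in c("AGATAC", "YGATAY", "ATTTKTA")) {
    for (s in seqs) {
      got <- scan_sequence(s, cons)
      bs_f <- Biostrings::matchPattern(cons, Biostrings::DNAString(s),
                                       fixed = FALSE)
      expect_equal(got$start[got$strand == "+"],
                   as.integer(BiocGenerics::start(bs_f)))
      bs_r <- Biostrings::matchPattern(revcomp_iupac(cons),
                                       Biostrings::DNAString(s),
                                       fixed = FALSE)
      expect_equal(got$start[got$strand == "-"],
                   as.integer(BiocGenerics::start(bs_r)))
    }
  }
})

test_that("hit fractions count peaks with at least one occurrence on either strand", {
  seqs <- c(p1 = "TTAGATACTT", p2 = "TTGTATCTTT",  # fwd / revcomp
            p3 = "AGATACAGATAC", p4 = "CCCCCCCCCC")
  hf <- peak_hit_fraction(seqs, tibble::tibble(name = "So",
                                               consensus = "AGATAC"))
  expect_equal(hf$n_with_hit, 3L)
  expect_equal(hf$fraction, 0.75)
  none <- peak_hit_fraction(seqs, tibble::tibble(name = "none",
                                                 consensus = "TTTTTTTTTT"))
  expect_equal(none$fraction, 0)
  expect_error(peak_hit_fraction(character(0)), "empty")
})

test_that("planted motifs are recovered: fraction >= planted rate plus background", {
  config <- synthetic_config(
    seed = 305, n_genes = 400, n_peaks = 1000,
    planted_motifs = tibble::tibble(name = "So", consensus = "AGATAC",
                                    fraction = 0.4)
  )
  ann <- simulate_annotation(config)
  pk <- simulate_peaks(ann, config)
  sq <- simulate_sequences(pk$peaks, config)
  hf <- peak_hit_fraction(sq$sequences,
                          tibble::tibble(name = "So", consensus = "AGATAC"))
  expect_gte(hf$fraction, 0.4)
  # background rate measured on the unplanted subset explains the excess
  unplanted <- sq$sequences[setdiff(names(sq$sequences),
                                    sq$ground_truth$planted$So)]
  bg_rate <- mean(vapply(unplanted, function(s) {
    length(oracle_scan_forward(s, "AGATAC")) +
      length(oracle_scan_forward(s, "GTATCT")) > 0
  }, logical(1)))
  expect_equal(hf$fraction, 0.4 + 0.6 * bg_rate, tolerance = 0.05 / 0.4)
})

test_that("shuffling preserves base composition and the seed fixes the result", {
  withr::with_seed(34, {
    seqs <- setNames(random_dna(40, 120), sprintf("s%02d", 1:40))
  })
  motifs <- tibble::tibble(name = "So", consensus = "AGATAC")
  a <- shuffle_enrichment(seqs, motifs, n_shuffles = 5, seed = 99)
  b <- shuffle_enrichment(seqs, motifs, n_shuffles = 5, seed = 99)
  expect_identical(a, b)
  c2 <- shuffle_enrichment(seqs, motifs, n_shuffles = 5, seed = 100)
  expect_false(identical(a$background_fraction, c2$background_fraction))

  comp <- function(x) table(strsplit(paste(x, collapse = ""), "")[[1]])
  sh <- sotargets:::shuffle_sequences(seqs)
  expect_equal(comp(sh), comp(seqs))
  expect_equal(nchar(sh), nchar(seqs), ignore_attr = TRUE)
})

test_that("a strongly planted motif is significant against the shuffled background", {
  config <- synthetic_config(
    seed = 306, n_genes = 300, n_peaks = 400,
    planted_motifs = tibble::tibble(name = "Hr78/Usp",
                                    consensus = "CGGTCACACTG",
                                    fraction = 0.6)
  )
  ann <- simulate_annotation(config)
  pk <- simulate_peaks(ann, config)
  sq <- simulate_sequences(pk$peaks, config)
  enr <- shuffle_enrichment(sq$sequences,
                            tibble::tibble(name = "Hr78/Usp",
                                           consensus = "CGGTCACACTG"),
                            n_shuffles = 99, seed = 7)
  expect_gt(enr$enrichment_ratio, 1)
  expect_equal(enr$empirical_p, 1 / 100)
})

test_that("FASTA write/read round-trips peak sequences", {
  withr::with_seed(35, {
    seqs <- setNames(random_dna(10, 80), sprintf("peak_%02d", 1:10))
  })
  fa <- tempfile(fileext = ".fasta")
  write_peak_sequences(seqs, fa)
  expect_equal(read_peak_sequences(fa), seqs)
})
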
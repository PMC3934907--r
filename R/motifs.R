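# IUPAC degenerate-consensus motif scanning.
#
# Scanning semantics: a motif matches at an offset when every motif
# position's IUPAC set contains the sequence base at that position.
# An N in the *sequence* matches nothing (conservative); an N in the
# motif matches any base. Both strands are scanned by matching the
# reverse complement of the motif against the forward sequence;
# overlapping occurrences are all reported, and a hit is unique per
# (offset, strand) with palindromic motifs reported once per offset.

IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code A single IUPAC character (e.g. `"Y"`).
#' @return Character vector of the bases the code stands for;
#'   `N -> c("A","C","G","T")`.
#' @examples
#' expand_iupac("Y")  # C T
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1 || nchar(code) != 1) {
    abort("`code` must be a single character.")
  }
  set <- IUPAC_SETS[toupper(code)]
  if (is.na(set)) abort(sprintf("Invalid IUPAC code '%s'.", code))
  strsplit(set, "")[[1]]
}

validate_consensus <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1 ||
      nchar(consensus) < 4) {
    abort("A motif consensus must be a single string of length >= 4.")
  }
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf("Invalid IUPAC code(s) in consensus '%s': %s",
                  consensus, paste(unique(bad), collapse = ", ")))
  }
  paste(chars, collapse = "")
}

iupac_regex <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (nchar(set) == 1) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of an IUPAC consensus
#'
#' @param consensus IUPAC consensus string.
#' @return The reverse-complemented consensus (degenerate codes map to
#'   their complements, e.g. `R <-> Y`).
#' @export
revcomp_iupac <- function(consensus) {
  consensus <- validate_consensus(consensus)
  chars <- strsplit(consensus, "")[[1]]
  paste(rev(IUPAC_COMPLEMENT[chars]), collapse = "")
}

#' Built-in degenerate motifs found enriched in So peak regions
#'
#' The So motif AGATAC with its degenerate consensus YGATAY, plus the
#' consensus motifs of the other factors recovered from the peak set:
#' Optix, the Iroquois-complex homeodomain factors, the DNA Replication
#' Element (DRE/Dref), Trithorax-like, the Hr78/Ultraspiracle nuclear
#' hormone receptors, and the AT-rich homeodomain class shared by
#' Abd-B, Cad and Hb.
#'
#' @return A tibble with columns `name`, `consensus` (8 rows).
#' @export
builtin_motifs <- function() {
  tibble(
    name = c("So", "So-consensus", "Optix", "Iro-C", "DRE", "Trl",
             "Hr78/Usp", "Abd-B/Cad/Hb-class"),
    consensus = c("AGATAC", "YGATAY", "STTWTCA", "AACAYAA", "TATCGATA",
                  "AGAGMGMG", "CGGTCACACTG", "ATTTKTA")
  )
}

#' Scan one sequence for a degenerate motif
#'
#' Reports every occurrence (overlapping included) of the motif on the
#' forward strand and, when `both_strands`, of its reverse complement,
#' labeled by strand. A motif that equals its own reverse complement
#' reports one hit per offset. Offsets are 1-based start positions on
#' the forward sequence. A motif longer than the sequence yields zero
#' hits.
#'
#' @param seq A single DNA string over `A,C,G,T,N` (case-insensitive).
#'   `N` in the sequence matches no motif position.
#' @param consensus IUPAC consensus string.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A tibble with columns `start` (1-based) and `strand`,
#'   ordered by start then strand.
#' @examples
#' scan_sequence("TTAGATACTT", "AGATAC")   # one + hit at 3
#' scan_sequence("TTGTATCTTT", "AGATAC")   # one - hit (GTATCT)
#' @export
scan_sequence <- function(seq, consensus, both_strands = TRUE) {
  if (!is.character(seq) || length(seq) != 1) {
    abort("`seq` must be a single string.")
  }
  consensus <- validate_consensus(consensus)
  seq <- toupper(seq)
  hits_at <- function(pattern) {
    if (nchar(pattern) > nchar(seq)) return(integer(0))
    m <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), seq,
                  perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- hits_at(consensus)
  out <- tibble(start = fwd, strand = rep("+", length(fwd)))
  rc <- revcomp_iupac(consensus)
  if (both_strands && rc != consensus) {
    rev_hits <- hits_at(rc)
    out <- dplyr::bind_rows(out, tibble(start = rev_hits,
                                        strand = rep("-", length(rev_hits))))
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

# Vectorized "has at least one hit" over a character vector of sequences.
has_motif_hit <- function(seqs, consensus, both_strands = TRUE) {
  consensus <- validate_consensus(consensus)
  seqs <- toupper(seqs)
  hit <- grepl(iupac_regex(consensus), seqs, perl = TRUE)
  if (both_strands) {
    rc <- revcomp_iupac(consensus)
    if (rc != consensus) hit <- hit | grepl(iupac_regex(rc), seqs, perl = TRUE)
  }
  hit
}

#' Fraction of peak sequences containing each motif
#'
#' The per-motif occurrence statistic: the fraction of peaks with at
#' least one motif occurrence on either strand of their sequence.
#'
#' @param sequences Named character vector of peak sequences (names =
#'   peak ids), or a tibble with columns `peak_id`, `seq`.
#' @param motifs Motif tibble with columns `name`, `consensus`
#'   (default [builtin_motifs()]).
#' @return A tibble: `name`, `consensus`, `n_peaks`, `n_with_hit`,
#'   `fraction`.
#' @export
peak_hit_fraction <- function(sequences, motifs = builtin_motifs()) {
  seqs <- as_sequence_vector(sequences)
  if (length(seqs) == 0) abort("`sequences` is empty.")
  assert_columns(motifs, c("name", "consensus"), "motifs")
  purrr::pmap_dfr(motifs[c("name", "consensus")], function(name, consensus) {
    hit <- has_motif_hit(seqs, consensus)
    tibble(name = name, consensus = consensus,
           n_peaks = length(seqs), n_with_hit = sum(hit),
           fraction = mean(hit))
  })
}

as_sequence_vector <- function(sequences) {
  if (is.data.frame(sequences)) {
    assert_columns(sequences, c("peak_id", "seq"), "sequences")
    return(setNames(toupper(sequences$seq), sequences$peak_id))
  }
  if (!is.character(sequences)) {
    abort("`sequences` must be a named character vector or a tibble with peak_id/seq.")
  }
  toupper(sequences)
}

# Mononucleotide shuffle: permute the letters of each sequence, which
# preserves each sequence's base composition exactly.
shuffle_sequences <- function(seqs) {
  vapply(strsplit(seqs, ""), function(ch) {
    paste(sample(ch), collapse = "")
  }, character(1))
}

#' Motif enrichment against a shuffled-sequence background
#'
#' Compares the observed fraction of peaks carrying each motif with the
#' mean fraction over `n_shuffles` rounds of per-sequence
#' mononucleotide shuffling (composition-preserving). The empirical
#' P-value uses the add-one estimator
#' `(1 + # rounds with shuffled fraction >= observed) / (n_shuffles + 1)`.
#' Fully deterministic under `seed`; the caller's RNG state is left
#' untouched.
#'
#' @inheritParams peak_hit_fraction
#' @param n_shuffles Number of shuffle rounds (>= 1).
#' @param seed Integer seed for the shuffles.
#' @return A tibble: `name`, `consensus`, `n_peaks`, `n_with_hit`,
#'   `fraction`, `background_fraction`, `enrichment_ratio`
#'   (`Inf` when the background fraction is 0 and the foreground is
#'   not), `empirical_p`.
#' @export
shuffle_enrichment <- function(sequences, motifs = builtin_motifs(),
                               n_shuffles = 99, seed = 1) {
  seqs <- as_sequence_vector(sequences)
  if (length(seqs) == 0) abort("`sequences` is empty.")
  if (!is.numeric(n_shuffles) || n_shuffles < 1) {
    abort("`n_shuffles` must be >= 1.")
  }
  n_shuffles <- as.integer(n_shuffles)
  observed <- peak_hit_fraction(seqs, motifs)
  bg <- with_local_seed(seed, {
    chars <- strsplit(seqs, "")
    vapply(seq_len(n_shuffles), function(r) {
      shuffled <- vapply(chars, function(ch) paste(sample(ch), collapse = ""),
                         character(1))
      vapply(motifs$consensus, function(cons) {
        mean(has_motif_hit(shuffled, cons))
      }, numeric(1))
    }, numeric(nrow(motifs)))
  })
  bg <- matrix(bg, nrow = nrow(motifs))  # motifs x rounds
  observed |>
    dplyr::mutate(
      background_fraction = rowMeans(bg),
      enrichment_ratio = dplyr::case_when(
        .data$background_fraction > 0 ~ .data$fraction / .data$background_fraction,
        .data$fraction > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      empirical_p = (1 + rowSums(bg >= matrix(.data$fraction, nrow = nrow(bg),
                                              ncol = ncol(bg)))) /
        (n_shuffles + 1)
    )
}

#' Read peak sequences from FASTA
#'
#' Record ids are taken as peak ids (text before the first whitespace).
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_peak_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write peak sequences to FASTA
#'
#' @param sequences Named character vector (names = peak ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_sequences <- function(sequences, path) {
  seqs <- as_sequence_vector(sequences)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L
  )
  invisible(path)
}

#' Write a motif enrichment summary table
#'
#' Tab-separated with header `MOTIF, CONSENSUS, N_PEAKS, N_WITH_HIT,
#' FRACTION, BG_FRACTION, RATIO, EMP_P` (background columns `NA` when
#' only the foreground was computed).
#'
#' @param summary Tibble from [peak_hit_fraction()] or
#'   [shuffle_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_summary <- function(summary, path) {
  assert_columns(summary, c("name", "consensus", "n_peaks", "n_with_hit",
                            "fraction"), "summary")
  tibble(
    MOTIF = summary$name,
    CONSENSUS = summary$consensus,
    N_PEAKS = summary$n_peaks,
    N_WITH_HIT = summary$n_with_hit,
    FRACTION = summary$fraction,
    BG_FRACTION = summary[["background_fraction"]] %||% rep(NA_real_, nrow(summary)),
    RATIO = summary[["enrichment_ratio"]] %||% rep(NA_real_, nrow(summary)),
    EMP_P = summary[["empirical_p"]] %||% rep(NA_real_, nrow(summary))
  ) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
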
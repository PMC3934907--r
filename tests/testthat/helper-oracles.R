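# Brute-force oracles, independent of the package implementation.
# Each one is a direct transcription of the definition it checks:
# linear scans over all pairs, no indexes, no interval libraries.

# Point/interval distance to a single TSS position: 0 if the position
# lies inside [start, end), else the position difference from the
# nearer edge.
oracle_point_interval_dist <- function(p, start, end) {
  if (p >= start && p < end) return(0L)
  as.integer(min(abs(p - start), abs(p - (end - 1))))
}

# Nearest TSS for one interval by scanning every gene on the
# chromosome. Returns all tied gene ids (sorted) and the distance.
oracle_nearest_tss <- function(genes, chrom, start, end) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  d <- vapply(tss, oracle_point_interval_dist, integer(1),
              start = start, end = end)
  best <- min(d)
  list(gene_id = sort(g$gene_id[d == best]), distance = best)
}

# Peak-gene assignment by scanning every pair: overlap if the
# half-open intervals intersect; otherwise the gap in bp. Returns the
# assignment rows for one peak (all overlaps, or all nearest ties).
oracle_assign_one <- function(peak, genes) {
  g <- genes[genes$chrom == peak$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  ov <- peak$start < g$end & g$start < peak$end
  if (any(ov)) {
    return(tibble::tibble(peak_id = peak$peak_id,
                          gene_id = sort(g$gene_id[ov]),
                          status = "GENE_OVERLAP", gene_distance = 0L))
  }
  gap <- ifelse(peak$end <= g$start, g$start - peak$end,
                peak$start - g$end)
  best <- min(gap)
  tibble::tibble(peak_id = peak$peak_id,
                 gene_id = sort(g$gene_id[gap == best]),
                 status = "GENE_CLOSE", gene_distance = as.integer(best))
}

# Character-by-character IUPAC scan of one strand.
oracle_scan_forward <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  s <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(toupper(consensus), "")[[1]]
  k <- length(m)
  hits <- integer(0)
  if (length(s) >= k) {
    for (off in seq_len(length(s) - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!s[off + j - 1] %in% sets[[m[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, off)
    }
  }
  hits
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of
# every n-subset of an N-element universe with K marked elements.
oracle_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Small deterministic fixtures ---------------------------------------

toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    name = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(200L, 500L, 800L, 100L),
    end = c(400L, 600L, 900L, 300L),
    strand = c("+", "-", "+", "-")
  )
}

random_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    name = sprintf("g%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(5000L, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    peak_id = sprintf("pk%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(2000L, n, replace = TRUE),
    score = round(runif(n, 0, 700), 3),
    fold = round(runif(n, 0.5, 50), 3)
  )
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
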
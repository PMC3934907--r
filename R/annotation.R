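#' Read a gene annotation into a tidy gene table
#'
#' Parses gene-level features from GFF3, GTF or BED6 into a tibble with
#' one row per gene. Coordinates are normalized to the package-internal
#' convention: 0-based, half-open `[start, end)`. GFF3/GTF input
#' (1-based, inclusive) is converted at this boundary; BED is already
#' 0-based half-open and is taken as-is. Only `gene` features are kept
#' from GFF3/GTF, so the gene extent is the annotated gene span
#' (UTRs and introns included), not a transcript or exon model.
#'
#' @param path Path to the annotation file.
#' @param format One of `"gff3"`, `"gtf"`, `"bed"`. Defaults to a guess
#'   from the file extension.
#' @return A tibble with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end` (0-based half-open) and `strand` (`"+"` or `"-"`).
#'   Malformed lines, unknown strand symbols and duplicated gene ids
#'   raise errors naming the file and line.
#' @examples
#' path <- tempfile(fileext = ".bed")
#' writeLines("chr2L\t100\t200\tgeneA\t0\t-", path)
#' read_gene_annotation(path)
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gff = "gff3", gff3 = "gff3", gtf = "gtf", bed = "bed",
      abort(sprintf("Cannot guess annotation format from extension '.%s'.", ext))
    )
  }
  genes <- switch(format,
    gff3 = read_gff_genes(path, dialect = "gff3"),
    gtf  = read_gff_genes(path, dialect = "gtf"),
    bed  = read_bed_genes(path)
  )
  validate_genes(genes, what = path)
  genes
}

parse_fail <- function(path, line_no, msg) {
  abort(sprintf("%s, line %d: %s", path, line_no, msg))
}

read_gff_genes <- function(path, dialect) {
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(sprintf("%s: no feature lines found.", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < 9) {
      parse_fail(path, line_no[i],
                 sprintf("expected 9 tab-separated fields, found %d", length(f)))
    }
    if (tolower(f[3]) != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      parse_fail(path, line_no[i], "non-numeric start/end field")
    }
    if (start < 1 || end < start) {
      parse_fail(path, line_no[i],
                 sprintf("invalid 1-based coordinates %d..%d", start, end))
    }
    if (!f[7] %in% c("+", "-")) {
      parse_fail(path, line_no[i],
                 sprintf("unknown strand symbol '%s'", f[7]))
    }
    attrs <- f[9]
    if (dialect == "gff3") {
      gene_id <- gff3_attr(attrs, c("ID", "gene_id"))
      name <- gff3_attr(attrs, c("Name", "gene_name"))
    } else {
      gene_id <- gtf_attr(attrs, "gene_id")
      name <- gtf_attr(attrs, "gene_name")
    }
    if (is.na(gene_id)) {
      parse_fail(path, line_no[i], "attribute field lacks a gene identifier")
    }
    rows[[i]] <- tibble(
      gene_id = gene_id,
      name = if (is.na(name)) gene_id else name,
      chrom = f[1],
      start = start - 1L,   # 1-based inclusive -> 0-based half-open
      end = end,
      strand = f[7]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort(sprintf("%s: no 'gene' features found.", path))
  }
  out
}

gff3_attr <- function(attrs, keys) {
  for (key in keys) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]+)"))[, 2]
    if (!is.na(m)) return(trimws(m))
  }
  NA_character_
}

gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, "\\s+\"([^\"]+)\""))[, 2]
  if (is.na(m)) NA_character_ else m
}

read_bed_genes <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(sprintf("%s: no BED records found.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < 6) {
      parse_fail(path, line_no[i],
                 sprintf("expected >= 6 BED fields, found %d", length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      parse_fail(path, line_no[i], "non-numeric start/end field")
    }
    if (start < 0 || end <= start) {
      parse_fail(path, line_no[i],
                 sprintf("invalid BED interval %d..%d", start, end))
    }
    if (!f[6] %in% c("+", "-")) {
      parse_fail(path, line_no[i], sprintf("unknown strand symbol '%s'", f[6]))
    }
    rows[[i]] <- tibble(
      gene_id = f[4], name = f[4], chrom = f[1],
      start = start, end = end, strand = f[6]
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a gene table to BED6 or GFF3
#'
#' Inverse of [read_gene_annotation()]: internal 0-based half-open
#' coordinates are converted back to the target dialect (GFF3 1-based
#' inclusive; BED unchanged), so write/read round-trips are exact.
#'
#' @param genes Gene tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @param chrom_sizes Optional named vector of chromosome lengths;
#'   written as `##sequence-region` pragmas in GFF3 output.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path, format = c("bed", "gff3"),
                                  chrom_sizes = NULL) {
  format <- match.arg(format)
  validate_genes(genes)
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     genes$chrom, genes$start, genes$end,
                     genes$gene_id, genes$strand)
  } else {
    header <- "##gff-version 3"
    if (!is.null(chrom_sizes)) {
      header <- c(header, sprintf("##sequence-region %s 1 %d",
                                  names(chrom_sizes), as.integer(chrom_sizes)))
    }
    lines <- c(header, sprintf(
      "%s\tsotargets\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genes$chrom, genes$start + 1L, genes$end, genes$strand,
      genes$gene_id, genes$name
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Transcription start site of each gene
#'
#' The TSS is the 5'-most transcribed base: `start` for `+`-strand
#' genes and `end - 1` (the last covered base, 0-based) for `-`-strand
#' genes.
#'
#' @param genes Gene tibble.
#' @return Integer vector of 0-based TSS positions, one per gene.
#' @examples
#' tss_of(tibble::tibble(gene_id = "g", chrom = "X", start = 100,
#'                       end = 200, strand = "-"))  # 199
#' @export
tss_of <- function(genes) {
  validate_genes(genes)
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}

#' Build a sorted per-chromosome TSS index
#'
#' One entry per gene at its [tss_of()] position, sorted by
#' `(chrom, pos, gene_id)`; the sort order is what makes nearest-TSS
#' queries deterministic under ties.
#'
#' @param genes Gene tibble (non-empty).
#' @return A tibble with columns `chrom`, `pos`, `gene_id`, sorted.
#' @export
build_tss_index <- function(genes) {
  validate_genes(genes)
  if (nrow(genes) == 0) abort("Cannot build a TSS index from an empty annotation.")
  tibble(chrom = genes$chrom, pos = tss_of(genes), gene_id = genes$gene_id) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$gene_id)
}

# Nearest-TSS query for one half-open interval [s, e) on one chromosome
# of a sorted index. Distance is 0 when a TSS lies inside the interval,
# otherwise the position difference from the nearer interval edge
# (|p - start| below, |p - (end-1)| above). Returns all tied gene ids,
# sorted. `pos`/`gid` are the chromosome's sorted index columns.
.tss_query_one <- function(pos, gid, s, e) {
  n <- length(pos)
  lo <- findInterval(s - 1, pos)   # entries at position <= s-1 (strictly below s)
  hi <- findInterval(e - 1, pos)   # entries at position <= e-1 (inside or below)
  if (hi > lo) {
    inside <- (lo + 1):hi
    return(list(gene_id = sort(gid[inside]), distance = 0L))
  }
  cand_pos <- integer(0)
  d_left <- if (lo >= 1) s - pos[lo] else Inf
  d_right <- if (hi + 1 <= n) pos[hi + 1] - (e - 1) else Inf
  d <- min(d_left, d_right)
  ids <- character(0)
  if (is.finite(d_left) && d_left == d) {
    ids <- c(ids, gid[pos == pos[lo]])
  }
  if (is.finite(d_right) && d_right == d) {
    ids <- c(ids, gid[pos == pos[hi + 1]])
  }
  list(gene_id = sort(unique(ids)), distance = as.integer(d))
}

#' Nearest TSS to genomic positions
#'
#' For each query position, returns the gene(s) whose TSS is closest on
#' the same chromosome, with the unsigned distance. Equidistant TSSs on
#' both sides are all returned, ordered by `gene_id`.
#'
#' @param tss_index Index from [build_tss_index()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return A tibble with columns `query` (input row number), `chrom`,
#'   `pos`, `gene_id`, `distance`; more than one row per query on ties.
#'   Queries on chromosomes with no indexed TSS return zero rows.
#' @export
nearest_tss <- function(tss_index, chrom, pos) {
  assert_columns(tss_index, c("chrom", "pos", "gene_id"), "tss_index")
  if (nrow(tss_index) == 0) abort("Empty TSS index.")
  stopifnot(length(chrom) == length(pos))
  by_chrom <- split(tss_index, tss_index$chrom)
  out <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    idx <- by_chrom[[chrom[i]]]
    if (is.null(idx)) next
    hit <- .tss_query_one(idx$pos, idx$gene_id, pos[i], pos[i] + 1L)
    out[[i]] <- tibble(query = i, chrom = chrom[i], pos = pos[i],
                       gene_id = hit$gene_id, distance = hit$distance)
  }
  dplyr::bind_rows(out)
}
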
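#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' The single conversion site for externally supplied 1-based inclusive
#' intervals (GFF3, published locus coordinates such as the rDNA repeat
#' chrXII:451275-469084) into the package's internal 0-based half-open
#' convention.
#'
#' @param start,end 1-based inclusive interval bounds.
#' @return A list with `start` (0-based) and `end` (exclusive).
#' @export
one_based_to_zero <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = as.integer(start - 1L), end = as.integer(end))
}

#' Write fragments as 6-column BED
#'
#' Columns: chrom, start, end, name (`condition.replicate`), score (0),
#' strand (`.`).
#'
#' @param fragments A fragment tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- tibble::tibble(
    chrom = fragments$chrom, start = fragments$start, end = fragments$end,
    name = paste(fragments$condition, fragments$replicate, sep = "."),
    score = 0L, strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read fragments from a 6-column BED file
#'
#' @param path BED file written by [write_fragments_bed()] (or any BED
#'   whose name field is `condition.replicate`).
#' @return A fragment tibble: `chrom`, `start`, `end`, `condition`,
#'   `replicate`.
#' @export
read_fragments_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand"),
                         col_types = "ciicic", progress = FALSE)
  parts <- strsplit(bed$name, ".", fixed = TRUE)
  tibble::tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    condition = vapply(parts, function(p) paste(p[-length(p)], collapse = "."), ""),
    replicate = as.integer(vapply(parts, function(p) p[length(p)], ""))
  )
}

#' Read exclusion regions from a BED file
#'
#' @param path 3+ column BED file (0-based half-open).
#' @return A tibble: `chrom`, `start`, `end`.
#' @export
read_exclusions_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  tibble::tibble(chrom = as.character(bed[[1]]),
                 start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
}

#' Read gene annotation from GFF3
#'
#' Imports `gene`-type records via rtracklayer and converts them to the
#' internal 0-based convention: the TSS is the transcription-start
#' coordinate on the gene's strand, the TES the end coordinate.
#'
#' @param path GFF3 file (1-based inclusive).
#' @param chromosome_lengths Optional named vector of chromosome lengths;
#'   if omitted, taken from the GFF sequence info or the maximum gene end.
#' @return A `genome_annotation`.
#' @export
read_genes_gff3 <- function(path, chromosome_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  start0 <- one_based_to_zero(BiocGenerics::start(gr), BiocGenerics::end(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%05d", seq_along(gr))
  genes <- tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", start0$start, start0$end - 1L),
    tes = ifelse(strand == "+", start0$end - 1L, start0$start)
  )
  if (is.null(chromosome_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (anyNA(sl)) {
      pragmas <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (length(pragmas)) {
        parts <- strsplit(trimws(pragmas), "\\s+")
        sl <- stats::setNames(
          vapply(parts, function(p) as.integer(p[4]), 0L),
          vapply(parts, function(p) p[2], "")
        )
      }
    }
    chromosome_lengths <- if (length(sl) && all(!is.na(sl))) sl else
      tapply(pmax(genes$tss, genes$tes) + 1L, genes$chrom, max)
  }
  chroms <- tibble::tibble(chrom = names(chromosome_lengths),
                           length = as.integer(chromosome_lengths))
  new_genome_annotation(chroms, genes)
}

#' Write gene annotation as GFF3
#'
#' @param genome A `genome_annotation`.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  start1 <- pmin(g$tss, g$tes) + 1L
  end1 <- pmax(g$tss, g$tes) + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = g$strand, type = "gene", ID = g$gene_id
  )
  GenomeInfoDb::seqlengths(gr) <-
    chrom_lengths(genome)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer omits sequence-region pragmas; add them so chromosome
  # lengths survive a round trip
  lines <- readLines(path)
  pragmas <- sprintf("##sequence-region %s 1 %d", genome$chromosomes$chrom,
                     genome$chromosomes$length)
  writeLines(c(lines[1], pragmas, lines[-1]), path)
  invisible(path)
}

#' Write a dyad track as bedGraph
#'
#' Emits 0-based half-open runs of equal density (excluded positions are
#' omitted, matching their removal from coverage statistics).
#'
#' @param track A `dyad_track` or `smoothed_track`.
#' @param path Output bedGraph file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  rows <- purrr::imap_dfr(track$values, function(v, cc) {
    r <- rle(ifelse(is.na(v), NA_real_, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values)
    tibble::tibble(chrom = cc, start = starts[keep], end = ends[keep],
                   value = r$values[keep])
  })
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}
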
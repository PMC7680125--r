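#' Assign nucleosome calls to genes as +1, +2, ...
#'
#' For each gene, calls whose dyad lies between `TSS - upstream_slack`
#' and the TES (measured along the direction of transcription) are
#' collected and ordered by distance from the TSS; the first becomes the
#' +1 nucleosome, the next +2, and so on.  The small upstream slack
#' tolerates +1 nucleosomes called a few bp promoter-proximal of the
#' annotated TSS.
#'
#' @param calls A [call_nucleosomes()] tibble.
#' @param genome A [make_genome()]-style annotation.
#' @param upstream_slack Allowed bp upstream of the TSS (default 30).
#' @return A tibble: one row per assigned call with `gene_id`, `strand`,
#'   `position_index` (1, 2, ...), `tss_distance` and the call columns.
#'   Genes without any assigned call simply have no rows; their count is
#'   attached as attribute `n_genes_without_calls`.
#' @export
assign_to_genes <- function(calls, genome, upstream_slack = 30) {
  genes <- genome$genes
  joined <- dplyr::inner_join(
    dplyr::select(genes, "gene_id", "chrom", "strand", "tss", "tes"),
    calls, by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      dir = ifelse(.data$strand == "+", 1L, -1L),
      tss_distance = (.data$dyad - .data$tss) * .data$dir,
      gene_span = (.data$tes - .data$tss) * .data$dir
    ) |>
    dplyr::filter(.data$tss_distance >= -upstream_slack,
                  .data$tss_distance <= .data$gene_span) |>
    dplyr::arrange(.data$gene_id, .data$tss_distance) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(position_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-"dir", -"gene_span")
  attr(joined, "n_genes_without_calls") <-
    nrow(genes) - dplyr::n_distinct(joined$gene_id)
  joined
}

#' Filter genes for metagene analysis
#'
#' Keeps genes longer than `min_length` bp (strict), with at least
#' `min_nucleosomes` assigned nucleosomes, and with defined TSS/TES.
#' The defaults (> 560 bp, >= 4 nucleosomes) remove short genes whose
#' sparse arrays add background noise to +1-aligned averages.
#'
#' @param index An [assign_to_genes()] tibble.
#' @param genome The matching genome annotation.
#' @param min_length Minimum gene length in bp, exclusive.
#' @param min_nucleosomes Minimum assigned nucleosome count, inclusive.
#' @return Character vector of qualifying gene ids.
#' @export
filter_genes <- function(index, genome, min_length = 560, min_nucleosomes = 4) {
  genes <- genome$genes |>
    dplyr::filter(!is.na(.data$tss), !is.na(.data$tes),
                  abs(.data$tes - .data$tss) > min_length)
  counts <- index |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n >= min_nucleosomes)
  intersect(genes$gene_id, counts$gene_id)
}

#' Select genes with a significantly shifted nucleosome
#'
#' Returns the genes having at least one significant positional shift
#' (`p < alpha`) at a nucleosome in the given position-index set
#' (default +1..+4, the promoter-proximal coding-region array).
#'
#' @param shift_results A [run_shift_analysis()] tibble.
#' @param positions Position indices considered (default `1:4`).
#' @param alpha Significance level; `significant` is re-derived from
#'   `p_value < alpha` so the cutoff can be changed here.
#' @return Character vector of gene ids.
#' @export
select_shifted_genes <- function(shift_results, positions = 1:4, alpha = 0.01) {
  hits <- shift_results |>
    dplyr::filter(!.data$untestable, !is.na(.data$p_value),
                  .data$p_value < alpha,
                  !is.na(.data$position_index),
                  .data$position_index %in% positions,
                  !is.na(.data$gene_id))
  unique(hits$gene_id)
}

#' +1-aligned metagene dyad-density profile
#'
#' Averages two conditions' normalized dyad densities across a gene set
#' after aligning every gene on its condition-A +1 nucleosome dyad, with
#' offsets measured along the direction of transcription.  Using the same
#' (condition A) anchor for both conditions makes condition-B
#' repositioning visible as peak displacement on a shared axis.
#' Offsets that run off a chromosome are skipped per gene, with per-offset
#' gene counts kept.
#'
#' @param track_a,track_b Normalized `dyad_track`s for the two
#'   conditions.
#' @param index An [assign_to_genes()] tibble built from the condition-A
#'   calls (supplies the +1 anchors and strands).
#' @param genes Character vector of gene ids to average over.
#' @param offsets Integer offsets in bp relative to the +1 dyad.
#' @return A `metagene_profile` object: tibble `profile` with `offset`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, plus `n_genes`.
#' @export
metagene_profile <- function(track_a, track_b, index, genes,
                             offsets = -200:800) {
  anchors <- index |>
    dplyr::filter(.data$position_index == 1L, .data$gene_id %in% genes)
  if (!nrow(anchors)) stop("empty gene set: no +1 anchors to align on", call. = FALSE)
  sum_a <- sum_b <- numeric(length(offsets))
  n_a <- n_b <- integer(length(offsets))
  for (i in seq_len(nrow(anchors))) {
    dir <- if (anchors$strand[i] == "+") 1L else -1L
    pos <- anchors$dyad[i] + dir * offsets
    va <- track_values(track_a, anchors$chrom[i], pos)
    vb <- track_values(track_b, anchors$chrom[i], pos)
    ok_a <- !is.na(va); ok_b <- !is.na(vb)
    sum_a[ok_a] <- sum_a[ok_a] + va[ok_a]
    sum_b[ok_b] <- sum_b[ok_b] + vb[ok_b]
    n_a <- n_a + ok_a
    n_b <- n_b + ok_b
  }
  profile <- tibble::tibble(
    offset = offsets,
    mean_a = ifelse(n_a > 0, sum_a / n_a, NA_real_),
    mean_b = ifelse(n_b > 0, sum_b / n_b, NA_real_),
    n_a = n_a, n_b = n_b
  )
  structure(list(profile = profile, n_genes = nrow(anchors)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("<metagene_profile> ", x$n_genes, " genes, offsets ",
      min(x$profile$offset), "..", max(x$profile$offset), " bp\n", sep = "")
  invisible(x)
}

#' Median TSS-signed shift per nucleosome position
#'
#' Summarizes a shift analysis as the median signed shift at each
#' nucleosome position index over a gene set (the median is robust to the
#' occasional spurious match).  Positions with no contributing pairs are
#' absent from the output rather than reported as zero.
#'
#' @param shift_results A [run_shift_analysis()] tibble.
#' @param genes Optional character vector restricting to a gene set
#'   (`NULL` = all genes with assignments).
#' @param positions Optional position indices to keep (`NULL` = all).
#' @return A tibble: `position_index`, `median_shift` (bp), `mean_shift`,
#'   `n`.
#' @export
median_shift_by_position <- function(shift_results, genes = NULL,
                                     positions = NULL) {
  d <- shift_results |>
    dplyr::filter(!is.na(.data$position_index), !is.na(.data$shift))
  if (!is.null(genes)) d <- dplyr::filter(d, .data$gene_id %in% genes)
  if (!is.null(positions)) {
    d <- dplyr::filter(d, .data$position_index %in% positions)
  }
  d |>
    dplyr::group_by(position_index = .data$position_index) |>
    dplyr::summarise(
      median_shift = stats::median(.data$shift),
      mean_shift = mean(.data$shift),
      n = dplyr::n(),
      .groups = "drop"
    )
}
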
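#' Match nucleosome calls between two conditions by footprint overlap
#'
#' Candidate pairs are calls on the same chromosome whose 147-bp
#' footprints overlap by at least 73 bp, which is equivalent to a dyad
#' distance of at most 74 bp (`overlap = 147 - |delta|`).  Among the
#' candidates a one-to-one matching is chosen greedily by smallest
#' `|delta|`, ties broken by the smaller (then larger) dyad coordinate,
#' making the matching deterministic and symmetric in its pair set.
#'
#' @param calls_a,calls_b Call tibbles from [call_nucleosomes()]
#'   (conditions A and B, e.g. wild type and mutant).
#' @param min_overlap Minimum footprint overlap in bp.
#' @return A tibble of pairs with per-condition call statistics, `delta`
#'   (`dyad_b - dyad_a`, genome coordinates) and `overlap`.  Unmatched
#'   calls are attached as attributes `unmatched_a` / `unmatched_b`.
#' @export
match_calls <- function(calls_a, calls_b, min_overlap = 73) {
  max_delta <- 147L - as.integer(min_overlap)
  a <- dplyr::mutate(calls_a, .id_a = dplyr::row_number())
  b <- dplyr::mutate(calls_b, .id_b = dplyr::row_number())
  cand <- dplyr::inner_join(
    dplyr::select(a, ".id_a", chrom = "chrom", dyad_a = "dyad",
                  dyad_mean_a = "dyad_mean", dyad_sd_a = "dyad_sd",
                  occupancy_a = "occupancy", untestable_a = "untestable"),
    dplyr::select(b, ".id_b", chrom = "chrom", dyad_b = "dyad",
                  dyad_mean_b = "dyad_mean", dyad_sd_b = "dyad_sd",
                  occupancy_b = "occupancy", untestable_b = "untestable"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(delta = .data$dyad_b - .data$dyad_a,
                  overlap = 147L - abs(.data$delta)) |>
    dplyr::filter(.data$overlap >= min_overlap) |>
    dplyr::arrange(abs(.data$delta), pmin(.data$dyad_a, .data$dyad_b),
                   pmax(.data$dyad_a, .data$dyad_b))
  used_a <- rep(FALSE, nrow(a))
  used_b <- rep(FALSE, nrow(b))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$.id_a[i]; ib <- cand$.id_b[i]
    if (!used_a[ia] && !used_b[ib]) {
      take[i] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  pairs <- cand[take, , drop = FALSE] |>
    dplyr::select(-".id_a", -".id_b") |>
    dplyr::arrange(.data$chrom, .data$dyad_a)
  attr(pairs, "unmatched_a") <- dplyr::select(a[!used_a, , drop = FALSE], -".id_a")
  attr(pairs, "unmatched_b") <- dplyr::select(b[!used_b, , drop = FALSE], -".id_b")
  pairs
}

#' Welch's t-test for a dyad shift on matched nucleosome pairs
#'
#' Treats each raw dyad inside a call's footprint as one observation of
#' the nucleosome's position, so the per-call dyad mean, dyad standard
#' deviation and occupancy play the roles of sample mean, SD and n in a
#' two-sample Welch test:
#' `t = (m_A - m_B) / sqrt(s_A^2/n_A + s_B^2/n_B)`,
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' This equals a literal two-sample Welch test on the two dyad multisets.
#' Pairs with occupancy < 2 on either side or zero spread on both sides
#' are flagged untestable (`t`, `df`, `p_value` set to `NA`) rather than
#' tested.
#'
#' @param pairs A [match_calls()] tibble (columns `dyad_mean_*`,
#'   `dyad_sd_*`, `occupancy_*`).
#' @return The pairs tibble with `t`, `df`, `p_value` and `untestable`
#'   columns added.
#' @export
welch_test <- function(pairs) {
  m_a <- pairs$dyad_mean_a; m_b <- pairs$dyad_mean_b
  s_a <- pairs$dyad_sd_a;   s_b <- pairs$dyad_sd_b
  n_a <- pairs$occupancy_a; n_b <- pairs$occupancy_b
  untestable <- n_a < 2L | n_b < 2L | (s_a == 0 & s_b == 0)
  va <- ifelse(untestable, NA_real_, s_a^2 / n_a)
  vb <- ifelse(untestable, NA_real_, s_b^2 / n_b)
  t <- (m_a - m_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1L) + vb^2 / (n_b - 1L))
  p <- ifelse(untestable, NA_real_, 2 * stats::pt(-abs(t), df))
  dplyr::mutate(pairs, t = t, df = df, p_value = p, untestable = untestable)
}

#' TSS-signed nucleosome shift
#'
#' Converts a genomic dyad displacement into a transcription-oriented
#' shift: positive values mean the nucleosome moved downstream, away from
#' the TSS, on its gene's strand.
#'
#' @param delta Genomic displacement(s), `dyad_b - dyad_a` in bp.
#' @param strand Gene strand, `"+"` or `"-"` (recycled).
#' @return Signed shift(s) in bp; `NA` strand gives `NA`.
#' @export
signed_shift <- function(delta, strand) {
  dplyr::case_when(
    strand == "+" ~ as.numeric(delta),
    strand == "-" ~ -as.numeric(delta),
    TRUE ~ NA_real_
  )
}

#' Full condition-versus-condition nucleosome shift analysis
#'
#' Composes matching, Welch testing, gene assignment and shift signing:
#' calls are matched by footprint overlap, each matched pair is tested
#' for a positional shift, pairs are assigned to genes and position
#' indices (+1, +2, ...) through the condition-A calls, and shifts are
#' reported TSS-signed.  Significance is a raw `p < alpha` cutoff (no
#' multiple-testing correction, which is also how the source analysis
#' thresholds shifts); a Benjamini-Hochberg `fdr` column is provided for
#' users but does not feed the `significant` flag.
#'
#' @param calls_a,calls_b Call tibbles (A = reference / wild type).
#' @param genome A [make_genome()]-style annotation with the gene table.
#' @param alpha Two-sided significance level (default 0.01).
#' @param min_overlap Matching threshold in bp.
#' @param upstream_slack Promoter slack for +1 assignment, see
#'   [assign_to_genes()].
#' @return A tibble of shift results: pair columns plus `t`, `df`,
#'   `p_value`, `fdr`, `gene_id`, `strand`, `position_index`,
#'   `shift` (TSS-signed bp), `significant`, `untestable`.  Summary
#'   counts (`n_pairs`, `n_tested`, `n_significant`, `n_untestable`) are
#'   attached as attribute `summary`.
#' @export
run_shift_analysis <- function(calls_a, calls_b, genome, alpha = 0.01,
                               min_overlap = 73, upstream_slack = 30) {
  pairs <- match_calls(calls_a, calls_b, min_overlap = min_overlap)
  res <- welch_test(pairs)
  index <- assign_to_genes(calls_a, genome, upstream_slack = upstream_slack)
  res <- dplyr::left_join(
    res,
    dplyr::select(index, "chrom", dyad_a = "dyad", "gene_id", "strand",
                  "position_index"),
    by = c("chrom", "dyad_a")
  )
  # a call sitting in two genes' windows keeps its closest-gene assignment
  res <- res |>
    dplyr::arrange(.data$chrom, .data$dyad_a, .data$position_index) |>
    dplyr::distinct(.data$chrom, .data$dyad_a, .data$dyad_b, .keep_all = TRUE)
  res <- res |>
    dplyr::mutate(
      shift = signed_shift(.data$delta, .data$strand),
      fdr = stats::p.adjust(.data$p_value, method = "BH"),
      significant = !.data$untestable & !is.na(.data$p_value) &
        .data$p_value < alpha
    )
  attr(res, "summary") <- tibble::tibble(
    n_pairs = nrow(res),
    n_tested = sum(!res$untestable),
    n_significant = sum(res$significant),
    n_untestable = sum(res$untestable)
  )
  res
}
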
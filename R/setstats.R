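#' Hypergeometric probability of a gene-set overlap
#'
#' Probability of observing exactly `x` genes in common between a group
#' of `n` genes and a group of `D` genes drawn from a universe of `N`
#' genes:
#' `C(D, x) * C(N - D, n - x) / C(N, n)`,
#' computed in log-binomial space so it stays exact to double precision
#' for universes in the thousands.
#'
#' @param x Overlap count(s).
#' @param n Size of group 1.
#' @param D Size of group 2.
#' @param N Universe size (total genes).
#' @return Probability (vectorized over `x`).
#' @export
#' @examples
#' hypergeom_pmf(2, n = 3, D = 4, N = 10)  # 0.3
hypergeom_pmf <- function(x, n, D, N) {
  check_overlap_query(x, n, D, N)
  exp(lchoose(D, x) + lchoose(N - D, n - x) - lchoose(N, n))
}

#' Tail probability of a gene-set overlap
#'
#' Enrichment direction (default): probability of an overlap at least as
#' large as observed, `sum_{k >= x} pmf(k)`.  The depletion tail
#' (`sum_{k <= x}`) is available by flag.
#'
#' @inheritParams hypergeom_pmf
#' @param tail `"enrichment"` (upper tail, default) or `"depletion"`.
#' @return Probability.
#' @export
#' @examples
#' overlap_pvalue(2, n = 3, D = 4, N = 10)  # 1/3
overlap_pvalue <- function(x, n, D, N, tail = c("enrichment", "depletion")) {
  tail <- match.arg(tail)
  check_overlap_query(x, n, D, N)
  support <- max(0, n + D - N):min(n, D)
  vapply(x, function(xi) {
    k <- if (tail == "enrichment") support[support >= xi] else support[support <= xi]
    if (!length(k)) return(0)
    lp <- lchoose(D, k) + lchoose(N - D, n - k) - lchoose(N, n)
    m <- max(lp)
    exp(m + log(sum(exp(lp - m))))
  }, 0)
}

check_overlap_query <- function(x, n, D, N) {
  if (any(c(x, n, D, N) < 0) || n > N || D > N || any(x > pmin(n, D))) {
    stop("invalid overlap query: need 0 <= x <= min(n, D) and n, D <= N",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Venn partition counts of two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids; duplicates are
#'   removed with a warning.
#' @return A one-row tibble: `only_a`, `only_b`, `both`.
#' @export
venn_counts <- function(set_a, set_b) {
  if (anyDuplicated(set_a) || anyDuplicated(set_b)) {
    warning("duplicate gene ids removed before counting")
  }
  a <- unique(set_a)
  b <- unique(set_b)
  both <- length(intersect(a, b))
  tibble::tibble(only_a = length(a) - both, only_b = length(b) - both,
                 both = both)
}

#' Select differentially expressed genes by fold change and FDR
#'
#' Applies the strict selection used on expression tables: fold change
#' over `min_fc` in either direction and FDR strictly below `max_fdr`.
#' Boundary rows (exactly 1.5-fold, exactly 10% FDR) are excluded.
#' Fold changes may be given as signed ratios (negative = down, e.g. -2
#' is 2-fold down) or as log2 ratios; declare which with `fc_type`.
#'
#' @param table A tibble with columns `gene_id`, `fold_change`, `fdr`.
#' @param min_fc Fold-change threshold (ratio scale), strict.
#' @param max_fdr FDR threshold, strict.
#' @param fc_type `"ratio"` (signed ratio) or `"log2"`.
#' @return The qualifying rows with a `direction` column
#'   (`"up"` / `"down"`).
#' @export
filter_gene_table <- function(table, min_fc = 1.5, max_fdr = 0.10,
                              fc_type = c("ratio", "log2")) {
  fc_type <- match.arg(fc_type)
  need <- c("gene_id", "fold_change", "fdr")
  if (!all(need %in% names(table))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  magnitude <- if (fc_type == "log2") 2^abs(table$fold_change) else abs(table$fold_change)
  up <- table$fold_change > 0
  table |>
    dplyr::mutate(.magnitude = magnitude, .up = up) |>
    dplyr::filter(.data$.magnitude > min_fc, .data$fdr < max_fdr) |>
    dplyr::mutate(direction = ifelse(.data$.up, "up", "down")) |>
    dplyr::select(-".magnitude", -".up")
}
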
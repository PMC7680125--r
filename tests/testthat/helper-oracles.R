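# Independent oracles and small fixtures used across the suite.

# Brute-force greedy peak picking: literally iterate "take the global
# maximum, suppress everything within the exclusion width" on the raw
# vector.  Kept deliberately naive and separate from the package's
# sorted-candidate implementation.
brute_force_greedy <- function(v, exclusion_width, max_calls = NULL) {
  v[is.na(v)] <- 0
  halo <- exclusion_width - 1L
  out <- integer()
  repeat {
    if (all(v <= 0)) break
    p <- which.max(v)  # ties: smallest index
    out <- c(out, p)
    v[max(1L, p - halo):min(length(v), p + halo)] <- 0
    if (!is.null(max_calls) && length(out) >= max_calls) break
  }
  sort(out) - 1L  # 0-based
}

# Exact hypergeometric pmf by rational-arithmetic enumeration, valid for
# small N where choose() is exact in double precision.
enum_hypergeom_pmf <- function(x, n, D, N) {
  choose(D, x) * choose(N - D, n - x) / choose(N, n)
}

enum_hypergeom_tail <- function(x, n, D, N) {
  k <- x:min(n, D)
  sum(enum_hypergeom_pmf(k, n, D, N))
}

# A hand-laid two-gene genome for coordinate arithmetic tests:
# one + strand gene with TSS 1000 and one - strand gene with TSS 5000.
tiny_genome <- function(len = 10000L) {
  nucshift:::new_genome_annotation(
    tibble::tibble(chrom = "chrI", length = len),
    tibble::tibble(
      gene_id = c("gplus", "gminus"),
      chrom = "chrI",
      strand = c("+", "-"),
      tss = c(1000L, 5000L),
      tes = c(2500L, 3500L)
    )
  )
}

# Minimal call tibble from explicit per-call summary statistics.
make_calls <- function(chrom, dyad, dyad_mean = dyad, dyad_sd = 0,
                       occupancy = 100L) {
  n <- length(dyad)
  tibble::tibble(
    chrom = rep_len(chrom, n), dyad = as.integer(dyad),
    dyad_mean = as.numeric(rep_len(dyad_mean, n)),
    dyad_sd = as.numeric(rep_len(dyad_sd, n)),
    occupancy = as.integer(rep_len(occupancy, n)),
    score = 1, footprint_start = as.integer(dyad) - 73L,
    footprint_end = as.integer(dyad) + 73L,
    untestable = rep_len(occupancy, n) < 2 | rep_len(dyad_sd, n) == 0
  )
}
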
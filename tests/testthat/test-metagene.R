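test_that("calls are assigned to genes as +1, +2, ... along the strand", {
  g <- tiny_genome()
  calls <- make_calls("chrI", c(1070, 1235, 1400, 4930, 4765), dyad_sd = 5)
  idx <- assign_to_genes(calls, g)
  plus <- idx[idx$gene_id == "gplus", ]
  expect_equal(plus$dyad[order(plus$position_index)], c(1070, 1235, 1400))
  minus <- idx[idx$gene_id == "gminus", ]
  expect_equal(minus$dyad[order(minus$position_index)], c(4930, 4765))
})

test_that("the upstream slack window bounds +1 assignment", {
  g <- tiny_genome()
  too_far <- make_calls("chrI", 900, dyad_sd = 5)   # TSS - 100
  expect_equal(nrow(assign_to_genes(too_far, g, upstream_slack = 30)), 0)
  at_slack <- make_calls("chrI", 970, dyad_sd = 5)  # TSS - 30
  expect_equal(assign_to_genes(at_slack, g, upstream_slack = 30)$position_index, 1L)
  beyond_tes <- make_calls("chrI", 2600, dyad_sd = 5)
  expect_equal(nrow(assign_to_genes(beyond_tes, g)), 0)
})

test_that("gene filter applies the strict >560 bp / >=4 nucleosome rule", {
  mk_gene <- function(len) nucshift:::new_genome_annotation(
    tibble::tibble(chrom = "c1", length = 100000L),
    tibble::tibble(gene_id = "g", chrom = "c1", strand = "+",
                   tss = 1000L, tes = 1000L + as.integer(len))
  )
  calls4 <- make_calls("c1", c(1070, 1235, 1400, 1560), dyad_sd = 5)
  # length exactly 560 is excluded ("larger than")
  g560 <- mk_gene(560)
  expect_length(filter_genes(assign_to_genes(calls4, g560), g560), 0)
  # 561 with 4 nucleosomes is included (all four dyads sit in the body)
  g561 <- mk_gene(561)
  expect_equal(filter_genes(assign_to_genes(calls4, g561), g561), "g")
  g1200 <- mk_gene(1200)
  expect_equal(filter_genes(assign_to_genes(calls4, g1200), g1200), "g")
  # only 3 nucleosomes: excluded
  calls3 <- make_calls("c1", c(1070, 1235, 1400), dyad_sd = 5)
  expect_length(filter_genes(assign_to_genes(calls3, g1200), g1200), 0)
})

test_that("shifted-gene selection respects the position window and alpha", {
  res <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    position_index = c(2L, 5L, 2L),
    p_value = c(0.001, 0.001, 0.5),
    untestable = FALSE,
    shift = c(10, 10, 1)
  )
  expect_equal(select_shifted_genes(res), "gA")
  expect_length(select_shifted_genes(res, alpha = 0), 0)
  expect_setequal(select_shifted_genes(res, positions = 1:5), c("gA", "gB"))
})

test_that("metagene profile peaks at the array offsets and shows programmed shifts", {
  cfg <- list(n_genes = 30, chromosome_length = 100000L, fuzziness_sd = 0,
              fragment_length_sd = 0, shift_spec = c("2" = 10), seed = 17,
              n_per_gene = 4)
  res <- run_pipeline(cfg, quiet = TRUE)
  prof <- metagene_profile(
    build_track(filter_regions(fragments_to_dyads(
      simulate_fragments(res$truth_wt, res$genome, 300,
                         fragment_length_sd = 0, seed = 18))), res$genome),
    build_track(filter_regions(fragments_to_dyads(
      simulate_fragments(res$truth_mut, res$genome, 300,
                         fragment_length_sd = 0, seed = 19))), res$genome),
    res$gene_index, res$filtered_genes, offsets = -50:550
  )
  p <- prof$profile
  peak_at <- function(col, lo, hi) {
    w <- p$offset >= lo & p$offset <= hi
    p$offset[w][which.max(p[[col]][w])]
  }
  # noise-free arrays spaced 165 bp: wt peaks at 0, 165, 330, 495
  expect_equal(peak_at("mean_a", -40, 40), 0)
  expect_equal(peak_at("mean_a", 120, 210), 165)
  expect_equal(peak_at("mean_a", 290, 380), 330)
  # condition B's +2 peak moved to 175
  expect_equal(peak_at("mean_b", 120, 210), 175)
  expect_equal(peak_at("mean_b", -40, 40), 0)
  expect_equal(prof$n_genes, length(res$filtered_genes))
})

test_that("single-gene profile equals that gene's oriented track window", {
  g <- tiny_genome(12000L)
  map <- place_nucleosomes(g, n_per_gene = 3, fuzziness_sd = 10)
  fr <- simulate_fragments(map, g, 200, seed = 23)
  dy <- fragments_to_dyads(fr)
  tr <- build_track(dy, g)
  calls <- call_nucleosomes(smooth_track(tr, 20), dy)
  idx <- assign_to_genes(calls, g)
  anchor <- idx[idx$gene_id == "gminus" & idx$position_index == 1, ]
  prof <- metagene_profile(tr, tr, idx, "gminus", offsets = 0:100)
  manual <- tr$values$chrI[anchor$dyad - 0:100 + 1L]  # minus strand: downstream = decreasing
  expect_equal(prof$profile$mean_a, manual)
})

test_that("median shift summaries are medians with per-cell counts", {
  res <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g1"),
    position_index = c(2L, 2L, 2L, 1L),
    shift = c(8, 10, 12, 3),
    p_value = 0.001, untestable = FALSE
  )
  out <- median_shift_by_position(res)
  expect_equal(out$median_shift[out$position_index == 2], 10)
  expect_equal(out$n[out$position_index == 2], 3L)
  expect_equal(out$median_shift[out$position_index == 1], 3)
  # empty cells are absent, not zero
  expect_false(3L %in% out$position_index)
  only_g2 <- median_shift_by_position(res, genes = "g2")
  expect_equal(only_g2$median_shift, 10)
})

test_that("median shift is robust to a small fraction of spurious matches", {
  set.seed(31)
  clean <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100), position_index = 2L,
    shift = round(rnorm(100, 10, 1.5)), p_value = 1e-4, untestable = FALSE
  )
  contaminated <- clean
  contaminated$shift[1:10] <- c(-60, 70, -55, 62, -74, 66, -58, 71, -63, 59)
  m1 <- median_shift_by_position(clean)$median_shift
  m2 <- median_shift_by_position(contaminated)$median_shift
  expect_lt(abs(m1 - m2), 2)
})

test_that("profiles and signed shifts are invariant under coordinate mirroring", {
  base <- list(n_genes = 20, chromosome_length = 80000L, n_per_gene = 3,
               shift_spec = c("2" = 10), seed = 29)
  res <- run_pipeline(base, quiet = TRUE)
  L <- res$genome$chromosomes$length[1]
  mirror_genome <- nucshift:::new_genome_annotation(
    res$genome$chromosomes,
    dplyr::mutate(res$genome$genes, tss = L - 1L - tss, tes = L - 1L - tes,
                  strand = ifelse(strand == "+", "-", "+"))
  )
  mirror_calls <- function(calls) {
    dplyr::arrange(dplyr::mutate(calls,
      dyad = L - 1L - dyad, dyad_mean = L - 1 - dyad_mean,
      footprint_start = dyad - 73L, footprint_end = dyad + 73L
    ), chrom, dyad)
  }
  sh_m <- run_shift_analysis(mirror_calls(res$calls_wt),
                             mirror_calls(res$calls_mut), mirror_genome)
  ms <- median_shift_by_position(res$shifts)
  ms_m <- median_shift_by_position(sh_m)
  expect_equal(ms_m$median_shift, ms$median_shift)
  expect_equal(ms_m$n, ms$n)
})

test_that("empty gene set is an explicit error", {
  res <- run_pipeline(list(n_genes = 10, chromosome_length = 40000L,
                           n_per_gene = 3, seed = 2), quiet = TRUE)
  tr <- build_track(fragments_to_dyads(
    simulate_fragments(res$truth_wt, res$genome, 100, seed = 3)), res$genome)
  expect_error(metagene_profile(tr, tr, res$gene_index, character(0)),
               "empty gene set")
})
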
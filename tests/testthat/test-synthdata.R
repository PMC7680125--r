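test_that("make_genome handles degenerate, deterministic and infeasible cases", {
  empty <- make_genome(1, 100000, 0, seed = 1)
  expect_equal(nrow(empty$genes), 0)

  a <- make_genome(1, 100000, 10, min_gene_length = 2000, seed = 7)
  b <- make_genome(1, 100000, 10, min_gene_length = 2000, seed = 7)
  expect_identical(a, b)
  expect_setequal(unique(a$genes$strand), c("+", "-"))

  expect_error(make_genome(1, 10000, 50, min_gene_length = 2000, seed = 1),
               "cannot place")
})

test_that("genes are placed non-overlapping within chromosome bounds", {
  g <- make_genome(2, 60000, 30, min_gene_length = 1500, seed = 3)$genes
  expect_true(all(pmin(g$tss, g$tes) >= 0))
  expect_true(all(pmax(g$tss, g$tes) < 60000))
  expect_false(any(duplicated(g$gene_id)))
  for (cc in unique(g$chrom)) {
    gg <- g[g$chrom == cc, ]
    gg <- gg[order(pmin(gg$tss, gg$tes)), ]
    expect_true(all(pmin(gg$tss, gg$tes)[-1] > pmax(gg$tss, gg$tes)[-nrow(gg)]))
  }
  # strand orientation invariant
  expect_true(all(ifelse(g$strand == "+", g$tss < g$tes, g$tss > g$tes)))
})

test_that("place_nucleosomes follows the NFR + spacing rule on both strands", {
  map <- place_nucleosomes(tiny_genome(), nfr_length = 140, spacing = 165,
                           n_per_gene = 2, fuzziness_sd = 0)
  plus <- map[map$gene_id == "gplus", ]
  expect_equal(plus$dyad[plus$position_index == 1], 1070)
  expect_equal(plus$dyad[plus$position_index == 2], 1235)
  minus <- map[map$gene_id == "gminus", ]
  expect_equal(minus$dyad[minus$position_index == 1], 4930)
  expect_equal(minus$dyad[minus$position_index == 2], 4765)
})

test_that("place_nucleosomes yields n_per_gene entries per gene with indices", {
  g <- make_genome(1, 500000, 100, min_gene_length = 1500, seed = 2)
  map <- place_nucleosomes(g, n_per_gene = 4)
  expect_equal(nrow(map), 400)
  expect_setequal(unique(map$position_index), 1:4)
})

test_that("apply_shifts moves only listed positions, strand-relative", {
  map <- place_nucleosomes(tiny_genome(), nfr_length = 140, spacing = 165,
                           n_per_gene = 3)
  shifted <- apply_shifts(map, c("2" = 10))
  get <- function(m, gene, k) m$dyad[m$gene_id == gene & m$position_index == k]
  expect_equal(get(shifted, "gplus", 2), 1245)
  expect_equal(get(shifted, "gplus", 1), 1070)
  expect_equal(get(shifted, "gminus", 2), 4755)
  expect_identical(apply_shifts(map, numeric(0)), map)
})

test_that("strand mirror: shifting a mirrored map mirrors the shifted map", {
  g <- make_genome(1, 50000, 8, min_gene_length = 1500, seed = 9)
  map <- place_nucleosomes(g, n_per_gene = 3)
  L <- g$chromosomes$length[1]
  mirror_genome <- nucshift:::new_genome_annotation(
    g$chromosomes,
    dplyr::mutate(g$genes, tss = L - 1L - tss, tes = L - 1L - tes,
                  strand = ifelse(strand == "+", "-", "+"))
  )
  mirror_map <- place_nucleosomes(mirror_genome, n_per_gene = 3)
  spec <- c("2" = 7)
  a <- apply_shifts(map, spec)
  b <- apply_shifts(mirror_map, spec)
  key <- function(m) m[order(m$gene_id, m$position_index), ]
  expect_equal(key(b)$dyad, L - 1L - key(a)$dyad)
})

test_that("simulate_fragments conserves counts and honours the dyad convention", {
  g <- tiny_genome()
  map <- place_nucleosomes(g, n_per_gene = 1, fuzziness_sd = 0,
                           occupancy_weights = 1)
  fr <- simulate_fragments(map, g, fragments_per_unit_weight = 100,
                           fragment_length_sd = 0, seed = 4)
  expect_equal(nrow(fr), 200)  # two genes x 100
  dy <- fragments_to_dyads(fr)
  expect_setequal(unique(dy$pos), map$dyad)

  # conservation with fractional weights
  map2 <- dplyr::mutate(map, weight = c(0.4, 1.6))
  fr2 <- simulate_fragments(map2, g, fragments_per_unit_weight = 25, seed = 4)
  expect_equal(nrow(fr2), sum(round(map2$weight * 25)))

  # seed determinism
  expect_identical(fr, simulate_fragments(map, g, 100, fragment_length_sd = 0,
                                          seed = 4))
})

test_that("fragment dyad dispersion matches the programmed fuzziness", {
  g <- nucshift:::new_genome_annotation(
    tibble::tibble(chrom = "chrI", length = 100000L),
    tibble::tibble(gene_id = "g1", chrom = "chrI", strand = "+",
                   tss = 40000L, tes = 60000L)
  )
  map <- place_nucleosomes(g, n_per_gene = 1, fuzziness_sd = 20)
  fr <- simulate_fragments(map, g, fragments_per_unit_weight = 10000, seed = 8)
  dy <- fragments_to_dyads(fr)
  # SD of a Normal(., 20) sample of n = 10000: 3-sigma band 20 +/- 0.6
  expect_lt(abs(sd(dy$pos) - 20), 0.6)
})

test_that("noiseless titrations lie exactly on the Hill curve", {
  conc <- default_titration_concentrations()
  expect_length(conc, 12)
  expect_equal(range(conc), c(0, 60))
  tt <- simulate_titration(5, 1.3, conc, noise_sd = 0, replicates = 2, seed = 1)
  expect_equal(tt$fraction_bound, hill_curve(tt$concentration, 5, 1.3))
  expect_equal(hill_curve(5, 5, 1.3), 0.5)        # midpoint identity
  expect_equal(hill_curve(0, 5, 1.3), 0)          # lower limit
  expect_gt(hill_curve(1e6, 5, 1.3), 1 - 1e-6)    # upper limit
  expect_false(any(tt$clipped))
})

test_that("noiseless time courses follow the saturating exponential with slope v0", {
  tc <- simulate_timecourse(1.0, 20, noise_sd = 0)
  expect_equal(tc$signal, 20 * (1 - exp(-0.05 * tc$time)))
  # analytic slope at 0 equals v0: finite difference on a fine grid
  eps <- 1e-6
  fine <- simulate_timecourse(1.0, 20, times = c(0, eps), noise_sd = 0)
  expect_equal(diff(fine$signal) / eps, 1.0, tolerance = 1e-6)
  flat <- simulate_timecourse(0, 20, noise_sd = 0)
  expect_true(all(flat$signal == 0))
})
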
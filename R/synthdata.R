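#' Generate a synthetic genome annotation
#'
#' Builds a small genome of one or more chromosomes and places
#' non-overlapping genes on it, each with a well-defined transcription
#' start site (TSS) and end site (TES).  Genes are assigned round-robin to
#' chromosomes, given lengths between `min_gene_length` and
#' 1.5x `min_gene_length`, separated by random gaps, and randomly
#' stranded (both strands are always represented when two or more genes
#' are requested).
#'
#' All coordinates are 0-based.  For a `+` strand gene `tss < tes`; for a
#' `-` strand gene `tss > tes`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp.
#' @param n_genes Total number of genes to place.
#' @param min_gene_length Minimum gene length in bp.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#'
#' @return A `genome_annotation` object: a list with tibbles
#'   `chromosomes` (`chrom`, `length`) and `genes`
#'   (`gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @export
#' @examples
#' g <- make_genome(1, 100000, 10, min_gene_length = 2000, seed = 7)
#' g$genes
make_genome <- function(n_chromosomes, chromosome_length, n_genes,
                        min_gene_length = 1000, seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 1, n_genes >= 0)
  set.seed(seed)
  chroms <- tibble::tibble(
    chrom = sprintf("chr%s", as.roman(seq_len(n_chromosomes))),
    length = as.integer(chromosome_length)
  )
  if (n_genes == 0) {
    genes <- tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      tss = integer(), tes = integer()
    )
    return(new_genome_annotation(chroms, genes))
  }
  chrom_of <- rep(chroms$chrom, length.out = n_genes)
  lens <- as.integer(round(min_gene_length * stats::runif(n_genes, 1, 1.5)))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  if (n_genes >= 2 && length(unique(strand)) == 1L) {
    strand[n_genes] <- setdiff(c("+", "-"), strand[1])
  }
  genes <- purrr::map_dfr(chroms$chrom, function(cc) {
    idx <- which(chrom_of == cc)
    if (!length(idx)) return(NULL)
    slack <- chromosome_length - sum(lens[idx])
    if (slack < 0) {
      stop("cannot place ", length(idx), " genes of >= ", min_gene_length,
           " bp on a ", chromosome_length, " bp chromosome", call. = FALSE)
    }
    # random gaps before each gene and after the last one
    w <- stats::runif(length(idx) + 1)
    gaps <- floor(slack * w / sum(w))
    starts <- cumsum(gaps[seq_along(idx)] + c(0L, lens[idx[-length(idx)]]))
    ends <- starts + lens[idx]
    str_cc <- strand[idx]
    tibble::tibble(
      gene_id = sprintf("g%04d", idx),
      chrom = cc,
      strand = str_cc,
      tss = as.integer(ifelse(str_cc == "+", starts, ends - 1L)),
      tes = as.integer(ifelse(str_cc == "+", ends - 1L, starts))
    )
  })
  new_genome_annotation(chroms, dplyr::arrange(genes, .data$gene_id))
}

new_genome_annotation <- function(chromosomes, genes) {
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  print(x$chromosomes, n = 5)
  print(x$genes, n = 5)
  invisible(x)
}

chrom_lengths <- function(genome) {
  stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
}

#' Place regular nucleosome arrays downstream of every TSS
#'
#' Emulates promoter-proximal nucleosome organisation: a nucleosome-free
#' region (NFR) at the promoter followed by a regularly spaced array.  The
#' +k nucleosome dyad is placed at
#' `TSS + nfr_length/2 + (k - 1) * spacing` measured along the direction
#' of transcription.
#'
#' @param genome A [make_genome()] annotation.
#' @param nfr_length Nucleosome-free region width in bp; the +1 dyad sits
#'   `nfr_length / 2` downstream of the TSS.
#' @param spacing Dyad-to-dyad repeat length in bp.  Values below 147 bp
#'   imply sterically overlapping nucleosomes and trigger a warning.
#' @param n_per_gene Number of nucleosomes (+1 ... +n) per gene.
#' @param fuzziness_sd Per-nucleosome dyad dispersion (bp), recycled
#'   across positions.
#' @param occupancy_weights Relative occupancy per position index,
#'   recycled to `n_per_gene`.
#' @param condition Condition label stored with the map.
#'
#' @return A tibble (`true_nucleosome_map`): `chrom`, `dyad`,
#'   `fuzziness_sd`, `weight`, `gene_id`, `position_index`, `strand`,
#'   `condition`.  Nucleosomes falling outside their chromosome are
#'   dropped with a warning.
#' @export
place_nucleosomes <- function(genome, nfr_length = 140, spacing = 165,
                              n_per_gene = 4, fuzziness_sd = 20,
                              occupancy_weights = 1, condition = "wt") {
  stopifnot(n_per_gene >= 1, nfr_length >= 0)
  if (spacing < 147) {
    warning("spacing < 147 bp implies overlapping nucleosome footprints")
  }
  genes <- genome$genes
  weights <- rep_len(occupancy_weights, n_per_gene)
  fuzz <- rep_len(fuzziness_sd, n_per_gene)
  k <- seq_len(n_per_gene)
  map <- tidyr::crossing(genes, tibble::tibble(
    position_index = k, weight = weights, fuzziness_sd = fuzz
  ))
  dir <- ifelse(map$strand == "+", 1L, -1L)
  map$dyad <- as.integer(map$tss + dir *
    (round(nfr_length / 2) + (map$position_index - 1L) * spacing))
  lens <- chrom_lengths(genome)
  inside <- map$dyad >= 0L & map$dyad < lens[map$chrom]
  if (any(!inside)) {
    warning(sum(!inside), " nucleosome(s) fell outside a chromosome and were dropped")
  }
  map |>
    dplyr::filter(inside) |>
    dplyr::mutate(condition = condition) |>
    dplyr::select("chrom", "dyad", "fuzziness_sd", "weight", "gene_id",
                  "position_index", "strand", "condition")
}

#' Apply condition-specific dyad shifts to a true nucleosome map
#'
#' Moves the nucleosomes at selected position indices by a signed number
#' of base pairs measured along the direction of transcription: positive
#' shifts move a nucleosome downstream, i.e. away from the TSS, so on a
#' `-` strand gene a positive shift decreases the genomic coordinate.
#'
#' @param map A [place_nucleosomes()] map.
#' @param shift_spec Named numeric vector mapping position index to a
#'   signed shift in bp, e.g. `c("2" = 10, "3" = 10)`.  Names may carry a
#'   leading `+`.
#' @param condition Optional new condition label for the returned map.
#'
#' @return The map with shifted dyads; entries whose index is absent from
#'   `shift_spec` are untouched.
#' @export
apply_shifts <- function(map, shift_spec, condition = NULL) {
  if (length(shift_spec)) {
    idx <- as.integer(sub("^\\+", "", names(shift_spec)))
    if (anyNA(idx)) stop("shift_spec names must be position indices")
    m <- match(map$position_index, idx)
    shift <- ifelse(is.na(m), 0, shift_spec[m])
    dir <- ifelse(map$strand == "+", 1L, -1L)
    map$dyad <- as.integer(map$dyad + dir * shift)
  }
  if (!is.null(condition)) map$condition <- condition
  map
}

#' Simulate mononucleosomal MNase fragments from a true nucleosome map
#'
#' Each map entry contributes `round(weight * fragments_per_unit_weight)`
#' fragments.  A fragment's dyad is drawn from
#' `Normal(true dyad, fuzziness_sd)` and rounded; its length from
#' `Normal(fragment_length_mean, fragment_length_sd)`, rounded and floored
#' at 50 bp.  The fragment is placed so that its midpoint
#' `floor((start + end - 1) / 2)` -- the same dyad convention used by
#' [fragments_to_dyads()] -- equals the drawn dyad.  Fragments running off
#' a chromosome end are clipped to the chromosome and flagged.
#'
#' @param map A true nucleosome map.
#' @param genome The genome the map lives on (for chromosome bounds).
#' @param fragments_per_unit_weight Fragments generated per unit of
#'   occupancy weight.
#' @param fragment_length_mean,fragment_length_sd Fragment length model in
#'   bp (mononucleosomal MNase protection is ~147 bp).
#' @param replicate Replicate index recorded with each fragment.
#' @param seed Integer seed.
#'
#' @return A tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `condition`, `replicate`, `clipped`.
#' @export
simulate_fragments <- function(map, genome, fragments_per_unit_weight = 300,
                               fragment_length_mean = 147,
                               fragment_length_sd = 10,
                               replicate = 1L, seed = 1) {
  stopifnot(fragment_length_mean >= 1)
  set.seed(seed)
  n_per <- as.integer(round(map$weight * fragments_per_unit_weight))
  i <- rep(seq_len(nrow(map)), n_per)
  n <- length(i)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), condition = character(),
                          replicate = integer(), clipped = logical()))
  }
  dyad <- as.integer(round(stats::rnorm(n, map$dyad[i], map$fuzziness_sd[i])))
  len <- as.integer(pmax(50L, round(
    stats::rnorm(n, fragment_length_mean, fragment_length_sd))))
  start <- dyad - (len - 1L) %/% 2L
  end <- start + len
  lens <- chrom_lengths(genome)
  lim <- unname(lens[map$chrom[i]])
  clipped <- start < 0L | end > lim
  start <- pmax(start, 0L)
  end <- pmin(end, lim)
  tibble::tibble(
    chrom = map$chrom[i],
    start = start, end = as.integer(end),
    condition = map$condition[i],
    replicate = as.integer(replicate),
    clipped = clipped
  )
}

#' Hill binding curve
#'
#' Fraction bound at enzyme concentration `conc` for a Hill model with
#' dissociation constant `kd` and Hill coefficient `h`:
#' `f = conc^h / (kd^h + conc^h)` (0 at `conc = 0`).
#'
#' @param conc Concentration(s), nM.
#' @param kd Dissociation constant, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @return Fraction bound in `[0, 1]`.
#' @export
hill_curve <- function(conc, kd, h) {
  stopifnot(kd > 0, h > 0)
  ifelse(conc <= 0, 0, conc^h / (kd^h + conc^h))
}

#' Default EMSA titration series
#'
#' A two-fold dilution series from 60 nM down (11 points) plus a
#' zero-enzyme point: 12 concentrations spanning 0-60 nM, the range used
#' for remodeler EMSA titrations.
#'
#' @return Numeric vector of 12 concentrations (nM), ascending.
#' @export
default_titration_concentrations <- function() {
  sort(c(0, 60 / 2^(10:0)))
}

#' Simulate an EMSA binding titration
#'
#' Generates fraction-bound measurements on a Hill curve with additive
#' Gaussian noise, clipped to `[0, 1]` (clipping recorded, not hidden).
#'
#' @param kd True dissociation constant, nM.
#' @param h True Hill coefficient.
#' @param concentrations Concentration series, nM.
#' @param noise_sd Gaussian noise standard deviation (fraction-bound
#'   units).
#' @param replicates Number of replicate titrations.
#' @param seed Integer seed.
#'
#' @return A tibble: `concentration`, `fraction_bound`, `replicate`,
#'   `clipped`.
#' @export
simulate_titration <- function(kd, h,
                               concentrations = default_titration_concentrations(),
                               noise_sd = 0.03, replicates = 3, seed = 1) {
  stopifnot(kd > 0, h > 0, all(concentrations >= 0), replicates >= 1)
  set.seed(seed)
  grid <- tidyr::crossing(replicate = seq_len(replicates),
                          concentration = concentrations)
  f <- hill_curve(grid$concentration, kd, h) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  clipped <- f < 0 | f > 1
  tibble::tibble(
    concentration = grid$concentration,
    fraction_bound = pmin(pmax(f, 0), 1),
    replicate = grid$replicate,
    clipped = clipped
  )
}

#' Simulate a remodeling or ATPase time course
#'
#' Signal follows a saturating exponential
#' `plateau * (1 - exp(-(v0 / plateau) * t))` whose analytic slope at
#' `t = 0` equals the initial rate `v0`, with additive Gaussian noise
#' floored at zero.
#'
#' @param v0 True initial rate, nM/s.
#' @param plateau Reaction amplitude, nM.
#' @param times Time points in seconds (non-negative, increasing).
#' @param noise_sd Gaussian noise SD, nM.
#' @param seed Integer seed.
#'
#' @return A tibble: `time`, `signal`.
#' @export
simulate_timecourse <- function(v0, plateau,
                                times = c(0, 10, 20, 40, 80, 160, 320, 640),
                                noise_sd = 0, seed = 1) {
  stopifnot(v0 >= 0, plateau > 0, all(times >= 0), !is.unsorted(times, strictly = TRUE))
  set.seed(seed)
  mu <- plateau * (1 - exp(-(v0 / plateau) * times))
  tibble::tibble(
    time = times,
    signal = pmax(0, mu + stats::rnorm(length(times), 0, noise_sd))
  )
}
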
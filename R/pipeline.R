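#' Default pipeline configuration
#'
#' All tunable parameters of the simulate -> dyads -> call -> shift ->
#' metagene pipeline with their defaults.  Any subset can be overridden
#' through the `config` argument of [run_pipeline()]; unknown keys are
#' rejected.
#'
#' @return A named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    n_chromosomes = 1L,
    chromosome_length = 500000L,
    n_genes = 200L,
    min_gene_length = 1200L,
    nfr_length = 140,
    spacing = 165,
    n_per_gene = 5L,
    fuzziness_sd = 20,
    occupancy_weights = 1,
    shift_spec = c("2" = 10, "3" = 10, "4" = 10),
    fragments_per_nucleosome = 300,
    fragment_length_mean = 147,
    fragment_length_sd = 10,
    exclusions = NULL,
    pool = "raw",
    sigma = 20,
    exclusion_width = 147,
    min_occupancy = 10,
    alpha = 0.01,
    min_overlap = 73,
    upstream_slack = 30,
    gene_min_length = 560,
    gene_min_nucleosomes = 4,
    shifted_positions = 1:4,
    offsets = -200:800,
    seed = 1L
  )
}

#' Run the full synthetic nucleosome-shift pipeline
#'
#' One seeded, configured, logged run of every stage: genome and true
#' nucleosome maps are simulated (the mutant with the configured
#' position-specific shifts applied), MNase fragments generated for both
#' conditions, dyad tracks built and smoothed, nucleosomes called,
#' conditions matched and Welch-tested, and +1-aligned metagene
#' summaries computed.  Reruns with the same config are bit-identical.
#'
#' @param config Named list overriding [default_pipeline_config()], or a
#'   path to a YAML file with the same keys.
#' @param out_dir Optional directory; when given, stage outputs (TSV/BED/
#'   bedGraph) and a `provenance.json` record (full config, seeds, stage
#'   counts, package version) are written there.
#' @param quiet Suppress per-stage messages.
#' @return A list: `genome`, `truth_wt`, `truth_mut`, `calls_wt`,
#'   `calls_mut`, `shifts`, `gene_index`, `filtered_genes`,
#'   `shifted_genes`, `profile`, `median_shift`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$shift_spec)) {
      config$shift_spec <- unlist(config$shift_spec)
    }
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  say <- function(...) if (!quiet) message("[nucshift] ", ...)

  seed <- as.integer(cfg$seed)
  say("simulating genome: ", cfg$n_genes, " genes on ", cfg$n_chromosomes,
      " chromosome(s)")
  genome <- make_genome(cfg$n_chromosomes, cfg$chromosome_length, cfg$n_genes,
                        cfg$min_gene_length, seed = seed)
  truth_wt <- place_nucleosomes(genome, cfg$nfr_length, cfg$spacing,
                                cfg$n_per_gene, cfg$fuzziness_sd,
                                cfg$occupancy_weights, condition = "wt")
  truth_mut <- apply_shifts(truth_wt, cfg$shift_spec, condition = "mut")

  frags_wt <- simulate_fragments(truth_wt, genome, cfg$fragments_per_nucleosome,
                                 cfg$fragment_length_mean, cfg$fragment_length_sd,
                                 seed = seed + 1L)
  frags_mut <- simulate_fragments(truth_mut, genome, cfg$fragments_per_nucleosome,
                                  cfg$fragment_length_mean, cfg$fragment_length_sd,
                                  seed = seed + 2L)
  say("fragments: ", nrow(frags_wt), " wt, ", nrow(frags_mut), " mut")

  exclusions <- cfg$exclusions
  dyads_wt <- filter_regions(fragments_to_dyads(frags_wt), exclusions)
  dyads_mut <- filter_regions(fragments_to_dyads(frags_mut), exclusions)
  track_wt <- build_track(dyads_wt, genome, exclusions, pool = cfg$pool)
  track_mut <- build_track(dyads_mut, genome, exclusions, pool = cfg$pool)

  calls_wt <- call_nucleosomes(smooth_track(track_wt, cfg$sigma), dyads_wt,
                               cfg$exclusion_width, cfg$min_occupancy)
  calls_mut <- call_nucleosomes(smooth_track(track_mut, cfg$sigma), dyads_mut,
                                cfg$exclusion_width, cfg$min_occupancy)
  say("calls: ", nrow(calls_wt), " wt, ", nrow(calls_mut), " mut")

  shifts <- run_shift_analysis(calls_wt, calls_mut, genome, alpha = cfg$alpha,
                               min_overlap = cfg$min_overlap,
                               upstream_slack = cfg$upstream_slack)
  s <- attr(shifts, "summary")
  say("pairs: ", s$n_pairs, " matched, ", s$n_tested, " tested, ",
      s$n_significant, " significant at alpha = ", cfg$alpha)

  gene_index <- assign_to_genes(calls_wt, genome, cfg$upstream_slack)
  filtered_genes <- filter_genes(gene_index, genome, cfg$gene_min_length,
                                 cfg$gene_min_nucleosomes)
  shifted_genes <- intersect(
    select_shifted_genes(shifts, cfg$shifted_positions, cfg$alpha),
    filtered_genes
  )
  profile <- if (length(shifted_genes)) {
    metagene_profile(track_wt, track_mut, gene_index, shifted_genes,
                     cfg$offsets)
  } else NULL
  median_shift <- median_shift_by_position(
    shifts, genes = if (length(shifted_genes)) shifted_genes else NULL
  )

  result <- list(genome = genome, truth_wt = truth_wt, truth_mut = truth_mut,
                 calls_wt = calls_wt, calls_mut = calls_mut, shifts = shifts,
                 gene_index = gene_index, filtered_genes = filtered_genes,
                 shifted_genes = shifted_genes, profile = profile,
                 median_shift = median_shift, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(truth_wt, file.path(out_dir, "truth_wt.tsv"))
    readr::write_tsv(truth_mut, file.path(out_dir, "truth_mut.tsv"))
    write_fragments_bed(frags_wt, file.path(out_dir, "fragments_wt.bed"))
    write_fragments_bed(frags_mut, file.path(out_dir, "fragments_mut.bed"))
    write_track_bedgraph(track_wt, file.path(out_dir, "track_wt.bedGraph"))
    write_track_bedgraph(track_mut, file.path(out_dir, "track_mut.bedGraph"))
    readr::write_tsv(calls_wt, file.path(out_dir, "calls_wt.tsv"))
    readr::write_tsv(calls_mut, file.path(out_dir, "calls_mut.tsv"))
    readr::write_tsv(shifts, file.path(out_dir, "shifts.tsv"))
    readr::write_tsv(median_shift, file.path(out_dir, "median_shift.tsv"))
    if (!is.null(profile)) {
      readr::write_tsv(profile$profile, file.path(out_dir, "metagene_profile.tsv"))
    }
    write_genes_gff3(genome, file.path(out_dir, "genes.gff3"))
    provenance <- list(
      package = "nucshift",
      version = as.character(utils::packageVersion("nucshift")),
      config = cfg,
      counts = list(
        fragments_wt = nrow(frags_wt), fragments_mut = nrow(frags_mut),
        dyads_removed_wt = attr(dyads_wt, "n_removed"),
        dyads_removed_mut = attr(dyads_mut, "n_removed"),
        calls_wt = nrow(calls_wt), calls_mut = nrow(calls_mut),
        pairs = s$n_pairs, tested = s$n_tested,
        significant = s$n_significant, untestable = s$n_untestable,
        filtered_genes = length(filtered_genes),
        shifted_genes = length(shifted_genes)
      )
    )
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  result
}
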
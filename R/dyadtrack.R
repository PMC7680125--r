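#' Convert paired-end fragments to dyad positions
#'
#' The dyad of a protected fragment is estimated as the midpoint of its
#' closed base interval, `floor((start + end - 1) / 2)`, which is exact
#' for odd fragment lengths and rounds down for even ones.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, optionally
#'   `condition`, `replicate`) with 0-based half-open coordinates.
#' @return A tibble of dyads: `chrom`, `pos`, plus any `condition` /
#'   `replicate` columns present in the input.
#' @export
#' @examples
#' fragments_to_dyads(tibble::tibble(chrom = "chrI", start = 100, end = 247))
fragments_to_dyads <- function(fragments) {
  stopifnot(all(fragments$end > fragments$start))
  keep <- intersect(c("condition", "replicate"), names(fragments))
  dplyr::bind_cols(
    tibble::tibble(
      chrom = fragments$chrom,
      pos = as.integer((fragments$start + fragments$end - 1L) %/% 2L)
    ),
    fragments[keep]
  )
}

#' Remove dyads falling in excluded regions
#'
#' Drops dyads whose position lies inside any exclusion interval
#' (0-based, half-open), as done for the repetitive rDNA locus whose
#' multi-mapping reads would otherwise dominate local coverage.  The
#' number of removed dyads is attached as attribute `n_removed`.
#'
#' @param dyads Dyad tibble from [fragments_to_dyads()].
#' @param exclusions Tibble of regions: `chrom`, `start`, `end`
#'   (0-based half-open), or `NULL` for no filtering.
#' @return The filtered dyad tibble.
#' @export
filter_regions <- function(dyads, exclusions = NULL) {
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    attr(dyads, "n_removed") <- 0L
    return(dyads)
  }
  drop <- rep(FALSE, nrow(dyads))
  for (i in seq_len(nrow(exclusions))) {
    drop <- drop | (dyads$chrom == exclusions$chrom[i] &
                      dyads$pos >= exclusions$start[i] &
                      dyads$pos < exclusions$end[i])
  }
  out <- dyads[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Build a normalized dyad-density track
#'
#' Counts dyads per base pair and normalizes to the mean genome-wide
#' coverage over non-excluded positions, so that the mean track value
#' over non-excluded bases is exactly 1.  Excluded positions are masked
#' with `NA` (they are removed from the normalization denominator, not
#' zero-filled).
#'
#' When the dyads carry a `replicate` column with several replicates,
#' `pool` controls how they are combined: `"raw"` (default) sums raw dyad
#' counts across replicates before normalizing once; for
#' `"mean-of-normalized"` each replicate is normalized on its own and the
#' per-bp normalized values are averaged.
#'
#' @param dyads Dyad tibble (already or not yet region-filtered; the
#'   exclusions are applied here as well).
#' @param genome A [make_genome()] annotation giving chromosome lengths.
#' @param exclusions Optional exclusion regions as in [filter_regions()].
#' @param pool `"raw"` or `"mean-of-normalized"` replicate pooling.
#' @return A `dyad_track` object: per-chromosome numeric vectors (one
#'   value per bp, `NA` at excluded positions), with the normalization
#'   factor and retained dyad count attached.
#' @export
build_track <- function(dyads, genome, exclusions = NULL,
                        pool = c("raw", "mean-of-normalized")) {
  pool <- match.arg(pool)
  dyads <- filter_regions(dyads, exclusions)
  if (nrow(dyads) == 0) stop("no dyads left after exclusion filtering", call. = FALSE)
  lens <- chrom_lengths(genome)
  bad <- dyads$pos < 0L | dyads$pos >= lens[dyads$chrom]
  if (any(bad)) stop("dyad positions outside chromosome bounds", call. = FALSE)

  mask <- excluded_mask(genome, exclusions)
  non_excl_len <- sum(vapply(mask, function(m) sum(!m), 0))

  one_track <- function(dd) {
    counts <- purrr::imap(mask, function(m, cc) {
      p <- dd$pos[dd$chrom == cc]
      v <- as.numeric(tabulate(p + 1L, nbins = length(m)))
      v[m] <- NA_real_
      v
    })
    factor <- nrow(dd) / non_excl_len
    list(values = purrr::map(counts, ~ .x / factor), norm_factor = factor,
         n_dyads = nrow(dd))
  }

  if (pool == "mean-of-normalized" && "replicate" %in% names(dyads) &&
      dplyr::n_distinct(dyads$replicate) > 1) {
    reps <- split(dyads, dyads$replicate)
    tracks <- purrr::map(reps, one_track)
    values <- purrr::map(names(mask), function(cc) {
      Reduce(`+`, purrr::map(tracks, ~ .x$values[[cc]])) / length(tracks)
    })
    names(values) <- names(mask)
    tr <- list(values = values,
               norm_factor = mean(purrr::map_dbl(tracks, "norm_factor")),
               n_dyads = nrow(dyads))
  } else {
    tr <- one_track(dyads)
  }
  condition <- if ("condition" %in% names(dyads)) {
    paste(unique(dyads$condition), collapse = "+")
  } else NA_character_
  structure(
    list(values = tr$values, norm_factor = tr$norm_factor,
         n_dyads = tr$n_dyads, condition = condition, pool = pool),
    class = "dyad_track"
  )
}

excluded_mask <- function(genome, exclusions = NULL) {
  lens <- chrom_lengths(genome)
  mask <- purrr::map(lens, ~ rep(FALSE, .x))
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      cc <- exclusions$chrom[i]
      if (!cc %in% names(mask)) next
      s <- max(0L, exclusions$start[i])
      e <- min(lens[[cc]], exclusions$end[i])
      if (e > s) mask[[cc]][(s + 1L):e] <- TRUE
    }
  }
  mask
}

#' @export
print.dyad_track <- function(x, ...) {
  cat("<dyad_track> ", length(x$values), " chromosome(s), ",
      x$n_dyads, " dyads, condition ", x$condition,
      ", mean non-excluded density 1\n", sep = "")
  invisible(x)
}

#' Tidy a dyad track into a long tibble
#'
#' @param x A `dyad_track`.
#' @param ... Unused.
#' @return A tibble: `chrom`, `pos` (0-based), `density`, `excluded`.
#' @export
tidy.dyad_track <- function(x, ...) {
  purrr::imap_dfr(x$values, function(v, cc) {
    tibble::tibble(chrom = cc, pos = seq_along(v) - 1L,
                   density = v, excluded = is.na(v))
  })
}

#' Extract track values over a window
#'
#' @param track A `dyad_track` or smoothed track.
#' @param chrom Chromosome name.
#' @param positions 0-based positions; out-of-bounds positions yield `NA`.
#' @return Numeric vector of densities (`NA` where masked or outside).
#' @export
track_values <- function(track, chrom, positions) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(rep(NA_real_, length(positions)))
  out <- rep(NA_real_, length(positions))
  ok <- positions >= 0L & positions < length(v)
  out[ok] <- v[positions[ok] + 1L]
  out
}
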
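#' Gaussian-smooth a dyad-density track
#'
#' Convolves each per-bp density vector with a Gaussian kernel truncated
#' at +/- 4 sigma and normalized to unit sum.  Excluded (masked) and
#' out-of-chromosome positions contribute zero to the numerator; values
#' are renormalized by the kernel mass falling inside the chromosome, so
#' a flat unmasked track stays flat up to its ends.  Masked positions
#' remain masked in the output.
#'
#' @param track A [build_track()] `dyad_track`.
#' @param sigma Kernel standard deviation in bp.
#' @return A `smoothed_track`: per-chromosome smoothed vectors (`NA` at
#'   masked positions) plus the sigma used.
#' @export
smooth_track <- function(track, sigma = 20) {
  stopifnot(sigma > 0)
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  values <- purrr::map(track$values, function(v) {
    masked <- is.na(v)
    x <- ifelse(masked, 0, v)
    num <- pad_filter(x, kern, half)
    den <- pad_filter(rep(1, length(v)), kern, half)
    out <- num / den
    out[masked] <- NA_real_
    out
  })
  structure(list(values = values, sigma = sigma), class = "smoothed_track")
}

pad_filter <- function(x, kern, half) {
  y <- stats::filter(c(rep(0, half), x, rep(0, half)), kern, sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Call stereotypic nucleosome positions with a greedy algorithm
#'
#' Repeatedly takes the highest remaining point of the smoothed dyad
#' signal as a nucleosome dyad and suppresses further calls within the
#' exclusion width center-to-center (`|delta dyad| < exclusion_width`),
#' so 147-bp footprints of accepted calls never overlap.  Ties in height
#' are broken by the smaller coordinate, then by chromosome name;
#' the procedure is deterministic.
#'
#' Each call is then completed from the raw dyads inside its 147-bp
#' footprint `[dyad - 73, dyad + 73]`: `occupancy` is the dyad count,
#' `dyad_sd` the n-1 sample standard deviation of those positions (0 when
#' fewer than two dyads), and `dyad_mean` their mean.  Calls whose
#' occupancy falls below `min_occupancy` are discarded.  Calls with
#' occupancy < 2 or zero spread are flagged `untestable`.
#'
#' @param smoothed A [smooth_track()] result.
#' @param raw_dyads The dyad tibble the track was built from (after any
#'   exclusion filtering).
#' @param exclusion_width Minimum center-to-center distance between calls
#'   in bp (147 = one nucleosome footprint).
#' @param min_occupancy Minimum raw-dyad support for a reported call.
#' @param max_calls Optional cap on the number of calls per chromosome.
#' @return A tibble of calls: `chrom`, `dyad`, `dyad_mean`, `dyad_sd`,
#'   `occupancy`, `score`, `footprint_start`, `footprint_end`,
#'   `untestable`, sorted by chromosome and dyad.
#' @export
call_nucleosomes <- function(smoothed, raw_dyads, exclusion_width = 147,
                             min_occupancy = 10, max_calls = NULL) {
  stopifnot(exclusion_width >= 1)
  out <- purrr::imap_dfr(smoothed$values, function(v, cc) {
    peaks <- greedy_peaks(v, exclusion_width, max_calls)
    if (!length(peaks)) return(NULL)
    pos <- raw_dyads$pos[raw_dyads$chrom == cc]
    stats <- footprint_stats(peaks, pos)
    tibble::tibble(
      chrom = cc,
      dyad = peaks,
      dyad_mean = stats$mean,
      dyad_sd = stats$sd,
      occupancy = stats$n,
      score = v[peaks + 1L],
      footprint_start = peaks - 73L,
      footprint_end = peaks + 73L,
      untestable = stats$n < 2L | stats$sd == 0
    )
  })
  if (!nrow(out)) return(out)
  out |>
    dplyr::filter(.data$occupancy >= min_occupancy) |>
    dplyr::arrange(.data$chrom, .data$dyad)
}

# Greedy maximum selection on one smoothed vector: equivalent to
# iterating global-argmax + suppression because candidates are visited in
# (height desc, position asc) order and acceptance only depends on
# previously accepted (higher) calls.
greedy_peaks <- function(v, exclusion_width, max_calls = NULL) {
  cand <- which(!is.na(v) & v > 0)
  if (!length(cand)) return(integer())
  ord <- cand[order(-v[cand], cand)]
  blocked <- rep(FALSE, length(v))
  accepted <- integer()
  halo <- exclusion_width - 1L
  for (p in ord) {
    if (blocked[p]) next
    accepted <- c(accepted, p)
    blocked[max(1L, p - halo):min(length(v), p + halo)] <- TRUE
    if (!is.null(max_calls) && length(accepted) >= max_calls) break
  }
  sort(accepted) - 1L  # to 0-based
}

# Occupancy / mean / sd of raw dyads within each 147-bp footprint.
# Footprints of calls >= 147 bp apart are disjoint, so each dyad belongs
# to at most one call.  Sorted positions + findInterval keep this linear
# in the number of dyads.
footprint_stats <- function(peaks, pos) {
  ps <- sort(pos)
  lo <- findInterval(peaks - 73L - 0.5, ps)
  hi <- findInterval(peaks + 73L + 0.5, ps)
  n <- hi - lo
  mu <- rep(NA_real_, length(peaks))
  sd <- numeric(length(peaks))
  for (j in seq_along(peaks)) {
    if (n[j] >= 1L) {
      x <- ps[(lo[j] + 1L):hi[j]]
      mu[j] <- mean(x)
      if (n[j] >= 2L) sd[j] <- stats::sd(x)
    }
  }
  list(n = as.integer(n), mean = mu, sd = sd)
}
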
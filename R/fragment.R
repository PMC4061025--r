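#' Estimate the sheared-fragment length from strand-separated pileups
#'
#' Sequenced reads are much shorter than the fragments they came from, so
#' forward-strand tags pile up 5' of the binding site and reverse-strand
#' tags 3' of it. The fragment length is estimated from that shift:
#' coverage regions are built for each strand separately and given log10
#' excess ratios from per-strand background fits; regions with
#' log10(ER) > `max_log_er` (default 50) are discarded as likely alignment
#' artefacts; forward/reverse region pairs that overlap uniquely (a 1:1
#' match — each member overlaps no other region on the opposite strand) are
#' collected; the `max_pairs` (default 200) most significant pairs, ranked
#' by the weaker strand's log10(ER), contribute the distance between their
#' midpoints; the estimate is the median of those distances, rounded to the
#' nearest integer.
#'
#' For symmetric end-read pileups this midpoint distance is close to
#' (fragment length - read length) rather than the fragment length itself;
#' the median distance is nevertheless used directly as the estimate, and
#' tags are extended by it downstream.
#'
#' @param tags Unextended tag tibble with both strands present.
#' @param chroms Optional chromosome table for bounds checking.
#' @param max_pairs Number of most-significant pairs used (default 200).
#' @param min_pairs Minimum acceptable pair count (default 20); below it an
#'   error advises supplying a fragment length explicitly.
#' @param max_log_er Per-strand log10(ER) ceiling above which regions are
#'   excluded (default 50).
#' @param measure Region depth measure for the per-strand fits (see
#'   [count_cumulative()]).
#' @return An object of class `fragment_estimate`: list with `length`
#'   (integer bp), `pairs_used` and `distances` (per-pair midpoint
#'   distances, bp).
#' @export
estimate_fragment_length <- function(tags, chroms = NULL, max_pairs = 200,
                                     min_pairs = 20, max_log_er = 50,
                                     measure = c("tag_count", "max_depth")) {
  measure <- match.arg(measure)
  tags <- validate_tags(tags, chroms)
  strand_regions <- function(s) {
    sub <- tags[tags$strand == s, ]
    if (nrow(sub) == 0L) {
      abort(sprintf("no tags on the %s strand; cannot estimate fragment length",
                    if (s == "+") "forward" else "reverse"),
            class = "occupeakr_fragment_error")
    }
    reg <- build_regions(sub)
    cnt <- count_cumulative(reg, measure = measure)
    fit <- fit_background(cnt)
    reg <- assign_significance(reg, cnt, fit, measure = measure)
    reg[reg$log_er <= max_log_er, ]
  }
  fwd <- strand_regions("+")
  rev <- strand_regions("-")
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    abort("no regions left after the log10(ER) artefact filter",
          class = "occupeakr_fragment_error")
  }

  pairs <- unique_overlap_pairs(fwd, rev)
  if (nrow(pairs) < min_pairs) {
    abort(sprintf(paste0(
      "only %d uniquely overlapping forward/reverse region pairs (need >= %d); ",
      "supply the fragment length explicitly"), nrow(pairs), min_pairs),
      class = "occupeakr_fragment_error")
  }
  pairs <- pairs[order(-pairs$significance), ]
  pairs <- head(pairs, max_pairs)
  med <- median(pairs$distance)
  if (med <= 0) {
    abort("median forward-to-reverse midpoint distance is not positive; strand orientation anomaly",
          class = "occupeakr_fragment_error")
  }
  out <- list(
    length = as.integer(round(med)),
    pairs_used = nrow(pairs),
    distances = pairs$distance
  )
  class(out) <- "fragment_estimate"
  out
}

# 1:1 overlapping forward/reverse region pairs across all chromosomes, with
# pair significance = min of the two strands' log10(ER) and midpoint distance
# (reverse midpoint minus forward midpoint).
unique_overlap_pairs <- function(fwd, rev) {
  per_chrom <- function(f, r) {
    fir <- IRanges::IRanges(f$start + 1, f$end)
    rir <- IRanges::IRanges(r$start + 1, r$end)
    hits <- IRanges::findOverlaps(fir, rir)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ok <- tabulate(q, length(fir))[q] == 1L & tabulate(s, length(rir))[s] == 1L
    q <- q[ok]; s <- s[ok]
    tibble::tibble(
      significance = pmin(f$log_er[q], r$log_er[s]),
      distance = (r$start[s] + r$end[s]) / 2 - (f$start[q] + f$end[q]) / 2
    )
  }
  chroms <- intersect(unique(fwd$chrom), unique(rev$chrom))
  purrr::map_dfr(chroms, function(cc) {
    per_chrom(fwd[fwd$chrom == cc, ], rev[rev$chrom == cc, ])
  })
}

#' @export
print.fragment_estimate <- function(x, ...) {
  cat(sprintf("Fragment length estimate: %d bp (median of %d pair distances)\n",
              x$length, x$pairs_used))
  invisible(x)
}

#' Extend tags 3' to the reconstructed fragment length
#'
#' Forward tags grow rightward from their start, reverse tags leftward from
#' their end, so both strands' tags come to cover the full original
#' fragment. Intervals are clamped to the chromosome. Strand is retained
#' for bookkeeping only; downstream peak calling merges the strands.
#'
#' @param tags Tag tibble.
#' @param length Fragment length in bp (> 0).
#' @param chroms Chromosome table (needed for right-end clamping).
#' @return Tag tibble with the same rows, extended.
#' @export
#' @examples
#' chroms <- tibble::tibble(chrom = "chr1", length = 1000)
#' tags <- tibble::tibble(chrom = "chr1", start = 100, end = 136, strand = "+")
#' extend_tags(tags, 200, chroms)
extend_tags <- function(tags, length, chroms) {
  if (length(length) != 1L || !is.finite(length) || length <= 0) {
    abort("fragment length must be a single positive number",
          class = "occupeakr_type_error")
  }
  chroms <- as_chrom_table(chroms)
  tags <- validate_tags(tags, chroms)
  if (nrow(tags) == 0L) return(tags)
  clen <- chroms$length[match(tags$chrom, chroms$chrom)]
  fwd <- tags$strand == "+"
  tags$end[fwd] <- pmin(tags$start[fwd] + length, clen[fwd])
  tags$start[!fwd] <- pmax(tags$end[!fwd] - length, 0)
  tags
}
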
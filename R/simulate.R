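#' Simulate a uniform background tag set
#'
#' Places `n_tags` single-end tags with 5' starts drawn uniformly over each
#' chromosome's mappable range (chromosomes weighted by length) and strands
#' drawn as fair coin flips — the null condition in which every genomic
#' position is equally likely to receive a tag. Deterministic for a fixed
#' seed.
#'
#' @param chroms Chromosome table.
#' @param n_tags Number of background tags.
#' @param read_length Read length in bp (default 36).
#' @param seed Integer RNG seed (mandatory; no global RNG state is used).
#' @return Tag tibble in generation order.
#' @export
#' @examples
#' chroms <- tibble::tibble(chrom = "chr1", length = 1e5)
#' tags <- simulate_background(chroms, 1000, seed = 1)
simulate_background <- function(chroms, n_tags, read_length = 36, seed) {
  chroms <- as_chrom_table(chroms)
  stopifnot(n_tags > 0, read_length > 0, all(chroms$length >= read_length))
  withr::with_seed(seed, sim_background_impl(chroms, n_tags, read_length))
}

sim_background_impl <- function(chroms, n_tags, read_length) {
  idx <- sample.int(nrow(chroms), n_tags, replace = TRUE,
                    prob = chroms$length)
  len <- chroms$length[idx]
  # uniform 5' start over the placements that keep the read on-chromosome
  start <- floor(runif(n_tags, min = 0, max = len - read_length + 1))
  start <- pmin(start, len - read_length)
  tibble::tibble(
    chrom = chroms$chrom[idx],
    start = start,
    end = start + read_length,
    strand = ifelse(runif(n_tags) < 0.5, "+", "-")
  )
}

#' Simulate a ChIP-seq tag set with known enriched loci
#'
#' Generates the uniform background of [simulate_background()] plus, for
#' each locus, `n_fragments` DNA fragments of `fragment_length` bp whose 5'
#' ends fall uniformly within half a fragment length of the locus centre.
#' Each fragment emits one single-end read: from the fragment's 5' end on
#' the forward strand or from its 3' end on the reverse strand, chosen per
#' fragment by `read_mode` (default a fair coin, as in single-end
#' sequencing of both fragment ends at random).
#'
#' @param chroms Chromosome table.
#' @param n_background Background tag count (0 allowed for pure spike-ins).
#' @param loci Tibble of enriched loci: `chrom`, `center` (0-based bp),
#'   `n_fragments`.
#' @param read_length Read length in bp (default 36).
#' @param fragment_length Fragment length in bp (default 200).
#' @param seed Integer RNG seed.
#' @param read_mode One of `"coin"` (each fragment reports one random end),
#'   `"both"` (both ends), `"forward"`, `"reverse"`.
#' @return List with `tags` (tag tibble: background first, then locus
#'   reads) and `truth` (tibble of ground-truth enriched intervals,
#'   overlapping loci merged with a warning).
#' @export
simulate_chipseq <- function(chroms, n_background, loci, read_length = 36,
                             fragment_length = 200, seed,
                             read_mode = c("coin", "both", "forward", "reverse")) {
  chroms <- as_chrom_table(chroms)
  read_mode <- match.arg(read_mode)
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("chrom", "center", "n_fragments") %in% names(loci)))
  clen <- chroms$length[match(loci$chrom, chroms$chrom)]
  if (anyNA(clen)) {
    abort("locus chromosome absent from chromosome table", class = "occupeakr_type_error")
  }
  half <- fragment_length / 2
  if (any(loci$center - half < 0) || any(loci$center + half + fragment_length > clen)) {
    abort("locus too close to a chromosome end for its fragment length",
          class = "occupeakr_type_error")
  }

  tags <- withr::with_seed(seed, {
    bg <- if (n_background > 0) {
      sim_background_impl(chroms, n_background, read_length)
    } else {
      tibble::tibble(chrom = character(0), start = numeric(0),
                     end = numeric(0), strand = character(0))
    }
    spike <- sim_loci_impl(loci, read_length, fragment_length, read_mode)
    dplyr::bind_rows(bg, spike)
  })

  truth <- tibble::tibble(
    chrom = loci$chrom,
    start = loci$center - half,
    end = loci$center + half + fragment_length
  )
  merged <- merge_intervals(truth)
  if (nrow(merged) < nrow(truth)) {
    warn(sprintf("%d overlapping truth loci merged into %d intervals",
                 nrow(truth), nrow(merged)))
    truth <- merged
  }
  list(tags = tags, truth = truth)
}

sim_loci_impl <- function(loci, read_length, fragment_length, read_mode) {
  total <- sum(loci$n_fragments)
  if (total == 0L) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0)))
  }
  chrom <- rep(loci$chrom, loci$n_fragments)
  center <- rep(loci$center, loci$n_fragments)
  half <- fragment_length / 2
  frag5 <- floor(runif(total, min = center - half, max = center + half + 1))
  fwd_read <- function(f5) tibble::tibble(chrom = chrom, start = f5,
                                          end = f5 + read_length, strand = "+")
  rev_read <- function(f5) tibble::tibble(chrom = chrom,
                                          start = f5 + fragment_length - read_length,
                                          end = f5 + fragment_length, strand = "-")
  switch(read_mode,
    coin = {
      side <- runif(total) < 0.5
      dplyr::bind_rows(fwd_read(frag5)[side, ], rev_read(frag5)[!side, ])
    },
    both = dplyr::bind_rows(fwd_read(frag5), rev_read(frag5)),
    forward = fwd_read(frag5),
    reverse = rev_read(frag5)
  )
}

# Union of strictly overlapping intervals (half-open) into connected
# components; abutting intervals share no coordinate and stay separate.
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  purrr::map_dfr(split(x, x$chrom), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end), min.gapwidth = 0L)
    tibble::tibble(chrom = g$chrom[1], start = IRanges::start(ir) - 1,
                   end = as.numeric(IRanges::end(ir)))
  }) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' The package's reference simulation scenario
#'
#' A 10 Mb chromosome with 1e5 uniform background tags of 36 bp and 100
#' evenly spaced enriched loci of 50 fragments each (fragment length
#' 200 bp), seed 7 — the standard test-bed used throughout the package's
#' tests for sensitivity and calibration checks.
#'
#' @return List of arguments accepted by [simulate_chipseq()].
#' @export
default_simulation_spec <- function() {
  list(
    chroms = tibble::tibble(chrom = "chrS", length = 1e7),
    n_background = 1e5,
    loci = tibble::tibble(
      chrom = "chrS",
      center = round(seq(5e4, 1e7 - 5e4, length.out = 100)),
      n_fragments = 50
    ),
    read_length = 36,
    fragment_length = 200,
    seed = 7
  )
}
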
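#' Build maximal coverage regions from tags
#'
#' A region is a maximal genomic interval in which every base is covered by
#' at least one tag. Each region is annotated with its maximum overlap depth
#' (the largest number of tags stacked on any single base — the model's n),
#' the number of contributing tags and its area (the summed lengths of the
#' contributing tags, in bp). Intervals are half-open, so tags that merely
#' abut end-to-start share no covered base and do not merge.
#'
#' @param tags Tag tibble (`chrom`, `start`, `end`, `strand`); strand is
#'   ignored here — filter beforehand for strand-specific regions.
#' @param chroms Optional chromosome table used to bounds-check coordinates.
#' @return A tibble of regions sorted by (chrom, start) with columns
#'   `chrom`, `start`, `end`, `max_depth`, `tag_count`, `area` and `log_er`
#'   (`NA` until filled by [assign_significance()]).
#' @export
#' @examples
#' tags <- tibble::tibble(chrom = "chr1", start = c(100, 100, 150),
#'                        end = c(136, 136, 186), strand = "+")
#' build_regions(tags)
build_regions <- function(tags, chroms = NULL) {
  tags <- validate_tags(tags, chroms)
  empty <- tibble::tibble(
    chrom = character(0), start = numeric(0), end = numeric(0),
    max_depth = integer(0), tag_count = integer(0), area = numeric(0),
    log_er = numeric(0)
  )
  if (nrow(tags) == 0L) return(empty)
  parts <- split(seq_len(nrow(tags)), tags$chrom) # sorted by chromosome name
  out <- lapply(names(parts), function(cc) {
    i <- parts[[cc]]
    reg <- build_regions_chrom(tags$start[i], tags$end[i]) # sorted by start
    tibble::add_column(reg, chrom = cc, .before = 1L)
  })
  dplyr::bind_rows(out)
}

# Coverage sweep for one chromosome via run-length-encoded pileup. Regions
# are connected components of strictly overlapping tags: min.gapwidth = 0
# keeps tags that merely abut (zero shared base) in separate regions.
build_regions_chrom <- function(start, end) {
  ir <- IRanges::IRanges(start = start + 1, end = end) # 1-based closed
  reg <- IRanges::reduce(ir, min.gapwidth = 0L)
  cov <- IRanges::coverage(ir)
  vw <- IRanges::Views(cov, reg)
  hits <- IRanges::findOverlaps(ir, reg) # every tag lies in exactly one region
  subj <- S4Vectors::subjectHits(hits)
  tibble::tibble(
    start = IRanges::start(reg) - 1,
    end = as.numeric(IRanges::end(reg)),
    max_depth = as.integer(IRanges::viewMaxs(vw)),
    tag_count = tabulate(subj, nbins = length(reg)),
    area = as.vector(rowsum(as.numeric(IRanges::width(ir)), subj)),
    log_er = NA_real_
  )
}

#' Cumulative region counts by overlap depth
#'
#' Counts N(n), the number of regions containing at least n overlapping
#' tags, for n = 1 up to the largest value observed (or `n_cap`). This
#' cumulative table is what the background model N(n) = p^n * A + B is
#' fitted to.
#'
#' Two readings of "a region with at least n overlapping tags" are
#' supported. The default, `measure = "tag_count"`, counts the tags that
#' form the region: for uniformly scattered tags the number of tags per
#' coverage clump is geometrically distributed, so the background model is
#' essentially exact under this reading. `measure = "max_depth"` instead
#' uses the largest number of tags stacked on any single base; it is kept
#' for sensitivity analysis but shows a visible geometric lack of fit on
#' uniform data.
#'
#' @param regions Region tibble from [build_regions()].
#' @param n_cap Optional largest depth to tabulate (the model fit uses
#'   n = 1..4; significance assignment needs the full table).
#' @param measure Region depth measure: `"tag_count"` (default) or
#'   `"max_depth"`.
#' @return A tibble with columns `n` and `N`, where `N` is non-increasing
#'   and `N[1]` equals the total number of regions.
#' @export
#' @examples
#' regions <- tibble::tibble(chrom = "chr1", start = 0, end = 1,
#'                           max_depth = c(1, 1, 2, 5), tag_count = c(1, 1, 2, 5),
#'                           area = 1, log_er = NA_real_)
#' count_cumulative(regions)
count_cumulative <- function(regions, n_cap = NULL,
                             measure = c("tag_count", "max_depth")) {
  measure <- match.arg(measure)
  if (nrow(regions) == 0L) {
    abort("cannot tabulate depths of an empty region set",
          class = "occupeakr_type_error")
  }
  d <- regions[[measure]]
  n_max <- max(d)
  if (!is.null(n_cap)) n_max <- min(n_max, n_cap)
  n <- seq_len(n_max)
  tibble::tibble(n = n, N = vapply(n, function(k) sum(d >= k), numeric(1)))
}
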
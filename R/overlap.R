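#' Flag intervals of one set that overlap another
#'
#' Overlap means at least one shared genome coordinate: with half-open
#' intervals, max(starts) < min(ends). Abutting intervals (end == start) do
#' not overlap.
#'
#' @param a,b Interval tibbles with `chrom`, `start`, `end` (half-open).
#' @return `a` with an added logical column `overlaps` marking rows that
#'   share at least one coordinate with some interval of `b`.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "c", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "c", start = c(199, 200), end = c(300, 400))
#' interval_overlaps(a, b) # overlaps: coordinate 199 is shared with b[1,]
interval_overlaps <- function(a, b) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  hit <- rep(FALSE, nrow(a))
  for (cc in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == cc)
    bi <- which(b$chrom == cc)
    air <- IRanges::IRanges(a$start[ai] + 1, a$end[ai])
    bir <- IRanges::IRanges(b$start[bi] + 1, b$end[bi])
    hit[ai] <- IRanges::overlapsAny(air, bir)
  }
  a$overlaps <- hit
  a
}

#' Merge peak sets from several sources into width-corrected merged peaks
#'
#' The union of all intervals is split into connected components ("merged
#' peaks"), which equalise peak-width differences between callers before
#' overlap comparisons. For each source, every merged peak records whether
#' the source called it and the most significant value among the source
#' peaks it absorbs (column 5 / `significance` when present, `log_er`
#' otherwise).
#'
#' @param sources Named list of peak tibbles (`chrom`, `start`, `end`,
#'   optional `significance` or `log_er`).
#' @return Tibble of disjoint merged peaks with, per source `s`, columns
#'   `s_present` and `s_best`.
#' @export
merge_peak_sets <- function(sources) {
  stopifnot(is.list(sources), length(sources) > 0, !is.null(names(sources)),
            all(nzchar(names(sources))))
  sources <- purrr::map(sources, tibble::as_tibble)
  all_iv <- dplyr::bind_rows(purrr::map(sources, ~ .x[, c("chrom", "start", "end")]))
  merged <- merge_intervals(all_iv)
  for (nm in names(sources)) {
    src <- sources[[nm]]
    sig <- if ("significance" %in% names(src)) src$significance
           else if ("log_er" %in% names(src)) src$log_er
           else rep(NA_real_, nrow(src))
    present <- rep(FALSE, nrow(merged))
    best <- rep(NA_real_, nrow(merged))
    for (cc in intersect(unique(merged$chrom), unique(src$chrom))) {
      mi <- which(merged$chrom == cc)
      si <- which(src$chrom == cc)
      mir <- IRanges::IRanges(merged$start[mi] + 1, merged$end[mi])
      sir <- IRanges::IRanges(src$start[si] + 1, src$end[si])
      hits <- IRanges::findOverlaps(sir, mir)
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      present[mi[unique(s)]] <- TRUE
      if (length(q) > 0L) {
        mx <- tapply(sig[si][q], s, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
        best[mi[as.integer(names(mx))]] <- as.numeric(mx)
      }
    }
    merged[[paste0(nm, "_present")]] <- present
    merged[[paste0(nm, "_best")]] <- best
  }
  merged
}

#' Two-sample Z-test for a difference in proportions
#'
#' Pooled-variance two-sample Z statistic for comparing overlap proportions
#' k1/n1 and k2/n2, with a two-sided p-value from the standard normal. When
#' the pooled proportion is degenerate (both 0 or both 1) the statistic is
#' 0 and p = 1.
#'
#' @param k1,n1 Successes and trials in sample 1.
#' @param k2,n2 Successes and trials in sample 2.
#' @return One-row tibble: `estimate1`, `estimate2`, `statistic` (z) and
#'   `p.value`.
#' @export
#' @examples
#' proportion_z_test(80, 100, 50, 100)
proportion_z_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(
    estimate1 = p1, estimate2 = p2,
    statistic = z,
    p.value = if (z == 0) 1 else 2 * pnorm(-abs(z))
  )
}
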
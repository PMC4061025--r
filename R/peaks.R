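#' Call peaks with the internal background model
#'
#' Runs the full pipeline on a tag table: optional PCR-duplicate removal;
#' fragment-length estimation from strand-separated pileups (unless a
#' length is supplied); 3' extension of all tags to that length; strand
#' merging; then, per sampling window (chromosome-wide by default),
#' coverage regions are built, the cumulative depth counts N(n) are fitted
#' with N(n) = p^n * A + B, and every region receives
#' log_er = log10(N_obs(n) / (p^n * A)) for its depth n. Regions with
#' log_er at or above `threshold` become peaks.
#'
#' When overlapping windows are used, each region is evaluated in the
#' window containing its midpoint, so no region is counted twice. Windows
#' whose counts cannot support a fit (e.g. no region of depth 4) are
#' skipped with a warning and flagged in the summary; if every window
#' fails, the run errors.
#'
#' @param tags Tag tibble (see [read_sam_tags()]).
#' @param chroms Chromosome table.
#' @param threshold log10 excess-ratio threshold; the default 2 calls
#'   regions with at least a 100-fold excess over background.
#' @param window_size Background-sampling window in bp, or `NULL` (default)
#'   for one window per chromosome.
#' @param fragment_length Fragment length in bp to extend tags to,
#'   bypassing estimation; `NULL` (default) estimates it from the data.
#' @param remove_dup If `TRUE`, collapse PCR duplicates first (default
#'   `FALSE`; duplicate removal is optional).
#' @param categories Peak colour bands: a tibble with columns `lower`
#'   (log_er band floor) and `rgb` ("r,g,b" strings); defaults to three
#'   bands starting at log_er 2, 5 and 10.
#' @param measure Region depth measure used for N(n) and significance:
#'   `"tag_count"` (default) or `"max_depth"` (see [count_cumulative()]).
#' @return An object of class `occupeak_calls`: list with `peaks` (tibble:
#'   `chrom`, `start`, `end`, `area`, `log_er`, `category_rgb`), `summary`
#'   (one row per window: fitted p, A, B, N(1..4), peak count and genome
#'   coverage), `fragment_length`, `threshold`, `window_size`. Has
#'   [tidy()], [glance()], `print()` and [autoplot()] methods.
#' @export
call_peaks <- function(tags, chroms, threshold = 2, window_size = NULL,
                       fragment_length = NULL, remove_dup = FALSE,
                       categories = NULL,
                       measure = c("tag_count", "max_depth")) {
  measure <- match.arg(measure)
  chroms <- as_chrom_table(chroms)
  tags <- validate_tags(tags, chroms)
  if (nrow(tags) == 0L) {
    abort("no tags supplied", class = "occupeakr_type_error")
  }
  categories <- categories %||% default_er_categories()
  if (remove_dup) tags <- remove_duplicates(tags)

  if (is.null(fragment_length)) {
    est <- estimate_fragment_length(tags, chroms, measure = measure)
    fragment_length <- est$length
    inform(sprintf("reconstructed fragment length: %d bp (from %d region pairs)",
                   est$length, est$pairs_used))
  }
  extended <- extend_tags(tags, fragment_length, chroms)

  regions <- build_regions(extended, chroms)
  windows <- partition_windows(chroms, window_size)
  win_of <- assign_window(regions, windows)

  summaries <- vector("list", nrow(windows))
  peak_rows <- vector("list", nrow(windows))
  n_ok <- 0L
  for (w in seq_len(nrow(windows))) {
    reg_w <- regions[which(win_of == w), ]
    res <- window_call(reg_w, windows[w, ], threshold, measure)
    if (is.null(res)) {
      warn(sprintf("window %s:%.0f-%.0f: insufficient background depth; skipped",
                   windows$chrom[w], windows$start[w], windows$end[w]))
      summaries[[w]] <- window_summary_row(windows[w, ], NULL, reg_w, NULL, measure)
    } else {
      n_ok <- n_ok + 1L
      peak_rows[[w]] <- res$peaks
      summaries[[w]] <- window_summary_row(windows[w, ], res$fit, reg_w, res$peaks, measure)
    }
  }
  if (n_ok == 0L) {
    abort("background fit failed in every window; no peaks can be called",
          class = "occupeakr_fit_error")
  }

  peaks <- dplyr::bind_rows(peak_rows)
  if (nrow(peaks) > 0L) {
    peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
    peaks$category_rgb <- er_category(peaks$log_er, categories)
  } else {
    peaks <- tibble::tibble(
      chrom = character(0), start = numeric(0), end = numeric(0),
      area = numeric(0), log_er = numeric(0), category_rgb = character(0)
    )
  }
  out <- list(
    peaks = peaks,
    summary = dplyr::bind_rows(summaries),
    fragment_length = fragment_length,
    threshold = threshold,
    window_size = window_size
  )
  class(out) <- "occupeak_calls"
  out
}

# Index (into windows) of the window owning each region: the first window on
# the region's chromosome containing the region midpoint.
assign_window <- function(regions, windows) {
  if (nrow(regions) == 0L) return(integer(0))
  out <- rep(NA_integer_, nrow(regions))
  for (cc in unique(regions$chrom)) {
    ri <- which(regions$chrom == cc)
    wi <- which(windows$chrom == cc)
    if (length(wi) == 0L) next
    mid <- floor((regions$start[ri] + regions$end[ri]) / 2)
    mir <- IRanges::IRanges(mid + 1, mid + 1)
    wir <- IRanges::IRanges(windows$start[wi] + 1, windows$end[wi])
    hit <- IRanges::findOverlaps(mir, wir, select = "first")
    out[ri] <- wi[hit]
  }
  out
}

# Fit + threshold inside one window; NULL when the counts cannot support a
# fit (caller skips the window).
window_call <- function(reg_w, window, threshold, measure) {
  if (nrow(reg_w) == 0L) return(NULL)
  counts <- count_cumulative(reg_w, measure = measure)
  fit <- tryCatch(fit_background(counts), occupeakr_fit_error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  reg_w <- assign_significance(reg_w, counts, fit, measure = measure)
  called <- reg_w[reg_w$log_er >= threshold, c("chrom", "start", "end", "area", "log_er")]
  list(fit = fit, counts = counts, peaks = called)
}

window_summary_row <- function(window, fit, reg_w, peaks, measure) {
  counts <- if (nrow(reg_w) > 0L) count_cumulative(reg_w, n_cap = 4, measure = measure) else NULL
  getN <- function(k) {
    if (is.null(counts)) return(NA_real_)
    v <- counts$N[match(k, counts$n)]
    ifelse(is.na(v), 0, v)
  }
  peak_bp <- if (is.null(peaks)) NA_real_ else sum(peaks$end - peaks$start)
  tibble::tibble(
    chrom = window$chrom, start = window$start, end = window$end,
    status = if (is.null(fit)) "skipped" else "ok",
    p = if (is.null(fit)) NA_real_ else fit$p,
    A = if (is.null(fit)) NA_real_ else fit$A,
    B = if (is.null(fit)) NA_real_ else fit$B,
    N1 = getN(1), N2 = getN(2), N3 = getN(3), N4 = getN(4),
    n_peaks = if (is.null(peaks)) NA_integer_ else nrow(peaks),
    peak_bp = peak_bp,
    # coverage over the window span and over the fitted mappable length
    coverage_window = peak_bp / (window$end - window$start),
    coverage_mappable = if (is.null(fit)) NA_real_ else peak_bp / fit$A
  )
}

#' Default excess-ratio colour bands
#'
#' Three bands of increasing significance for the BED itemRgb column:
#' log_er in \[2, 5) red, \[5, 10) blue, \[10, Inf) green. Override by
#' passing your own tibble of `lower` bounds and `rgb` strings to
#' [call_peaks()].
#'
#' @return Tibble with columns `lower` and `rgb`.
#' @export
default_er_categories <- function() {
  tibble::tibble(lower = c(2, 5, 10), rgb = c("255,0,0", "0,0,255", "0,128,0"))
}

er_category <- function(log_er, categories) {
  idx <- findInterval(log_er, categories$lower)
  idx[idx < 1L] <- 1L
  categories$rgb[idx]
}

#' Randomly subsample a tag table
#'
#' Keeps each tag independently with probability `fraction`, reproducibly
#' for a fixed seed. Used to study the effect of read density on peak
#' calling (e.g. 12.5/25/50/75% subsets).
#'
#' @param tags Tag tibble.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer RNG seed.
#' @return Subsampled tag tibble (order preserved).
#' @export
subsample_tags <- function(tags, fraction, seed) {
  tags <- validate_tags(tags)
  if (length(fraction) != 1L || !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "occupeakr_type_error")
  }
  if (fraction == 1) return(tags)
  keep <- withr::with_seed(seed, runif(nrow(tags)) < fraction)
  tags[keep, ]
}

#' @export
print.occupeak_calls <- function(x, ...) {
  cat(sprintf("Peak calls: %d peaks at log10(ER) >= %.2f (fragment length %d bp)\n",
              nrow(x$peaks), x$threshold, as.integer(x$fragment_length)))
  cat(sprintf("  windows: %d (%d fitted, %d skipped)\n",
              nrow(x$summary), sum(x$summary$status == "ok"),
              sum(x$summary$status == "skipped")))
  invisible(x)
}

#' @export
tidy.occupeak_calls <- function(x, ...) x$peaks

#' @export
glance.occupeak_calls <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$peaks),
    n_windows = nrow(x$summary),
    n_windows_skipped = sum(x$summary$status == "skipped"),
    fragment_length = as.integer(x$fragment_length),
    threshold = x$threshold,
    peak_bp = sum(x$peaks$end - x$peaks$start)
  )
}
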
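#' Partition chromosomes into background-sampling windows
#'
#' With `window_size = NULL` (the default) each chromosome is one window —
#' the recommended setting, since chromosome-wide background fits give the
#' better positive predictive value. Otherwise each chromosome of length L
#' gets k = ceiling(L / ws) windows of width ws whose starts are spread
#' uniformly, round(i * (L - ws) / (k - 1)) for i = 0..k-1, so the windows
#' jointly cover the chromosome with minimal overlap. A window size
#' exceeding the chromosome length falls back to a single chromosome-wide
#' window (with a message). Window sizes below 0.1 Mb are not recommended:
#' few background regions remain to fit.
#'
#' @param chroms Chromosome table.
#' @param window_size Window width in bp, or `NULL` for chromosome-wide.
#' @return Tibble of windows: `chrom`, `start`, `end` (0-based half-open).
#' @export
#' @examples
#' partition_windows(tibble::tibble(chrom = "c", length = 250), 100)
partition_windows <- function(chroms, window_size = NULL) {
  chroms <- as_chrom_table(chroms)
  if (is.null(window_size)) {
    return(tibble::tibble(chrom = chroms$chrom, start = 0, end = chroms$length))
  }
  if (length(window_size) != 1L || !is.finite(window_size) || window_size <= 0) {
    abort("window_size must be a single positive number or NULL",
          class = "occupeakr_type_error")
  }
  purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    ws <- window_size
    if (ws >= len) {
      if (ws > len) {
        inform(sprintf("window size %.0f exceeds %s length %.0f; using one chromosome-wide window",
                       ws, chroms$chrom[i], len))
      }
      return(tibble::tibble(chrom = chroms$chrom[i], start = 0, end = len))
    }
    k <- ceiling(len / ws)
    starts <- round((0:(k - 1)) * (len - ws) / (k - 1))
    tibble::tibble(chrom = chroms$chrom[i], start = starts, end = starts + ws)
  })
}
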
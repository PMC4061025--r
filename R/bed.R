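#' Write called peaks as a nine-column BED file
#'
#' Header comment lines record the reconstructed fragment length and the
#' applied log10(ER) threshold, followed by a UCSC track line enabling
#' itemRgb. Body columns: chrom, start, end, area (summed tag lengths in
#' bp), log10(ER) with two decimals, then three unused placeholders
#' (".", 0, 0) keeping the itemRgb column ninth, and the RGB colour of the
#' peak's excess-ratio band. [read_peak_bed()] inverts this losslessly.
#'
#' @param x An `occupeak_calls` object, or a peak tibble with columns
#'   `chrom`, `start`, `end`, `area`, `log_er`, `category_rgb`.
#' @param path Output path.
#' @param fragment_length,threshold Recorded in the header; taken from `x`
#'   when it is an `occupeak_calls` object.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(x, path, fragment_length = NA, threshold = NA) {
  if (inherits(x, "occupeak_calls")) {
    fragment_length <- x$fragment_length
    threshold <- x$threshold
    x <- x$peaks
  }
  peaks <- tibble::as_tibble(x)
  if (nrow(peaks) > 0L) {
    ord <- order(peaks$chrom, peaks$start, peaks$end)
    peaks <- peaks[ord, ]
    if (anyDuplicated(peaks[, c("chrom", "start", "end")])) {
      abort("duplicate peak intervals; refusing to write", class = "occupeakr_io_error")
    }
  }
  header <- c(
    sprintf("# fragment_length=%s",
            if (is.na(fragment_length)) "NA" else sprintf("%d", as.integer(fragment_length))),
    sprintf("# log10_er_threshold=%s",
            if (is.na(threshold)) "NA" else sprintf("%.2f", threshold)),
    "track name=\"occupeakr_peaks\" itemRgb=\"On\""
  )
  body <- if (nrow(peaks) > 0L) {
    sprintf("%s\t%.0f\t%.0f\t%.0f\t%.2f\t.\t0\t0\t%s",
            peaks$chrom, peaks$start, peaks$end, peaks$area, peaks$log_er,
            peaks$category_rgb)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a peak BED file written by [write_peak_bed()]
#'
#' @param path Path to the BED file.
#' @return A peak tibble (`chrom`, `start`, `end`, `area`, `log_er`,
#'   `category_rgb`) with the header's fragment length and threshold in
#'   attributes `fragment_length` and `threshold`.
#' @export
read_peak_bed <- function(path) {
  lines <- readLines(path)
  frag <- NA_integer_
  thr <- NA_real_
  m <- grep("^# fragment_length=", lines, value = TRUE)
  if (length(m) > 0L) frag <- suppressWarnings(as.integer(sub(".*=", "", m[1])))
  m <- grep("^# log10_er_threshold=", lines, value = TRUE)
  if (length(m) > 0L) thr <- suppressWarnings(as.numeric(sub(".*=", "", m[1])))
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (length(body) == 0L) {
    peaks <- tibble::tibble(
      chrom = character(0), start = numeric(0), end = numeric(0),
      area = numeric(0), log_er = numeric(0), category_rgb = character(0)
    )
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 9L)) {
      abort(sprintf("malformed peak BED row %d: expected 9 columns",
                    which(lengths(parts) < 9L)[1]),
            class = "occupeakr_io_error")
    }
    getf <- function(i) vapply(parts, `[[`, character(1), i)
    peaks <- tibble::tibble(
      chrom = getf(1L),
      start = as.numeric(getf(2L)),
      end = as.numeric(getf(3L)),
      area = as.numeric(getf(4L)),
      log_er = as.numeric(getf(5L)),
      category_rgb = getf(9L)
    )
  }
  attr(peaks, "fragment_length") <- frag
  attr(peaks, "threshold") <- thr
  peaks
}

#' Read a generic BED file of intervals
#'
#' Accepts any BED with at least three columns; column 4 is kept as `name`
#' and numeric column 5 as `significance` when present. Track and comment
#' lines are skipped.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end` and, when available, `name`
#'   and `significance`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                  !startsWith(lines, "browser") & nzchar(lines)]
  if (length(body) == 0L) {
    return(tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort(sprintf("malformed BED row %d: fewer than 3 columns",
                  which(lengths(parts) < 3L)[1]),
          class = "occupeakr_io_error")
  }
  getf <- function(i) vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_,
                             character(1))
  out <- tibble::tibble(
    chrom = getf(1L),
    start = as.numeric(getf(2L)),
    end = as.numeric(getf(3L))
  )
  if (all(lengths(parts) >= 4L)) out$name <- getf(4L)
  if (all(lengths(parts) >= 5L)) out$significance <- suppressWarnings(as.numeric(getf(5L)))
  out
}

#' Write intervals as a minimal BED3 file
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  writeLines(sprintf("%s\t%.0f\t%.0f", intervals$chrom, intervals$start,
                     intervals$end), path)
  invisible(path)
}
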
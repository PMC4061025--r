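#' Read a chromosome-lengths file
#'
#' Reads a two-column text file of chromosome name and length in bp, one
#' chromosome per line (the format shipped with UCSC "chrom.sizes" files),
#' separated by whitespace.
#'
#' @param path Path to the text file.
#' @return A tibble with columns `chrom` (character) and `length` (double),
#'   in file order.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t10000", "chr2\t5000"), f)
#' read_chrom_table(f)
read_chrom_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("chromosome-lengths file is empty", class = "occupeakr_io_error")
  }
  parts <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    abort(
      sprintf("malformed chromosome-lengths line %d: expected 'name length'", bad[1]),
      class = "occupeakr_io_error"
    )
  }
  chroms <- tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1L),
    length = suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  )
  as_chrom_table(chroms)
}

#' Validate and normalise a chromosome table
#'
#' @param x A data frame with columns `chrom` and `length`.
#' @return A validated tibble with unique chromosome names and positive
#'   integer lengths.
#' @export
as_chrom_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("chrom", "length") %in% names(x))) {
    abort("a chromosome table needs columns `chrom` and `length`",
          class = "occupeakr_type_error")
  }
  if (anyDuplicated(x$chrom)) {
    abort("duplicated chromosome names in chromosome table",
          class = "occupeakr_type_error")
  }
  if (any(!is.finite(x$length)) || any(x$length <= 0) || any(x$length != floor(x$length))) {
    abort("chromosome lengths must be positive integers",
          class = "occupeakr_type_error")
  }
  dplyr::select(x, "chrom", "length")
}

# Internal: check a tag tibble has the expected columns and, when a
# chromosome table is supplied, that coordinates fall inside the chromosomes.
validate_tags <- function(tags, chroms = NULL, arg = "tags") {
  tags <- tibble::as_tibble(tags)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(tags))) {
    abort(sprintf("`%s` needs columns chrom, start, end, strand", arg),
          class = "occupeakr_type_error")
  }
  if (nrow(tags) > 0L) {
    if (any(tags$start < 0) || any(tags$end <= tags$start)) {
      abort(sprintf("`%s` has intervals violating 0 <= start < end", arg),
            class = "occupeakr_type_error")
    }
    if (!all(tags$strand %in% c("+", "-"))) {
      abort(sprintf("`%s` strand must be '+' or '-'", arg),
            class = "occupeakr_type_error")
    }
    if (!is.null(chroms)) {
      chroms <- as_chrom_table(chroms)
      len <- chroms$length[match(tags$chrom, chroms$chrom)]
      if (anyNA(len)) {
        missing <- unique(tags$chrom[is.na(len)])
        abort(sprintf("`%s` uses chromosomes absent from the chromosome table: %s",
                      arg, paste(missing, collapse = ", ")),
              class = "occupeakr_type_error")
      }
      if (any(tags$end > len)) {
        abort(sprintf("`%s` has intervals extending past the chromosome end", arg),
              class = "occupeakr_type_error")
      }
    }
  }
  tags
}
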
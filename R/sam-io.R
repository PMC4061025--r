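#' Read single-end SAM alignments into a tag table
#'
#' Converts mapped, primary SAM records into tags: strand-aware genomic
#' intervals in 0-based half-open coordinates. The strand comes from the
#' reverse-complement flag (0x10); unmapped (0x4), secondary (0x100) and
#' supplementary (0x800) records are skipped. The interval width is the
#' reference span of the CIGAR string (operations M, D, N, =, X), falling
#' back to the SEQ length when the CIGAR is `*`.
#'
#' Records on chromosomes absent from `chroms` are skipped and their count
#' reported via a message, so alignment files containing scaffolds can be
#' restricted to the chromosomes of interest simply by omitting the
#' scaffolds from the lengths file.
#'
#' @param path Path to a SAM file (headered or headerless).
#' @param chroms Chromosome table (see [read_chrom_table()]).
#' @return A tibble of tags with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"`/`"-"`), in file order.
#' @export
read_sam_tags <- function(path, chroms) {
  chroms <- as_chrom_table(chroms)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body) == 0L) {
    abort("no tags: SAM file contains no alignment records",
          class = "occupeakr_io_error")
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0L) {
    abort(sprintf("malformed SAM line %d: fewer than 11 fields", body[short[1]]),
          class = "occupeakr_io_error")
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- suppressWarnings(as.integer(getf(2L)))
  pos <- suppressWarnings(as.numeric(getf(4L)))
  bad <- which(is.na(flag) | is.na(pos))
  if (length(bad) > 0L) {
    abort(sprintf("malformed SAM line %d: non-numeric FLAG or POS", body[bad[1]]),
          class = "occupeakr_io_error")
  }
  rname <- getf(3L)
  cigar <- getf(6L)
  seq <- getf(10L)

  mapped <- bitwAnd(flag, 0x4L) == 0L & rname != "*" &
    bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  known <- rname %in% chroms$chrom
  n_unknown <- sum(mapped & !known)
  if (n_unknown > 0L) {
    inform(sprintf("skipped %d record(s) on chromosomes absent from the chromosome table",
                   n_unknown))
  }
  keep <- mapped & known
  if (!any(keep)) {
    abort("no tags: SAM file contains no mapped records on known chromosomes",
          class = "occupeakr_io_error")
  }

  width <- cigar_ref_width(cigar[keep])
  no_cigar <- is.na(width)
  if (any(no_cigar)) {
    sw <- nchar(seq[keep])
    sw[seq[keep] == "*"] <- NA_integer_
    width[no_cigar] <- sw[no_cigar]
    if (anyNA(width)) {
      first <- body[keep][which(is.na(width))[1]]
      abort(sprintf("malformed SAM line %d: cannot determine alignment length (CIGAR and SEQ both '*')",
                    first),
            class = "occupeakr_io_error")
    }
  }

  tags <- tibble::tibble(
    chrom = rname[keep],
    start = pos[keep] - 1,
    end = pos[keep] - 1 + width,
    strand = ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+")
  )
  validate_tags(tags, chroms)
}

# Reference span of CIGAR strings; NA for "*".
cigar_ref_width <- function(cigar) {
  out <- rep(NA_real_, length(cigar))
  todo <- cigar != "*"
  if (!any(todo)) return(out)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar[todo], perl = TRUE)
  ops <- regmatches(cigar[todo], m)
  out[todo] <- vapply(ops, function(o) {
    if (length(o) == 0L) return(NA_real_)
    len <- as.numeric(sub(".$", "", o))
    code <- substr(o, nchar(o), nchar(o))
    sum(len[code %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
  out
}

#' Write a tag table as a SAM file
#'
#' Emits a minimal valid single-end SAM file: an `@HD`/`@SQ` header built
#' from the chromosome table, then one record per tag with the 1-based POS,
#' a pure-match CIGAR of the tag width and the reverse flag set for
#' minus-strand tags. Sequences and qualities are written as `*` (tags are
#' coordinates, not base calls). [read_sam_tags()] inverts this exactly.
#'
#' @param tags Tag tibble (`chrom`, `start`, `end`, `strand`).
#' @param chroms Chromosome table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_tags <- function(tags, chroms, path) {
  chroms <- as_chrom_table(chroms)
  tags <- validate_tags(tags, chroms)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%.0f", chroms$chrom, chroms$length)
  )
  if (nrow(tags) > 0L) {
    recs <- sprintf(
      "t%06d\t%d\t%s\t%.0f\t255\t%.0fM\t*\t0\t0\t*\t*",
      seq_len(nrow(tags)),
      ifelse(tags$strand == "-", 16L, 0L),
      tags$chrom,
      tags$start + 1,
      tags$end - tags$start
    )
  } else {
    recs <- character(0)
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Remove PCR duplicates from a tag table
#'
#' Keeps at most one tag per (chromosome, 5' position, strand) key. The 5'
#' position is the start for forward tags and the end for reverse tags, so
#' reads of varying trimmed length that stem from the same fragment end
#' collapse onto one key. Order-stable: the first occurrence survives.
#' Apply before any 3' extension.
#'
#' @param tags Tag tibble.
#' @return Tag tibble with duplicates dropped.
#' @export
#' @examples
#' tags <- tibble::tibble(
#'   chrom = "chr1", start = c(100, 100, 100), end = c(136, 136, 136),
#'   strand = c("+", "+", "-")
#' )
#' remove_duplicates(tags) # one forward + one reverse survive
remove_duplicates <- function(tags) {
  tags <- validate_tags(tags)
  if (nrow(tags) == 0L) return(tags)
  pos5 <- ifelse(tags$strand == "+", tags$start, tags$end)
  key <- paste(tags$chrom, pos5, tags$strand, sep = "\r")
  tags[!duplicated(key), ]
}
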
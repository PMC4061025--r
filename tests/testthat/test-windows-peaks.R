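test_that("window partition follows the uniform minimal-overlap layout", {
  w <- partition_windows(tibble::tibble(chrom = "c", length = 250), 100)
  expect_equal(w$start, c(0, 75, 150))
  expect_equal(w$end, c(100, 175, 250))

  two <- partition_windows(tibble::tibble(chrom = c("a", "b"),
                                          length = c(500, 700)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$end, c(500, 700))

  # window larger than the chromosome: one chromosome-wide window, a message
  expect_message(
    big <- partition_windows(tibble::tibble(chrom = "c", length = 250), 400),
    "chromosome-wide")
  expect_equal(big$end, 250)
})

test_that("window partitions cover every chromosome with bounded overlap", {
  set.seed(3)
  for (rep in 1:200) {
    len <- sample(10:10000, 1)
    ws <- sample(1:len, 1)
    w <- partition_windows(tibble::tibble(chrom = "c", length = len), ws)
    covered <- logical(len)
    for (i in seq_len(nrow(w))) covered[(w$start[i] + 1):w$end[i]] <- TRUE
    expect_true(all(covered))
    expect_true(all(w$end - w$start <= max(ws, len)))
    if (nrow(w) > 1) {
      expect_true(all(w$start[-1] > w$start[-nrow(w)] - ws)) # overlap < ws
    }
  }
})

spiked <- do.call(simulate_chipseq, default_simulation_spec())
chrS <- tibble::tibble(chrom = "chrS", length = 1e7)

test_that("raising the threshold only removes peaks", {
  t2 <- call_peaks(spiked$tags, chrS, threshold = 2, fragment_length = 36)
  t4 <- call_peaks(spiked$tags, chrS, threshold = 4, fragment_length = 36)
  expect_lt(nrow(t4$peaks), nrow(t2$peaks))
  key <- function(p) paste(p$chrom, p$start, p$end)
  expect_true(all(key(t4$peaks) %in% key(t2$peaks)))
  tinf <- call_peaks(spiked$tags, chrS, threshold = Inf, fragment_length = 36)
  expect_equal(nrow(tinf$peaks), 0L)
})

test_that("small sampling windows gain almost no peaks over chromosome-wide", {
  cw <- call_peaks(spiked$tags, chrS, fragment_length = 36)
  sw <- call_peaks(spiked$tags, chrS, fragment_length = 36, window_size = 1e5)
  gained <- interval_overlaps(sw$peaks, cw$peaks)
  expect_lte(sum(!gained$overlaps), 0.05 * nrow(cw$peaks))
})

test_that("per-window summaries report the fit and peak bookkeeping", {
  cw <- call_peaks(spiked$tags, chrS, fragment_length = 36)
  s <- cw$summary
  expect_equal(nrow(s), 1L)
  expect_equal(s$status, "ok")
  expect_true(s$p > 0 && s$p < 1 && s$A > 0 && s$B >= 0)
  expect_equal(s$n_peaks, nrow(cw$peaks))
  expect_equal(s$peak_bp, sum(cw$peaks$end - cw$peaks$start))
  gl <- glance(cw)
  expect_equal(gl$n_peaks, nrow(cw$peaks))
  expect_identical(tidy(cw), cw$peaks)
})

test_that("subsampled datasets keep only true enriched loci among their peaks", {
  sub <- subsample_tags(spiked$tags, 0.125, seed = 99)
  expect_equal(nrow(subsample_tags(spiked$tags, 1, seed = 1)), nrow(spiked$tags))
  expect_identical(sub, subsample_tags(spiked$tags, 0.125, seed = 99))
  n <- nrow(spiked$tags)
  expect_lt(abs(nrow(sub) - 0.125 * n), 3 * sqrt(n * 0.125 * 0.875))
  cs <- call_peaks(sub, chrS, fragment_length = 36)
  full <- call_peaks(spiked$tags, chrS, fragment_length = 36)
  expect_lt(nrow(cs$peaks), nrow(full$peaks)) # reduced power
  if (nrow(cs$peaks) > 0) {
    hit <- interval_overlaps(cs$peaks, spiked$truth)
    expect_true(all(hit$overlaps))
  }
})

test_that("peak BED output is formatted and round-trips losslessly", {
  peaks <- tibble::tibble(
    chrom = c("chr1", "chr1"), start = c(1000, 5000), end = c(1600, 5400),
    area = c(7200, 900), log_er = c(3.41, 11.2),
    category_rgb = c("255,0,0", "0,128,0")
  )
  f <- tempfile(fileext = ".bed")
  write_peak_bed(peaks, f, fragment_length = 164, threshold = 2)
  lines <- readLines(f)
  expect_equal(lines[4], "chr1\t1000\t1600\t7200\t3.41\t.\t0\t0\t255,0,0")
  expect_true(any(grepl("fragment_length=164", lines)))
  expect_true(any(grepl("log10_er_threshold=2.00", lines)))

  back <- read_peak_bed(f)
  expect_equal(attr(back, "fragment_length"), 164L)
  expect_equal(attr(back, "threshold"), 2)
  f2 <- tempfile(fileext = ".bed")
  write_peak_bed(back, f2, fragment_length = attr(back, "fragment_length"),
                 threshold = attr(back, "threshold"))
  expect_identical(readLines(f), readLines(f2))

  # empty peak set: header-only file
  f3 <- tempfile(fileext = ".bed")
  write_peak_bed(peaks[0, ], f3, fragment_length = 164, threshold = 2)
  expect_equal(length(readLines(f3)), 3L)
  expect_equal(nrow(read_peak_bed(f3)), 0L)

  # duplicate intervals refuse to serialise
  dup <- peaks[c(1, 1), ]
  expect_error(write_peak_bed(dup, tempfile()), "duplicate")
})

test_that("peak colours follow the excess-ratio bands", {
  cats <- default_er_categories()
  expect_equal(occupeakr:::er_category(c(2.1, 5, 25), cats),
               c("255,0,0", "0,0,255", "0,128,0"))
  cw <- call_peaks(spiked$tags, chrS, fragment_length = 36)
  expect_true(all(cw$peaks$category_rgb %in% cats$rgb))
})

test_that("a run where no window can be fitted errors out", {
  few <- tibble::tibble(chrom = "c", start = c(0, 100, 200), end = c(36, 136, 236),
                        strand = "+")
  expect_error(
    suppressWarnings(call_peaks(few, toy_chroms(1000, "c"), fragment_length = 36)),
    "every window")
})
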
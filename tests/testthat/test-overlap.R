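test_that("overlap means a shared coordinate under half-open intervals", {
  a <- tibble::tibble(chrom = "c", start = 100, end = 200)
  expect_true(interval_overlaps(a, tibble::tibble(chrom = "c", start = 199,
                                                  end = 300))$overlaps)
  expect_false(interval_overlaps(a, tibble::tibble(chrom = "c", start = 200,
                                                   end = 300))$overlaps)
  # chromosomes partition the genome: same coordinates, different chrom
  expect_false(interval_overlaps(a, tibble::tibble(chrom = "d", start = 100,
                                                   end = 200))$overlaps)
})

test_that("overlap flags agree with the brute-force oracle on random sets", {
  set.seed(17)
  for (rep in 1:10) {
    mk <- function(n) {
      s <- sample(0:5000, n, replace = TRUE)
      tibble::tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     start = s, end = s + sample(1:300, n, replace = TRUE))
    }
    a <- mk(40); b <- mk(25)
    expect_equal(interval_overlaps(a, b)$overlaps, oracle_overlaps(a, b))
    # the predicate is symmetric across the two sets
    expect_equal(interval_overlaps(b, a)$overlaps, oracle_overlaps(b, a))
  }
})

test_that("merged peaks are the connected components of the union", {
  one <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(50, 150),
                        log_er = c(3, 4))
  m1 <- merge_peak_sets(list(x = one))
  expect_equal(m1[, c("start", "end")],
               tibble::tibble(start = c(0, 100), end = c(50, 150)),
               ignore_attr = TRUE)
  expect_true(all(m1$x_present))
  expect_equal(m1$x_best, c(3, 4))

  two <- tibble::tibble(chrom = "c", start = 120, end = 220, log_er = 9)
  m2 <- merge_peak_sets(list(x = one, y = two))
  expect_equal(nrow(m2), 2L)
  joint <- m2[m2$start == 100, ]
  expect_equal(joint$end, 220)
  expect_true(joint$x_present && joint$y_present)
  expect_equal(joint$y_best, 9)
  solo <- m2[m2$start == 0, ]
  expect_false(solo$y_present)

  # when several source peaks hit one merged peak the most significant wins
  many <- tibble::tibble(chrom = "c", start = c(0, 30), end = c(40, 60),
                         log_er = c(2, 7))
  m3 <- merge_peak_sets(list(x = many))
  expect_equal(m3$x_best, 7)

  # idempotence: merging the merged set reproduces it
  again <- merge_peak_sets(list(m = m2[, c("chrom", "start", "end")]))
  expect_equal(again[, c("chrom", "start", "end")],
               m2[, c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("merged component structure matches a sort-based oracle", {
  set.seed(23)
  for (rep in 1:10) {
    s <- sample(0:3000, 60, replace = TRUE)
    x <- tibble::tibble(chrom = "c", start = s,
                        end = s + sample(1:200, 60, replace = TRUE))
    got <- merge_peak_sets(list(a = x))
    # oracle: sort, then sweep accumulating the running maximum end
    o <- x[order(x$start), ]
    comp_start <- o$start[1]; comp_end <- o$end[1]
    starts <- c(); ends <- c()
    for (i in 2:nrow(o)) {
      if (o$start[i] < comp_end) comp_end <- max(comp_end, o$end[i])
      else { starts <- c(starts, comp_start); ends <- c(ends, comp_end)
             comp_start <- o$start[i]; comp_end <- o$end[i] }
    }
    starts <- c(starts, comp_start); ends <- c(ends, comp_end)
    expect_equal(got$start, starts)
    expect_equal(got$end, ends)
  }
})

test_that("the pooled proportion Z-test behaves as the textbook formula", {
  eq <- proportion_z_test(30, 100, 60, 200)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  zt <- proportion_z_test(80, 100, 50, 100)
  expect_equal(zt$statistic, 4.4474959, tolerance = 1e-7)
  expect_equal(zt$p.value, 8.687712e-06, tolerance = 1e-6)
  # cross-check: z^2 equals the uncorrected chi-square statistic
  pt <- stats::prop.test(c(80, 50), c(100, 100), correct = FALSE)
  expect_equal(zt$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(zt$p.value, pt$p.value, tolerance = 1e-10)

  # antisymmetry
  sw <- proportion_z_test(50, 100, 80, 100)
  expect_equal(sw$statistic, -zt$statistic)
  expect_equal(sw$p.value, zt$p.value)

  # degenerate proportions
  expect_equal(proportion_z_test(0, 10, 0, 20)$p.value, 1)
  expect_equal(proportion_z_test(10, 10, 20, 20)$statistic, 0)
})

test_that("generic BED files read with optional name and significance", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=x",
               "c1\t0\t100\tpk1\t3.5",
               "c1\t200\t300\tpk2\t8.1"), f)
  b <- read_bed(f)
  expect_equal(b$significance, c(3.5, 8.1))
  writeLines(c("c1\t0\t100"), f)
  expect_equal(names(read_bed(f)), c("chrom", "start", "end"))
  writeLines(c("c1\t0"), f)
  expect_error(read_bed(f), "malformed")
})
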
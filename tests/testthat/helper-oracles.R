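# Independent oracles used across the suite. All deliberately naive
# (per-base arrays, O(n*m) double loops, dense grid search) so they share no
# code with the implementation they check.

# Naive oracle for coverage regions on one chromosome: tags sorted by
# start, swept into connected components of strictly overlapping tags
# (abutting tags share no base and start a new component), then a per-base
# depth array gives each component's maximum depth.
oracle_regions <- function(start, end, chrom_len) {
  depth <- integer(chrom_len)
  for (i in seq_along(start)) {
    idx <- (start[i] + 1):end[i]
    depth[idx] <- depth[idx] + 1L
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  comp <- integer(length(start))
  cur <- 1L; comp[1] <- 1L; cur_end <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] < cur_end) { # strict: equality means abutment
      comp[i] <- cur
      cur_end <- max(cur_end, end[i])
    } else {
      cur <- cur + 1L
      comp[i] <- cur
      cur_end <- end[i]
    }
  }
  out <- data.frame(start = tapply(start, comp, min),
                    end = tapply(end, comp, max),
                    tag_count = as.integer(tabulate(comp)),
                    area = as.numeric(tapply(end - start, comp, sum)))
  out$max_depth <- vapply(seq_len(nrow(out)), function(j) {
    max(depth[(out$start[j] + 1):out$end[j]])
  }, integer(1))
  rownames(out) <- NULL
  out[, c("start", "end", "max_depth", "tag_count", "area")]
}

# Direct cumulative counting of a depth vector.
oracle_count <- function(depths, n_max = max(depths)) {
  vapply(seq_len(n_max), function(k) sum(depths >= k), numeric(1))
}

# Dense grid search minimising the same log10 least-squares objective as
# fit_background, refined over three zoom levels around the incumbent.
oracle_grid_fit <- function(N) {
  obj <- function(p, A, B) {
    pred <- p^(1:4) * A + B
    if (any(pred <= 0)) return(Inf)
    sum((log10(pred) - log10(N))^2)
  }
  best <- list(val = Inf)
  p_rng <- c(1e-4, 0.9)
  A_rng <- c(N[1] / 10, N[1] * 100)
  B_rng <- c(0, N[4])
  for (zoom in 1:4) {
    ps <- seq(p_rng[1], p_rng[2], length.out = 25)
    As <- exp(seq(log(A_rng[1]), log(A_rng[2]), length.out = 25))
    Bs <- seq(B_rng[1], B_rng[2], length.out = 25)
    for (p in ps) for (A in As) for (B in Bs) {
      v <- obj(p, A, B)
      if (v < best$val) best <- list(val = v, p = p, A = A, B = B)
    }
    dp <- diff(p_rng) / 12; dA <- diff(log(A_rng)) / 12; dB <- diff(B_rng) / 12
    p_rng <- c(max(1e-6, best$p - dp), min(0.999, best$p + dp))
    A_rng <- exp(c(log(best$A) - dA, log(best$A) + dA))
    B_rng <- c(max(0, best$B - dB), best$B + dB)
  }
  best
}

# O(n*m) overlap flags: half-open intervals share a coordinate iff
# max(starts) < min(ends) on the same chromosome.
oracle_overlaps <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          max(a$start[i], b$start[j]) < min(a$end[i], b$end[j])) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# Exhaustive-pairing fragment-length oracle: per-base regions per strand,
# all-vs-all overlap pairing, symmetric uniqueness, ranking by the weaker
# member's tag count, top `max_pairs` midpoint distances, median. Fully
# independent of the package's IRanges/fit-based path.
oracle_fragment_length <- function(tags, chrom_len, max_pairs = 200) {
  f <- tags[tags$strand == "+", ]
  r <- tags[tags$strand == "-", ]
  fr <- oracle_regions(f$start, f$end, chrom_len)
  rr <- oracle_regions(r$start, r$end, chrom_len)
  n_f <- nrow(fr); n_r <- nrow(rr)
  cnt_f <- integer(n_f); cnt_r <- integer(n_r)
  pairs <- vector("list", n_f)
  for (i in seq_len(n_f)) { # every (i, j) combination is examined
    ov <- rr$start < fr$end[i] & fr$start[i] < rr$end
    js <- which(ov)
    cnt_f[i] <- length(js)
    cnt_r[js] <- cnt_r[js] + 1L
    pairs[[i]] <- lapply(js, function(j) c(i, j))
  }
  pairs <- unlist(pairs, recursive = FALSE)
  keep <- Filter(function(pr) cnt_f[pr[1]] == 1L && cnt_r[pr[2]] == 1L, pairs)
  sig <- vapply(keep, function(pr) min(fr$tag_count[pr[1]], rr$tag_count[pr[2]]),
                numeric(1))
  keep <- keep[order(-sig)]
  keep <- keep[seq_len(min(max_pairs, length(keep)))]
  dist <- vapply(keep, function(pr) {
    (rr$start[pr[2]] + rr$end[pr[2]]) / 2 - (fr$start[pr[1]] + fr$end[pr[1]]) / 2
  }, numeric(1))
  list(length = median(dist), pairs_used = length(keep))
}

# Random tag set on a toy chromosome for property tests.
random_tags <- function(n, chrom_len, read_len_range = c(10, 60), chrom = "t") {
  w <- sample(read_len_range[1]:read_len_range[2], n, replace = TRUE)
  s <- sample(0:(chrom_len - max(w)), n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = s, end = s + w,
                 strand = sample(c("+", "-"), n, replace = TRUE))
}

toy_chroms <- function(len = 1e5, chrom = "t") {
  tibble::tibble(chrom = chrom, length = len)
}

# Fragment-geometry simulation: enough enriched loci that the estimator's
# top-200 selection is saturated by true pairs (the regime the method
# assumes), with a light uniform background so the per-strand fits have
# background depth.
fragment_sim <- function(seed = 7, n_loci = 300, n_frag = 30,
                         fragment_length = 200, read_length = 36) {
  chroms <- tibble::tibble(chrom = "chrS", length = 1e7)
  loci <- tibble::tibble(
    chrom = "chrS",
    center = round(seq(2e4, 1e7 - 2e4, length.out = n_loci)),
    n_fragments = n_frag
  )
  sim <- simulate_chipseq(chroms, 2e4, loci, read_length = read_length,
                          fragment_length = fragment_length, seed = seed,
                          read_mode = "both")
  c(sim, list(chroms = chroms))
}
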
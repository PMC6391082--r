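peaks_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

test_that("stitching merges peaks within the gap and leaves distant peaks alone", {
  expect_equal(nrow(stitch_peaks(peaks_df(character(), numeric(), numeric()), 100)), 0L)

  one <- stitch_peaks(peaks_df("chr1", 100, 200), 1e6)
  expect_equal(one[, c("start", "end")], data.frame(start = 100, end = 200))
  expect_equal(one$constituent_count, 1L)

  two <- peaks_df("chr1", c(0, 200), c(100, 300))
  merged <- stitch_peaks(two, 150)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(0, 300))
  expect_equal(merged$constituent_count, 2L)
  apart <- stitch_peaks(two, 50)
  expect_equal(nrow(apart), 2L)
  expect_equal(apart$constituent_count, c(1L, 1L))

  expect_error(stitch_peaks(two, -1), "non-negative")
})

test_that("stitching matches the pairwise-merge oracle, is idempotent, and is monotone in distance", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:40, 1L)
    start <- sample(0:50000, n)
    peaks <- peaks_df(sample(c("chr1", "chr2"), n, replace = TRUE),
                      start, start + sample(100:2000, n, replace = TRUE))
    d <- sample(c(0, 100, 1000, 5000), 1L)
    got <- stitch_peaks(peaks, d)
    want <- oracle_stitch(peaks, d)
    expect_equal(got[, c("chrom", "start", "end")], want)
    # idempotence
    again <- stitch_peaks(got[, c("chrom", "start", "end")], d)
    expect_equal(again[, c("chrom", "start", "end")],
                 got[, c("chrom", "start", "end")])
    # gap contract
    by_chr <- split(got, got$chrom)
    for (b in by_chr) {
      if (nrow(b) > 1L) expect_true(all(b$start[-1L] - b$end[-nrow(b)] > d))
    }
    # monotonicity in stitch distance
    counts <- vapply(c(0, 200, 2000, 20000), function(dd)
      nrow(stitch_peaks(peaks, dd)), numeric(1L))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("region scoring subtracts input, clamps at zero, and sums densities", {
  regs <- stitch_peaks(peaks_df("chr1", c(0, 1000, 5000), c(100, 1100, 5100)), 10)
  scored <- score_regions(regs, treatment = c(10, 3, 5), control = c(4, 7, 5))
  expect_equal(scored$signal, c(6, 0, 0))

  # bedGraph mode: density x overlapped bases, hand-summed
  tr <- data.frame(chrom = "chr1", start = c(0, 50, 1000), end = c(50, 100, 1100),
                   value = c(0.2, 0.4, 0.1))
  ct <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(100, 1100),
                   value = c(0.1, 0.05))
  scored2 <- score_regions(regs, tr, ct)
  expect_equal(scored2$signal,
               c((50 * 0.2 + 50 * 0.4) - 100 * 0.1, 100 * 0.1 - 100 * 0.05, 0))

  expect_error(score_regions(regs, c(1, NA, 3), c(0, 0, 0)), "Missing treatment")
})

test_that("rank/cut handles flat landscapes and matches the quadratic-signal oracle", {
  flat <- data.frame(chrom = "chr1", start = 1:5 * 1000, end = 1:5 * 1000 + 100,
                     region_id = paste0("r", 1:5), constituent_count = 1L,
                     signal = rep(3, 5))
  expect_warning(rk <- rank_and_cut(flat), "egenerate")
  expect_false(any(rk$is_super))
  expect_setequal(rk$rank, 1:5)

  sq <- data.frame(chrom = "chr1", start = 1:50 * 1e4, end = 1:50 * 1e4 + 100,
                   region_id = paste0("r", 1:50), constituent_count = 1L,
                   signal = (1:50)^2)
  rk <- rank_and_cut(sq)
  expect_setequal(rk$signal[rk$is_super], oracle_super_set((1:50)^2))
  # rank 1 is the max signal
  expect_equal(rk$signal[rk$rank == 1L], 2500)
})

test_that("cutoff is scale invariant, the super set is an upper set, and the slope-scan oracle agrees for N <= 200", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:200, 1L)
    sig <- switch(sample(1:3, 1L),
                  stats::runif(n, 0, 10),
                  stats::rexp(n, 1),
                  c(stats::runif(n - min(3L, n - 1L), 0.5, 1.5),
                    stats::runif(min(3L, n - 1L), 8, 15)))
    regs <- data.frame(chrom = "chr1", start = seq_len(n) * 1e5,
                       end = seq_len(n) * 1e5 + 100,
                       region_id = paste0("r", seq_len(n)),
                       constituent_count = 1L, signal = sig)
    rk <- suppressWarnings(rank_and_cut(regs))
    expect_setequal(rk$signal[rk$is_super], oracle_super_set(sig))
    # scale invariance
    regs2 <- regs; regs2$signal <- sig * stats::runif(1, 0.01, 100)
    rk2 <- suppressWarnings(rank_and_cut(regs2))
    expect_equal(rk2$region_id[rk2$is_super], rk$region_id[rk$is_super])
    # upper set: every non-super signal <= every super signal
    if (any(rk$is_super))
      expect_true(max(c(rk$signal[!rk$is_super], -Inf)) <= min(rk$signal[rk$is_super]))
  }
})

test_that("planted super-enhancers are recovered exactly across seeds", {
  for (seed in 1:20) {
    land <- gen_enhancer_landscape(seed, n_background = 200L, n_super = 8L,
                                   super_fold = 10)
    res <- call_super_enhancers(land$peaks, land$treatment, land$control)
    called <- res$ranking$region_id[res$ranking$is_super]
    expect_setequal(called, land$truth$planted_supers)
  }
})

test_that("locus association reports distance, rank and strand-aware relative position", {
  rk <- data.frame(chrom = "chr1", start = c(10400, 20000), end = c(12000, 21000),
                   region_id = c("A", "B"), constituent_count = 1L,
                   signal = c(9, 10), rank = c(2L, 1L), is_super = TRUE)
  # locus inside a super-enhancer
  inside <- associate_locus(list(chrom = "chr1", start = 10500, end = 10600,
                                 name = "L", strand = "+"), rk)
  expect_equal(inside$distance_bp, 0)
  expect_equal(inside$relative_position, "overlapping")

  # minus-strand locus: 5' lies at higher coordinates
  minus <- associate_locus(list(chrom = "chr1", start = 10000, end = 10100,
                                name = "L", strand = "-"), rk)
  expect_equal(minus$distance_bp, 300)
  expect_equal(minus$relative_position, "upstream")
  expect_equal(minus$super_id, "A")

  # equidistant candidates resolve to the higher rank
  rk2 <- data.frame(chrom = "chr1", start = c(0, 1200), end = c(100, 1300),
                    region_id = c("lo", "hi"), constituent_count = 1L,
                    signal = c(5, 50), rank = c(2L, 1L), is_super = TRUE)
  tie <- associate_locus(list(chrom = "chr1", start = 600, end = 700,
                              name = "L", strand = "+"), rk2)
  expect_equal(tie$super_id, "hi")

  # cross-chromosome candidates are never matched
  expect_error(associate_locus(list(chrom = "chrX", start = 0, end = 100,
                                    name = "L", strand = "+"), rk),
               "chromosome")
  rk$is_super <- FALSE
  expect_error(associate_locus(list(chrom = "chr1", start = 0, end = 100,
                                    name = "L", strand = "+"), rk),
               "No super-enhancers")
})
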
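# minimal ordered-stats frame from a vector of densities (kmers per bp),
# densest first as select_y_contigs would emit
stats_from_density <- function(dens, eff_len = 10000L) {
  dens <- sort(dens, decreasing = TRUE)
  data.frame(rank = seq_along(dens),
             contig_id = sprintf("c%03d", seq_along(dens)),
             eff_len = eff_len, bp_per_kmer = 1 / dens)
}

test_that("the two-level step yields a single ratio near the density fold change", {
  st <- stats_from_density(c(rep(0.01, 5), rep(0.00333, 5)))
  scan <- ratio_scan(st, window = 5L)
  expect_identical(nrow(scan), 1L)
  expect_identical(scan$position, 5L)
  expect_equal(scan$ratio, 0.01 / 0.00333, tolerance = 1e-10)
  bp <- call_breakpoints(scan, peak_min_ratio = 1.5)
  expect_identical(bp, 5L)
})

test_that("a flat density profile scans to all-ones and no breakpoints", {
  st <- stats_from_density(rep(0.02, 14))
  scan <- ratio_scan(st, window = 5L)
  expect_identical(nrow(scan), 5L)  # n - 2w + 1
  expect_true(all(abs(scan$ratio - 1) < 1e-12))
  expect_identical(call_breakpoints(scan, 1.5), integer(0))
})

test_that("scan ratios equal a direct recomputation from the definition", {
  set.seed(401)
  for (w in c(3L, 5L)) {
    dens <- sort(stats::runif(25, 0.001, 0.05), decreasing = TRUE)
    st <- stats_from_density(dens)
    scan <- ratio_scan(st, window = w)
    n <- length(dens)
    expect_identical(scan$position, w:(n - w))
    for (r in seq_len(nrow(scan))) {
      i <- scan$position[r]
      trailing <- mean(dens[(i - w + 1):i])   # [i-w, i) in 0-based terms
      leading <- mean(dens[(i + 1):(i + w)])  # [i, i+w)
      expect_equal(scan$ratio[r], trailing / leading)
    }
  }
  expect_error(ratio_scan(stats_from_density(rep(0.01, 9)), window = 5L),
               "smaller window")
})

test_that("the reciprocal-scale convention averages bp-per-kmer instead", {
  dens <- c(rep(0.01, 5), rep(0.002, 5))
  st <- stats_from_density(dens)
  s1 <- ratio_scan(st, 5L)
  s2 <- ratio_scan(st, 5L, convention = "bp_per_kmer")
  expect_equal(s1$ratio, 5)
  expect_equal(s2$ratio, mean(1 / dens[6:10]) / mean(1 / dens[1:5]))
})

test_that("peaks are strict interior maxima with leftmost plateau ties", {
  mk_scan <- function(r) {
    out <- data.frame(position = seq(5L, by = 1L, length.out = length(r)),
                      trailing_mean = NA, leading_mean = NA, ratio = r)
    attr(out, "window") <- 5L
    class(out) <- c("density_scan", "data.frame")
    out
  }
  # plateau resolves to the leftmost position
  bp <- call_breakpoints(mk_scan(c(1, 1.1, 2, 2, 2, 1.2, 1)), 1.5,
                         min_separation = 2L)
  expect_identical(bp, 7L)
  # sub-threshold peaks are not called
  expect_identical(call_breakpoints(mk_scan(c(1, 1.4, 1.2, 1)), 1.3,
                                    min_separation = 1L), 6L)
  expect_identical(call_breakpoints(mk_scan(c(1, 1.4, 1.2, 1)), 1.5,
                                    min_separation = 1L), integer(0))
  # a ratio rising into the scan edge is a tail, not a peak
  expect_identical(call_breakpoints(mk_scan(c(1, 1.1, 1.3, 1.6, 1.9)), 1.5,
                                    min_separation = 2L), integer(0))
  # two separated peaks survive the separation constraint
  bp2 <- call_breakpoints(mk_scan(c(1, 3, 1, 1, 1, 1, 2.5, 1)), 1.5,
                          min_separation = 3L)
  expect_identical(bp2, c(6L, 11L))
})

test_that("blocks partition the ordered contigs at the breakpoints", {
  st <- stats_from_density(seq(0.05, 0.01, length.out = 10))
  blocks <- assign_blocks(st, 5L)
  expect_identical(blocks$blocks$n_contigs, c(5L, 5L))
  expect_identical(blocks$contigs$block_index, rep(1:2, each = 5))
  one <- assign_blocks(st)
  expect_identical(one$blocks$n_contigs, 10L)
  # partition: every contig in exactly one block, order preserved
  multi <- assign_blocks(st, c(2L, 7L))
  expect_identical(multi$contigs$contig_id, st$contig_id)
  expect_identical(as.integer(table(multi$contigs$block_index)), c(2L, 5L, 3L))
  expect_error(assign_blocks(st, c(7L, 2L)), "increasing")
  expect_error(assign_blocks(st, 10L), "inside")
  expect_error(assign_blocks(st, 0L), "inside")
})

test_that("block mean densities decrease with block index on sorted input", {
  set.seed(402)
  for (rep in 1:10) {
    dens <- sort(stats::rlnorm(30, -4, 1), decreasing = TRUE)
    st <- stats_from_density(dens)
    bps <- sort(sample(1:29, sample(0:3, 1)))
    blocks <- assign_blocks(st, bps)
    expect_true(all(diff(blocks$blocks$mean_density) < 0))
    expect_true(all(diff(blocks$blocks$mean_bp_per_kmer) > 0))
    # spans recompute directly
    expect_identical(blocks$blocks$total_span,
                     as.integer(tapply(st$eff_len, blocks$contigs$block_index,
                                       sum)))
  }
})

test_that("window choice does not matter below the stratum size", {
  dens <- c(rep(0.03, 8), rep(0.01, 8))
  for (w in 2:5) {
    scan <- ratio_scan(stats_from_density(dens), window = w)
    expect_identical(call_breakpoints(scan, 1.5, min_separation = w), 8L)
  }
})

test_that("planted strata are recovered from noisy planted densities", {
  # three strata with 3x density steps, >= 2*window contigs each, Poisson
  # counts around the planted mean; recovery of both boundaries within +/- 1
  set.seed(403)
  n_per <- 15L
  lambda <- c(160, 53, 18)  # planted kmers per 10 kb contig
  counts <- unlist(lapply(lambda, function(l) stats::rpois(n_per, l)))
  st <- stats_from_density(counts / 10000)
  scan <- ratio_scan(st, 5L)
  bps <- call_breakpoints(scan, 1.5, 5L)
  expect_identical(length(bps), 2L)
  expect_true(all(abs(sort(bps) - c(n_per, 2L * n_per)) <= 1L))
  blocks <- assign_blocks(st, bps)
  expect_identical(nrow(blocks$blocks), 3L)
})
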
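# build a kmer_count_table directly from a named integer vector of counts,
# keyed by canonical code
mock_table <- function(counts_by_code, sample_id, k = 16L) {
  codes <- as.numeric(names(counts_by_code))
  o <- order(codes)
  structure(list(sample_id = sample_id, k = k, canonical = TRUE,
                 codes = codes[o], counts = as.integer(counts_by_code)[o],
                 total_kmers = sum(as.numeric(counts_by_code))),
            class = "kmer_count_table")
}

test_that("find_error_trough locates the interior minimum between error peak and mode", {
  h <- data.frame(count = c(1L, 2L, 3L, 10L, 20L, 21L),
                  n_kmers = c(1000L, 300L, 50L, 20L, 400L, 380L))
  expect_identical(find_error_trough(h), 10L)
  # strictly decreasing histogram has no interior mode
  h2 <- data.frame(count = 1:3, n_kmers = c(100L, 50L, 10L))
  expect_error(find_error_trough(h2), "no trough")
  # ties break toward the smaller count
  h3 <- data.frame(count = c(1L, 2L, 4L, 6L, 12L),
                   n_kmers = c(900L, 40L, 40L, 90L, 300L))
  expect_identical(find_error_trough(h3), 2L)
})

test_that("trough of a simulated noisy sample separates errors from coverage", {
  cfg <- simulation_config(
    autosome_length = 30000L,
    strata = list(stratum_spec("s1", 30000L, 0.005)),
    contig_length = 10000L, n_pairs = 1L, coverage = 25, error_rate = 0.01,
    seed = 42L)
  region <- simulate_sex_region(cfg)
  reads <- simulate_reads(list(X = region$x_seq, Y = region$y_seq), cfg, "M1")
  hist <- coverage_histogram(count_kmers(unname(reads), k = 16L))
  trough <- find_error_trough(hist, smooth = TRUE)
  past <- hist$count > trough
  mode_count <- hist$count[past][which.max(hist$n_kmers[past])]
  expect_gt(trough, 2L)
  expect_lt(trough, mode_count)
  # the main mode sits near the shared-kmer depth (2 haplotypes x 25x,
  # corrected for the fraction of read windows a k-mer survives in)
  depth <- 2 * 25 * (cfg$read_length - 16 + 1) / cfg$read_length
  expect_lt(abs(mode_count - depth) / depth, 0.2)
})

test_that("the published six-sample cutoffs behave as inclusive bounds", {
  th <- paper_thresholds()
  codes <- as.character(1:4)
  tabs <- list(
    mock_table(stats::setNames(c(30L, 24L, 25L, 30L), codes), "refM"),
    mock_table(stats::setNames(c(0L, 0L, 21L, 22L), codes), "refF"),
    mock_table(stats::setNames(c(5L, 5L, 3L, 5L), codes), "M2"),
    mock_table(stats::setNames(c(2L, 2L, 9L, 2L), codes), "F2"),
    mock_table(stats::setNames(c(3L, 3L, 3L, 3L), codes), "M3"),
    mock_table(stats::setNames(c(0L, 0L, 8L, 0L), codes), "F3"))
  got <- select_male_specific(tabs, th)
  # kmer 1: all predicates pass; kmer 2: refM count 24 fails "more than 24";
  # kmer 3: every bound exactly at its inclusive limit; kmer 4: refF 22 > 21
  expect_identical(got$codes, c(1, 3))
})

test_that("selection equals direct predicate enumeration on random counts", {
  set.seed(201)
  n <- 10000L
  codes <- sort(sample(0:(4^16 - 1), n))
  counts <- sapply(1:6, function(i) sample(0:40, n, replace = TRUE))
  # force the documented boundary pairs into the pool
  counts[1:8, 1] <- c(24L, 25L, 30L, 30L, 30L, 30L, 30L, 30L)
  counts[1:8, 2] <- c(0L, 0L, 21L, 22L, 0L, 0L, 0L, 0L)
  counts[1:8, 3] <- c(9L, 9L, 9L, 9L, 2L, 3L, 9L, 9L)
  counts[1:8, 4] <- c(0L, 0L, 0L, 0L, 0L, 0L, 9L, 10L)
  th <- paper_thresholds()
  tabs <- lapply(1:6, function(i) {
    nz <- counts[, i] > 0L
    mock_table(stats::setNames(counts[nz, i], codes[nz]),
               th$sample_id[i])
  })
  got <- select_male_specific(tabs, th)
  want <- codes[counts[, 1] >= 25 & counts[, 2] <= 21 &
                  counts[, 3] >= 3 & counts[, 4] <= 9 &
                  counts[, 5] >= 3 & counts[, 6] <= 8]
  expect_identical(got$codes, want)
  # order invariance
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_identical(select_male_specific(tabs[perm], th)$codes, want)
})

test_that("thresholds act monotonically on the retained set", {
  set.seed(202)
  n <- 2000L
  codes <- sort(sample(0:(4^16 - 1), n))
  tabs <- list(
    mock_table(stats::setNames(sample(0:40, n, TRUE), codes), "M1"),
    mock_table(stats::setNames(sample(0:40, n, TRUE), codes), "F1"))
  base_th <- rbind(
    sample_thresholds("M1", "male", "reference", male_min = 10L),
    sample_thresholds("F1", "female", "reference", female_max = 5L))
  base <- select_male_specific(tabs, base_th)$codes
  up_f <- base_th; up_f$female_max[2] <- 8L
  expect_true(all(base %in% select_male_specific(tabs, up_f)$codes))
  up_m <- base_th; up_m$male_min[1] <- 15L
  expect_true(all(select_male_specific(tabs, up_m)$codes %in% base))
})

test_that("the literal female reading inverts the tolerance predicate", {
  codes <- as.character(1:3)
  tabs <- list(
    mock_table(stats::setNames(c(20L, 20L, 20L), codes), "M1"),
    mock_table(stats::setNames(c(0L, 5L, 12L), codes), "F1"))
  th <- rbind(sample_thresholds("M1", "male", "reference", male_min = 10L),
              sample_thresholds("F1", "female", "reference", female_max = 9L))
  expect_identical(select_male_specific(tabs, th)$codes, c(1, 2))
  expect_identical(select_male_specific(tabs, th, female_rule = "literal")$codes, 3)
})

test_that("degenerate sample designs are rejected", {
  tab <- mock_table(stats::setNames(5L, "1"), "M1")
  th_m <- sample_thresholds("M1", "male", "reference", male_min = 3L)
  expect_error(select_male_specific(list(tab), th_m), "female")
  tab_f <- mock_table(stats::setNames(5L, "1"), "F1")
  expect_error(
    select_male_specific(list(tab_f),
                         sample_thresholds("F1", "female", "reference",
                                           female_max = 2L)),
    "male")
  tab_k <- mock_table(stats::setNames(5L, "1"), "F1", k = 15L)
  th2 <- rbind(th_m, sample_thresholds("F1", "female", "reference",
                                       female_max = 2L))
  expect_error(select_male_specific(list(tab, tab_k), th2), "mix")
})
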
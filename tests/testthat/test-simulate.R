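small_cfg <- function(seed, strata = list(stratum_spec("s1", 20000L, 0.005)),
                      ...) {
  simulation_config(autosome_length = 20000L, strata = strata,
                    contig_length = 5000L, n_pairs = 1L, coverage = 8,
                    seed = seed, ...)
}

test_that("zero planted divergence leaves Y identical to X", {
  cfg <- small_cfg(7L, strata = list(stratum_spec("s0", 20000L, 0)))
  region <- simulate_sex_region(cfg)
  expect_identical(region$y_seq, region$x_seq)
  expect_identical(nrow(region$variants), 0L)
  em <- emit_phased_contigs(region, cfg)
  sexy <- em$truth$origin != "autosome"
  expect_true(all(em$truth$planted_kmer_count[sexy] == 0L))
})

test_that("variant counts are Poisson-scaled and exactly seed-reproducible", {
  cfg <- simulation_config(autosome_length = 10000L,
                           strata = list(stratum_spec("s1", 10000L, 0.002)),
                           contig_length = 10000L, n_pairs = 1L, coverage = 5,
                           seed = 99L)
  r1 <- simulate_sex_region(cfg)
  r2 <- simulate_sex_region(cfg)
  expect_identical(r1, r2)
  n <- r1$strata$n_variants
  # central 99% interval of Poisson(20)
  expect_true(n >= stats::qpois(0.005, 20) && n <= stats::qpois(0.995, 20))
  # substitutions always differ from the ancestral base
  xc <- strsplit(r1$x_seq, "")[[1]]; yc <- strsplit(r1$y_seq, "")[[1]]
  expect_identical(which(xc != yc) - 1L, r1$variants$pos)
  # pairwise spacing exceeds k so no window covers two variants
  expect_true(all(diff(r1$variants$pos) > cfg$k))
})

test_that("planted k-mer densities track the stratum density ratio", {
  cfg <- simulation_config(
    autosome_length = 10000L,
    strata = list(stratum_spec("hi", 100000L, 0.01),
                  stratum_spec("lo", 100000L, 0.00333)),
    contig_length = 10000L, n_pairs = 1L, coverage = 5, seed = 17L)
  region <- simulate_sex_region(cfg)
  em <- emit_phased_contigs(region, cfg)
  tr <- em$truth
  dens <- tapply(tr$planted_kmer_count, tr$origin, sum)[c("hi", "lo")] / 100000
  r <- dens[["hi"]] / dens[["lo"]]
  # expected 0.01/0.00333 = 3.003; 3 sigma of the Poisson counts either side
  n_hi <- 0.01 * 1e5; n_lo <- 0.00333 * 1e5
  tol <- 3 * 3.003 * sqrt(1 / n_hi + 1 / n_lo)
  expect_lt(abs(r - 3.003), tol)
})

test_that("planted counts match direct matching of planted k-mers", {
  cfg <- small_cfg(23L)
  region <- simulate_sex_region(cfg)
  em <- emit_phased_contigs(region, cfg)
  # the truly Y-specific vocabulary: canonical k-mers of Y absent from X
  ytab <- count_kmers(region$y_seq, k = cfg$k)
  xtab <- count_kmers(region$x_seq, k = cfg$k)
  yonly <- ytab$codes[lookup_counts(xtab, ytab$codes) == 0L]
  for (i in which(em$truth$origin != "autosome")) {
    ct <- em$contigs[[i]]
    yh <- em$truth$y_hap[i]
    got <- match_kmer_set(yonly, if (yh == 1L) ct$hap1 else ct$hap2,
                          k = cfg$k)$count
    expect_identical(got, em$truth$planted_kmer_count[i])
  }
})

test_that("contig emission randomises the Y haplotype and plants N runs", {
  cfg <- simulation_config(autosome_length = 10000L,
                           strata = list(stratum_spec("s1", 500000L, 0.002)),
                           contig_length = 5000L, n_pairs = 1L, coverage = 5,
                           seed = 31L)
  region <- simulate_sex_region(cfg)
  em <- emit_phased_contigs(region, cfg)
  tr <- em$truth[em$truth$origin != "autosome", ]
  expect_identical(nrow(tr), 100L)
  # Y haplotype index ~ Bernoulli(0.5): 3 sigma band around 50
  expect_lt(abs(sum(tr$y_hap == 1L) - 50), 3 * sqrt(100 * 0.25))
  # N-run contigs lose exactly 10% of effective length on both haplotypes
  has_n <- !is.na(tr$n_run_start)
  expect_gt(sum(has_n), 0L)
  for (i in which(em$truth$origin != "autosome" & !is.na(em$truth$n_run_start))) {
    expect_identical(effective_length(em$contigs[[i]]$hap1), 4500L)
    expect_identical(effective_length(em$contigs[[i]]$hap2), 4500L)
  }
})

test_that("a contig inside a zero-divergence stratum has identical haplotypes", {
  cfg <- small_cfg(13L, strata = list(stratum_spec("null", 20000L, 0)))
  region <- simulate_sex_region(cfg)
  em <- emit_phased_contigs(region, cfg)
  for (i in which(em$truth$origin == "null"))
    expect_identical(em$contigs[[i]]$hap1, em$contigs[[i]]$hap2)
})

test_that("read simulation hits the target depth and is error-free at rate 0", {
  cfg <- small_cfg(19L)
  region <- simulate_sex_region(cfg)
  reads <- simulate_reads(list(X = region$x_seq, Y = region$y_seq), cfg, "M1")
  per_hap <- table(sub("^M1_([A-Za-z]+)_.*$", "\\1", names(reads)))
  expected <- as.integer(round(cfg$coverage * 20000 / cfg$read_length))
  expect_identical(as.integer(per_hap[["X"]]), expected)
  expect_identical(as.integer(per_hap[["Y"]]), expected)
  # every read (or its reverse complement) is an exact substring of its source
  src <- c(X = region$x_seq, Y = region$y_seq)
  some <- sample(seq_along(reads), 50)
  for (i in some) {
    hap <- sub("^M1_([A-Za-z]+)_.*$", "\\1", names(reads)[i])
    hit <- grepl(reads[i], src[[hap]], fixed = TRUE) ||
      grepl(oracle_revcomp(reads[i]), src[[hap]], fixed = TRUE)
    expect_true(hit)
  }
})

test_that("per-base errors land at the configured rate", {
  cfg <- small_cfg(37L, error_rate = 0.01)
  region <- simulate_sex_region(cfg)
  reads <- simulate_reads(list(X = region$x_seq), cfg, "M1")
  # align by construction: regenerate the same starts/strands at rate 0
  cfg0 <- small_cfg(37L, error_rate = 0)
  clean <- simulate_reads(list(X = region$x_seq), cfg0, "M1")
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads, clean))
  total <- sum(nchar(reads))
  p_hat <- mism / total
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / total))
})

test_that("identical config and seed give byte-identical dataset files", {
  cfg <- small_cfg(41L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("substreams are independent: adding a pair leaves pair 1 untouched", {
  cfg1 <- small_cfg(43L)
  cfg2 <- simulation_config(autosome_length = 20000L,
                            strata = list(stratum_spec("s1", 20000L, 0.005)),
                            contig_length = 5000L, n_pairs = 2L, coverage = 8,
                            seed = 43L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg1, d1)
  simulate_dataset(cfg2, d2)
  for (f in c("reads/M1.fastq.gz", "reads/F1.fastq.gz", "assembly.fasta",
              "truth_contigs.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("overly dense strata are rejected with guidance", {
  cfg <- small_cfg(3L, strata = list(stratum_spec("dense", 20000L, 0.08)))
  expect_error(simulate_sex_region(cfg), "lower the density")
})

test_that("synthetic hit tables reduce to collinear best hits", {
  cfg <- small_cfg(47L, strata = list(stratum_spec("s1", 20000L, 0.01)))
  region <- simulate_sex_region(cfg)
  em <- emit_phased_contigs(region, cfg)
  hits <- simulate_synteny_hits(em$truth, seed = 47L)
  expect_true(all(c("qseqid", "sseqid", "bitscore", "rank_in_query") %in%
                    names(hits)))
  bh <- best_hits(hits)
  expect_true(all(bh$sseqid == "chr10"))
  yc <- em$truth[em$truth$origin != "autosome", ]
  expect_identical(sort(bh$qseqid), sort(yc$contig_id))
})
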
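BASES <- c("A", "C", "G", "T")

# Derive a per-stream sub-seed from the master seed, so each random stream
# (region, contigs, each sample's reads) is independent: adding a sample does
# not shift any other stream's output. Result always < 2^31 - 1.
substream_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) * 1009
  as.integer((as.numeric(seed) * 69091 + h) %% 2147483647)
}

random_dna_chars <- function(L) sample(BASES, L, replace = TRUE)

# Substitute the bases at `pos` (1-based) with a uniformly chosen different
# base; operates on a character vector of single bases.
substitute_bases <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  chars
}

# Poisson(density * L) variant positions with pairwise spacing > k, placed
# uniformly: n positions drawn without replacement from 1..(L - n*k), sorted,
# then spread by adding (i-1)*k to the i-th. The count is exactly
# Poisson-distributed (no thinning bias) and each substitution creates ~k
# novel k-mers with no window covering two variants.
place_spaced_variants <- function(L, density, k) {
  n <- stats::rpois(1L, density * L)
  if (n == 0L) return(integer(0))
  slack <- L - n * k
  if (slack < n)
    stop("variant density ", density, " too high to keep >k spacing over ",
         L, " bp; lower the density")
  x <- sort(sample.int(slack, n))
  x + (seq_len(n) - 1L) * k
}

#' Specify one Y stratum
#'
#' A stratum is a contiguous span of the simulated Y carrying male-specific
#' substitutions (relative to the shared X) at a fixed density — the
#' generative counterpart of a k-mer density block.
#'
#' @param name stratum label.
#' @param length span in bp.
#' @param variant_density substitutions per bp introduced on Y relative to X
#'   (0 to 0.1; e.g. 0.01 plants about one male-specific SNV per 100 bp).
#' @return a `stratum_spec` list.
#' @export
stratum_spec <- function(name, length, variant_density) {
  stopifnot(length >= 1, variant_density >= 0, variant_density <= 0.1)
  structure(list(name = name, length = as.integer(length),
                 variant_density = variant_density), class = "stratum_spec")
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: three strata of 200 kb each at variant densities 0.01 / 0.0033 /
#' 0.0011 (3x steps, i.e. 20 contigs of 10 kb per stratum), a 200 kb
#' autosomal background, three male/female pairs sequenced at 20x per
#' haplotype with 100 bp reads. `error_rate` defaults to 0 (noiseless
#' baseline); robustness runs use 0.01.
#'
#' @param autosome_length non-sex-linked background length in bp.
#' @param strata ordered list of [stratum_spec()]s (densest first by
#'   convention, though not required).
#' @param contig_length tile size for the phased assembly, bp.
#' @param n_pairs number of male/female pairs (first pair = reference).
#' @param coverage sequencing depth per haplotype.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate (< 0.05).
#' @param seed master seed (mandatory; all streams derive from it).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(autosome_length = 200000L,
                              strata = list(
                                stratum_spec("stratum1", 200000L, 0.01),
                                stratum_spec("stratum2", 200000L, 0.0033),
                                stratum_spec("stratum3", 200000L, 0.0011)),
                              contig_length = 10000L,
                              n_pairs = 3L,
                              coverage = 20,
                              read_length = 100L,
                              error_rate = 0,
                              k = 16L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(autosome_length > 0, contig_length > 0, n_pairs >= 1,
            coverage > 0, read_length > 0, error_rate >= 0, error_rate < 0.05,
            length(strata) >= 1)
  for (s in strata)
    if (s$length < contig_length)
      stop("stratum ", s$name, " shorter than contig_length")
  structure(list(autosome_length = as.integer(autosome_length),
                 strata = strata, contig_length = as.integer(contig_length),
                 n_pairs = as.integer(n_pairs), coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate the ancestral X and the stratified Y
#'
#' The X is uniform random DNA over the total stratum span; the Y is the X
#' with, per stratum, a Poisson number of substitutions at the stratum's
#' variant density, placed uniformly with pairwise spacing greater than k (so
#' each substitution creates about k Y-specific k-mers and no window covers
#' two variants). Substituted bases always differ from the original.
#'
#' @param cfg a [simulation_config()].
#' @return list with `x_seq`, `y_seq` (strings), `strata` (data.frame `name`,
#'   `start`, `end` 0-based half-open, `variant_density`, `n_variants`), and
#'   `variants` (data.frame `pos` 0-based on Y, `stratum`).
#' @export
simulate_sex_region <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "region"))
  L <- sum(vapply(cfg$strata, `[[`, integer(1), "length"))
  x <- random_dna_chars(L)
  y <- x
  offset <- 0L
  strata_rows <- list(); var_rows <- list()
  for (s in cfg$strata) {
    pos <- place_spaced_variants(s$length, s$variant_density, cfg$k)
    y[offset + pos] <- substitute_bases(y[offset + pos], seq_along(pos))
    strata_rows[[s$name]] <- data.frame(
      name = s$name, start = offset, end = offset + s$length,
      variant_density = s$variant_density, n_variants = length(pos))
    if (length(pos))
      var_rows[[s$name]] <- data.frame(pos = offset + pos - 1L,
                                       stratum = s$name)
    offset <- offset + s$length
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows)
              else data.frame(pos = integer(0), stratum = character(0))
  rownames(variants) <- NULL
  strata <- do.call(rbind, strata_rows); rownames(strata) <- NULL
  list(x_seq = paste(x, collapse = ""), y_seq = paste(y, collapse = ""),
       strata = strata, variants = variants)
}

# Planted-kmer count for a sex contig [a, b) (0-based on Y): number of
# k-windows inside the contig that cover >= 1 planted variant and no N.
# Variants are spaced > k apart, so windows of different variants are
# disjoint. n_run is a contig-local 0-based half-open N interval (or NULL).
planted_kmer_count <- function(a, b, k, var_pos, n_run = NULL) {
  v <- var_pos[var_pos >= a & var_pos < b]
  if (!length(v)) return(0L)
  total <- 0L
  for (p in v) {
    s_lo <- max(a, p - k + 1L); s_hi <- min(p, b - k)
    if (s_hi < s_lo) next
    starts <- s_lo:s_hi
    if (!is.null(n_run)) {
      na <- a + n_run[1]; nb <- a + n_run[2]
      if (p >= na && p < nb) next  # variant itself masked by N
      starts <- starts[starts + k <= na | starts >= nb]
    }
    total <- total + length(starts)
  }
  as.integer(total)
}

#' Tile the simulated genome into phased contigs
#'
#' The sex region is tiled into non-overlapping contigs of `contig_length`;
#' each sex contig's haplotype pair is (X window, Y window) with the
#' Y-carrying haplotype index randomised per contig. Autosomal contigs have
#' identical haplotypes except for rare heterozygous SNVs (density 0.001).
#' 5% of contigs receive a central N run covering 10% of their length (on
#' both haplotypes) to exercise effective-length bookkeeping.
#'
#' @param region output of [simulate_sex_region()].
#' @param cfg the [simulation_config()].
#' @param male_autosome optional list(hap1, hap2) of the reference male's
#'   autosome copies; generated here (shared background + het SNVs) when NULL.
#' @return list with `contigs` (list of [phased_contig()]), `truth`
#'   (data.frame: `contig_id`, `origin`, `y_hap`, `start`, `end`,
#'   `n_run_start`, `n_run_end`, `planted_kmer_count`), and `autosome`
#'   (the list(hap1, hap2) used, for read simulation).
#' @export
emit_phased_contigs <- function(region, cfg, male_autosome = NULL) {
  set.seed(substream_seed(cfg$seed, "contigs"))
  k <- cfg$k; cl <- cfg$contig_length
  if (is.null(male_autosome)) {
    auto <- random_dna_chars(cfg$autosome_length)
    snv <- sort(sample.int(cfg$autosome_length,
                           stats::rpois(1L, 0.001 * cfg$autosome_length)))
    auto2 <- substitute_bases(auto, snv)
    male_autosome <- list(hap1 = paste(auto, collapse = ""),
                          hap2 = paste(auto2, collapse = ""))
  }
  Lsex <- nchar(region$x_seq)
  n_sex <- Lsex %/% cl
  n_auto <- cfg$autosome_length %/% cl
  n_total <- n_sex + n_auto
  y_idx <- sample(c(1L, 2L), n_sex, replace = TRUE)
  n_run_flag <- stats::runif(n_total) < 0.05
  n_run_len <- as.integer(round(0.1 * cl))

  contigs <- vector("list", n_total)
  truth <- vector("list", n_total)
  stratum_of <- function(a) {
    s <- region$strata
    s$name[a >= s$start & a < s$end][1]
  }
  insert_n <- function(seq, start0, len) {
    paste0(substr(seq, 1, start0), strrep("N", len),
           substr(seq, start0 + len + 1, nchar(seq)))
  }
  for (i in seq_len(n_total)) {
    sex <- i <= n_sex
    if (sex) {
      a <- (i - 1L) * cl; b <- a + cl
      xw <- substr(region$x_seq, a + 1L, b)
      yw <- substr(region$y_seq, a + 1L, b)
      id <- sprintf("ctg%03d", i)
      origin <- stratum_of(a)
      yh <- y_idx[i]
      h1 <- if (yh == 1L) yw else xw
      h2 <- if (yh == 1L) xw else yw
    } else {
      j <- i - n_sex
      a <- (j - 1L) * cl; b <- a + cl
      h1 <- substr(male_autosome$hap1, a + 1L, b)
      h2 <- substr(male_autosome$hap2, a + 1L, b)
      id <- sprintf("aut%03d", j)
      origin <- "autosome"
      yh <- NA_integer_
    }
    nr <- c(NA_integer_, NA_integer_)
    if (n_run_flag[i]) {
      start0 <- as.integer((cl - n_run_len) %/% 2)
      h1 <- insert_n(h1, start0, n_run_len)
      h2 <- insert_n(h2, start0, n_run_len)
      nr <- c(start0, start0 + n_run_len)
    }
    pk <- if (sex)
      planted_kmer_count(a, b, k, region$variants$pos,
                         if (n_run_flag[i]) nr else NULL)
    else 0L
    contigs[[i]] <- phased_contig(id, h1, h2)
    truth[[i]] <- data.frame(contig_id = id, origin = origin, y_hap = yh,
                             start = a, end = b, n_run_start = nr[1],
                             n_run_end = nr[2], planted_kmer_count = pk,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(contigs = contigs, truth = truth, autosome = male_autosome)
}

#' Simulate uniform-coverage error-bearing reads from a set of haplotypes
#'
#' Uniform read start positions to the configured per-haplotype depth
#' (realised read count = round(coverage * length / read_length) per
#' haplotype), random strand, per-base substitution errors at `error_rate`.
#' Fully deterministic given the master seed and sample id.
#'
#' @param haplotypes named character vector (or list) of source sequences.
#' @param cfg the [simulation_config()].
#' @param sample_id sample label; also names the random substream.
#' @return character vector of reads (names = read ids).
#' @export
simulate_reads <- function(haplotypes, cfg, sample_id) {
  set.seed(substream_seed(cfg$seed, paste0("reads-", sample_id)))
  rl <- cfg$read_length
  out <- lapply(names(haplotypes), function(hn) {
    src <- haplotypes[[hn]]
    L <- nchar(src)
    n <- as.integer(round(cfg$coverage * L / rl))
    starts <- sample.int(L - rl + 1L, n, replace = TRUE)
    reads <- substring(src, starts, starts + rl - 1L)
    flip <- stats::runif(n) < 0.5
    if (any(flip))
      reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
    if (cfg$error_rate > 0) {
      hit <- which(stats::runif(n * rl) < cfg$error_rate)
      if (length(hit)) {
        ri <- (hit - 1L) %/% rl + 1L
        pp <- (hit - 1L) %% rl + 1L
        repl <- sample(BASES, length(hit), replace = TRUE)
        for (j in seq_along(hit)) {
          orig <- substr(reads[ri[j]], pp[j], pp[j])
          b <- repl[j]
          if (b == orig) b <- sample(setdiff(BASES, orig), 1L)
          substr(reads[ri[j]], pp[j], pp[j]) <- b
        }
      }
    }
    names(reads) <- sprintf("%s_%s_%06d", sample_id, hn, seq_len(n))
    reads
  })
  unlist(out)
}

write_fastq_gz <- function(reads, path, qual_char = "I") {
  rl <- nchar(reads)
  rec <- paste0("@", names(reads), "\n", reads, "\n+\n",
                vapply(rl, function(n) strrep(qual_char, n), character(1)))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Default per-sample thresholds for the synthetic study design
#'
#' At 20x per-haplotype depth, Y-specific k-mers sit near the hemizygous peak
#' (about 17x after window-length correction) while error k-mers sit at
#' counts 1-2; the reference male cut of 5 and additional-male cut of 3 sit
#' in the trough between the two, and `female_max = 2` tolerates the rare
#' error-generated appearance of a Y k-mer in a female read set.
#'
#' @param n_pairs number of male/female pairs (pair 1 = reference).
#' @return a `sample_thresholds` data.frame matching [simulate_dataset()]'s
#'   sample naming (`M1`, `F1`, `M2`, ...).
#' @export
synthetic_thresholds <- function(n_pairs = 3L) {
  out <- list(sample_thresholds("M1", "male", "reference", male_min = 5L),
              sample_thresholds("F1", "female", "reference", female_max = 2L))
  for (i in seq_len(n_pairs - 1L) + 1L) {
    out <- c(out, list(
      sample_thresholds(paste0("M", i), "male", "additional", male_min = 3L),
      sample_thresholds(paste0("F", i), "female", "additional",
                        female_max = 2L)))
  }
  do.call(rbind, out)
}

#' Generate a complete ground-truthed synthetic dataset on disk
#'
#' Simulates the stratified sex region and autosome, tiles the reference
#' male's phased assembly, and sequences every individual: male i carries
#' {X, Y} plus a diploid autosome, female i carries {X, X'} (X' = X with
#' heterozygous SNVs at density 0.001, individual-specific) plus a diploid
#' autosome. Pair 1's male is the assembled reference individual. Writes
#' gzipped FASTQ per sample, the phased-contig FASTA (`_1`/`_2` suffixes),
#' truth TSVs and the echoed configuration JSON; outputs are byte-identical
#' across runs with the same config and seed.
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return list with `cfg`, `samples` (data.frame: `sample_id`, `sex`,
#'   `role`, `path`), `assembly_path`, `region`, `truth` (per-contig
#'   data.frame), `contigs`.
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "reads"), showWarnings = FALSE)
  region <- simulate_sex_region(cfg)
  emitted <- emit_phased_contigs(region, cfg)

  # phased assembly FASTA
  assembly_path <- file.path(outdir, "assembly.fasta")
  seqs <- unlist(lapply(emitted$contigs, function(ct)
    stats::setNames(c(ct$hap1, ct$hap2),
                    paste0(ct$contig_id, c("_1", "_2")))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), assembly_path,
                              width = 80L)

  # per-individual genotypes and reads
  samples <- list()
  for (i in seq_len(cfg$n_pairs)) {
    mid <- paste0("M", i); fid <- paste0("F", i)
    if (i == 1L) {
      m_auto <- emitted$autosome
    } else {
      set.seed(substream_seed(cfg$seed, paste0("auto-", mid)))
      m_auto <- list(hap1 = emitted$autosome$hap1,
                     hap2 = local({
                       ch <- strsplit(emitted$autosome$hap1, "")[[1]]
                       snv <- sort(sample.int(length(ch),
                                              stats::rpois(1L, 0.001 * length(ch))))
                       paste(substitute_bases(ch, snv), collapse = "")
                     }))
    }
    set.seed(substream_seed(cfg$seed, paste0("xprime-", fid)))
    xch <- strsplit(region$x_seq, "")[[1]]
    snv <- sort(sample.int(length(xch),
                           stats::rpois(1L, 0.001 * length(xch))))
    x_prime <- paste(substitute_bases(xch, snv), collapse = "")
    set.seed(substream_seed(cfg$seed, paste0("auto-", fid)))
    f_auto2 <- local({
      ch <- strsplit(emitted$autosome$hap1, "")[[1]]
      snv <- sort(sample.int(length(ch),
                             stats::rpois(1L, 0.001 * length(ch))))
      paste(substitute_bases(ch, snv), collapse = "")
    })

    m_haps <- list(X = region$x_seq, Y = region$y_seq,
                   autoA = m_auto$hap1, autoB = m_auto$hap2)
    f_haps <- list(X = region$x_seq, Xp = x_prime,
                   autoA = emitted$autosome$hap1, autoB = f_auto2)
    for (s in list(list(id = mid, sex = "male", haps = m_haps),
                   list(id = fid, sex = "female", haps = f_haps))) {
      reads <- simulate_reads(s$haps, cfg, s$id)
      p <- file.path(outdir, "reads", paste0(s$id, ".fastq.gz"))
      write_fastq_gz(reads, p)
      samples[[s$id]] <- data.frame(
        sample_id = s$id, sex = s$sex,
        role = if (i == 1L) "reference" else "additional", path = p,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, samples); rownames(samples) <- NULL

  utils::write.table(emitted$truth, file.path(outdir, "truth_contigs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(region$strata, file.path(outdir, "truth_strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(region$variants, file.path(outdir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_json <- cfg
  cfg_json$strata <- lapply(cfg$strata, unclass)
  jsonlite::write_json(unclass(cfg_json), file.path(outdir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(cfg = cfg, samples = samples, assembly_path = assembly_path,
       region = region, truth = emitted$truth, contigs = emitted$contigs)
}

#' Simulate a best-hit table for synteny anchoring (synthetic)
#'
#' Stand-in for a tabular protein/nucleotide alignment of Y contigs against
#' an annotated reference: each Y-origin contig receives a primary hit on
#' `chrom` at a position collinear with its position on the simulated Y
#' (plus jitter), and a fraction of contigs receive lower-scoring secondary
#' hits on decoy chromosomes. Purely synthetic — exercises the best-hit
#' reduction and collinearity reporting.
#'
#' @param truth per-contig truth data.frame from [simulate_dataset()].
#' @param seed integer seed.
#' @param chrom primary reference chromosome name.
#' @param offset reference bp corresponding to Y position 0.
#' @param jitter sd of Gaussian jitter on anchor positions, bp.
#' @return data.frame in the 12-column tabular hit dialect.
#' @export
simulate_synteny_hits <- function(truth, seed, chrom = "chr10",
                                  offset = 15e6, jitter = 2000) {
  set.seed(substream_seed(seed, "synteny"))
  yc <- truth[truth$origin != "autosome", , drop = FALSE]
  rows <- lapply(seq_len(nrow(yc)), function(i) {
    mid <- offset + (yc$start[i] + yc$end[i]) / 2 +
      round(stats::rnorm(1, 0, jitter))
    len <- 400L + sample.int(400L, 1L)
    primary <- data.frame(
      qseqid = yc$contig_id[i], sseqid = chrom, pident = 85 + stats::runif(1) * 10,
      length = len, mismatch = sample.int(20L, 1L), gapopen = sample.int(3L, 1L),
      qstart = 1L, qend = len, sstart = as.integer(mid - len / 2),
      send = as.integer(mid + len / 2), evalue = 1e-50,
      bitscore = 200 + stats::runif(1) * 100, stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.2) {
      decoy <- primary
      decoy$sseqid <- sample(c("chr2", "chr3", "chr13"), 1L)
      decoy$sstart <- sample.int(3e7, 1L)
      decoy$send <- decoy$sstart + len
      decoy$bitscore <- primary$bitscore - 50 - stats::runif(1) * 50
      rbind(primary, decoy)
    } else primary
  })
  out <- do.call(rbind, rows)
  out$rank_in_query <- stats::ave(seq_len(nrow(out)), out$qseqid,
                                  FUN = seq_along)
  rownames(out) <- NULL
  out
}
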
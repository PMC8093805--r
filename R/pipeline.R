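#' Pipeline configuration
#'
#' One namespace for every stage parameter, so thresholds cannot drift
#' between stages. `samples` combines the read manifest with the per-sample
#' count thresholds.
#'
#' @param samples data.frame with columns `sample_id`, `sex`, `role`, `path`
#'   (FASTQ/FASTA, possibly gzipped).
#' @param thresholds a `sample_thresholds` data.frame covering every sample.
#' @param assembly path to the phased assembly FASTA.
#' @param hap_pattern haplotype-suffix regex (see [read_phased_fasta()]).
#' @param k k-mer length.
#' @param canonical strand-collapsed counting/matching.
#' @param selection a [y_selection_config()].
#' @param window,peak_min_ratio,min_separation segmentation parameters (see
#'   [ratio_scan()] and [call_breakpoints()]).
#' @param hits optional tabular alignment hits path for synteny anchoring.
#' @param female_rule see [select_male_specific()].
#' @param outdir output directory.
#' @param write_counts also write each sample's full k-mer count table TSV
#'   (large; off by default).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(samples, thresholds, assembly,
                            hap_pattern = "_([12])$", k = 16L,
                            canonical = TRUE,
                            selection = y_selection_config(),
                            window = 5L, peak_min_ratio = 1.5,
                            min_separation = window,
                            hits = NULL, female_rule = "exceeds",
                            outdir, write_counts = FALSE) {
  stopifnot(all(c("sample_id", "sex", "role", "path") %in% names(samples)))
  structure(list(samples = samples, thresholds = thresholds,
                 assembly = assembly, hap_pattern = hap_pattern,
                 k = as.integer(k), canonical = canonical,
                 selection = selection, window = as.integer(window),
                 peak_min_ratio = peak_min_ratio,
                 min_separation = as.integer(min_separation),
                 hits = hits, female_rule = female_rule, outdir = outdir,
                 write_counts = write_counts),
            class = "pipeline_config")
}

stage_wrap <- function(stage, outdir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(outdir, ".partial")
    writeLines(sprintf("failed_stage=%s", stage), marker)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full strata-detection pipeline
#'
#' Stages: per-sample k-mer counting, male-specific filtering, per-contig
#' scoring, Y-contig selection, density-ratio segmentation into k-mer density
#' blocks, and (when a hits file is configured) synteny anchoring. Every
#' intermediate table is written to `outdir` as TSV, plus a `manifest.json`
#' recording input checksums, parameters and per-stage record counts. With an
#' empty male-specific set (or fewer selected contigs than the scan needs)
#' later stages are skipped cleanly and the manifest says so. Outputs are
#' byte-identical across re-runs with an identical config.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress messages (stderr).
#' @return (invisibly) list with `manifest`, `tables`, `kmer_set`, `stats`,
#'   `selected`, `scan`, `breakpoints`, `blocks`, `anchors`, `collinearity`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(cfg$outdir, ".partial"))
  t0 <- Sys.time()

  # -- count ---------------------------------------------------------------
  tables <- stage_wrap("count", cfg$outdir, {
    lapply(seq_len(nrow(cfg$samples)), function(i) {
      s <- cfg$samples[i, ]
      say("[count] %s (%s)", s$sample_id, s$path)
      tab <- count_kmers(s$path, k = cfg$k, canonical = cfg$canonical,
                         sample_id = s$sample_id)
      if (isTRUE(cfg$write_counts))
        write_kmer_table(tab, file.path(cfg$outdir,
                                        paste0("counts_", s$sample_id, ".tsv")))
      tab
    })
  })

  # -- filter --------------------------------------------------------------
  kmer_set <- stage_wrap("filter", cfg$outdir, {
    say("[filter] deriving male-specific k-mer set")
    select_male_specific(tables, cfg$thresholds,
                         female_rule = cfg$female_rule)
  })
  write_kmer_set(kmer_set, file.path(cfg$outdir, "male_specific_kmers.tsv"))

  # -- score ---------------------------------------------------------------
  scored <- stage_wrap("score", cfg$outdir, {
    say("[score] matching %d k-mers against the phased assembly",
        length(kmer_set$codes))
    contigs <- read_phased_fasta(cfg$assembly, cfg$hap_pattern)
    score_contigs(contigs, kmer_set, canonical = cfg$canonical)
  })

  # -- select --------------------------------------------------------------
  selected <- stage_wrap("select", cfg$outdir, {
    select_y_contigs(scored, cfg$selection)
  })
  stats_out <- scored
  stats_out$selected <- scored$contig_id %in% selected$contig_id
  utils::write.table(stats_out, file.path(cfg$outdir, "contig_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("[select] %d / %d contigs selected as Y-linked",
      nrow(selected), nrow(scored))

  # -- segment -------------------------------------------------------------
  scan <- NULL; breakpoints <- integer(0); blocks <- NULL
  if (nrow(selected) >= 2L * cfg$window) {
    seg <- stage_wrap("segment", cfg$outdir, {
      scan <- ratio_scan(selected, window = cfg$window)
      bps <- call_breakpoints(scan, peak_min_ratio = cfg$peak_min_ratio,
                              min_separation = cfg$min_separation)
      list(scan = scan, breakpoints = bps,
           blocks = assign_blocks(selected, bps))
    })
    scan <- seg$scan; breakpoints <- seg$breakpoints; blocks <- seg$blocks
    write_scan_tsv(scan, file.path(cfg$outdir, "density_scan.tsv"))
    write_blocks_tsv(blocks, file.path(cfg$outdir, "blocks.tsv"))
    say("[segment] %d breakpoints -> %d blocks", length(breakpoints),
        nrow(blocks$blocks))
  } else if (nrow(selected) > 0L) {
    blocks <- stage_wrap("segment", cfg$outdir,
                         assign_blocks(selected, integer(0)))
    write_blocks_tsv(blocks, file.path(cfg$outdir, "blocks.tsv"))
    say("[segment] too few contigs for a window-%d scan; one block",
        cfg$window)
  } else {
    say("[segment] no contigs selected; segmentation not attempted")
  }

  # -- anchor --------------------------------------------------------------
  anchors <- NULL; collin <- NULL
  if (!is.null(cfg$hits) && !is.null(blocks)) {
    res <- stage_wrap("anchor", cfg$outdir, {
      hits <- if (is.character(cfg$hits)) read_blast_tab(cfg$hits)
              else cfg$hits
      a <- synteny_anchors(hits, blocks)
      list(anchors = a, collin = collinearity_report(a, blocks))
    })
    anchors <- res$anchors; collin <- res$collin
    utils::write.table(anchors, file.path(cfg$outdir, "anchors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(collin, file.path(cfg$outdir, "collinearity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    parameters = list(
      k = cfg$k, canonical = cfg$canonical,
      selection = unclass(cfg$selection), window = cfg$window,
      peak_min_ratio = cfg$peak_min_ratio,
      min_separation = cfg$min_separation,
      female_rule = cfg$female_rule,
      thresholds = cfg$thresholds),
    inputs = list(
      samples = cfg$samples,
      sample_md5 = as.list(tools::md5sum(cfg$samples$path)),
      assembly = cfg$assembly,
      assembly_md5 = unname(tools::md5sum(cfg$assembly))),
    counts = list(
      kmers_per_sample = stats::setNames(
        lapply(tables, function(t) length(t$codes)),
        vapply(tables, function(t) t$sample_id, character(1))),
      male_specific_kmers = length(kmer_set$codes),
      contigs_scored = nrow(scored),
      contigs_with_matches = sum(scored$kmers_hap1 + scored$kmers_hap2 > 0),
      contigs_ratio_pass = sum(!is.na(scored$y_hap) &
                                 scored$ratio >= cfg$selection$min_ratio),
      contigs_selected = nrow(selected),
      breakpoints = length(breakpoints),
      blocks = if (is.null(blocks)) 0L else nrow(blocks$blocks)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  say("[done] %.1f s elapsed", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(manifest = manifest, tables = tables, kmer_set = kmer_set,
                 stats = stats_out, selected = selected, scan = scan,
                 breakpoints = breakpoints, blocks = blocks,
                 anchors = anchors, collinearity = collin))
}

#' Compare a pipeline result with simulation ground truth
#'
#' Summarises end-to-end recovery: Y-haplotype assignment accuracy over
#' selected sex-region contigs, number of blocks vs planted strata, the
#' agreement between block membership and planted stratum membership (after
#' matching each block to its majority stratum), and the offset of each
#' called breakpoint from the nearest truth boundary in the density-sorted
#' order.
#'
#' @param result return value of [run_pipeline()].
#' @param truth per-contig truth data.frame from [simulate_dataset()].
#' @return list with `n_selected`, `n_true_y`, `false_positives`,
#'   `hap_accuracy`, `n_blocks`, `n_strata`, `membership_agreement`,
#'   `breakpoint_offsets`.
#' @export
evaluate_against_truth <- function(result, truth) {
  sel <- result$selected
  tr <- truth[match(sel$contig_id, truth$contig_id), ]
  is_y <- tr$origin != "autosome"
  hap_acc <- if (any(is_y))
    mean(sel$y_hap[is_y] == tr$y_hap[is_y]) else NA_real_
  n_strata <- length(unique(truth$origin[truth$origin != "autosome"]))
  n_blocks <- if (is.null(result$blocks)) 0L else nrow(result$blocks$blocks)

  membership <- NA_real_; offsets <- integer(0)
  if (!is.null(result$blocks)) {
    bc <- result$blocks$contigs
    bt <- truth$origin[match(bc$contig_id, truth$contig_id)]
    # majority-stratum label per block, then fraction of contigs whose
    # block's label matches their planted stratum
    lab <- vapply(split(bt, bc$block_index), function(x)
      names(sort(table(x), decreasing = TRUE))[1], character(1))
    membership <- mean(lab[as.character(bc$block_index)] == bt)
    # truth boundaries in the density-sorted order: cumulative stratum sizes
    ord_strata <- bt[!duplicated(bt)]
    sizes <- as.integer(table(bt)[ord_strata])
    tb <- cumsum(sizes)[-length(sizes)]
    if (length(result$breakpoints) && length(tb))
      offsets <- vapply(result$breakpoints, function(b)
        min(abs(b - tb)), numeric(1))
  }
  list(n_selected = nrow(sel), n_true_y = sum(is_y),
       false_positives = sum(!is_y), hap_accuracy = hap_acc,
       n_blocks = n_blocks, n_strata = n_strata,
       membership_agreement = membership,
       breakpoint_offsets = as.integer(offsets))
}
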
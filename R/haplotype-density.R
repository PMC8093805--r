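#' Effective sequence length
#'
#' Length after excluding ambiguous/gap bases (`N`/`n`); with
#' `mask_aware = TRUE` soft-masked (lowercase) repeat bases are excluded as
#' well. Used as the denominator of male-specific k-mer density so that
#' unresolved gaps (and, for fully repeat-resolved long-read contigs, masked
#' repeats) do not dilute it.
#'
#' @param seq character vector of DNA strings.
#' @param mask_aware logical, applied to every element.
#' @return integer vector of effective lengths in bp.
#' @export
effective_length <- function(seq, mask_aware = FALSE) {
  cpp_effective_length(as.character(seq), isTRUE(mask_aware))
}

#' Read a phased assembly FASTA into phased contigs
#'
#' The two haplotypes of a contig are identified by a suffix convention on the
#' record names (default `<id>_1` / `<id>_2`); records lacking a partner are
#' dropped with a warning.
#'
#' @param path FASTA path.
#' @param hap_pattern regex with one capture group extracting the haplotype
#'   index ("1" or "2"); stripping the match yields the contig id.
#' @param is_bac logical (recycled): mask-aware effective-length rule applies.
#' @return list of `phased_contig` objects (fields `contig_id`, `hap1`,
#'   `hap2`, `is_bac`).
#' @export
read_phased_fasta <- function(path, hap_pattern = "_([12])$", is_bac = FALSE) {
  seqs <- read_sequences(path)
  hap <- regmatches(names(seqs), regexec(hap_pattern, names(seqs)))
  ok <- lengths(hap) == 2L
  if (!all(ok)) {
    warning(sum(!ok), " records do not match the haplotype suffix; dropped")
    seqs <- seqs[ok]; hap <- hap[ok]
  }
  idx <- vapply(hap, `[`, character(1), 2L)
  ids <- sub(hap_pattern, "", names(seqs))
  is_bac <- rep_len(is_bac, length(unique(ids)))
  out <- lapply(seq_along(unique(ids)), function(i) {
    id <- unique(ids)[i]
    h1 <- seqs[ids == id & idx == "1"]
    h2 <- seqs[ids == id & idx == "2"]
    if (length(h1) != 1L || length(h2) != 1L) {
      warning("contig ", id, " lacks a complete haplotype pair; dropped")
      return(NULL)
    }
    phased_contig(id, unname(h1), unname(h2), is_bac = is_bac[i])
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Construct a phased contig
#'
#' @param contig_id unique contig label.
#' @param hap1,hap2 the two haplotype sequences (non-empty DNA strings).
#' @param is_bac mask-aware length rule applies (long-read contigs with
#'   resolved, soft-masked repeats).
#' @return a `phased_contig` list.
#' @export
phased_contig <- function(contig_id, hap1, hap2, is_bac = FALSE) {
  if (nchar(hap1) == 0L || nchar(hap2) == 0L)
    stop("haplotype sequences must be non-empty")
  structure(list(contig_id = contig_id, hap1 = hap1, hap2 = hap2,
                 is_bac = isTRUE(is_bac)),
            class = "phased_contig")
}

#' Score contigs by differential male-specific k-mer matching
#'
#' Matches the male-specific set against both haplotypes of each contig. The
#' haplotype with more matches is the putative Y copy (`y_hap`); an exact tie
#' carries no phasing signal and yields `y_hap = NA`. `ratio` is
#' larger/smaller count, with a zero denominator mapping to `Inf` (one
#' haplotype entirely lacks the male vocabulary — the cleanest phasing
#' signal). `bp_per_kmer` is the Y-haplotype effective length per matched
#' k-mer.
#'
#' @param contigs a `phased_contig` or list of them.
#' @param kmers a `male_kmer_set` (or numeric code vector).
#' @param k k-mer length; taken from `kmers` when it is a `male_kmer_set`.
#' @param canonical strand convention for matching.
#' @return data.frame of class `contig_kmer_stats` with one row per contig:
#'   `contig_id`, `kmers_hap1`, `kmers_hap2`, `eff_len_hap1`, `eff_len_hap2`,
#'   `ratio`, `y_hap`, `eff_len`, `bp_per_kmer`.
#' @export
score_contigs <- function(contigs, kmers, k = 16L, canonical = TRUE) {
  if (inherits(contigs, "phased_contig")) contigs <- list(contigs)
  if (inherits(kmers, "male_kmer_set")) {
    k <- kmers$k
    kmers <- kmers$codes
  }
  codes <- sort(unique(as.numeric(kmers)))
  rows <- lapply(contigs, function(ct) {
    n1 <- length(cpp_match_positions(ct$hap1, codes, as.integer(k), canonical))
    n2 <- length(cpp_match_positions(ct$hap2, codes, as.integer(k), canonical))
    e1 <- effective_length(ct$hap1, mask_aware = ct$is_bac)
    e2 <- effective_length(ct$hap2, mask_aware = ct$is_bac)
    if (n1 == n2) {
      y <- NA_integer_
      ratio <- if (n1 == 0L) NA_real_ else 1
    } else {
      y <- if (n1 > n2) 1L else 2L
      lo <- min(n1, n2)
      ratio <- if (lo == 0L) Inf else max(n1, n2) / lo
    }
    eff <- if (is.na(y)) NA_integer_ else c(e1, e2)[y]
    nky <- if (is.na(y)) NA_integer_ else c(n1, n2)[y]
    data.frame(contig_id = ct$contig_id, kmers_hap1 = n1, kmers_hap2 = n2,
               eff_len_hap1 = e1, eff_len_hap2 = e2, ratio = ratio,
               y_hap = y, eff_len = eff,
               bp_per_kmer = if (!is.na(nky) && nky > 0) eff / nky else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contig_kmer_stats", "data.frame")
  out
}

#' Y-contig selection thresholds
#'
#' Defaults reproduce the published cascade: at least a 2.5-fold difference in
#' male-specific k-mer matches between the two phased haplotypes, at least 30
#' male-specific k-mers on the Y haplotype, and a density of at least one
#' k-mer per 2 kb of effective length. All bounds are inclusive.
#'
#' @param min_ratio minimum haplotype ratio (default 2.5).
#' @param min_kmers minimum Y-haplotype match count (default 30).
#' @param max_bp_per_kmer maximum effective bp per k-mer (default 2000).
#' @return a `y_selection_config` list.
#' @export
y_selection_config <- function(min_ratio = 2.5, min_kmers = 30L,
                               max_bp_per_kmer = 2000) {
  stopifnot(min_ratio > 0, min_kmers > 0, max_bp_per_kmer > 0)
  structure(list(min_ratio = min_ratio, min_kmers = as.integer(min_kmers),
                 max_bp_per_kmer = max_bp_per_kmer),
            class = "y_selection_config")
}

#' Select Y-linked contigs
#'
#' Retains contigs with a determined Y haplotype whose ratio, Y-haplotype
#' k-mer count and density pass the thresholds (all inclusive; an infinite
#' ratio passes any `min_ratio`). Output is sorted densest first (ascending
#' `bp_per_kmer`), ties broken by `contig_id`, so downstream segmentation is
#' deterministic.
#'
#' @param stats a `contig_kmer_stats` data.frame from [score_contigs()].
#' @param cfg a [y_selection_config()].
#' @return the selected rows, densest first, with a `rank` column prepended.
#' @export
select_y_contigs <- function(stats, cfg = y_selection_config()) {
  y_kmers <- ifelse(is.na(stats$y_hap), NA_integer_,
                    ifelse(stats$y_hap == 1L, stats$kmers_hap1, stats$kmers_hap2))
  keep <- !is.na(stats$y_hap) &
    stats$ratio >= cfg$min_ratio &
    y_kmers >= cfg$min_kmers &
    stats$bp_per_kmer <= cfg$max_bp_per_kmer
  out <- stats[which(keep), , drop = FALSE]
  out <- out[order(out$bp_per_kmer, out$contig_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("contig_kmer_stats", "data.frame")
  out
}
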
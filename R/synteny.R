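#' Read tabular alignment hits (12-column BLAST outfmt 6 dialect)
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Subject coordinates are 1-based inclusive.
#' `rank_in_query` (file order within each query) is added on read and serves
#' as the tie-breaker for "first hit".
#'
#' @param path hits file path.
#' @return data.frame of hits with `rank_in_query` appended.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = cols, stringsAsFactors = FALSE)
  df$rank_in_query <- stats::ave(seq_len(nrow(df)), df$qseqid,
                                 FUN = seq_along)
  df
}

#' Reduce alignment hits to one best hit per query
#'
#' Per query, keeps the hit with maximal bitscore; ties break by smaller
#' `rank_in_query` (file order), then lexicographic subject id. Queries with
#' no hits are simply absent. Idempotent.
#'
#' @param hits data.frame as returned by [read_blast_tab()]; if
#'   `rank_in_query` is missing it is derived from row order.
#' @return data.frame with one row per distinct query.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  if (is.null(hits$rank_in_query))
    hits$rank_in_query <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                                     FUN = seq_along)
  o <- order(hits$qseqid, -hits$bitscore, hits$rank_in_query, hits$sseqid)
  sorted <- hits[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place contigs on the reference via best-hit anchors
#'
#' One anchor per contig at most: the midpoint of the best hit's subject
#' interval (orientation ignored — anchors are approximate placements, not
#' alignments).
#'
#' @param hits alignment hits (reduced with [best_hits()] internally).
#' @param blocks a `kmer_density_blocks` (to attach `block_index` and density
#'   `rank`); contigs without a block assignment are dropped.
#' @return data.frame of anchors: `contig_id`, `subject_chrom`, `anchor_pos`,
#'   `block_index`, `rank`.
#' @export
synteny_anchors <- function(hits, blocks) {
  bh <- best_hits(hits)
  ctg <- blocks$contigs
  keep <- bh$qseqid %in% ctg$contig_id
  bh <- bh[keep, , drop = FALSE]
  m <- match(bh$qseqid, ctg$contig_id)
  out <- data.frame(contig_id = bh$qseqid,
                    subject_chrom = bh$sseqid,
                    anchor_pos = floor((bh$sstart + bh$send) / 2),
                    block_index = ctg$block_index[m],
                    rank = ctg$rank[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kendall tau-a between two vectors: (concordant - discordant) / total pairs.
kendall_tau_a <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  conc <- 0L; disc <- 0L
  for (i in seq_len(n - 1L)) {
    dx <- sign(x[(i + 1L):n] - x[i])
    dy <- sign(y[(i + 1L):n] - y[i])
    conc <- conc + sum(dx * dy > 0)
    disc <- disc + sum(dx * dy < 0)
  }
  (conc - disc) / (n * (n - 1L) / 2)
}

#' Per-block collinearity summary of synteny anchors
#'
#' For each block: the dominant subject chromosome (mode of best-hit
#' chromosomes, ties to the lexicographically smaller name), the fraction of
#' the block's anchors on it, the anchor span on it, the secondary
#' chromosomes hit, and a rank-order concordance score in [-1, 1] between
#' contig density rank and anchor position among same-chromosome anchors
#' (Kendall-type: concordant minus discordant pairs over all pairs). A block
#' with fewer than two same-chromosome anchors has undefined concordance
#' (`NA`).
#'
#' @param anchors data.frame from [synteny_anchors()].
#' @param blocks a `kmer_density_blocks`.
#' @return data.frame with one row per block: `block_index`, `n_contigs`,
#'   `n_anchored`, `dominant_chrom`, `frac_dominant`, `anchor_min`,
#'   `anchor_max`, `concordance`, `secondary_chroms`.
#' @export
collinearity_report <- function(anchors, blocks) {
  per <- lapply(blocks$blocks$block_index, function(b) {
    a <- anchors[anchors$block_index == b, , drop = FALSE]
    nb <- blocks$blocks$n_contigs[blocks$blocks$block_index == b]
    if (nrow(a) == 0L)
      return(data.frame(block_index = b, n_contigs = nb, n_anchored = 0L,
                        dominant_chrom = NA_character_, frac_dominant = NA_real_,
                        anchor_min = NA_real_, anchor_max = NA_real_,
                        concordance = NA_real_, secondary_chroms = "",
                        stringsAsFactors = FALSE))
    tab <- table(a$subject_chrom)
    dom <- sort(names(tab)[tab == max(tab)])[1]  # mode; ties lexicographic
    on_dom <- a[a$subject_chrom == dom, , drop = FALSE]
    conc <- if (nrow(on_dom) >= 2L)
      kendall_tau_a(on_dom$rank, on_dom$anchor_pos) else NA_real_
    sec <- tab[names(tab) != dom]
    sec_str <- if (length(sec))
      paste(sprintf("%s:%d", names(sec), as.integer(sec)), collapse = ",")
    else ""
    data.frame(block_index = b, n_contigs = nb, n_anchored = nrow(a),
               dominant_chrom = dom,
               frac_dominant = nrow(on_dom) / nrow(a),
               anchor_min = min(on_dom$anchor_pos),
               anchor_max = max(on_dom$anchor_pos),
               concordance = conc, secondary_chroms = sec_str,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}
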
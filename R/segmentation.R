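#' Leading/trailing density-ratio scan over density-sorted contigs
#'
#' With contigs sorted densest first, position `i` (a 0-based boundary: the
#' number of contigs already passed) gets the ratio of the mean male-specific
#' k-mer density of the trailing `window` contigs (indices `[i-window, i)`,
#' the denser side already passed) to that of the leading `window` contigs
#' (`[i, i+window)`, about to be entered). A step drop in density shows up as
#' a local peak above 1; within a homogeneous block the ratio hovers near 1.
#'
#' Densities are averaged as k-mers per effective bp (the reciprocal of
#' `bp_per_kmer`); set `convention = "bp_per_kmer"` to average the reciprocal
#' scale instead (means of reciprocals differ).
#'
#' @param ordered a `contig_kmer_stats` data.frame sorted densest first
#'   (e.g. from [select_y_contigs()]).
#' @param window number of contigs on each side (default 5).
#' @param convention scale on which means are taken.
#' @return a `density_scan` data.frame: `position` (0-based boundary index,
#'   `window <= position <= n - window`), `trailing_mean`, `leading_mean`,
#'   `ratio`; `n - 2*window + 1` rows.
#' @export
ratio_scan <- function(ordered, window = 5L,
                       convention = c("kmers_per_bp", "bp_per_kmer")) {
  convention <- match.arg(convention)
  window <- as.integer(window)
  n <- nrow(ordered)
  if (n < 2L * window)
    stop("need at least 2*window = ", 2L * window, " contigs (have ", n,
         "); use a smaller window")
  dens <- if (convention == "kmers_per_bp") 1 / ordered$bp_per_kmer
          else ordered$bp_per_kmer
  cs <- c(0, cumsum(dens))
  win_mean <- function(from) (cs[from + window] - cs[from]) / window  # 1-based
  pos <- window:(n - window)
  trailing <- vapply(pos - window + 1L, win_mean, numeric(1))
  leading <- vapply(pos + 1L, win_mean, numeric(1))
  ratio <- if (convention == "kmers_per_bp") trailing / leading
           else leading / trailing
  out <- data.frame(position = pos, trailing_mean = trailing,
                    leading_mean = leading, ratio = ratio)
  attr(out, "window") <- window
  attr(out, "convention") <- convention
  class(out) <- c("density_scan", "data.frame")
  out
}

#' Call block boundaries at peaks of the density-ratio scan
#'
#' A breakpoint is a scan position whose ratio reaches `peak_min_ratio` and is
#' a strict local maximum within `min_separation` positions on either side;
#' plateau ties resolve to the leftmost position. Breakpoint `i` means "block
#' boundary before contig `i`" (0-based).
#'
#' The first and last scan positions are never called: over density-sorted
#' contigs the leading window at the end of the list holds the smallest order
#' statistics of the final block, so the ratio drifts upward into the scan
#' boundary even when the block is homogeneous — a monotone rise into the
#' edge is a tail artifact, not a peak. A peak must therefore have at least
#' one scan position on each side whenever the scan has interior positions
#' at all (scans of one or two positions — the minimum-size input — are
#' exempt, since there is no interior to prefer).
#'
#' @param scan a `density_scan` from [ratio_scan()].
#' @param peak_min_ratio minimum peak height (> 1; default 1.5). There is no
#'   principled universal value — a step between strata of r-fold density
#'   difference produces a peak near r, so the default separates >1.5-fold
#'   shifts from within-block sampling noise.
#' @param min_separation minimum distance between peaks in scan positions
#'   (default: the scan's window).
#' @return integer vector of breakpoint positions (possibly empty).
#' @export
call_breakpoints <- function(scan, peak_min_ratio = 1.5,
                             min_separation = attr(scan, "window")) {
  stopifnot(peak_min_ratio > 1)
  min_separation <- as.integer(min_separation)
  r <- scan$ratio
  n <- length(r)
  bp <- integer(0)
  candidates <- if (n >= 3L) 2:(n - 1L) else seq_len(n)
  for (i in candidates) {
    if (r[i] < peak_min_ratio) next
    lo <- max(1L, i - min_separation); hi <- min(n, i + min_separation)
    left <- if (lo <= i - 1L) r[lo:(i - 1L)] else numeric(0)
    right <- if (i + 1L <= hi) r[(i + 1L):hi] else numeric(0)
    # leftmost-of-plateau: strictly greater than everything left of it,
    # at least as large as everything right of it
    if (all(r[i] > left) && all(r[i] >= right)) bp <- c(bp, scan$position[i])
  }
  bp
}

#' Assign density-sorted contigs to k-mer density blocks
#'
#' `k` breakpoints partition the ordered contig list into `k + 1` contiguous
#' runs (blocks), numbered from 1 at the densest end. Each block is a
#' candidate recombination-suppression stratum: a run of Y contigs sharing a
#' level of male-specific k-mer density.
#'
#' @param ordered a `contig_kmer_stats` data.frame sorted densest first.
#' @param breakpoints strictly increasing integer positions in `(0, n)`
#'   (0-based boundaries, e.g. from [call_breakpoints()]).
#' @return a `kmer_density_blocks` list with `blocks` (per-block summary
#'   data.frame: `block_index`, `n_contigs`, `total_span`, `mean_density`,
#'   `mean_bp_per_kmer`) and `contigs` (the input with `block_index` added).
#' @export
assign_blocks <- function(ordered, breakpoints = integer(0)) {
  n <- nrow(ordered)
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("breakpoints must be strictly increasing")
    if (any(breakpoints <= 0L | breakpoints >= n))
      stop("breakpoints must lie strictly inside (0, n)")
  }
  bounds <- c(0L, breakpoints, n)
  idx <- rep(seq_len(length(bounds) - 1L), diff(bounds))
  contigs <- cbind(ordered, block_index = idx)
  per <- lapply(split(seq_len(n), idx), function(rows) {
    d <- ordered[rows, , drop = FALSE]
    md <- mean(1 / d$bp_per_kmer)
    data.frame(block_index = idx[rows[1]], n_contigs = length(rows),
               total_span = sum(d$eff_len), mean_density = md,
               mean_bp_per_kmer = 1 / md)
  })
  blocks <- do.call(rbind, per)
  rownames(blocks) <- rownames(contigs) <- NULL
  structure(list(blocks = blocks, contigs = contigs),
            class = "kmer_density_blocks")
}

#' @export
print.kmer_density_blocks <- function(x, ...) {
  cat(sprintf("kmer_density_blocks: %d blocks over %d contigs\n",
              nrow(x$blocks), nrow(x$contigs)))
  print(x$blocks)
  invisible(x)
}

#' Write the scan and blocks TSVs
#'
#' @param scan a `density_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @param blocks a `kmer_density_blocks`.
#' @export
write_blocks_tsv <- function(blocks, path) {
  d <- blocks$contigs
  out <- data.frame(block_index = d$block_index, contig_id = d$contig_id,
                    rank = d$rank, bp_per_kmer = d$bp_per_kmer,
                    eff_len = d$eff_len)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
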
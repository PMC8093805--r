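#' @useDynLib ystrata, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reverse-complement DNA strings
#'
#' Case is preserved on complementation; `N`/`n` complement to themselves.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Encode a k-mer window as a canonical integer code
#'
#' Bases map to 2 bits each (A=0, C=1, G=2, T=3, leftmost base most
#' significant); the canonical code is the smaller of the forward and
#' reverse-complement encodings, making counts read-strand independent.
#' Codes are returned as doubles because 4^16 exceeds R's integer range;
#' they are exact for k <= 26.
#'
#' @param windows character vector of DNA windows, each of length `k`.
#' @param k expected window length; every element must have this length.
#' @param canonical collapse strands to the numerically smaller encoding.
#' @return numeric vector of codes; `NA` where a window contains a non-ACGT
#'   character (such windows carry no usable k-mer).
#' @examples
#' encode_kmer(strrep("A", 16))          # 0
#' encode_kmer("ACGTNACGTACGTACG")       # NA: ambiguous base
#' @export
encode_kmer <- function(windows, k = unique(nchar(windows)), canonical = TRUE) {
  if (length(k) != 1L) stop("windows must share a single length k")
  if (any(nchar(windows) != k)) stop("window length differs from k = ", k)
  cpp_encode_kmers(windows, canonical)
}

#' Decode integer k-mer codes back to DNA strings
#'
#' @param codes numeric vector of codes, each < 4^k.
#' @param k k-mer length.
#' @return character vector of uppercase DNA strings.
#' @export
decode_kmer <- function(codes, k = 16L) {
  if (any(codes < 0 | codes >= 4^k)) stop("code out of range for k = ", k)
  cpp_decode_kmers(codes, as.integer(k))
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; format is inferred from
#' the file name (`.fastq`/`.fq`, optionally `.gz`, read as FASTQ; anything
#' else as FASTA). Only the sequence lines are used; qualities are ignored.
#'
#' @param path file path.
#' @return character vector of sequences (names = record ids).
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Count canonical k-mers across a set of reads
#'
#' Every length-k window of every sequence contributes one count to its
#' canonical k-mer; windows overlapping a non-ACGT character are skipped
#' entirely (standard k-mer counter behaviour). A read of length L with no
#' ambiguous bases contributes L - k + 1 windows.
#'
#' @param x character vector of sequences, or one or more FASTA/FASTQ file
#'   paths (read with [read_sequences()]).
#' @param k k-mer length (default 16).
#' @param canonical collapse strands (default TRUE); set FALSE for stranded
#'   counting.
#' @param sample_id label stored with the table.
#' @return a `kmer_count_table`: list with `sample_id`, `k`, `canonical`,
#'   `codes` (sorted numeric codes), `counts` (integer), `total_kmers`.
#' @export
count_kmers <- function(x, k = 16L, canonical = TRUE, sample_id = "sample") {
  k <- as.integer(k)
  if (k < 1L || k > 26L) stop("k must be between 1 and 26")
  if (length(x) > 0 && all(file.exists(x))) {
    x <- unlist(lapply(x, read_sequences), use.names = FALSE)
  }
  res <- cpp_count_kmers(as.character(x), k, canonical)
  structure(
    list(sample_id = sample_id, k = k, canonical = canonical,
         codes = res$codes, counts = res$counts, total_kmers = res$total),
    class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table '%s': %d distinct %d-mers, %.0f total (%s)\n",
              x$sample_id, length(x$codes), x$k, x$total_kmers,
              if (x$canonical) "canonical" else "stranded"))
  invisible(x)
}

#' Look up counts of k-mer codes in a count table
#'
#' Absent codes count as 0.
#'
#' @param table a `kmer_count_table`.
#' @param codes numeric vector of canonical codes.
#' @return integer vector of counts, same length as `codes`.
#' @export
lookup_counts <- function(table, codes) {
  idx <- findInterval(codes, table$codes)
  out <- integer(length(codes))
  hit <- idx > 0L
  hit[hit] <- table$codes[idx[hit]] == codes[hit]
  out[hit] <- table$counts[idx[hit]]
  out
}

#' Histogram of k-mer occurrence counts
#'
#' Bins the count table by occurrence count: `n_kmers[c]` is the number of
#' distinct canonical k-mers seen exactly `c` times. The diploid-coverage
#' structure of a sample shows up here as an error peak at counts 1-2, a
#' trough, and a main mode near the sequencing depth.
#'
#' @param table a `kmer_count_table`.
#' @return a `coverage_histogram`: data.frame with columns `count`, `n_kmers`,
#'   sorted by count; empty for an empty table.
#' @export
coverage_histogram <- function(table) {
  tab <- table(table$counts)
  out <- data.frame(count = as.integer(names(tab)),
                    n_kmers = as.integer(tab))
  out <- out[order(out$count), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coverage_histogram", "data.frame")
  out
}

#' Match a k-mer set against a sequence
#'
#' Exact canonical window matching: returns the 0-based start positions
#' (half-open windows) whose canonical code is in the set. Each window
#' position is counted once. `N` and soft-masked characters are allowed in
#' the sequence; windows overlapping an `N` never match.
#'
#' @param kmers numeric vector of canonical codes (any order), or a
#'   `male_kmer_set`.
#' @param sequence a single DNA string.
#' @param k k-mer length.
#' @param canonical must match the convention used to build the set.
#' @return list with `count` (integer) and `positions` (0-based integer
#'   starts).
#' @export
match_kmer_set <- function(kmers, sequence, k = 16L, canonical = TRUE) {
  if (inherits(kmers, "male_kmer_set")) {
    k <- kmers$k
    kmers <- kmers$codes
  }
  pos <- cpp_match_positions(as.character(sequence)[1],
                             sort(unique(as.numeric(kmers))),
                             as.integer(k), canonical)
  list(count = length(pos), positions = pos)
}

#' Write / read the k-mer count table TSV dialect
#'
#' Header `kmer<TAB>count`; k-mers written as uppercase canonical strings in
#' ascending code order, so output is deterministic.
#'
#' @param table a `kmer_count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  df <- data.frame(kmer = decode_kmer(table$codes, table$k),
                   count = table$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_table
#' @param sample_id label for the reconstructed table.
#' @param canonical strand convention recorded on the table.
#' @export
read_kmer_table <- function(path, sample_id = basename(path), canonical = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  k <- if (nrow(df)) unique(nchar(df$kmer)) else 16L
  if (length(k) != 1L) stop("mixed k-mer lengths in ", path)
  codes <- encode_kmer(df$kmer, k = k, canonical = canonical)
  o <- order(codes)
  structure(
    list(sample_id = sample_id, k = as.integer(k), canonical = canonical,
         codes = codes[o], counts = df$count[o],
         total_kmers = sum(as.numeric(df$count))),
    class = "kmer_count_table")
}
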
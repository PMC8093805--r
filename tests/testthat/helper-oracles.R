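# Naive reference implementations, independent of the package's encoded-
# integer path: string-level window enumeration and dictionary counting.
# For fixed-length ACGT strings lexicographic order equals code order, so
# the canonical representative can be taken at string level.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

oracle_canonical <- function(w) {
  w <- toupper(w)
  rc <- oracle_revcomp(w)
  ifelse(grepl("^[ACGT]+$", w), pmin(w, rc), NA_character_)
}

# dictionary of canonical k-mer string -> count over all valid windows
oracle_count <- function(seqs, k) {
  canon <- oracle_canonical(unlist(lapply(seqs, oracle_windows, k = k)))
  table(canon[!is.na(canon)])
}

# 0-based positions of windows whose canonical string is in `set`
oracle_match <- function(set, seq, k) {
  canon <- oracle_canonical(oracle_windows(seq, k))
  which(!is.na(canon) & canon %in% set) - 1L
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Direct data.frame comparison of a kmer_count_table with an oracle dictionary
expect_table_equals_oracle <- function(tab, oracle) {
  got <- data.frame(kmer = decode_kmer(tab$codes, tab$k), count = tab$counts,
                    stringsAsFactors = FALSE)
  want <- data.frame(kmer = names(oracle), count = as.integer(oracle),
                     stringsAsFactors = FALSE)
  want <- want[order(want$kmer), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
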
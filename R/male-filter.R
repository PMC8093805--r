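#' Per-sample inclusion/exclusion thresholds
#'
#' Males carry `male_min` (inclusive lower bound on occurrence count); females
#' carry `female_max` (inclusive upper tolerance, allowing error-level
#' presence). The count cutoffs are meant to capture k-mers sitting at the
#' hemizygous (half-diploid) coverage peak of the Y while staying above the
#' sequencing-error band.
#'
#' @param sample_id sample label; must match the count table it applies to.
#' @param sex "male" or "female".
#' @param role "reference" (the assembled individual) or "additional".
#' @param male_min integer, males only.
#' @param female_max integer, females only.
#' @return one-row data.frame of class `sample_thresholds`.
#' @export
sample_thresholds <- function(sample_id, sex = c("male", "female"),
                              role = c("additional", "reference"),
                              male_min = NA_integer_, female_max = NA_integer_) {
  sex <- match.arg(sex)
  role <- match.arg(role)
  if (sex == "male") {
    if (is.na(male_min) || male_min < 1) stop("males need male_min >= 1")
    female_max <- NA_integer_
  } else {
    if (is.na(female_max) || female_max < 0) stop("females need female_max >= 0")
    male_min <- NA_integer_
  }
  out <- data.frame(sample_id = sample_id, sex = sex, role = role,
                    male_min = as.integer(male_min),
                    female_max = as.integer(female_max),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_thresholds", "data.frame")
  out
}

#' The shipped "published cutoffs" threshold profile
#'
#' Six-sample western date-palm design: a deep reference male/female pair plus
#' two additional male/female pairs. The published exclusive phrasings are
#' normalised to inclusive bounds: reference male kept above 24 (male_min 25),
#' reference female excluded above 21 (female_max 21), additional males kept at
#' >= 3, additional females excluded above 9 and 8 respectively.
#'
#' @param sample_ids character vector of six sample ids in the order reference
#'   male, reference female, male 2, female 2, male 3, female 3.
#' @return `sample_thresholds` data.frame with six rows.
#' @export
paper_thresholds <- function(sample_ids = c("refM", "refF", "M2", "F2", "M3", "F3")) {
  stopifnot(length(sample_ids) == 6L)
  rbind(
    sample_thresholds(sample_ids[1], "male", "reference", male_min = 25L),
    sample_thresholds(sample_ids[2], "female", "reference", female_max = 21L),
    sample_thresholds(sample_ids[3], "male", "additional", male_min = 3L),
    sample_thresholds(sample_ids[4], "female", "additional", female_max = 9L),
    sample_thresholds(sample_ids[5], "male", "additional", male_min = 3L),
    sample_thresholds(sample_ids[6], "female", "additional", female_max = 8L))
}

#' Locate the sequencing-error trough of a coverage histogram
#'
#' A k-mer coverage spectrum descends from a large error peak at low counts
#' to a local minimum (the trough) and rises again toward the coverage mode.
#' The trough is located as the end of the initial descent: scanning bins in
#' ascending count order (optionally after smoothing with a 3-bin running
#' mean), the first position where the histogram turns upward; within an
#' initial plateau, ties break toward the smaller count (never below 2, the
#' smallest count that can sit between the error peak and the mode). Counts
#' absent from the histogram are not candidates. The trough separates the
#' error band from genuine genomic k-mers and is the natural anchor for
#' per-sample count thresholds.
#'
#' A histogram that never turns upward (monotone decreasing: no interior
#' coverage mode) has no trough and raises an error; thresholds must then be
#' set manually.
#'
#' @param hist a `coverage_histogram` (or data.frame with `count`, `n_kmers`).
#' @param smooth logical; smooth bins with a 3-wide running mean before
#'   scanning (default FALSE; recommended for noisy spectra).
#' @return integer count value at the trough.
#' @export
find_error_trough <- function(hist, smooth = FALSE) {
  if (is.null(hist) || nrow(hist) == 0L) stop("empty histogram: no trough")
  h <- hist[order(hist$count), , drop = FALSE]
  v <- as.numeric(h$n_kmers)
  n <- length(v)
  if (smooth && n >= 3L) {
    sm <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
    sm[is.na(sm)] <- v[is.na(sm)]
    v <- sm
  }
  turn <- which(diff(v) > 0)
  if (!length(turn))
    stop("histogram is monotone decreasing, no interior mode: no trough; ",
         "set thresholds manually")
  i_star <- turn[1]  # last bin of the initial descent
  cand <- which(h$count >= 2L & seq_len(n) <= i_star)
  if (!length(cand)) cand <- i_star
  low <- cand[v[cand] == min(v[cand])]
  h$count[low[1]]  # leftmost of a plateau: the smaller count
}

#' Derive the male-specific k-mer set from per-sample count tables
#'
#' A k-mer is retained iff its count is at least `male_min` in every male
#' table and at most `female_max` in every female table (absent keys count
#' as 0, so a k-mer a female lacks entirely passes her tolerance trivially).
#' The retained set is the presumed hemizygous-Y vocabulary: present at
#' coverage in all males, absent (beyond error tolerance) in all females.
#'
#' @param tables list of `kmer_count_table`, one per sample.
#' @param thresholds `sample_thresholds` data.frame covering every table's
#'   `sample_id`; must include at least one male and one female.
#' @param female_rule "exceeds" (default; discard when a female count exceeds
#'   her tolerance) or "literal" (discard when a female count is at or below
#'   it — the inverted reading of the published phrasing, retained only for
#'   comparison).
#' @return a `male_kmer_set`: list with `k`, `codes` (strictly ascending),
#'   and `provenance` (the thresholds applied).
#' @export
select_male_specific <- function(tables, thresholds,
                                 female_rule = c("exceeds", "literal")) {
  female_rule <- match.arg(female_rule)
  ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_ids among tables")
  if (!all(ids %in% thresholds$sample_id))
    stop("missing thresholds for: ",
         paste(setdiff(ids, thresholds$sample_id), collapse = ", "))
  th <- thresholds[match(ids, thresholds$sample_id), , drop = FALSE]
  ks <- vapply(tables, function(t) t$k, integer(1))
  if (length(unique(ks)) != 1L) stop("tables mix different k")
  males <- which(th$sex == "male")
  females <- which(th$sex == "female")
  if (length(males) == 0L) stop("at least one male table required")
  if (length(females) == 0L) stop("at least one female table required")

  # seed candidates from the most stringent male (smallest candidate set),
  # then apply the remaining predicates; conjunctive, so order-invariant
  seed <- males[1]
  cand <- tables[[seed]]$codes[tables[[seed]]$counts >= th$male_min[seed]]
  for (i in setdiff(males, seed)) {
    keep <- lookup_counts(tables[[i]], cand) >= th$male_min[i]
    cand <- cand[keep]
  }
  for (i in females) {
    cnt <- lookup_counts(tables[[i]], cand)
    keep <- if (female_rule == "exceeds") cnt <= th$female_max[i]
            else cnt > th$female_max[i]
    cand <- cand[keep]
  }
  structure(list(k = ks[1], codes = cand, provenance = th),
            class = "male_kmer_set")
}

#' @export
print.male_kmer_set <- function(x, ...) {
  cat(sprintf("male_kmer_set: %d canonical %d-mers (from %d samples)\n",
              length(x$codes), x$k, nrow(x$provenance)))
  invisible(x)
}

#' Write / read a male-specific k-mer set
#'
#' TSV with a single `kmer` column (uppercase canonical strings, ascending
#' code order) plus a JSON sidecar `<path>.provenance.json` recording the
#' thresholds that produced the set.
#'
#' @param set a `male_kmer_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kmer_set <- function(set, path) {
  df <- data.frame(kmer = decode_kmer(set$codes, set$k))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(set$provenance, paste0(path, ".provenance.json"),
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  k <- if (nrow(df)) unique(nchar(df$kmer)) else 16L
  if (length(k) != 1L) stop("mixed k-mer lengths in ", path)
  codes <- sort(encode_kmer(df$kmer, k = k))
  side <- paste0(path, ".provenance.json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else NULL
  structure(list(k = as.integer(k), codes = codes, provenance = prov),
            class = "male_kmer_set")
}
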
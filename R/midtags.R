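# MID (molecular identifier) tag finding at the read ends, sample
# assignment, and MID-set diagnostics.

#' Standard 10-nt MID barcode set and example Ig primers
#'
#' `basic_mid_set()` returns the nine 10-nt MID tags of the standard
#' GS FLX "basic" barcode set used to multiplex amplicon libraries.
#' `example_primers()` returns degenerate Ig V/J primer sets (IUPAC codes)
#' for human heavy chain and mouse heavy/light chains, suitable for
#' examples and synthetic fixtures.
#'
#' @return For `basic_mid_set()`, a character vector of nine MIDs. For
#'   `example_primers()`, a list with elements `forward` and `reverse`.
#' @examples
#' min_pairwise_hamming(basic_mid_set())
#' @export
basic_mid_set <- function() {
  c("ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG", "ATCAGACACG",
    "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC", "TAGTATCAGC")
}

#' @param organism one of `"human"`, `"mouse_heavy"`, `"mouse_light"`.
#' @rdname basic_mid_set
#' @export
example_primers <- function(organism = c("human", "mouse_heavy",
                                         "mouse_light")) {
  organism <- match.arg(organism)
  switch(organism,
    human = list(
      forward = c("TGCGMCAGGCCCCYGGACAAR", "ARGRAAGGCCCTGGAGTGG",
                  "CCGCCAGGCTCCAGGSAAG", "MGGGAAGGGRCTGGAGTGG",
                  "GAAAGGCCTGGAGTGGATGGG", "TTGAGTGGCTGGGRAGGAC"),
      reverse = "TGACCRKGGTHCCYTGGCCC"),
    mouse_heavy = list(
      forward = c("AGRTYCARCTGCARCAGYC", "TGCAGCTKMAGSAGTCAG",
                  "GARGTGAAGCTKSTSGAGTC", "GAGGAGTCTGGAGGAGGCTT",
                  "CTGGGATATTGCAGCCCTCC", "AGGTGTGCATTGTGAGGTGC",
                  "GTSAGGTGCAGCTKGTRGA", "CAATCCCAGGTTCACCTACAA"),
      reverse = "GTGGTBCCTTSGCCCCAG"),
    mouse_light = list(
      forward = c("MTGATGACCCARTCTCCA", "SRGATATTGTGATGACGCAGG",
                  "AWTGTDCTSACCCARTCTCC", "CCTGTGGRGACATTGTGAT",
                  "AYCCVGATGACYCAGTCT", "CCAGATGTGAYRTYCARATG",
                  "BCAGTGTGACATCCRVAT", "ACACAGGCTCCAGCTTCTCT",
                  "TCCCAGGCTGTTGTGACTC", "CAACTTGTGCTCACTCAGTC",
                  "CTCTAGGAAGCACAGTCAAAC"),
      reverse = "GTGGTBCCTTSGCCCCAG"))
}

#' Reverse complement of DNA/IUPAC strings
#'
#' IUPAC-aware (R<->Y, M<->K, W<->W, S<->S, H<->D, B<->V, N<->N).
#' Vectorised; gap characters (`-`) pass through unchanged.
#'
#' @param seq character vector of IUPAC strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "RM"))
#' @export
reverse_complement <- function(seq) {
  if (!length(seq)) return(character())
  up <- toupper(seq)
  bad <- grepl("[^ACGTRYMKWSHBDVN-]", up)
  if (any(bad)) stop("unknown character in sequence: ", seq[bad][1])
  comp <- chartr("ACGTRYMKWSHBDVN", "TGCAYRKMWSDVHBN", up)
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

#' Hamming distance between equal-length strings
#'
#' @param a,b strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming_distance requires equal lengths (", nchar(a), " vs ",
         nchar(b), ")")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Minimum pairwise Hamming distance of a MID set
#'
#' @param mids character vector of equal-length MID tags.
#' @return The smallest Hamming distance over all pairs.
#' @export
min_pairwise_hamming <- function(mids) {
  stopifnot(length(mids) >= 2)
  prs <- utils::combn(length(mids), 2)
  min(apply(prs, 2, function(p) hamming_distance(mids[p[1]], mids[p[2]])))
}

#' Minimal distinguishing inner (gene-proximal) MID length
#'
#' The smallest `k` such that the gene-proximal length-`k` suffixes of all
#' MIDs, together with their reverse complements, are pairwise distinct --
#' i.e. a perfect match of `k` inner bases identifies both the MID and its
#' orientation unambiguously. Returns `max(nchar(mids)) + 1` as a sentinel
#' when no `k` up to the full MID length distinguishes the set.
#'
#' @param mids character vector of MID tags.
#' @return Integer `k`.
#' @examples
#' min_distinguishing_inner_length(basic_mid_set())
#' @export
min_distinguishing_inner_length <- function(mids) {
  stopifnot(length(mids) >= 1)
  for (k in seq_len(min(nchar(mids)))) {
    sufs <- substring(mids, nchar(mids) - k + 1L)
    all_k <- c(sufs, reverse_complement(sufs))
    if (!anyDuplicated(all_k)) return(k)
  }
  max(nchar(mids)) + 1L
}

# all occurrences (1-based starts) of fixed pattern in subject
fixed_starts <- function(pattern, subject) {
  if (nchar(pattern) == 0 || nchar(pattern) > nchar(subject))
    return(integer())
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Find a MID tag at one read end
#'
#' Scans the search window (`config$search_range` bases at the chosen
#' end) for a perfect full match of any MID or its reverse complement;
#' when none exists, falls back to a perfect match of the
#' `config$min_mid_len` gene-proximal inner bases (the MID suffix in
#' sense orientation at the 5' end; its reverse complement at the 3'
#' end). A full match is always preferred over a partial one. Among
#' competing hits the one closest to the read end wins; remaining ties go
#' to the lower MID index.
#'
#' @param seq read sequence (character string).
#' @param end `"five_prime"` or `"three_prime"`.
#' @param config a [clean_config].
#' @return A `mid_hit` (list with `mid_index`, `end`, `orientation`,
#'   `match_type`, `start`, `stop`; 1-based inclusive span on the read),
#'   or `NULL` when nothing matches.
#' @export
find_mid_at_end <- function(seq, end = c("five_prime", "three_prime"),
                            config) {
  end <- match.arg(end)
  stopifnot(inherits(config, "clean_config"))
  if (!length(config$mids)) return(NULL)
  r <- config$search_range
  n <- nchar(seq)
  win <- if (end == "five_prime") c(1L, min(r, n)) else c(max(1L, n - r + 1L), n)
  wstr <- substr(seq, win[1], win[2])

  best <- NULL
  consider <- function(hit) {
    if (is.null(best)) return(hit)
    # closest to the read end wins; then lower MID index; then sense first
    key <- function(h) {
      edge <- if (end == "five_prime") h$start else -h$stop
      c(edge, h$mid_index, if (h$orientation == "sense") 0L else 1L)
    }
    a <- key(hit); b <- key(best)
    for (j in seq_along(a)) {
      if (a[j] < b[j]) return(hit)
      if (a[j] > b[j]) return(best)
    }
    best
  }
  scan <- function(patterns, orientations, type) {
    hits <- NULL
    for (i in seq_along(config$mids)) {
      for (o in seq_along(orientations)) {
        for (s in fixed_starts(patterns[[o]][i], wstr)) {
          hits[[length(hits) + 1L]] <- structure(list(
            mid_index = i, end = end, orientation = orientations[o],
            match_type = type,
            start = win[1] + s - 1L,
            stop = win[1] + s - 1L + nchar(patterns[[o]][i]) - 1L
          ), class = "mid_hit")
        }
      }
    }
    hits
  }
  full <- scan(list(config$mids, reverse_complement(config$mids)),
               c("sense", "antisense"), "full")
  for (h in full) best <- consider(h)
  if (!is.null(best)) return(best)

  k <- config$min_mid_len
  sufs <- substring(config$mids, nchar(config$mids) - k + 1L)
  partial <- if (end == "five_prime")
    scan(list(sufs), "sense", "partial_inner")
  else
    scan(list(reverse_complement(sufs)), "antisense", "partial_inner")
  for (h in partial) best <- consider(h)
  best
}

#' Map an oriented MID pair to its sample
#'
#' After orientation normalisation the lookup key is (forward MID index,
#' reverse MID index): for a sense-oriented gene the 5' hit is the
#' forward MID; for an antisense gene the roles are swapped.
#'
#' @param hit5,hit3 `mid_hit` objects from the 5' and 3' ends.
#' @param orientation gene orientation, `"sense"` or `"antisense"`.
#' @param sample_table data frame with columns `fw`, `rv`, `sample`.
#' @return The sample id, or `NA_character_` when the combination is not
#'   in the table.
#' @export
assign_sample <- function(hit5, hit3, orientation = c("sense", "antisense"),
                          sample_table) {
  orientation <- match.arg(orientation)
  if (is.null(hit5) || is.null(hit3)) return(NA_character_)
  key <- if (orientation == "sense")
    c(hit5$mid_index, hit3$mid_index)
  else
    c(hit3$mid_index, hit5$mid_index)
  row <- which(sample_table$fw == key[1] & sample_table$rv == key[2])
  if (length(row)) sample_table$sample[row[1]] else NA_character_
}
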
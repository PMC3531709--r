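# Degenerate-primer identification: perfect IUPAC scan, edit-bounded
# partial match of the gene-proximal primer fraction, orientation and
# chimera logic.

# read-base x primer-code compatibility; a read N matches only primer N
# (the fully degenerate code), never a partially degenerate code.
iupac_expand <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  W = c("A", "T"), S = c("C", "G"),
  H = c("A", "C", "T"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

#' Does a read base satisfy an IUPAC primer code?
#'
#' `TRUE` iff the read base is in the code's expansion (R = A+G,
#' M = A+C, ..., N = any). An `N` in the read matches only the primer
#' code `N`, so low-confidence calls do not inflate matches.
#'
#' @param read_base character vector over `A,C,G,T,N`.
#' @param primer_base character vector of IUPAC codes (recycled).
#' @return Logical vector.
#' @examples
#' iupac_match(c("A", "C"), "R")
#' @export
iupac_match <- function(read_base, primer_base) {
  n <- max(length(read_base), length(primer_base))
  read_base <- rep_len(toupper(read_base), n)
  primer_base <- rep_len(toupper(primer_base), n)
  if (any(!read_base %in% c("A", "C", "G", "T", "N")))
    stop("read bases must be A/C/G/T/N")
  if (any(!primer_base %in% names(iupac_expand)))
    stop("unknown IUPAC code: ",
         paste(setdiff(primer_base, names(iupac_expand)), collapse = ","))
  mapply(function(rb, pb) rb %in% iupac_expand[[pb]], read_base, primer_base,
         USE.NAMES = FALSE)
}

# regex character class for one IUPAC primer code (for the perfect
# scan); compiled patterns are cached, the scan runs per read
.iupac_regex_cache <- new.env(parent = emptyenv())
iupac_regex <- function(pattern) {
  hit <- .iupac_regex_cache[[pattern]]
  if (!is.null(hit)) return(hit)
  rx <- paste(vapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    if (!ch %in% names(iupac_expand)) stop("unknown IUPAC code: ", ch)
    set <- iupac_expand[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
  .iupac_regex_cache[[pattern]] <- rx
  rx
}

# 1-based starts of all perfect IUPAC occurrences of pattern in subject
perfect_iupac_starts <- function(pattern, subject) {
  if (nchar(pattern) == 0 || nchar(pattern) > nchar(subject))
    return(integer())
  rx <- paste0("(?=", iupac_regex(pattern), ")")  # overlapping matches
  m <- gregexpr(rx, subject, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Trim a primer to its gene-proximal fraction
#'
#' Removes bases from the side furthest from the gene (the 5' end of the
#' primer as written 5' to 3'), keeping the gene-proximal
#' `ceiling(fraction * nchar(primer))` bases.
#'
#' @param primer IUPAC primer string.
#' @param fraction fraction in `(0, 1]` of the length to keep.
#' @return The trimmed primer string.
#' @examples
#' trim_primer("TGACCRKGGTHCCYTGGCCC", 0.5)
#' @export
trim_primer <- function(primer, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  keep <- as.integer(ceiling(fraction * nchar(primer)))
  substring(primer, nchar(primer) - keep + 1L)
}

# m x n logical: does window char j satisfy pattern code i?
iupac_match_matrix <- function(pattern, window) {
  pc <- strsplit(toupper(pattern), "")[[1]]
  wc <- strsplit(toupper(window), "")[[1]]
  t(vapply(pc, function(p) wc %in% iupac_expand[[p]], logical(length(wc))))
}

# final DP row D[m, 0..n] of the edit distance between pattern and window
# substrings. free_start = TRUE gives the semi-global (pattern-infix) form
# where a match may start anywhere in the window; FALSE anchors the start
# (plain Levenshtein against every window prefix).
edit_dp_final_row <- function(mm, free_start = TRUE) {
  m <- nrow(mm); n <- ncol(mm)
  prev <- if (free_start) rep(0, n + 1L) else as.numeric(0:n)
  if (m == 0) return(prev)
  for (i in seq_len(m)) {
    cost <- as.numeric(!mm[i, ])
    t_row <- pmin(prev[1:n] + cost, prev[2:(n + 1L)] + 1)
    prev <- cummin(c(i, t_row - seq_len(n))) + 0:n
  }
  prev
}

#' Best edit-bounded occurrence of an IUPAC pattern in a window
#'
#' Minimum, over all substrings of `window`, of the IUPAC-aware
#' Levenshtein distance to `pattern` (substitution, insertion and
#' deletion each cost 1; IUPAC-compatible pairs cost 0), computed by
#' semi-global dynamic programming, together with the optimal span. Ties
#' are broken toward the span closest to the window's outer edge
#' (`prefer_outer`), then toward the shortest span.
#'
#' @param window DNA string searched (a read-end window).
#' @param pattern non-empty IUPAC string.
#' @param prefer_outer which window edge is the read's outer edge,
#'   `"left"` or `"right"`; used only to break ties.
#' @return List with `edits`, `start`, `stop` (1-based inclusive span;
#'   `stop < start` denotes an empty span).
#' @examples
#' min_edit_occurrence("AAAACGTAAA", "ACGT")
#' @export
min_edit_occurrence <- function(window, pattern,
                                prefer_outer = c("left", "right")) {
  prefer_outer <- match.arg(prefer_outer)
  stopifnot(nchar(pattern) >= 1)
  n <- nchar(window)
  if (n == 0) return(list(edits = nchar(pattern), start = 1L, stop = 0L))
  mm <- iupac_match_matrix(pattern, window)
  final <- edit_dp_final_row(mm, free_start = TRUE)
  dmin <- min(final)
  ends <- which(final == dmin) - 1L  # 0-based end positions
  # for each candidate end, all starts achieving dmin: plain Levenshtein
  # of the reversed pattern against prefixes of the reversed window[1..j]
  rev_chars <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rp <- rev_chars(pattern)
  spans <- NULL
  for (j in ends) {
    if (j == 0) { spans <- rbind(spans, c(1L, 0L)); next }
    rw <- rev_chars(substr(window, 1L, j))
    fr <- edit_dp_final_row(iupac_match_matrix(rp, rw), free_start = FALSE)
    ts <- which(fr == dmin) - 1L            # consumed window chars
    ts <- ts[ts >= 1L]                      # start must be >= 1
    if (length(ts)) spans <- rbind(spans, cbind(j - ts + 1L, j))
    else spans <- rbind(spans, c(j + 1L, j))  # empty span at j
  }
  s <- spans[, 1]; e <- spans[, 2]
  ord <- if (prefer_outer == "left") order(s, e - s) else order(-e, s - e)
  list(edits = as.integer(dmin), start = as.integer(s[ord[1]]),
       stop = as.integer(e[ord[1]]))
}

primer_hit <- function(index, which, orientation, edits, start, stop,
                       fraction, end) {
  structure(list(primer_index = index, which = which,
                 orientation = orientation, edits = edits,
                 start = start, stop = stop,
                 matched_fraction = fraction, end = end),
            class = "primer_hit")
}

# best perfect hit on one end window for one primer list; NULL if none
best_perfect_hit <- function(wstr, woff, primers, which, end) {
  best <- NULL
  for (i in seq_along(primers)) {
    pats <- c(sense = primers[i], antisense = reverse_complement(primers[i]))
    for (o in names(pats)) {
      st <- perfect_iupac_starts(pats[[o]], wstr)
      if (!length(st)) next
      s <- if (end == "five_prime") min(st) else max(st)
      hit <- primer_hit(i, which, o, 0L, woff + s - 1L,
                        woff + s - 1L + nchar(pats[[o]]) - 1L, "full", end)
      if (is.null(best)) best <- hit
    }
    if (!is.null(best)) break  # lower primer index wins ties at 0 edits
  }
  best
}

best_partial_hit <- function(wstr, woff, primers, which, end, config) {
  best <- NULL
  prefer <- if (end == "five_prime") "left" else "right"
  for (i in seq_along(primers)) {
    tp <- trim_primer(primers[i], config$primer_fraction)
    pats <- c(sense = tp, antisense = reverse_complement(tp))
    for (o in names(pats)) {
      occ <- min_edit_occurrence(wstr, pats[[o]], prefer_outer = prefer)
      if (occ$edits > config$max_mismatches) next
      hit <- primer_hit(i, which, o, occ$edits, woff + occ$start - 1L,
                        woff + occ$stop - 1L, "trimmed", end)
      if (is.null(best) || hit$edits < best$edits) best <- hit
    }
  }
  best
}

#' Locate forward and reverse primers on a MID-trimmed read core
#'
#' Stage 1 scans both end windows (of `config$search_range` bases) for
#' perfect IUPAC matches of every forward and reverse primer and their
#' reverse complements. Stage 2, run only for an end with no perfect hit,
#' searches that window for the gene-proximal [trim_primer()] fraction of
#' every primer under the `config$max_mismatches` edit budget via
#' [min_edit_occurrence()]. A usable result needs an acceptable hit at
#' each end; the orientation of the forward primer fixes the gene
#' orientation, and a pair whose two hits share strand orientation is
#' flagged chimeric (a template-switching artifact). The gene is the
#' region strictly between the two primer spans.
#'
#' @param seq the MID-trimmed read core (or raw read in no-MID mode).
#' @param config a [clean_config].
#' @return A `primer_pair` (list with `fw_hit`, `rv_hit`,
#'   `gene_orientation`, `chimeric`, `gene_start`, `gene_stop`), or
#'   `NULL` when either end lacks an acceptable hit.
#' @export
locate_primers <- function(seq, config) {
  stopifnot(inherits(config, "clean_config"))
  n <- nchar(seq)
  r <- config$search_range
  w5 <- c(1L, min(r, n)); w3 <- c(max(1L, n - r + 1L), n)
  s5 <- substr(seq, w5[1], w5[2]); s3 <- substr(seq, w3[1], w3[2])

  ends <- list(five_prime = list(wstr = s5, off = w5[1]),
               three_prime = list(wstr = s3, off = w3[1]))
  hits <- list()
  for (e in names(ends)) {
    fw <- best_perfect_hit(ends[[e]]$wstr, ends[[e]]$off,
                           config$forward_primers, "forward", e)
    rv <- best_perfect_hit(ends[[e]]$wstr, ends[[e]]$off,
                           config$reverse_primers, "reverse", e)
    if (is.null(fw) && is.null(rv)) {
      fw <- best_partial_hit(ends[[e]]$wstr, ends[[e]]$off,
                             config$forward_primers, "forward", e, config)
      rv <- best_partial_hit(ends[[e]]$wstr, ends[[e]]$off,
                             config$reverse_primers, "reverse", e, config)
    }
    hits[[e]] <- list(forward = fw, reverse = rv)
  }

  pairs <- list(list(fw = hits$five_prime$forward, rv = hits$three_prime$reverse),
                list(fw = hits$three_prime$forward, rv = hits$five_prime$reverse))
  ok <- vapply(pairs, function(p) !is.null(p$fw) && !is.null(p$rv), TRUE)
  if (any(ok)) {
    cand <- pairs[ok]
    tot <- vapply(cand, function(p) p$fw$edits + p$rv$edits, 0L)
    pick <- cand[[which.min(tot)]]
    fw <- pick$fw; rv <- pick$rv
  } else {
    # no forward+reverse pairing; a same-orientation same-list pair at the
    # two ends is still reportable as a chimera
    for (lst in c("forward", "reverse")) {
      a <- hits$five_prime[[lst]]; b <- hits$three_prime[[lst]]
      if (!is.null(a) && !is.null(b) && a$orientation == b$orientation) {
        fw <- a; rv <- b
        inner5 <- a; inner3 <- b
        return(structure(list(
          fw_hit = a, rv_hit = b,
          gene_orientation = if (a$which == "forward" &&
                                 a$orientation == "sense") "sense"
                             else "antisense",
          chimeric = TRUE,
          gene_start = inner5$stop + 1L, gene_stop = inner3$start - 1L
        ), class = "primer_pair"))
      }
    }
    return(NULL)
  }
  inner5 <- if (fw$end == "five_prime") fw else rv
  inner3 <- if (fw$end == "three_prime") fw else rv
  structure(list(
    fw_hit = fw, rv_hit = rv,
    gene_orientation = if (fw$orientation == "sense") "sense" else "antisense",
    chimeric = fw$orientation == rv$orientation,
    gene_start = inner5$stop + 1L, gene_stop = inner3$start - 1L
  ), class = "primer_pair")
}
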
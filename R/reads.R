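#' Read collection with per-base quality scores
#'
#' A vectorised container for sequencer reads: an identifier, an uppercase
#' DNA string over `A,C,G,T,N`, and one integer quality score per base
#' (Phred-like, 0-40 as emitted by 454-style base callers).
#'
#' @param id character vector of non-empty, unique read identifiers.
#' @param seq character vector of DNA strings, same length as `id`.
#' @param qual list of integer vectors; `qual[[i]]` must have one score in
#'   `[0, 40]` per base of `seq[i]`.
#' @return An `ig_reads` object.
#' @examples
#' rd <- ig_reads("r1", "ACGT", list(c(30L, 30L, 35L, 40L)))
#' length(rd)
#' @export
ig_reads <- function(id = character(), seq = character(), qual = list()) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq) || length(id) != length(qual))
    stop("id, seq and qual must have equal lengths")
  if (anyNA(id) || any(!nzchar(id)))
    stop("read identifiers must be non-empty")
  qual <- lapply(qual, function(q) as.integer(q))
  bad <- which(nchar(seq) != vapply(qual, length, 0L))
  if (length(bad))
    stop("base/score count mismatch for read '", id[bad[1]], "'")
  rng <- unlist(qual, use.names = FALSE)
  if (length(rng) && (anyNA(rng) || any(rng < 0L) || any(rng > 40L)))
    stop("quality scores must be integers in [0, 40]")
  if (length(seq) && any(grepl("[^ACGTN]", seq)))
    stop("read bases must be over {A,C,G,T,N}")
  structure(list(id = id, seq = seq, qual = qual), class = "ig_reads")
}

#' @export
length.ig_reads <- function(x) length(x$id)

#' @export
`[.ig_reads` <- function(x, i) {
  ig_reads(x$id[i], x$seq[i], x$qual[i])
}

#' @export
c.ig_reads <- function(...) {
  parts <- list(...)
  ig_reads(
    unlist(lapply(parts, `[[`, "id")),
    unlist(lapply(parts, `[[`, "seq")),
    do.call(c, lapply(parts, `[[`, "qual"))
  )
}

#' @export
print.ig_reads <- function(x, ...) {
  cat(sprintf("<ig_reads> %d read(s)\n", length(x)))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %dnt  meanQ=%.1f\n", x$id[i], nchar(x$seq[i]),
                mean(x$qual[[i]])))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}
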
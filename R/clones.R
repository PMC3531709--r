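# Clone assembly utilities: consensus over aligned rows and
# alignment-column bookkeeping.

#' Column-wise consensus of aligned rows
#'
#' Per column, the most frequent symbol among `A,C,G,T,-`; ties are
#' broken by the fixed order `A < C < G < T < -`, so a nucleotide always
#' beats the gap on a tie.
#'
#' @param rows character vector of equal-length aligned strings.
#' @return The consensus string.
#' @examples
#' build_consensus(c("ACGT", "ACGA", "ACGA"))
#' @export
build_consensus <- function(rows) {
  if (!length(rows)) stop("cannot build a consensus of zero rows")
  if (length(unique(nchar(rows))) > 1)
    stop("aligned rows have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  order_sym <- c("A", "C", "G", "T", "-")
  paste(apply(mat, 2, function(col) {
    cnt <- table(factor(col, levels = order_sym))
    order_sym[which.max(cnt)]  # which.max takes the first max: tie order
  }), collapse = "")
}

#' Map an alignment column to a degapped read position
#'
#' @param aligned_row gapped row string.
#' @param column 1-based alignment column.
#' @return 1-based position in the degapped read, or `NA` at a gap
#'   column.
#' @examples
#' column_to_read_position("A-CG", 4)
#' @export
column_to_read_position <- function(aligned_row, column) {
  n <- nchar(aligned_row)
  if (column < 1 || column > n)
    stop("column ", column, " outside alignment of width ", n)
  ch <- strsplit(aligned_row, "")[[1]]
  if (ch[column] == "-") return(NA_integer_)
  sum(ch[seq_len(column)] != "-")
}

# vectorised column -> position map for a whole row (NA at gaps)
column_map <- function(aligned_row) {
  ch <- strsplit(aligned_row, "")[[1]]
  pos <- cumsum(ch != "-")
  pos[ch == "-"] <- NA_integer_
  as.integer(pos)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)
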
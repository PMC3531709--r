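# File readers/writers: FASTA+QUAL read pairs, the run-configuration text
# dialect, PIR clone alignments, and quality summaries.

# Accept either a file path or in-memory text (single string with newlines,
# or a character vector of lines).
as_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) return(readLines(x))
  if (length(x) == 1) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  as.character(x)
}

parse_fasta_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("FASTA text does not start with '>'")
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(s) paste(gsub("\\s", "", s), collapse = ""), "")
  # records with no sequence lines yield no split element; restore as ""
  out <- setNames(character(length(ids)), ids)
  if (length(seqs)) out[as.integer(names(seqs))] <- unname(seqs)
  out
}

parse_qual_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("QUAL text does not start with '>'")
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  quals <- rep(list(integer()), length(ids))
  body <- split(lines[!hdr], rec[!hdr])
  for (k in names(body)) {
    toks <- unlist(strsplit(trimws(body[[k]]), "\\s+"))
    toks <- toks[nzchar(toks)]
    v <- suppressWarnings(as.integer(toks))
    if (anyNA(v))
      stop("non-integer quality token in record '", ids[as.integer(k)], "'")
    quals[[as.integer(k)]] <- v
  }
  setNames(quals, ids)
}

#' Read a matched FASTA/QUAL pair of read files
#'
#' Reads a 454-style `.fna` FASTA file together with its `.qual` companion
#' (whitespace-separated integer scores, line wrapping ignored) into an
#' [ig_reads] collection. Records must appear in the same order with
#' matching identifiers, and each read must have exactly one score per
#' base; violations are hard errors naming the offending record.
#'
#' @param fasta,qual file paths, or the file contents as text.
#' @return An [ig_reads] object (bases uppercased).
#' @examples
#' rd <- read_fasta_qual(">r1\nacgt", ">r1\n30 30 35 40")
#' rd$seq
#' @export
read_fasta_qual <- function(fasta, qual) {
  seqs <- parse_fasta_lines(as_lines(fasta))
  quals <- parse_qual_lines(as_lines(qual))
  if (length(seqs) != length(quals))
    stop("FASTA has ", length(seqs), " records but QUAL has ", length(quals))
  mism <- which(names(seqs) != names(quals))
  if (length(mism))
    stop("record ", mism[1], ": FASTA id '", names(seqs)[mism[1]],
         "' does not match QUAL id '", names(quals)[mism[1]], "'")
  nb <- nchar(seqs); nq <- lengths(quals)
  bad <- which(nb != nq)
  if (length(bad))
    stop("read '", names(seqs)[bad[1]], "': ", nb[bad[1]], " bases but ",
         nq[bad[1]], " quality scores")
  ig_reads(names(seqs), unname(seqs), unname(quals))
}

#' Write a matched FASTA/QUAL pair
#'
#' Inverse of [read_fasta_qual()]; the FASTA side is written through
#' [Biostrings::writeXStringSet()].
#'
#' @param reads an [ig_reads] object.
#' @param fasta,qual output file paths.
#' @return Invisibly, `reads`.
#' @export
write_fasta_qual <- function(reads, fasta, qual) {
  stopifnot(inherits(reads, "ig_reads"))
  set <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(set, fasta)
  con <- file(qual, "w")
  on.exit(close(con))
  for (i in seq_along(reads$id)) {
    writeLines(c(paste0(">", reads$id[i]),
                 paste(reads$qual[[i]], collapse = " ")), con)
  }
  invisible(reads)
}

#' Cleaning run configuration
#'
#' Bundles all parameters of a cleaning run: MID tags, degenerate primers,
#' the two length ranges, the quality threshold, primer-search controls,
#' and the MID-combination-to-sample table.
#'
#' @param organism,chain free-text labels echoed in the log.
#' @param quality_threshold minimal average base score; a read passes only
#'   if its gene-region average is strictly greater.
#' @param max_mismatches edit-operation budget (substitutions, insertions
#'   or deletions) allowed in the partial primer match.
#' @param primer_fraction fraction in `(0, 1]` of each primer (measured
#'   from the gene-proximal end) used in the partial match.
#' @param search_range number of bases at each read end scanned for MIDs
#'   and primers.
#' @param min_mid_len number of gene-proximal MID bases that must match
#'   perfectly when the full MID is not found.
#' @param mids character vector of MID tags (plain `A,C,G,T`), numbered by
#'   position; may be empty for no-MID runs.
#' @param forward_primers,reverse_primers IUPAC primer strings, 5' to 3'.
#' @param minL1,maxL1 inclusive bounds on the raw read length.
#' @param minL2,maxL2 inclusive bounds on the between-primer gene length.
#' @param sample_table data frame with integer columns `fw`, `rv` (1-based
#'   MID indices, or both 0 in no-MID mode) and character column `sample`.
#' @return A `clean_config` object.
#' @examples
#' cfg <- clean_config(mids = c("ACGAGTGCGT", "ACGCTCGACA"),
#'                     forward_primers = "TGCGMCAGGCCCCYGGACAAR",
#'                     reverse_primers = "TGACCRKGGTHCCYTGGCCC",
#'                     sample_table = data.frame(fw = 1, rv = 2,
#'                                               sample = "s1"))
#' @export
clean_config <- function(organism = "Human", chain = "h",
                         quality_threshold = 20, max_mismatches = 2,
                         primer_fraction = 0.75, search_range = 50,
                         min_mid_len = 5, mids = character(),
                         forward_primers, reverse_primers,
                         minL1 = 200, maxL1 = 400, minL2 = 150, maxL2 = 360,
                         sample_table) {
  mids <- toupper(as.character(mids))
  forward_primers <- toupper(as.character(forward_primers))
  reverse_primers <- toupper(as.character(reverse_primers))
  if (!length(forward_primers) || !length(reverse_primers))
    stop("both primer lists must be non-empty")
  if (length(mids) && any(grepl("[^ACGT]", mids)))
    stop("MID tags must be plain A/C/G/T strings")
  if (!(minL1 > 0 && minL1 <= maxL1)) stop("need 0 < minL1 <= maxL1")
  if (!(minL2 > 0 && minL2 <= maxL2)) stop("need 0 < minL2 <= maxL2")
  if (primer_fraction <= 0 || primer_fraction > 1)
    stop("primer_fraction must be in (0, 1]")
  if (length(mids)) {
    if (min_mid_len < 1 || min_mid_len > min(nchar(mids)))
      stop("min_mid_len must be in [1, length of shortest MID]")
  }
  sample_table <- as.data.frame(sample_table)
  if (!all(c("fw", "rv", "sample") %in% names(sample_table)))
    stop("sample_table needs columns fw, rv, sample")
  sample_table$fw <- as.integer(sample_table$fw)
  sample_table$rv <- as.integer(sample_table$rv)
  sample_table$sample <- as.character(sample_table$sample)
  n <- length(mids)
  ok <- (sample_table$fw == 0 & sample_table$rv == 0) |
    (sample_table$fw >= 1 & sample_table$fw <= n &
       sample_table$rv >= 1 & sample_table$rv <= n)
  if (anyNA(ok) || !all(ok))
    stop("sample_table references MID indices outside 1..", n,
         " (or is not the no-MID row 0 0)")
  if (!length(mids) && !all(sample_table$fw == 0 & sample_table$rv == 0))
    stop("with no MIDs the table must contain only the 0 0 row")
  structure(list(
    organism = organism, chain = chain,
    quality_threshold = as.numeric(quality_threshold),
    max_mismatches = as.integer(max_mismatches),
    primer_fraction = as.numeric(primer_fraction),
    search_range = as.integer(search_range),
    min_mid_len = as.integer(min_mid_len),
    mids = mids, forward_primers = forward_primers,
    reverse_primers = reverse_primers,
    minL1 = as.integer(minL1), maxL1 = as.integer(maxL1),
    minL2 = as.integer(minL2), maxL2 = as.integer(maxL2),
    sample_table = sample_table
  ), class = "clean_config")
}

#' @export
print.clean_config <- function(x, ...) {
  cat("<clean_config>", x$organism, "chain", x$chain, "\n")
  cat(sprintf("  %d MID(s), %d forward / %d reverse primer(s), %d sample(s)\n",
              length(x$mids), length(x$forward_primers),
              length(x$reverse_primers), nrow(x$sample_table)))
  cat(sprintf("  L1 [%d,%d]  L2 [%d,%d]  Q>%g  m=%d  f=%g  r=%d  k_min=%d\n",
              x$minL1, x$maxL1, x$minL2, x$maxL2, x$quality_threshold,
              x$max_mismatches, x$primer_fraction, x$search_range,
              x$min_mid_len))
  invisible(x)
}

# section titles of the configuration dialect, matched case-insensitively
config_titles <- c(
  organism = "organism", chain = "chain",
  quality_threshold = "quality threshold",
  max_mismatches = "maximum mismatches allowed",
  primer_fraction = "fraction of primer to search",
  search_range = "range to search primers in",
  min_mid_len = "minimal mid length",
  mids = "mids", forward = "forward", reverse = "reverse",
  minimum_length = "minimum length", maximum_length = "maximum length",
  table = "table")

match_title <- function(line) {
  bare <- tolower(trimws(sub(":.*$", "", line)))
  hit <- which(config_titles == bare)
  if (length(hit)) names(config_titles)[hit[1]] else NA_character_
}

#' Parse a cleaning run-configuration file
#'
#' Parses the plain-text configuration dialect: titled sections (matched
#' case-insensitively, value after the colon or on the following line),
#' MID/primer/table lists each terminated by a line containing `#`, and
#' two values each for the minimum and maximum lengths (raw-read bound
#' first, between-primer bound second). MIDs are numbered by their order
#' of appearance. An empty MID list with the table row `0 0 sample`
#' selects no-MID mode.
#'
#' @param text file path or configuration text.
#' @return A [clean_config] object.
#' @seealso [format_clean_config()] for the inverse.
#' @export
parse_clean_config <- function(text) {
  lines <- trimws(as_lines(text))
  lines <- lines[nzchar(lines)]
  vals <- list()
  i <- 1L
  take_scalar <- function(line, i) {
    rest <- trimws(sub("^[^:]*:?", "", line))
    if (nzchar(rest)) list(value = rest, nxt = i + 1L)
    else if (i < length(lines)) list(value = lines[i + 1L], nxt = i + 2L)
    else stop("missing value for section at line ", i)
  }
  take_list <- function(i, what) {
    items <- character()
    j <- i + 1L
    repeat {
      if (j > length(lines))
        stop("missing '#' terminator for the ", what, " list")
      if (lines[j] == "#") break
      items <- c(items, lines[j])
      j <- j + 1L
    }
    list(items = items, nxt = j + 1L)
  }
  while (i <= length(lines)) {
    key <- match_title(lines[i])
    if (is.na(key)) stop("unrecognised configuration line: '", lines[i], "'")
    if (key %in% c("mids", "forward", "reverse", "table")) {
      got <- take_list(i, config_titles[[key]])
      vals[[key]] <- got$items
      i <- got$nxt
    } else {
      got <- take_scalar(lines[i], i)
      vals[[key]] <- got$value
      i <- got$nxt
    }
  }
  need <- c("quality_threshold", "max_mismatches", "primer_fraction",
            "search_range", "minimum_length", "maximum_length",
            "forward", "reverse", "table")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("configuration lacks section(s): ",
                         paste(config_titles[miss], collapse = ", "))
  two <- function(key) {
    v <- suppressWarnings(as.integer(strsplit(trimws(vals[[key]]),
                                              "\\s+")[[1]]))
    if (length(v) != 2 || anyNA(v))
      stop("section '", config_titles[[key]], "' needs two integer values")
    v
  }
  mins <- two("minimum_length"); maxs <- two("maximum_length")
  tab_rows <- strsplit(vals$table, "\\s+")
  if (!length(tab_rows)) stop("sample table is empty")
  bad <- which(lengths(tab_rows) < 3)
  if (length(bad)) stop("sample table row ", bad[1],
                        " does not have 'fw rv sample'")
  fw <- suppressWarnings(as.integer(vapply(tab_rows, `[`, "", 1)))
  rv <- suppressWarnings(as.integer(vapply(tab_rows, `[`, "", 2)))
  if (anyNA(fw) || anyNA(rv)) stop("non-integer MID index in sample table")
  smp <- vapply(tab_rows, function(r) paste(r[-(1:2)], collapse = " "), "")
  mids <- toupper(vals$mids %||% character())
  clean_config(
    organism = vals$organism %||% "", chain = vals$chain %||% "",
    quality_threshold = as.numeric(vals$quality_threshold),
    max_mismatches = as.integer(vals$max_mismatches),
    primer_fraction = as.numeric(vals$primer_fraction),
    search_range = as.integer(vals$search_range),
    min_mid_len = as.integer(vals$min_mid_len %||% 1),
    mids = mids,
    forward_primers = vals$forward, reverse_primers = vals$reverse,
    minL1 = mins[1], minL2 = mins[2], maxL1 = maxs[1], maxL2 = maxs[2],
    sample_table = data.frame(fw = fw, rv = rv, sample = smp,
                              stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a cleaning configuration to its text dialect
#'
#' @param config a [clean_config] object.
#' @return Character vector of lines; `parse_clean_config()` of the result
#'   reproduces `config`.
#' @export
format_clean_config <- function(config) {
  stopifnot(inherits(config, "clean_config"))
  tab <- sprintf("%d\t%d\t%s", config$sample_table$fw,
                 config$sample_table$rv, config$sample_table$sample)
  c(paste0("Organism: ", config$organism),
    paste0("Chain: ", config$chain),
    paste0("Quality threshold: ", config$quality_threshold),
    paste0("Maximum mismatches allowed: ", config$max_mismatches),
    paste0("Fraction of primer to search: ", config$primer_fraction),
    paste0("Range to search primers in: ", config$search_range),
    paste0("Minimal MID length: ", config$min_mid_len),
    "Mids:", config$mids, "#",
    "Forward:", config$forward_primers, "#",
    "Reverse:", config$reverse_primers, "#",
    paste("Minimum length:", config$minL1, config$minL2),
    paste("Maximum length:", config$maxL1, config$maxL2),
    "Table:", tab, "#")
}

#' Clonally related alignment with a germline/consensus row
#'
#' All rows are gapped strings of one common length; degapping a member
#' row reproduces the member's read bases. The germline (or consensus) row
#' is the comparison reference for indel and mutation calling.
#'
#' @param germline gapped germline/consensus string.
#' @param members named character vector of gapped member rows.
#' @param clone_id clone label.
#' @param germline_id identifier of the germline row.
#' @return A `clonal_alignment` object.
#' @export
clonal_alignment <- function(germline, members, clone_id = "clone",
                             germline_id = "GL") {
  germline <- toupper(germline)
  members <- toupper(members)
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("member rows must be named")
  w <- nchar(germline)
  bad <- which(nchar(members) != w)
  if (length(bad))
    stop("row '", names(members)[bad[1]], "' has aligned length ",
         nchar(members)[bad[1]], ", expected ", w)
  structure(list(clone_id = clone_id, germline_id = germline_id,
                 germline = germline, members = members),
            class = "clonal_alignment")
}

#' @export
print.clonal_alignment <- function(x, ...) {
  cat(sprintf("<clonal_alignment> %s: %d member(s), width %d (germline %s)\n",
              x$clone_id, length(x$members), nchar(x$germline),
              x$germline_id))
  invisible(x)
}

pir_chunk <- function(name, seq) {
  body <- substring(paste0(seq, "*"),
                    seq(1, nchar(seq) + 1, by = 60),
                    pmin(seq(60, nchar(seq) + 60, by = 60), nchar(seq) + 1))
  c(paste0(">P1;", name), name, body)
}

#' Parse a PIR-format clone alignment
#'
#' Parses the PIR alignment dialect emitted by classic multiple-alignment
#' tools: records headed by `>P1;name`, an optional description line,
#' sequence lines with `-` gaps terminated by `*`. The germline row is the
#' record whose name starts with `GL` (case-insensitive); if none does,
#' the first record is taken as germline.
#'
#' @param text file path or PIR text.
#' @param clone_id clone label attached to the result.
#' @return A [clonal_alignment].
#' @export
parse_pir_alignment <- function(text, clone_id = "clone") {
  lines <- trimws(as_lines(text))
  lines <- lines[nzchar(lines)]
  hdr_at <- grep("^>..;", lines)
  if (!length(hdr_at)) stop("no PIR records ('>P1;name') found")
  ids <- sub("^>..;", "", lines[hdr_at])
  ends <- c(hdr_at[-1] - 1L, length(lines))
  rows <- character(length(ids))
  for (k in seq_along(hdr_at)) {
    body <- lines[seq(hdr_at[k] + 1L, length.out = ends[k] - hdr_at[k])]
    if (length(body) && !grepl("^[ACGTNacgtn*-]+$", body[1]))
      body <- body[-1]  # description line
    seq <- paste(body, collapse = "")
    if (!grepl("\\*", seq))
      stop("record '", ids[k], "' lacks the '*' terminator")
    rows[k] <- toupper(sub("\\*.*$", "", gsub("\\s", "", seq)))
  }
  if (length(unique(nchar(rows))) > 1)
    stop("aligned rows have unequal lengths: ",
         paste(nchar(rows), collapse = ", "))
  gl <- grep("^GL", ids, ignore.case = TRUE)
  gl <- if (length(gl)) gl[1] else 1L
  clonal_alignment(rows[gl], setNames(rows[-gl], ids[-gl]),
                   clone_id = clone_id, germline_id = ids[gl])
}

#' Serialise a clone alignment to PIR text
#'
#' @param aln a [clonal_alignment].
#' @return Character vector of PIR lines (germline record first).
#' @export
format_pir_alignment <- function(aln) {
  stopifnot(inherits(aln, "clonal_alignment"))
  out <- pir_chunk(aln$germline_id, aln$germline)
  for (nm in names(aln$members)) out <- c(out, pir_chunk(nm, aln$members[[nm]]))
  out
}

#' Per-sequence and per-sample quality summary
#'
#' The average score of a read is the sum of its base scores divided by
#' its length; the sample average is the mean of the per-read averages.
#' Zero-length reads cannot be averaged and are excluded and reported.
#'
#' @param reads an [ig_reads] object.
#' @return A `quality_summary`: list with `per_sequence_averages`,
#'   `per_sequence_minima`, `sample_average` (`NaN` when no reads), and
#'   `skipped_ids` (ids of zero-length reads).
#' @examples
#' summarize_quality(ig_reads("r1", "ACG", list(c(10L, 20L, 40L))))
#' @export
summarize_quality <- function(reads) {
  stopifnot(inherits(reads, "ig_reads"))
  keep <- lengths(reads$qual) > 0
  avgs <- vapply(reads$qual[keep], mean, 0)
  mins <- vapply(reads$qual[keep], min, 0L)
  structure(list(
    per_sequence_averages = unname(avgs),
    per_sequence_minima = unname(mins),
    sample_average = if (length(avgs)) mean(avgs) else NaN,
    skipped_ids = reads$id[!keep]
  ), class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  cat(sprintf("<quality_summary> %d read(s), sample average %.2f\n",
              length(x$per_sequence_averages), x$sample_average))
  if (length(x$skipped_ids))
    cat("  skipped zero-length:", paste(x$skipped_ids, collapse = ", "), "\n")
  invisible(x)
}
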
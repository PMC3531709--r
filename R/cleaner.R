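# The full read-cleaning pipeline: L1 pre-filter -> MID identification ->
# primer identification -> L2 check -> average-quality check -> per-sample
# outputs and the two-part log.

#' Average base quality of a score vector
#'
#' @param quals non-empty integer vector of per-base scores.
#' @return Arithmetic mean.
#' @export
average_quality <- function(quals) {
  if (!length(quals)) stop("cannot average an empty quality vector")
  mean(quals)
}

#' Clean a single read
#'
#' Applies the cleaning stages in order and stops at the first failure:
#'
#' 1. `fail_L1` unless `minL1 <= nchar(seq) <= maxL1` (raw read as
#'    delivered).
#' 2. `fail_mids` (skipped in no-MID mode) unless both ends carry MID
#'    hits in the legitimate orientations (5' sense, 3' antisense) whose
#'    combination, in either order, is in the sample table. The MID spans
#'    and everything outward are removed.
#' 3. `fail_primers` unless [locate_primers()] finds a non-chimeric pair
#'    on the MID-trimmed core.
#' 4. Once the gene orientation is known the oriented (forward, reverse)
#'    MID key must itself be in the table, else `fail_mids`.
#' 5. `fail_L2` unless the between-primer gene length is within
#'    `[minL2, maxL2]`.
#' 6. `fail_quality` unless the average gene-region quality is strictly
#'    greater than the threshold.
#' 7. `pass`: the gene and its scores are reverse-complemented/reversed
#'    to sense orientation.
#'
#' @param id read identifier.
#' @param seq read sequence.
#' @param quals integer vector of per-base scores.
#' @param config a [clean_config].
#' @return A `clean_outcome`: list with `read_id`, `status`, `sample`
#'   (`NA` when no sample can be attributed), `gene`, `gene_quals`,
#'   `orientation`.
#' @export
clean_read <- function(id, seq, quals, config) {
  stopifnot(inherits(config, "clean_config"))
  out <- function(status, sample = NA_character_, gene = NA_character_,
                  gene_quals = NULL, orientation = NA_character_) {
    structure(list(read_id = id, status = status, sample = sample,
                   gene = gene, gene_quals = gene_quals,
                   orientation = orientation), class = "clean_outcome")
  }
  L1 <- nchar(seq)
  if (L1 < config$minL1 || L1 > config$maxL1) return(out("fail_L1"))

  tab <- config$sample_table
  no_mids <- length(config$mids) == 0
  if (no_mids) {
    core <- seq; core_quals <- quals
    samples <- c(tab$sample[tab$fw == 0 & tab$rv == 0][1], NA)
    key5 <- key3 <- NA_integer_
  } else {
    hit5 <- find_mid_at_end(seq, "five_prime", config)
    hit3 <- find_mid_at_end(seq, "three_prime", config)
    if (is.null(hit5) || is.null(hit3) ||
        hit5$orientation != "sense" || hit3$orientation != "antisense" ||
        hit5$stop >= hit3$start)
      return(out("fail_mids"))
    key5 <- hit5$mid_index; key3 <- hit3$mid_index
    s_fwd <- tab$sample[tab$fw == key5 & tab$rv == key3][1]
    s_rev <- tab$sample[tab$fw == key3 & tab$rv == key5][1]
    if (is.na(s_fwd) && is.na(s_rev)) return(out("fail_mids"))
    samples <- c(s_fwd, s_rev)
    core <- substr(seq, hit5$stop + 1L, hit3$start - 1L)
    core_quals <- quals[seq(hit5$stop + 1L, hit3$start - 1L)]
  }
  # provisional sample while orientation is unknown: 5'-as-forward order
  # first, then the flipped order
  provisional <- if (!is.na(samples[1])) samples[1] else samples[2]

  pr <- locate_primers(core, config)
  if (is.null(pr) || pr$chimeric)
    return(out("fail_primers", sample = provisional))

  orientation <- pr$gene_orientation
  sample <- if (no_mids) samples[1]
    else if (orientation == "sense") samples[1] else samples[2]
  if (is.na(sample)) return(out("fail_mids"))

  L2 <- max(0L, pr$gene_stop - pr$gene_start + 1L)
  if (L2 < config$minL2 || L2 > config$maxL2)
    return(out("fail_L2", sample = sample, orientation = orientation))

  gene <- substr(core, pr$gene_start, pr$gene_stop)
  gene_quals <- core_quals[seq(pr$gene_start, pr$gene_stop)]
  if (!(average_quality(gene_quals) > config$quality_threshold))
    return(out("fail_quality", sample = sample, orientation = orientation))

  if (orientation == "antisense") {
    gene <- reverse_complement(gene)
    gene_quals <- rev(gene_quals)
  }
  out("pass", sample = sample, gene = gene, gene_quals = gene_quals,
      orientation = orientation)
}

#' Clean a read set and write per-sample outputs and the run log
#'
#' Routes every read to exactly one destination. With an output
#' directory, writes `FailedInFindMIDs.txt`, `FailedInFindPrimers.txt`,
#' `FailedInCheckLength.txt` (both raw-length and between-primer length
#' failures), `FailedInQuality.txt` (all FASTA of the original untrimmed
#' reads), a gene-only `<sample>.txt` FASTA plus `<sample>.qual` per
#' sample, and the two-part tab-delimited `Log.txt`.
#'
#' @param reads an [ig_reads] object.
#' @param config a [clean_config].
#' @param outdir output directory, or `NULL` to skip file output.
#' @return A `clean_stats` object: per-sample table (`per_sample`),
#'   global counters (`totals`), and the outcome per read (`outcomes`).
#' @export
clean_dataset <- function(reads, config, outdir = NULL) {
  stopifnot(inherits(reads, "ig_reads"), inherits(config, "clean_config"))
  outcomes <- vector("list", length(reads))
  for (i in seq_len(length(reads)))
    outcomes[[i]] <- clean_read(reads$id[i], reads$seq[i], reads$qual[[i]],
                                config)
  status <- vapply(outcomes, `[[`, "", "status")
  sample <- vapply(outcomes, `[[`, "", "sample")
  orient <- vapply(outcomes, `[[`, "", "orientation")

  samples <- unique(config$sample_table$sample)
  per <- data.frame(sample = samples, total = 0L, failed_primers = 0L,
                    failed_length = 0L, failed_quality = 0L,
                    remaining = 0L, average_score = NaN,
                    stringsAsFactors = FALSE)
  for (k in seq_along(samples)) {
    in_s <- !is.na(sample) & sample == samples[k]
    per$total[k] <- sum(in_s)
    per$failed_primers[k] <- sum(in_s & status == "fail_primers")
    per$failed_length[k] <- sum(in_s & status == "fail_L2")
    per$failed_quality[k] <- sum(in_s & status == "fail_quality")
    per$remaining[k] <- sum(in_s & status == "pass")
    pass_q <- vapply(outcomes[in_s & status == "pass"],
                     function(o) mean(o$gene_quals), 0)
    per$average_score[k] <- if (length(pass_q)) mean(pass_q) else NaN
  }
  pct <- function(x, d) ifelse(d > 0, 100 * x / d, 0)
  per$pct_primers_of_total <- pct(per$failed_primers, per$total)
  per$pct_length_of_total <- pct(per$failed_length, per$total)
  per$pct_length_of_remaining <- pct(per$failed_length,
                                     per$total - per$failed_primers)
  per$pct_quality_of_total <- pct(per$failed_quality, per$total)
  per$pct_quality_of_remaining <-
    pct(per$failed_quality,
        per$total - per$failed_primers - per$failed_length)

  # fail_mids covers reads whose sample could never be attributed; they
  # are counted globally only
  totals <- list(
    reads_received = length(reads),
    failed_L1 = sum(status == "fail_L1"),
    failed_mids = sum(status == "fail_mids"),
    failed_primers = sum(status == "fail_primers"),
    failed_length = sum(status %in% c("fail_L1", "fail_L2")),
    failed_quality = sum(status == "fail_quality"),
    remaining = sum(status == "pass"),
    sense = sum(!is.na(orient) & orient == "sense" & status == "pass"),
    antisense = sum(!is.na(orient) & orient == "antisense" &
                      status == "pass")
  )
  stats <- structure(list(per_sample = per, totals = totals,
                          config = config, outcomes = outcomes),
                     class = "clean_stats")
  if (!is.null(outdir)) write_clean_outputs(reads, stats, outdir)
  stats
}

write_clean_outputs <- function(reads, stats, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  status <- vapply(stats$outcomes, `[[`, "", "status")
  write_fail <- function(file, keep) {
    sel <- which(keep)
    set <- Biostrings::DNAStringSet(setNames(reads$seq[sel], reads$id[sel]))
    Biostrings::writeXStringSet(set, file.path(outdir, file))
  }
  write_fail("FailedInFindMIDs.txt", status == "fail_mids")
  write_fail("FailedInFindPrimers.txt", status == "fail_primers")
  write_fail("FailedInCheckLength.txt", status %in% c("fail_L1", "fail_L2"))
  write_fail("FailedInQuality.txt", status == "fail_quality")
  sample <- vapply(stats$outcomes, `[[`, "", "sample")
  for (s in unique(stats$config$sample_table$sample)) {
    sel <- which(status == "pass" & !is.na(sample) & sample == s)
    genes <- ig_reads(reads$id[sel],
                      vapply(stats$outcomes[sel], `[[`, "", "gene"),
                      lapply(stats$outcomes[sel], `[[`, "gene_quals"))
    write_fasta_qual(genes, file.path(outdir, paste0(s, ".txt")),
                     file.path(outdir, paste0(s, ".qual")))
  }
  writeLines(format_clean_log(stats), file.path(outdir, "Log.txt"))
  invisible(stats)
}

#' Format the two-part cleaning log
#'
#' Part A is the tab-delimited per-sample table (sample, totals, failure
#' counts with their percentage columns, remaining count, average score);
#' part B reports run totals (reads received, L1/MID failures, sense and
#' antisense counts) and echoes the run parameters.
#'
#' @param stats a `clean_stats` object from [clean_dataset()].
#' @return Character vector of log lines.
#' @export
format_clean_log <- function(stats) {
  per <- stats$per_sample; t <- stats$totals; cfg <- stats$config
  fmt <- function(x) ifelse(is.nan(x), "NA", sprintf("%.2f", x))
  header <- paste(c("Sample", "Total", "Failed in primers", "% out of total",
                    "Failed in length", "% out of total", "% of the remaining",
                    "Failed in quality", "% out of total",
                    "% of the remaining", "Total remaining", "Average score"),
                  collapse = "\t")
  rows <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d\t%s\t%s\t%d\t%s",
                  per$sample, per$total, per$failed_primers,
                  fmt(per$pct_primers_of_total), per$failed_length,
                  fmt(per$pct_length_of_total),
                  fmt(per$pct_length_of_remaining), per$failed_quality,
                  fmt(per$pct_quality_of_total),
                  fmt(per$pct_quality_of_remaining), per$remaining,
                  fmt(per$average_score))
  c(header, rows, "",
    sprintf("Total sequences received\t%d", t$reads_received),
    sprintf("Failed in first length check (L1)\t%d", t$failed_L1),
    sprintf("Failed in finding MIDs\t%d", t$failed_mids),
    sprintf("Failed in finding primers\t%d", t$failed_primers),
    sprintf("Failed in length check\t%d", t$failed_length),
    sprintf("Failed in quality check\t%d", t$failed_quality),
    sprintf("Total remaining\t%d", t$remaining),
    sprintf("Sense\t%d", t$sense),
    sprintf("Antisense\t%d", t$antisense),
    "",
    sprintf("Organism\t%s", cfg$organism),
    sprintf("Chain\t%s", cfg$chain),
    sprintf("Quality threshold\t%g", cfg$quality_threshold),
    sprintf("Maximum mismatches allowed\t%d", cfg$max_mismatches),
    sprintf("Fraction of primer to search\t%g", cfg$primer_fraction),
    sprintf("Range to search primers in\t%d", cfg$search_range),
    sprintf("Minimal MID length\t%d", cfg$min_mid_len))
}

#' @export
print.clean_stats <- function(x, ...) {
  cat("<clean_stats>\n")
  cat(format_clean_log(x), sep = "\n")
  invisible(x)
}
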
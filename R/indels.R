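# Homopolymer-aware indel/mutation classifier: event extraction,
# homopolymer-tract logic, clone-sharing rules, AID-motif-aware
# low-quality point-mutation screening, and output routing.

#' Indel-screening parameters
#'
#' @param min_share minimum number of clone members (including the
#'   carrier) that must share an indel or a low-quality point mutation
#'   for it to be considered legitimate. The base rule "no other
#'   sequence shares it" corresponds to the default 2.
#' @param min_hpt_len minimum run length counted as a homopolymer tract
#'   (HPT). Short default (2) is deliberately broad: checking too many
#'   indels is preferred to keeping artifact ones.
#' @param min_qual minimal quality score for a point mutation to be
#'   trusted regardless of sharing; `-1` disables mutation screening.
#' @return An `indel_config` object.
#' @export
indel_config <- function(min_share = 2, min_hpt_len = 2, min_qual = -1) {
  stopifnot(min_share >= 1, min_hpt_len >= 1)
  structure(list(min_share = as.integer(min_share),
                 min_hpt_len = as.integer(min_hpt_len),
                 min_qual = as.integer(min_qual)),
            class = "indel_config")
}

#' Maximal homopolymer tracts of a sequence
#'
#' @param seq DNA string (no gaps).
#' @param min_len minimum run length reported.
#' @return Data frame with `start`, `end` (1-based inclusive), `base`,
#'   `length`, one row per maximal same-base run of length `>= min_len`.
#' @examples
#' find_hpts("AATCCC", 2)
#' @export
find_hpts <- function(seq, min_len) {
  stopifnot(min_len >= 1)
  ch <- strsplit(seq, "")[[1]]
  if (!length(ch))
    return(data.frame(start = integer(), end = integer(),
                      base = character(), length = integer()))
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             base = r$values[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

# per-column comparison of one member row against the germline row;
# columns where both rows are gaps are transparent: they neither break a
# gap run nor count toward its length
compare_rows <- function(member, germline) {
  if (nchar(member) != nchar(germline))
    stop("member and germline rows have unequal aligned lengths")
  mb <- strsplit(member, "")[[1]]
  gl <- strsplit(germline, "")[[1]]
  glmap <- cumsum(gl != "-")  # germline degapped position at/left of column

  state <- ifelse(gl == "-" & mb == "-", "skip",
           ifelse(gl == "-", "insertion",
           ifelse(mb == "-", "deletion",
           ifelse(gl == mb, "match", "mutation"))))

  indels <- list(); muts <- list()
  cur <- NULL  # open gap run: list(kind, col_start, col_end, length)
  close_run <- function() {
    if (!is.null(cur)) indels[[length(indels) + 1L]] <<- cur
    cur <<- NULL
  }
  for (j in seq_along(state)) {
    st <- state[j]
    if (st == "skip") next
    if (st %in% c("insertion", "deletion")) {
      if (!is.null(cur) && cur$kind == st) {
        cur$col_end <- j; cur$length <- cur$length + 1L
      } else {
        close_run()
        cur <- list(kind = st, col_start = j, col_end = j, length = 1L)
      }
    } else {
      close_run()
      if (st == "mutation")
        muts[[length(muts) + 1L]] <- list(column = j, gl_base = gl[j],
                                          read_base = mb[j],
                                          gl_pos = glmap[j])
    }
  }
  close_run()

  ind <- if (length(indels)) data.frame(
    kind = vapply(indels, `[[`, "", "kind"),
    col_start = vapply(indels, `[[`, 0L, "col_start"),
    col_end = vapply(indels, `[[`, 0L, "col_end"),
    length = vapply(indels, `[[`, 0L, "length"),
    stringsAsFactors = FALSE)
  else data.frame(kind = character(), col_start = integer(),
                  col_end = integer(), length = integer())
  # germline degapped coordinates: the deleted interval for deletions
  # (both run ends sit on germline bases); the two flanking positions for
  # insertions (glmap at a gap column counts the bases to its left)
  ind$gl_start <- glmap[ind$col_start]
  ind$gl_end <- ifelse(ind$kind == "deletion", glmap[ind$col_end],
                       glmap[ind$col_start] + 1L)
  mut <- if (length(muts)) data.frame(
    column = vapply(muts, `[[`, 0L, "column"),
    gl_base = vapply(muts, `[[`, "", "gl_base"),
    read_base = vapply(muts, `[[`, "", "read_base"),
    gl_pos = vapply(muts, `[[`, 0L, "gl_pos"),
    stringsAsFactors = FALSE)
  else data.frame(column = integer(), gl_base = character(),
                  read_base = character(), gl_pos = integer())
  list(indels = ind, mutations = mut)
}

#' Extract indel and mutation events from one aligned member row
#'
#' Compares a member row to the germline row position by position:
#' each maximal gap run becomes one event (gap in the germline row is an
#' insertion, gap in the member row a deletion), and each aligned
#' non-gap mismatch becomes a point-mutation event. Columns where both
#' rows are gaps are ignored.
#'
#' @param member,germline equal-length aligned strings.
#' @return List with data frames `indels` (`kind`, `col_start`,
#'   `col_end`, `length`, plus germline degapped coordinates `gl_start`,
#'   `gl_end`) and `mutations` (`column`, `gl_base`, `read_base`,
#'   `gl_pos`).
#' @examples
#' extract_events("ACTGT", "AC-GT")
#' @export
extract_events <- function(member, germline) {
  compare_rows(member, germline)
}

#' Is an indel inside or immediately adjacent to a homopolymer tract?
#'
#' An event is HPT-proximal when its germline locus is inside a tract of
#' length `>= min_hpt_len`, or at the position immediately 5' of such a
#' tract, or immediately 3' of it. Deletions carry the deleted germline
#' interval; insertions carry their two flanking germline positions.
#'
#' @param event list with `kind` (`"insertion"`/`"deletion"`) and
#'   germline degapped coordinates `gl_start`, `gl_end` (1-based
#'   inclusive; for insertions the left and right flanking positions).
#' @param germline_seq degapped germline string.
#' @param min_hpt_len minimum tract length.
#' @return `TRUE` or `FALSE`.
#' @export
is_near_hpt <- function(event, germline_seq, min_hpt_len) {
  hpts <- find_hpts(germline_seq, min_hpt_len)
  if (!nrow(hpts)) return(FALSE)
  if (event$kind == "deletion") {
    any(event$gl_start <= hpts$end + 1L & event$gl_end >= hpts$start - 1L)
  } else {
    any((event$gl_start >= hpts$start & event$gl_start <= hpts$end) |
        (event$gl_end >= hpts$start & event$gl_end <= hpts$end))
  }
}

#' Count clone members sharing an event
#'
#' Indels are shared when another member shows the same kind over the
#' same alignment-column interval; mutations when another member carries
#' the same substituted base at the same column. The carrier is included
#' in the count.
#'
#' @param event one row of an [extract_events()] data frame, as a list;
#'   mutations are recognised by the presence of `column`/`read_base`.
#' @param clone a [clonal_alignment].
#' @return Integer count.
#' @export
count_sharing <- function(event, clone) {
  stopifnot(inherits(clone, "clonal_alignment"))
  evs <- lapply(clone$members, compare_rows, germline = clone$germline)
  if (!is.null(event$column)) {
    sum(vapply(evs, function(e)
      any(e$mutations$column == event$column &
            e$mutations$read_base == event$read_base), TRUE))
  } else {
    sum(vapply(evs, function(e)
      any(e$indels$kind == event$kind &
            e$indels$col_start == event$col_start &
            e$indels$col_end == event$col_end), TRUE))
  }
}

#' Is a germline position inside an AID hotspot motif?
#'
#' The AID (activation-induced cytidine deaminase) hotspot motifs
#' containing a homopolymer pair are `AACA` and its complement `TGTT`;
#' a low-quality point mutation inside either is retained as plausibly
#' biological.
#'
#' @param position 1-based position on the degapped germline.
#' @param germline_seq degapped germline string.
#' @return `TRUE` or `FALSE`.
#' @examples
#' in_aid_motif(3, "GGAACAGG")
#' @export
in_aid_motif <- function(position, germline_seq) {
  for (motif in c("AACA", "TGTT")) {
    m <- gregexpr(paste0("(?=", motif, ")"), germline_seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    if (any(position >= m & position <= m + 3L)) return(TRUE)
  }
  FALSE
}

# classify one member given precomputed events for the whole clone
classify_events <- function(self, all_events, gl_deg, clone_size, quals,
                            config) {
  ev <- all_events[[self]]
  share_indel <- function(row) {
    sum(vapply(all_events, function(e)
      any(e$indels$kind == row$kind & e$indels$col_start == row$col_start &
            e$indels$col_end == row$col_end), TRUE))
  }
  share_mut <- function(row) {
    sum(vapply(all_events, function(e)
      any(e$mutations$column == row$column &
            e$mutations$read_base == row$read_base), TRUE))
  }
  # interleave events in alignment order, as the position-by-position
  # scan does: the first terminal verdict ends the sequence's screening
  items <- rbind(
    if (nrow(ev$indels))
      data.frame(col = ev$indels$col_start, type = "indel",
                 idx = seq_len(nrow(ev$indels))),
    if (nrow(ev$mutations))
      data.frame(col = ev$mutations$column, type = "mutation",
                 idx = seq_len(nrow(ev$mutations))))
  has_indel <- nrow(ev$indels) > 0
  uncertain <- FALSE
  if (!is.null(items) && nrow(items)) {
    items <- items[order(items$col), , drop = FALSE]
    for (k in seq_len(nrow(items))) {
      if (items$type[k] == "indel") {
        row <- as.list(ev$indels[items$idx[k], ])
        if (!is_near_hpt(row, gl_deg, config$min_hpt_len)) next  # legitimate
        if (share_indel(row) >= config$min_share) next           # shared
        if (clone_size == 1) { uncertain <- TRUE; next }
        return("artifact_indel")
      } else if (config$min_qual >= 0) {
        row <- as.list(ev$mutations[items$idx[k], ])
        q <- if (!is.null(quals)) quals[row$read_pos] else NA_integer_
        if (!is.na(q) && q >= config$min_qual) next
        if (in_aid_motif(row$gl_pos, gl_deg)) next
        if (clone_size > 1 && share_mut(row) < config$min_share)
          return("low_qual_mutation")
      }
    }
  }
  if (uncertain) return("uncertain")
  if (has_indel) "with_legitimate_indels" else "without_indels"
}

#' Classify one clone member
#'
#' Applies the screening rules to every indel and point mutation of one
#' member, in alignment order. An indel away from any homopolymer tract,
#' or shared by at least `min_share` members, is legitimate; an
#' HPT-proximal under-shared indel makes the sequence an artifact
#' (`artifact_indel`) in a multi-member clone, or `uncertain` in a
#' singleton clone. With `min_qual >= 0`, a point mutation below the
#' quality threshold that is outside the AID motifs and under-shared in
#' a multi-member clone makes the sequence `low_qual_mutation`. Terminal
#' verdicts dominate; otherwise `uncertain` dominates
#' `with_legitimate_indels` / `without_indels`.
#'
#' @param member name of the member row.
#' @param clone a [clonal_alignment].
#' @param quals integer vector of per-base scores for the member's
#'   degapped read, or `NULL` when unavailable.
#' @param config an [indel_config].
#' @return One of `"without_indels"`, `"with_legitimate_indels"`,
#'   `"uncertain"`, `"artifact_indel"`, `"low_qual_mutation"`.
#' @export
classify_sequence <- function(member, clone, quals = NULL, config) {
  stopifnot(inherits(clone, "clonal_alignment"),
            inherits(config, "indel_config"),
            member %in% names(clone$members))
  all_events <- lapply(clone$members, annotate_events, clone = clone)
  classify_events(member, all_events, degap(clone$germline),
                  length(clone$members), quals, config)
}

# events of one member with read positions attached
annotate_events <- function(row, clone) {
  ev <- compare_rows(row, clone$germline)
  if (nrow(ev$mutations)) {
    map <- column_map(row)
    ev$mutations$read_pos <- map[ev$mutations$column]
  } else ev$mutations$read_pos <- integer()
  ev
}

#' Classify every member of every clone
#'
#' @param clones list of [clonal_alignment] objects.
#' @param quals named list mapping member ids to integer score vectors
#'   (may be `NULL`).
#' @param config an [indel_config].
#' @return Data frame with `clone_id`, `member`, `class`.
#' @export
classify_clones <- function(clones, quals = NULL, config = indel_config()) {
  res <- lapply(clones, function(cl) {
    all_events <- lapply(cl$members, annotate_events, clone = cl)
    gl_deg <- degap(cl$germline)
    cls <- vapply(names(cl$members), function(nm)
      classify_events(nm, all_events, gl_deg, length(cl$members),
                      quals[[nm]], config), "")
    data.frame(clone_id = cl$clone_id, member = names(cl$members),
               class = unname(cls), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Run the indel identifier and write its outputs
#'
#' Routes every sequence to exactly one of four FASTA files:
#' `<name>-WithoutIndels.txt` (no artifact or uncertain indels,
#' including legitimate-indel sequences), `<name>-CloneOfSize1WithIndels.txt`
#' (uncertain), `<name>-IllegitimateIndels.txt` (artifact indels) and
#' `<name>-SeqsWithLowQualPointMuts.txt`; writes per-class counts to
#' `<name>-Ig-Indel-Identifier.log`.
#'
#' @inheritParams classify_clones
#' @param outdir output directory, or `NULL` to skip file output.
#' @param name stem for the output file names.
#' @return An `indel_summary`: list with the verdict table (`verdicts`)
#'   and per-class `counts`.
#' @export
run_indel_identifier <- function(clones, quals = NULL,
                                 config = indel_config(), outdir = NULL,
                                 name = "sample") {
  verdicts <- classify_clones(clones, quals, config)
  files <- c(without_indels = "WithoutIndels",
             with_legitimate_indels = "WithoutIndels",
             uncertain = "CloneOfSize1WithIndels",
             artifact_indel = "IllegitimateIndels",
             low_qual_mutation = "SeqsWithLowQualPointMuts")
  counts <- table(factor(verdicts$class, levels = names(files)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seqs <- unlist(lapply(clones, function(cl)
      setNames(vapply(cl$members, degap, ""), names(cl$members))))
    for (f in unique(files)) {
      sel <- verdicts$member[files[verdicts$class] == f]
      set <- Biostrings::DNAStringSet(seqs[sel])
      Biostrings::writeXStringSet(
        set, file.path(outdir, sprintf("%s-%s.txt", name, f)))
    }
    writeLines(c(
      sprintf("Sequences processed\t%d", nrow(verdicts)),
      sprintf("%s\t%d", names(counts), as.integer(counts)),
      sprintf("Parameters: min_share=%d min_hpt_len=%d min_qual=%d",
              config$min_share, config$min_hpt_len, config$min_qual)),
      file.path(outdir, sprintf("%s-Ig-Indel-Identifier.log", name)))
  }
  structure(list(verdicts = verdicts, counts = counts, config = config),
            class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf("<indel_summary> %d sequence(s)\n", nrow(x$verdicts)))
  print(x$counts)
  invisible(x)
}
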
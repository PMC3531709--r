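# Shared fixtures and independent oracles for the test suite.

# a run configuration over the standard basic MID set and the human
# Ig primer set, with three MID-keyed samples
default_config <- function(...) {
  clean_config(
    mids = basic_mid_set(),
    forward_primers = example_primers("human")$forward,
    reverse_primers = example_primers("human")$reverse,
    sample_table = data.frame(fw = c(1, 2, 3), rv = c(7, 8, 9),
                              sample = c("s1", "s2", "s3")),
    ...)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

degap_for_test <- function(x) gsub("-", "", x, fixed = TRUE)

# --- edit-distance oracles -------------------------------------------------

# brute force over every substring (plain A/C/G/T patterns): vectorised
# C Levenshtein from utils::adist
oracle_min_edit_plain <- function(window, pattern) {
  n <- nchar(window)
  idx <- which(upper.tri(matrix(TRUE, n + 1, n + 1), diag = FALSE),
               arr.ind = TRUE)
  subs <- substring(window, idx[, 1], idx[, 2] - 1L)  # all substrings
  min(c(nchar(pattern), utils::adist(subs, pattern)))
}

# tiny pure-R IUPAC-aware Levenshtein (for degenerate-pattern cases on
# short windows), written as a plain full-matrix DP per substring
oracle_edit_iupac <- function(pattern, sub) {
  m <- nchar(pattern); n <- nchar(sub)
  pa <- strsplit(pattern, "")[[1]]; wb <- strsplit(sub, "")[[1]]
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m; D[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n)) {
    cost <- if (iupac_match(wb[j], pa[i])) 0L else 1L
    D[i + 1, j + 1] <- min(D[i, j] + cost, D[i, j + 1] + 1L,
                           D[i + 1, j] + 1L)
  }
  D[m + 1, n + 1]
}

oracle_min_edit_iupac <- function(window, pattern) {
  n <- nchar(window)
  best <- nchar(pattern)  # empty substring: delete the whole pattern
  for (s in seq_len(n)) for (e in s:n)
    best <- min(best, oracle_edit_iupac(pattern, substr(window, s, e)))
  best
}

# --- homopolymer oracles ---------------------------------------------------

# exhaustive maximal-run scan: test every interval for run-ness and
# maximality
oracle_hpts <- function(seq, min_len) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (length(unique(ch[s:e])) != 1) next
      maximal <- (s == 1 || ch[s - 1] != ch[s]) &&
        (e == n || ch[e + 1] != ch[e])
      if (maximal && (e - s + 1) >= min_len)
        out <- rbind(out, data.frame(start = s, end = e, base = ch[s],
                                     length = e - s + 1))
    }
  }
  if (is.null(out))
    data.frame(start = integer(), end = integer(), base = character(),
               length = integer())
  else out
}

oracle_near_hpt <- function(kind, gl_start, gl_end, seq, min_len) {
  tr <- oracle_hpts(seq, min_len)
  if (!nrow(tr)) return(FALSE)
  for (k in seq_len(nrow(tr))) {
    if (kind == "deletion") {
      # positions the tract makes suspect: its own plus one either side
      suspect <- (tr$start[k] - 1L):(tr$end[k] + 1L)
      if (any(seq(gl_start, gl_end) %in% suspect)) return(TRUE)
    } else {
      inside <- tr$start[k]:tr$end[k]
      if (gl_start %in% inside || gl_end %in% inside) return(TRUE)
    }
  }
  FALSE
}

# --- MID-set oracle --------------------------------------------------------

# explicit pairwise check over every inner length, coded as loops over
# pairs and orientations rather than set deduplication
oracle_inner_length <- function(mids) {
  rc <- reverse_complement(mids)
  for (k in seq_len(min(nchar(mids)))) {
    frag <- function(x) substr(x, nchar(x) - k + 1, nchar(x))
    labels <- c(paste0("s", seq_along(mids)), paste0("a", seq_along(mids)))
    frags <- c(vapply(mids, frag, ""), vapply(rc, function(x)
      substr(x, 1, k), ""))
    # antisense inner fragment = first k of the reverse complement
    ok <- TRUE
    for (i in seq_along(frags)) for (j in seq_along(frags))
      if (i < j && frags[i] == frags[j]) ok <- FALSE
    if (ok) return(k)
  }
  max(nchar(mids)) + 1L
}

# a minimal hand-built clone: germline plus n identical members with an
# optional edit applied to the first member
small_clone <- function(germline, members, clone_id = "cl") {
  clonal_alignment(germline, members, clone_id = clone_id,
                   germline_id = paste0("GL_", clone_id))
}
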
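# Ground-truth generators: the deletion-injection simulator for
# benchmarking the indel classifier, a clonal-alignment fixture builder,
# and a synthetic 454-style read generator for testing the cleaner.

# sample() without its scalar-x surprise
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Deletion-injection simulation parameters
#'
#' @param p_del probability that a sequence receives a deletion.
#' @param hpt_len_range integer range the homopolymer-tract length is
#'   drawn from (uniform, redrawn until the sequence has a maximal run
#'   of exactly the drawn length).
#' @param dup_range integer range for the number of appended duplicate
#'   sequences carrying the same deletion (uniform).
#' @param seed seed used by [simulate_dataset()].
#' @return A `sim_params` object.
#' @export
sim_params <- function(p_del = 0.5, hpt_len_range = c(2L, 10L),
                       dup_range = c(0L, 10L), seed = 1L) {
  stopifnot(p_del >= 0, p_del <= 1, hpt_len_range[1] <= hpt_len_range[2],
            dup_range[1] <= dup_range[2])
  structure(list(p_del = p_del,
                 hpt_len_range = as.integer(hpt_len_range),
                 dup_range = as.integer(dup_range),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Inject at most one deletion per clone member
#'
#' For each member, with probability `p_del`: draw a tract length
#' uniformly from `hpt_len_range` restricted to the maximal-run lengths
#' actually present in the member (a bounded equivalent of redrawing
#' until a tract of the drawn length exists; a member with no drawable
#' tract is recorded as not injected); draw one such tract uniformly;
#' draw the deletion position uniformly from the tract's interior
#' positions plus its two flanking positions, never the first or last
#' position of the sequence; replace that base with `-`; and append a
#' uniformly drawn number of duplicate copies (ids suffixed `_dupN`).
#'
#' @param clone a [clonal_alignment] whose member rows contain no
#'   pre-existing gaps.
#' @param params a [sim_params].
#' @param seed optional seed (left untouched when `NULL`, so a caller
#'   can drive many clones from one RNG stream).
#' @return List with the simulated `clone` and a `truth` data frame
#'   (`id`, `injected`, `hpt_length`, `position`, `placement`,
#'   `duplicates`).
#' @export
inject_deletions <- function(clone, params, seed = NULL) {
  stopifnot(inherits(clone, "clonal_alignment"),
            inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (any(grepl("-", clone$members, fixed = TRUE)))
    stop("clone members must contain no pre-existing gaps")
  members <- clone$members
  out_members <- character(0)
  truth <- list()
  for (nm in names(members)) {
    row <- members[[nm]]
    rec <- list(id = nm, injected = FALSE, hpt_length = NA_integer_,
                position = NA_integer_, placement = NA_character_,
                duplicates = 0L)
    dups <- 0L
    if (runif(1) < params$p_del) {
      runs <- find_hpts(row, 1L)
      lens <- intersect(seq(params$hpt_len_range[1],
                            params$hpt_len_range[2]),
                        unique(runs$length))
      if (length(lens)) {
        L <- resample(lens)
        tracts <- runs[runs$length == L, , drop = FALSE]
        t_i <- resample(seq_len(nrow(tracts)))
        cand <- seq(tracts$start[t_i] - 1L, tracts$end[t_i] + 1L)
        cand <- cand[cand >= 2L & cand <= nchar(row) - 1L]
        pos <- resample(cand)
        placement <- if (pos < tracts$start[t_i]) "five_prime"
          else if (pos > tracts$end[t_i]) "three_prime" else "inside"
        substr(row, pos, pos) <- "-"
        dups <- resample(seq(params$dup_range[1], params$dup_range[2]))
        rec <- list(id = nm, injected = TRUE, hpt_length = L,
                    position = pos, placement = placement,
                    duplicates = dups)
      }
    }
    out_members <- c(out_members, setNames(row, nm))
    if (dups > 0)
      out_members <- c(out_members,
                       setNames(rep(row, dups),
                                paste0(nm, "_dup", seq_len(dups))))
    truth[[length(truth) + 1L]] <- rec
  }
  truth_df <- do.call(rbind, lapply(truth, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(clone = clonal_alignment(clone$germline, out_members,
                                clone_id = clone$clone_id,
                                germline_id = clone$germline_id),
       truth = truth_df)
}

#' Simulate deletions across a set of clones
#'
#' Seeds the RNG once from `params$seed` and applies
#' [inject_deletions()] to every clone.
#'
#' @param clones list of [clonal_alignment] objects.
#' @param params a [sim_params].
#' @return List with `clones` (simulated) and the combined `truth`
#'   table (with a `clone_id` column).
#' @export
simulate_dataset <- function(clones, params) {
  set.seed(params$seed)
  sims <- lapply(clones, inject_deletions, params = params)
  truth <- do.call(rbind, lapply(sims, function(s) {
    s$truth$clone_id <- s$clone$clone_id
    s$truth
  }))
  list(clones = lapply(sims, `[[`, "clone"), truth = truth)
}

#' Identification-fraction grid over classifier parameters
#'
#' Simulates deletions once, then runs the classifier over every
#' (`min_hpt_len`, `min_share`) combination and reports the percentage
#' of injected deletions whose carrier is classified as an artifact
#' (identified deletions / injected deletions x 100), both over all
#' injected sequences and restricted to multi-member clones.
#'
#' @param clones list of [clonal_alignment] objects (no gaps in
#'   members).
#' @param params a [sim_params].
#' @param hpt_lens vector of `min_hpt_len` values (grid rows).
#' @param share_thresholds vector of `min_share` values (grid columns).
#' @return List with matrices `grid` and `grid_multi` (rows named by
#'   `hpt_lens`, columns by `share_thresholds`), counts `n_injected`
#'   and `n_injected_multi`, and the simulation `truth` table.
#' @export
sweep_identification <- function(clones, params, hpt_lens = 2:5,
                                 share_thresholds = 1:12) {
  sim <- simulate_dataset(clones, params)
  prep <- lapply(sim$clones, function(cl) list(
    events = lapply(cl$members, annotate_events, clone = cl),
    gl = degap(cl$germline), size = length(cl$members),
    clone_id = cl$clone_id))
  sizes <- setNames(vapply(prep, `[[`, 0L, "size"),
                    vapply(prep, `[[`, "", "clone_id"))
  truth <- sim$truth
  inj <- truth[truth$injected, , drop = FALSE]
  inj_multi <- inj[sizes[inj$clone_id] > 1, , drop = FALSE]

  grid <- matrix(NA_real_, length(hpt_lens), length(share_thresholds),
                 dimnames = list(hpt_lens, share_thresholds))
  grid_multi <- grid
  for (hi in seq_along(hpt_lens)) {
    for (ti in seq_along(share_thresholds)) {
      cfg <- indel_config(min_share = share_thresholds[ti],
                          min_hpt_len = hpt_lens[hi], min_qual = -1)
      art <- unlist(lapply(prep, function(p)
        vapply(names(p$events), function(nm)
          classify_events(nm, p$events, p$gl, p$size, NULL, cfg) ==
            "artifact_indel", TRUE)))
      ids <- names(art)[art]
      grid[hi, ti] <- 100 * mean(inj$id %in% ids)
      grid_multi[hi, ti] <- if (nrow(inj_multi))
        100 * mean(inj_multi$id %in% ids) else NaN
    }
  }
  list(grid = grid, grid_multi = grid_multi,
       n_injected = nrow(inj), n_injected_multi = nrow(inj_multi),
       truth = truth, clones = sim$clones)
}

#' Generate a clonal-alignment fixture set
#'
#' Builds random clones of ungapped members around a random germline.
#' Member point mutations are placed only at positions that are neither
#' inside nor adjacent to any germline run of two or more identical
#' bases, and the substituted base always differs from both neighbours;
#' member homopolymer structure therefore equals the germline's exactly,
#' which is what makes deletion-injection round-trips exact.
#'
#' @param n_clones number of clones.
#' @param size_range inclusive range clone sizes are drawn from
#'   (uniform).
#' @param seq_length germline length in nt.
#' @param mutation_rate expected per-member fraction of mutated
#'   eligible positions.
#' @param seed RNG seed.
#' @return List with `clones` (list of [clonal_alignment]) and `quals`
#'   (named list of integer score vectors per member).
#' @export
generate_clonal_fixture <- function(n_clones = 85, size_range = c(1, 12),
                                    seq_length = 300, mutation_rate = 0.01,
                                    seed = 1L) {
  set.seed(seed)
  clones <- vector("list", n_clones)
  quals <- list()
  for (k in seq_len(n_clones)) {
    gl <- random_dna(seq_length)
    ch <- strsplit(gl, "")[[1]]
    rl <- rep(rle(ch)$lengths, rle(ch)$lengths)
    n <- length(ch)
    eligible <- which(seq_len(n) > 1 & seq_len(n) < n &
                        rl == 1 & c(2, rl[-n]) == 1 & c(rl[-1], 2) == 1)
    size <- resample(seq(size_range[1], size_range[2]))
    members <- character(size)
    for (s in seq_len(size)) {
      mb <- ch
      nmut <- rbinom(1, length(eligible), mutation_rate)
      for (p in resample(eligible, min(nmut, length(eligible)))) {
        mb[p] <- resample(setdiff(c("A", "C", "G", "T"),
                                  c(mb[p - 1], mb[p], mb[p + 1])))
      }
      members[s] <- paste(mb, collapse = "")
    }
    ids <- sprintf("c%03d_s%02d", k, seq_len(size))
    clones[[k]] <- clonal_alignment(gl, setNames(members, ids),
                                    clone_id = sprintf("clone%03d", k),
                                    germline_id = sprintf("GL_c%03d", k))
    for (id in ids)
      quals[[id]] <- sample(30:40, seq_length, replace = TRUE)
  }
  list(clones = clones, quals = quals)
}

#' Generate a synthetic amplicon read fixture with planted failures
#'
#' Assembles 454-style reads as adapter + forward MID + realised forward
#' primer (IUPAC codes resolved randomly) + random gene + reverse
#' complement of the reverse primer + reverse complement of the reverse
#' MID + adapter, reverse-complementing roughly half of them, and plants
#' one defect per requested failure mode: raw length out of bounds
#' (`fail_L1`), a destroyed 5' MID (`fail_mids`), a forward primer
#' corrupted beyond the edit budget (`fail_primers`), a too-short gene
#' (`fail_L2`), or low gene-region quality (`fail_quality`). The truth
#' table records the intended outcome and sample of every read.
#'
#' @param spec named integer vector of read counts per mode; names from
#'   `clean`, `fail_L1`, `fail_mids`, `fail_primers`, `fail_L2`,
#'   `fail_quality`.
#' @param config a [clean_config] with at least one MID-keyed sample.
#' @param seed RNG seed.
#' @return List with `reads` (an [ig_reads]) and `truth` (data frame
#'   `id`, `expected`, `sample`, `orientation`).
#' @export
generate_clean_fixture <- function(spec, config, seed = 1L) {
  stopifnot(inherits(config, "clean_config"), length(config$mids) > 0)
  allowed <- c("clean", "fail_L1", "fail_mids", "fail_primers", "fail_L2",
               "fail_quality")
  if (is.null(names(spec)) || !all(names(spec) %in% allowed))
    stop("spec names must be among: ", paste(allowed, collapse = ", "))
  set.seed(seed)
  tab <- config$sample_table[config$sample_table$fw > 0, , drop = FALSE]
  if (!nrow(tab)) stop("config has no MID-keyed samples")
  modes <- rep(names(spec), as.integer(spec))

  realize <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(ch)
      resample(setdiff(iupac_expand[[ch]], "N")), ""), collapse = "")
  }
  k <- config$min_mid_len
  mid_decoys_absent <- function(window5) {
    pats <- c(config$mids, reverse_complement(config$mids),
              substring(config$mids, nchar(config$mids) - k + 1L))
    !any(vapply(pats, function(p) grepl(p, window5, fixed = TRUE), TRUE))
  }

  ids <- sprintf("read%04d", seq_along(modes))
  seqs <- character(length(modes)); quals <- vector("list", length(modes))
  truth <- data.frame(id = ids, expected = modes,
                      sample = NA_character_,
                      orientation = NA_character_,
                      stringsAsFactors = FALSE)
  # total full-MID occurrences (either orientation) in a window; fixture
  # reads must show exactly the planted tag, or junction-made decoys
  # could out-compete it in the closest-to-the-end tie-break
  full_mid_hits <- function(window) {
    pats <- c(config$mids, reverse_complement(config$mids))
    sum(vapply(pats, function(p) {
      m <- gregexpr(p, window, fixed = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, 0L))
  }

  for (i in seq_along(modes)) {
    mode <- modes[i]
    row <- tab[1L + (i - 1L) %% nrow(tab), ]
    fw_template <- resample(config$forward_primers)
    rv_template <- resample(config$reverse_primers)
    repeat {  # whole-read redraw when a window is not decoy-clean
    fw_mid <- config$mids[row$fw]; rv_mid <- config$mids[row$rv]
    fwp <- realize(fw_template)
    rvp <- realize(rv_template)
    adapter5 <- random_dna(6); adapter3 <- random_dna(6)
    overhead <- nchar(adapter5) + nchar(adapter3) + nchar(fw_mid) +
      nchar(rv_mid) + nchar(fwp) + nchar(rvp)
    gmin <- max(config$minL2, config$minL1 - overhead + 1L)
    gmax <- min(config$maxL2, config$maxL1 - overhead - 1L)
    if (gmin > gmax) stop("length bounds leave no feasible gene length")
    glen <- resample(seq(gmin, gmax))
    gene <- random_dna(glen)
    gene_q <- sample(30:40, glen, replace = TRUE)

    if (mode == "fail_quality")
      gene_q <- sample(5:15, glen, replace = TRUE)
    if (mode == "fail_L2") {
      glen <- config$minL2 - 10L
      if (glen < 1) stop("minL2 too small to plant a short gene")
      gene <- random_dna(glen)
      gene_q <- sample(30:40, glen, replace = TRUE)
      pad <- config$minL1 - (overhead + glen) + 10L
      adapter3 <- paste0(adapter3, random_dna(max(0L, pad)))
    }
    if (mode == "fail_mids") {
      # every component of the checked window is redrawn on failure, so
      # an accidental MID decoy in the primer or gene cannot trap the loop
      repeat {
        fw_mid <- random_dna(nchar(fw_mid))
        # re-realise the same primer so the read length is unchanged
        fwp <- realize(fw_template)
        adapter5 <- random_dna(6)
        gene <- random_dna(glen)
        win <- substr(paste0(adapter5, fw_mid, fwp, gene), 1,
                      config$search_range)
        if (mid_decoys_absent(win)) break
      }
    }
    if (mode == "fail_primers") {
      budget <- config$max_mismatches
      trimmed <- vapply(c(config$forward_primers,
                          reverse_complement(config$forward_primers)),
                        trim_primer, "", fraction = config$primer_fraction)
      repeat {
        fwp <- random_dna(nchar(fwp))
        gene <- random_dna(glen)
        win <- substr(paste0(fwp, gene), 1, config$search_range)
        dmin <- min(vapply(trimmed, function(tp)
          min_edit_occurrence(win, tp)$edits, 0L))
        if (dmin > budget) break
      }
    }

    parts <- c(adapter5, fw_mid, fwp, gene, reverse_complement(rvp),
               reverse_complement(rv_mid), adapter3)
    seq <- paste(parts, collapse = "")
    if (mode == "fail_mids") break
    r <- config$search_range; n <- nchar(seq)
    if (full_mid_hits(substr(seq, 1, min(r, n))) == 1L &&
        full_mid_hits(substr(seq, max(1L, n - r + 1L), n)) == 1L) break
    }
    q <- c(sample(32:40, nchar(adapter5) + nchar(fw_mid) + nchar(fwp),
                  replace = TRUE),
           gene_q,
           sample(32:40, nchar(rvp) + nchar(rv_mid) + nchar(adapter3),
                  replace = TRUE))
    if (mode == "fail_L1") {
      extra <- config$maxL1 - nchar(seq) + 10L
      seq <- paste0(seq, random_dna(max(1L, extra)))
      q <- c(q, sample(32:40, max(1L, extra), replace = TRUE))
    }
    orientation <- if (runif(1) < 0.5) "sense" else "antisense"
    if (orientation == "antisense") {
      seq <- reverse_complement(seq)
      q <- rev(q)
    }
    seqs[i] <- seq; quals[[i]] <- q
    truth$orientation[i] <- orientation
    truth$sample[i] <- if (mode %in% c("fail_L1", "fail_mids"))
      NA_character_ else row$sample
  }
  list(reads = ig_reads(ids, seqs, quals), truth = truth)
}
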
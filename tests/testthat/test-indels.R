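test_that("homopolymer tracts are the maximal runs above the cutoff", {
  expect_equal(nrow(find_hpts("ACGT", 2)), 0)
  hp <- find_hpts("AATCCC", 2)
  expect_equal(hp$start, c(1, 4))
  expect_equal(hp$end, c(2, 6))
  expect_equal(hp$base, c("A", "C"))
  expect_equal(nrow(find_hpts("AAAA", 5)), 0)  # below cutoff

  set.seed(21)
  for (rep in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1),
                      replace = TRUE, prob = c(.4, .3, .2, .1)),
               collapse = "")
    ml <- sample(1:4, 1)
    got <- find_hpts(s, ml); want <- oracle_hpts(s, ml)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("event extraction reports maximal gap runs and mismatches", {
  none <- extract_events("ACGTT", "ACGTT")
  expect_equal(nrow(none$indels), 0)
  expect_equal(nrow(none$mutations), 0)

  ins <- extract_events("ACTGT", "AC-GT")  # gap in the germline row
  expect_equal(ins$indels$kind, "insertion")
  expect_equal(c(ins$indels$col_start, ins$indels$col_end), c(3, 3))
  expect_equal(ins$indels$length, 1)

  del <- extract_events("AC--T", "ACGGT")  # maximal two-column run
  expect_equal(del$indels$kind, "deletion")
  expect_equal(del$indels$length, 2)
  expect_equal(c(del$indels$gl_start, del$indels$gl_end), c(3, 4))

  mut <- extract_events("ACGTA", "ACCTA")
  expect_equal(nrow(mut$indels), 0)
  expect_equal(mut$mutations$column, 3)
  expect_equal(mut$mutations$gl_base, "C")
  expect_equal(mut$mutations$read_base, "G")

  expect_error(extract_events("ACG", "ACGT"), "unequal")
})

test_that("HPT proximity covers inside and both flanks, and nothing else", {
  # deletion of the middle A in CAAAG
  expect_true(is_near_hpt(list(kind = "deletion", gl_start = 3, gl_end = 3),
                          "CAAAG", 3))
  # deletion of the C immediately 5' of the tract
  expect_true(is_near_hpt(list(kind = "deletion", gl_start = 1, gl_end = 1),
                          "CAAAG", 3))
  # deletion of the G immediately 3' of the tract
  expect_true(is_near_hpt(list(kind = "deletion", gl_start = 5, gl_end = 5),
                          "CAAAG", 3))
  # no tract of length 2 exists anywhere in an alternating sequence
  for (p in 1:8)
    expect_false(is_near_hpt(list(kind = "deletion", gl_start = p,
                                  gl_end = p), "ACGTACGT", 2))

  set.seed(77)
  for (rep in 1:60) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                      prob = c(.4, .3, .2, .1)), collapse = "")
    ml <- sample(2:4, 1)
    p <- sample(2:29, 1)
    ev <- list(kind = "deletion", gl_start = p, gl_end = p)
    expect_equal(is_near_hpt(ev, s, ml),
                 oracle_near_hpt("deletion", p, p, s, ml), info = s)
    evi <- list(kind = "insertion", gl_start = p, gl_end = p + 1)
    expect_equal(is_near_hpt(evi, s, ml),
                 oracle_near_hpt("insertion", p, p + 1, s, ml), info = s)
  }
})

test_that("sharing counts identical events including the carrier", {
  gl <- "ACGGGTACGT"
  cl <- small_clone(gl, c(m1 = "AC-GGTACGT", m2 = "ACGGGTACGT",
                          m3 = "ACGGGTACGT"))
  ev <- as.list(extract_events(cl$members[["m1"]], gl)$indels[1, ])
  expect_equal(count_sharing(ev, cl), 1)

  cl3 <- small_clone(gl, c(m1 = "AC-GGTACGT", m2 = "AC-GGTACGT",
                           m3 = "AC-GGTACGT"))
  expect_equal(count_sharing(ev, cl3), 3)

  # same start column, different run length: a different indel
  cl_mix <- small_clone(gl, c(m1 = "AC-GGTACGT", m2 = "AC--GTACGT"))
  expect_equal(count_sharing(ev, cl_mix), 1)

  # mutations share by column and substituted base
  clm <- small_clone("ACGT", c(m1 = "AGGT", m2 = "AGGT", m3 = "ATGT"))
  mu <- as.list(extract_events("AGGT", "ACGT")$mutations[1, ])
  expect_equal(count_sharing(mu, clm), 2)
})

test_that("AID motif lookup covers AACA and TGTT occurrences", {
  expect_true(in_aid_motif(3, "GGAACAGG"))
  expect_true(in_aid_motif(4, "GGTGTTGG"))
  expect_false(in_aid_motif(1, "GGAACAGG"))
  for (p in 1:8) expect_false(in_aid_motif(p, "GGGGGGGG"))
  # overlapping occurrences are still found
  expect_true(in_aid_motif(5, "AACAACA"))
})

test_that("classification follows the artifact / uncertain / AID rules", {
  gl <- "GGCAATTGGC"  # AA tract at 4-5
  # unique deletion inside the AA tract, 3-member clone, min_share 2
  cl <- small_clone(gl, c(m1 = "GGCA-TTGGC", m2 = "GGCAATTGGC",
                          m3 = "GGCAATTGGC"))
  cfg <- indel_config(min_share = 2, min_hpt_len = 2, min_qual = -1)
  expect_equal(classify_sequence("m1", cl, NULL, cfg), "artifact_indel")
  expect_equal(classify_sequence("m2", cl, NULL, cfg), "without_indels")

  # the same deletion in a singleton clone cannot be judged: uncertain
  single <- small_clone(gl, c(m1 = "GGCA-TTGGC"))
  expect_equal(classify_sequence("m1", single, NULL, cfg), "uncertain")

  # a low-quality mutation inside AACA is kept
  gl2 <- "GGAACAGGTT"
  clm <- small_clone(gl2, c(m1 = "GGATCAGGTT", m2 = "GGAACAGGTT"))
  cfgq <- indel_config(min_share = 2, min_hpt_len = 2, min_qual = 10)
  quals <- rep(8L, 10)
  expect_equal(classify_sequence("m1", clm, quals, cfgq), "without_indels")
  # outside the motif the same low-quality unique mutation discards
  clm2 <- small_clone(gl2, c(m1 = "GGAACAGGTA", m2 = "GGAACAGGTT"))
  expect_equal(classify_sequence("m1", clm2, quals, cfgq),
               "low_qual_mutation")
  # high quality keeps it
  expect_equal(classify_sequence("m1", clm2, rep(35L, 10), cfgq),
               "without_indels")
})

test_that("a deletion shared widely enough is legitimate", {
  gl <- "GGCAATTGGC"
  cl <- small_clone(gl, c(m1 = "GGCA-TTGGC", m2 = "GGCA-TTGGC",
                          m3 = "GGCAATTGGC"))
  cfg2 <- indel_config(min_share = 2, min_hpt_len = 2)
  cfg3 <- indel_config(min_share = 3, min_hpt_len = 2)
  expect_equal(classify_sequence("m1", cl, NULL, cfg2),
               "with_legitimate_indels")
  expect_equal(classify_sequence("m1", cl, NULL, cfg3), "artifact_indel")
  # an indel away from any tract is legitimate regardless of sharing
  gl2 <- "ACGTACGTAC"
  cl2 <- small_clone(gl2, c(m1 = "ACGT-CGTAC", m2 = "ACGTACGTAC"))
  expect_equal(classify_sequence("m1", cl2, NULL,
                                 indel_config(min_share = 5,
                                              min_hpt_len = 2)),
               "with_legitimate_indels")
})

test_that("mutation screening is off at min_qual = -1 and spares singletons", {
  gl <- "ACGTACGTAC"
  cl <- small_clone(gl, c(m1 = "ACGTACGTAT", m2 = "ACGTACGTAC"))
  off <- indel_config(min_qual = -1)
  on <- indel_config(min_qual = 20)
  lowq <- rep(5L, 10)
  expect_equal(classify_sequence("m1", cl, lowq, off), "without_indels")
  expect_equal(classify_sequence("m1", cl, lowq, on), "low_qual_mutation")
  single <- small_clone(gl, c(m1 = "ACGTACGTAT"))
  expect_equal(classify_sequence("m1", single, lowq, on), "without_indels")
})

test_that("the four output classes partition the input", {
  fx <- generate_clonal_fixture(n_clones = 12, size_range = c(1, 6),
                                seq_length = 120, seed = 19)
  sim <- simulate_dataset(fx$clones, sim_params(p_del = 0.6, seed = 20))
  outdir <- tempfile()
  res <- run_indel_identifier(sim$clones, quals = NULL,
                              config = indel_config(min_share = 2),
                              outdir = outdir, name = "t")
  n_members <- sum(vapply(sim$clones, function(c) length(c$members), 0L))
  expect_equal(nrow(res$verdicts), n_members)
  expect_equal(sum(res$counts), n_members)
  files <- c("t-WithoutIndels.txt", "t-CloneOfSize1WithIndels.txt",
             "t-IllegitimateIndels.txt", "t-SeqsWithLowQualPointMuts.txt")
  ids <- unlist(lapply(files, function(f) {
    l <- readLines(file.path(outdir, f)); sub("^>", "", l[grepl("^>", l)])
  }))
  expect_equal(sort(ids), sort(res$verdicts$member))  # disjoint, exhaustive
  expect_true(file.exists(file.path(outdir, "t-Ig-Indel-Identifier.log")))

  # all-identical clones land in WithoutIndels
  plain <- small_clone("ACGTTACG", c(a = "ACGTTACG", b = "ACGTTACG"))
  r2 <- run_indel_identifier(list(plain))
  expect_true(all(r2$verdicts$class == "without_indels"))
})
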
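test_that("FASTA/QUAL pair reader parses, validates and round-trips", {
  expect_length(read_fasta_qual(character(), character()), 0)

  rd <- read_fasta_qual(">r1\nacgt", ">r1\n30 30 30 30")
  expect_equal(rd$id, "r1")
  expect_equal(rd$seq, "ACGT")   # bases uppercased
  expect_equal(rd$qual[[1]], c(30L, 30L, 30L, 30L))

  expect_error(read_fasta_qual(">r1\nACGT", ">r1\n30 30 30"), "r1")
  expect_error(read_fasta_qual(">r1\nACGT", ">rX\n30 30 30 30"), "rX")

  set.seed(71)
  rd <- ig_reads(sprintf("q%02d", 1:8),
                 vapply(5:12, random_seq, ""),
                 lapply(5:12, function(n) sample(0:40, n, replace = TRUE)))
  fa <- tempfile(); qu <- tempfile()
  write_fasta_qual(rd, fa, qu)
  expect_identical(read_fasta_qual(fa, qu), rd)
  # writing the parsed object again is byte-stable
  fa2 <- tempfile(); qu2 <- tempfile()
  write_fasta_qual(read_fasta_qual(fa, qu), fa2, qu2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_identical(readLines(qu), readLines(qu2))
})

test_that("run-configuration dialect parses the documented example values", {
  txt <- c("Organism: Human", "Chain: h", "Quality threshold: 20",
           "Maximum mismatches allowed: 2",
           "Fraction of primer to search: 0.75",
           "Range to search primers in: 50", "Minimal MID length: 5",
           "Mids:", basic_mid_set(), "#",
           "Forward:", example_primers("human")$forward, "#",
           "Reverse:", example_primers("human")$reverse, "#",
           "Minimum length: 200 150", "Maximum length: 400 360",
           "Table:", "1\t7\ts1", "2\t8\ts2", "#")
  cfg <- parse_clean_config(txt)
  expect_equal(cfg$minL1, 200L)
  expect_equal(cfg$maxL1, 400L)
  expect_equal(cfg$minL2, 150L)
  expect_equal(cfg$maxL2, 360L)
  expect_equal(cfg$max_mismatches, 2L)
  expect_equal(cfg$mids[2], "ACGCTCGACA")  # numbered by insertion order
  expect_equal(cfg$sample_table$sample, c("s1", "s2"))
})

test_that("no-MID mode, missing terminators and bad indices are handled", {
  base <- c("Organism: x", "Chain: h", "Quality threshold: 20",
            "Maximum mismatches allowed: 2",
            "Fraction of primer to search: 0.75",
            "Range to search primers in: 50", "Minimal MID length: 1")
  no_mid <- c(base, "Mids:", "#", "Forward:", "ACGTACGTACGTACGT", "#",
              "Reverse:", "TTTTCCCCGGGGAAAA", "#",
              "Minimum length: 200 150", "Maximum length: 400 360",
              "Table:", "0\t0\tonly_sample", "#")
  cfg <- parse_clean_config(no_mid)
  expect_length(cfg$mids, 0)
  expect_equal(cfg$sample_table$sample, "only_sample")

  bad_idx <- sub("0\t0\tonly_sample", "7\t1\ts", no_mid)
  expect_error(parse_clean_config(bad_idx), "MID")
  missing_hash <- c(base, "Mids:", "ACGT")
  expect_error(parse_clean_config(missing_hash), "#")
})

test_that("configuration serialisation round-trips random valid configs", {
  set.seed(5)
  for (rep in 1:5) {
    n_mid <- sample(2:6, 1)
    mids <- vapply(rep(10, n_mid), random_seq, "")
    cfg <- clean_config(
      organism = sample(c("Human", "Mouse"), 1), chain = "k",
      quality_threshold = sample(10:30, 1),
      max_mismatches = sample(1:4, 1),
      primer_fraction = sample(c(0.5, 0.75, 1), 1),
      search_range = sample(25:60, 1),
      min_mid_len = sample(1:5, 1), mids = mids,
      forward_primers = c("ARGRAAGGCCCTGGAGTGG", "CCGCCAGGCTCCAGGSAAG"),
      reverse_primers = "TGACCRKGGTHCCYTGGCCC",
      minL1 = 100, maxL1 = 500, minL2 = 50, maxL2 = 450,
      sample_table = data.frame(fw = 1:2, rv = c(2, 1),
                                sample = c("a", "b")))
    expect_identical(parse_clean_config(format_clean_config(cfg)), cfg)
  }
})

test_that("PIR alignments parse, pick the germline row and round-trip", {
  aln <- parse_pir_alignment(c(">P1;GL_1", "GL_1", "AC-GT*",
                               ">P1;m1", "m1", "ACTGT*"))
  expect_equal(nchar(aln$germline), 5)
  expect_equal(aln$germline_id, "GL_1")
  expect_equal(names(aln$members), "m1")
  expect_equal(gsub("-", "", aln$members[["m1"]]), "ACTGT")

  expect_error(parse_pir_alignment(c(">P1;GL", "d", "ACGTT*",
                                     ">P1;m", "d", "ACGTTA*")), "length")
  expect_error(parse_pir_alignment(c(">P1;GL", "d", "ACGTT")), "\\*")

  set.seed(9)
  fx <- generate_clonal_fixture(n_clones = 3, size_range = c(2, 4),
                                seq_length = 80, seed = 13)
  for (cl in fx$clones) {
    back <- parse_pir_alignment(format_pir_alignment(cl),
                                clone_id = cl$clone_id)
    expect_identical(back, cl)
  }
})

test_that("quality summaries match their definition and ignore order", {
  one <- summarize_quality(ig_reads("r", "AC", list(c(30L, 30L))))
  expect_equal(one$per_sequence_averages, 30)
  expect_equal(one$per_sequence_minima, 30L)
  expect_equal(one$sample_average, 30)

  tri <- summarize_quality(ig_reads("r", "ACG", list(c(10L, 20L, 40L))))
  expect_equal(tri$per_sequence_averages, 70 / 3)
  expect_equal(tri$per_sequence_minima, 10L)

  empty <- summarize_quality(ig_reads())
  expect_length(empty$per_sequence_averages, 0)
  expect_true(is.nan(empty$sample_average))

  set.seed(2)
  rd <- ig_reads(sprintf("r%d", 1:10), vapply(rep(20, 10), random_seq, ""),
                 lapply(1:10, function(i) sample(0:40, 20, replace = TRUE)))
  perm <- sample(10)
  expect_equal(summarize_quality(rd)$sample_average,
               summarize_quality(rd[perm])$sample_average)
})
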
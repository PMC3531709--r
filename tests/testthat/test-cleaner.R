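test_that("average quality is the arithmetic mean and errors when empty", {
  expect_equal(average_quality(c(20, 20, 20)), 20)
  expect_equal(average_quality(c(0, 40)), 20)
  expect_equal(average_quality(c(10, 20, 40)), 70 / 3)
  expect_error(average_quality(integer()), "empty")
})

test_that("cleaning stages trigger in order with the planted defect", {
  cfg <- default_config()
  fx <- generate_clean_fixture(
    c(clean = 4, fail_L1 = 2, fail_mids = 2, fail_primers = 2,
      fail_L2 = 2, fail_quality = 2), cfg, seed = 11)
  for (i in seq_len(length(fx$reads))) {
    o <- clean_read(fx$reads$id[i], fx$reads$seq[i], fx$reads$qual[[i]], cfg)
    expect_equal(o$status, sub("clean", "pass", fx$truth$expected[i]),
                 info = fx$reads$id[i])
    if (o$status == "pass")
      expect_equal(o$sample, fx$truth$sample[i])
  }
  # an overlong read fails L1 before any matching is attempted
  long <- paste(rep("A", cfg$maxL1 + 1), collapse = "")
  o <- clean_read("long", long, rep(40L, nchar(long)), cfg)
  expect_equal(o$status, "fail_L1")
})

test_that("quality threshold is strict: a boundary read fails", {
  cfg <- default_config(quality_threshold = 30)
  fx <- generate_clean_fixture(c(clean = 1), cfg, seed = 31)
  o <- clean_read(fx$reads$id[1], fx$reads$seq[1], fx$reads$qual[[1]], cfg)
  expect_equal(o$status, "pass")
  # set every gene base score to exactly the threshold
  q <- rep(30L, nchar(fx$reads$seq[1]))
  o30 <- clean_read(fx$reads$id[1], fx$reads$seq[1], q, cfg)
  expect_equal(o30$status, "fail_quality")
  o31 <- clean_read(fx$reads$id[1], fx$reads$seq[1], q + 1L, cfg)
  expect_equal(o31$status, "pass")
})

test_that("cleaning the reverse complement yields the identical gene", {
  cfg <- default_config()
  fx <- generate_clean_fixture(c(clean = 5), cfg, seed = 41)
  for (i in seq_len(length(fx$reads))) {
    o1 <- clean_read("fwd", fx$reads$seq[i], fx$reads$qual[[i]], cfg)
    o2 <- clean_read("rev", reverse_complement(fx$reads$seq[i]),
                     rev(fx$reads$qual[[i]]), cfg)
    expect_equal(o1$status, "pass")
    expect_equal(o2$status, "pass")
    expect_equal(o2$gene, o1$gene)
    expect_equal(o2$gene_quals, o1$gene_quals)
    expect_equal(o1$sample, o2$sample)
  }
})

test_that("dataset cleaning conserves reads and matches the truth table", {
  cfg <- default_config()
  spec <- c(clean = 30, fail_L1 = 5, fail_mids = 5, fail_primers = 5,
            fail_L2 = 3, fail_quality = 3)
  fx <- generate_clean_fixture(spec, cfg, seed = 59)
  outdir <- tempfile()
  st <- clean_dataset(fx$reads, cfg, outdir = outdir)

  status <- vapply(st$outcomes, `[[`, "", "status")
  expect_equal(sum(status == "pass"), 30)
  expect_equal(as.integer(table(status)[c("fail_L1", "fail_mids",
                                          "fail_primers", "fail_L2",
                                          "fail_quality")]),
               c(5L, 5L, 5L, 3L, 3L))
  # per-sample rows: total = primers + length + quality + remaining
  per <- st$per_sample
  expect_equal(per$total, per$failed_primers + per$failed_length +
                 per$failed_quality + per$remaining)
  # global conservation: received = L1 + MIDs + sum of sample totals
  expect_equal(st$totals$reads_received,
               st$totals$failed_L1 + st$totals$failed_mids +
                 sum(per$total))

  # file-level conservation: failure files + sample files == input
  count_fa <- function(f) sum(grepl("^>", readLines(file.path(outdir, f))))
  n_files <- sum(vapply(c("FailedInFindMIDs.txt", "FailedInFindPrimers.txt",
                          "FailedInCheckLength.txt", "FailedInQuality.txt",
                          paste0(unique(cfg$sample_table$sample), ".txt")),
                        count_fa, 0))
  expect_equal(n_files, length(fx$reads))

  # every passed gene re-checks against the bounds and threshold
  for (o in st$outcomes[status == "pass"]) {
    expect_gte(nchar(o$gene), cfg$minL2)
    expect_lte(nchar(o$gene), cfg$maxL2)
    expect_gt(mean(o$gene_quals), cfg$quality_threshold)
  }

  # the log holds the documented part-A columns
  log <- readLines(file.path(outdir, "Log.txt"))
  expect_match(log[1], "^Sample\tTotal\tFailed in primers")
  expect_equal(length(strsplit(log[2], "\t")[[1]]), 12)
})

test_that("input order does not change the counts", {
  cfg <- default_config()
  fx <- generate_clean_fixture(c(clean = 10, fail_mids = 3, fail_L2 = 2),
                               cfg, seed = 67)
  st1 <- clean_dataset(fx$reads, cfg)
  set.seed(1); perm <- sample(length(fx$reads))
  st2 <- clean_dataset(fx$reads[perm], cfg)
  expect_equal(st1$totals, st2$totals)
  a <- st1$per_sample[order(st1$per_sample$sample), ]
  b <- st2$per_sample[order(st2$per_sample$sample), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("widening the gene-length window never turns a pass into a fail", {
  cfg <- default_config()
  fx <- generate_clean_fixture(c(clean = 8, fail_L2 = 4), cfg, seed = 73)
  wide <- default_config(minL2 = 1, maxL2 = 1000)
  for (i in seq_len(length(fx$reads))) {
    o <- clean_read(fx$reads$id[i], fx$reads$seq[i], fx$reads$qual[[i]], cfg)
    ow <- clean_read(fx$reads$id[i], fx$reads$seq[i], fx$reads$qual[[i]],
                     wide)
    if (o$status == "pass") expect_equal(ow$status, "pass")
  }
})
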
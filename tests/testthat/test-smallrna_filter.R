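# Read cleaning, collapsing and the impurity filters.

ADAPTER3 <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming recovers inserts, flags dimers, tolerates one mismatch", {
  insert <- "ACGTACGTACGTACGTACGT"
  expect_identical(trim_adapter(paste0(insert, ADAPTER3), ADAPTER3), insert)
  # adapter dimer: read is the adapter alone
  expect_identical(trim_adapter(ADAPTER3, ADAPTER3), "")
  # one internal mismatch in the adapter copy still trims; verify against a
  # brute-force scan over all suffix start positions
  mut <- ADAPTER3
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  read <- paste0(insert, mut)
  expect_identical(trim_adapter(read, ADAPTER3), insert)
  brute_hit <- NA
  for (i in seq_len(nchar(read))) {
    ov <- min(nchar(read) - i + 1, nchar(ADAPTER3))
    if (ov < 6) break
    mm <- sum(orc_chars(substr(read, i, i + ov - 1)) !=
                orc_chars(substr(ADAPTER3, 1, ov)))
    if (mm <= 1) { brute_hit <- i; break }
  }
  expect_identical(nchar(insert), brute_hit - 1L)
  # no adapter found: read kept as-is (insert-only dialect)
  expect_identical(trim_adapter("ACGTTGCAGGTCCAATGCAT", ADAPTER3),
                   "ACGTTGCAGGTCCAATGCAT")
  # 5' adapter is prefix-anchored
  expect_identical(
    trim_adapter(paste0("GTTCAGAGTT", insert, ADAPTER3), ADAPTER3,
                 adapter5 = "ACACGACGCTCTTCCGATCTGTTCAGAGTT"),
    insert)
  expect_error(trim_adapter("ACGTXACGTACGT", ADAPTER3), "non-ACGTN")
})

test_that("junk rules fire in the documented order with the right reasons", {
  expect_identical(is_junk("AAAAAAAAAAAAAAAAAAAA")$reason, "single_base_80")
  expect_identical(is_junk("ACACACACACACACACAC")$reason, "only_AC")
  expect_identical(is_junk("GTGTGTTGGTTGTGGTTG")$reason, "only_GT")
  expect_identical(is_junk("ACGTNNACGTACGTACGTN")$reason, "n_rich")
  # exactly 80% of one base triggers the >= rule
  expect_true(is_junk("AAAAAAAACG")$junk)
  res <- is_junk("ACGTTGCAGGTCCAATGCAT")
  expect_false(res$junk)
  expect_true(is.na(res$reason))
})

test_that("collapsing counts every insert exactly once, in any order", {
  tags <- collapse_reads(c("ACGTACGTACGTACG", "ACGTACGTACGTACG",
                           "TTGACCTTGACCTTG"))
  expect_identical(tags$copy_number, c(2L, 1L))
  expect_identical(nrow(collapse_reads(character(0))), 0L)
  set.seed(11)
  pool <- replicate(40, orc_rand_dna(20))
  inserts <- sample(pool, 1000, replace = TRUE)
  tags <- collapse_reads(inserts)
  expect_identical(sum(tags$copy_number), 1000L)
  # independent tally
  for (i in sample(nrow(tags), 10))
    expect_identical(tags$copy_number[i], sum(inserts == tags$sequence[i]))
  # order invariance
  tags2 <- collapse_reads(rev(inserts))
  expect_identical(tags[order(tags$sequence), ],
                   tags2[order(tags2$sequence), ])
})

test_that("tag filters enforce copy-number and length bounds at the stated edges", {
  mk <- function(len, copies) data.frame(
    sequence = orc_rand_dna(len), copy_number = copies)
  set.seed(3)
  tags <- rbind(mk(20, 2), mk(14, 10), mk(15, 10), mk(26, 10), mk(27, 10))
  out <- apply_filters(tags)
  expect_identical(nchar(out$tags$sequence), c(15L, 26L))
  expect_identical(unname(out$report["copy_number"]), 2L)
  expect_identical(unname(out$report["length"]), 20L)
  expect_error(apply_filters(tags, min_len = 30, max_len = 20), "min_len")
  # exclusion database: exact and substring hits are removed
  db <- paste0("CCCC", tags$sequence[3], "GGGG")
  out2 <- apply_filters(tags, exclusion_db = db)
  expect_false(tags$sequence[3] %in% out2$tags$sequence)
  # idempotence: refiltering survivors changes nothing
  again <- apply_filters(out$tags)
  expect_identical(again$tags, out$tags)
  expect_true(all(again$report[c("junk", "n_content", "length",
                                 "exclusion_db", "copy_number")] == 0))
})

test_that("length histogram is copy-weighted and sums to one", {
  h1 <- length_histogram(data.frame(sequence = orc_rand_dna(22),
                                    copy_number = 5L))
  expect_identical(h1$fraction, 1)
  h2 <- length_histogram(data.frame(
    sequence = c(orc_rand_dna(21), orc_rand_dna(22)),
    copy_number = c(3L, 1L)))
  expect_equal(h2$fraction, c(0.75, 0.25))
  expect_identical(nrow(length_histogram(
    data.frame(sequence = character(0), copy_number = integer(0)))), 0L)
})

test_that("read-level screen conserves every input read exactly once", {
  cfg <- sim_config(seed = 5, library_depth = 4000)
  gt <- make_genome_with_hairpins(cfg)
  lib <- simulate_small_rna_library(gt, cfg)
  res <- filter_reads(lib$reads, adapter3 = cfg$adapter3)
  r <- res$report
  expect_identical(
    unname(r["input_reads"]),
    unname(sum(r[c("invalid", "low_resolution", "adapter_dimer", "junk",
                   "n_content", "length", "exclusion_db", "copy_number",
                   "surviving_reads")])))
  # permuting the reads yields the same surviving tag set
  perm <- lib$reads[sample(nrow(lib$reads)), ]
  res2 <- filter_reads(perm, adapter3 = cfg$adapter3)
  expect_identical(res$tags[order(res$tags$sequence), ],
                   res2$tags[order(res2$tags$sequence), ])
  expect_identical(r, res2$report)
})

test_that("collapsed-tag FASTA round-trips through the _x dialect", {
  tags <- data.frame(sequence = c("ACGTACGTACGTACG", "TTGACCTTGACCTTG"),
                     copy_number = c(12L, 3L))
  tf <- tempfile(fileext = ".fa")
  write_tag_fasta(tags, tf)
  back <- read_tag_fasta(tf)
  expect_identical(back, tags)
  expect_match(readLines(tf)[1], "^>tag1_x12$")
})
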
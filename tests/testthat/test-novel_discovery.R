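# Folding engine, genome mapping, precursor extraction and hairpin calling.

test_that("small canonical folds come out right", {
  f <- fold_rna("GGGAAACCC")
  expect_identical(f$dot_bracket, "(((...)))")
  expect_identical(sum(f$partner > 0) / 2, 3)
  expect_lt(f$energy, 0)
  f0 <- fold_rna("AAAAAAAAA")
  expect_identical(f0$dot_bracket, ".........")
  expect_identical(f0$energy, 0)
})

test_that("DP optimum equals exhaustive enumeration on short sequences", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(8:12, 1)
    # half the draws GC-biased so paired optima are exercised
    sq <- if (k %% 2 == 0) orc_rand_dna(n) else
      orc_rand_dna(n, prob = c(0.15, 0.35, 0.35, 0.15))
    f <- fold_rna(sq)
    expect_equal(f$energy, orc_enum_best_fold(sq), tolerance = 1e-9,
                 info = sq)
    # the DP's reported structure scores to its reported energy
    expect_equal(structure_energy(sq, f$partner), f$energy,
                 tolerance = 1e-9, info = sq)
  }
})

test_that("DP structure is self-consistent on longer sequences", {
  set.seed(32)
  for (k in 1:10) {
    sq <- orc_rand_dna(sample(40:90, 1))
    f <- fold_rna(sq)
    expect_equal(structure_energy(sq, f$partner), f$energy,
                 tolerance = 1e-9)
    expect_lte(f$energy, 0)
  }
})

test_that("unpaired constraints are honored and can only cost energy", {
  set.seed(33)
  for (k in 1:8) {
    sq <- orc_rand_dna(60, prob = c(0.2, 0.3, 0.3, 0.2))
    keep_open <- 20:30
    f_free <- fold_rna(sq)
    f_con <- fold_rna(sq, unpaired = keep_open)
    expect_true(all(f_con$partner[keep_open] == 0))
    expect_gte(f_con$energy, f_free$energy - 1e-9)
  }
})

test_that("genome mapping matches a naive scan on both strands", {
  set.seed(34)
  genome <- c(chrA = orc_rand_dna(3000), chrB = orc_rand_dna(2000))
  tag <- substr(genome[["chrA"]], 101, 122)
  loci <- map_tag_to_genome(tag, genome)
  expect_identical(loci$start, 101L)
  expect_identical(loci$end, 122L)
  expect_identical(loci$strand, "+")
  # reverse complement plants a minus-strand locus at the same coordinates
  rc <- orc_revcomp(substr(genome[["chrB"]], 501, 522))
  loci2 <- map_tag_to_genome(rc, genome)
  expect_identical(loci2$chrom, "chrB")
  expect_identical(loci2$start, 501L)
  expect_identical(loci2$strand, "-")
  # brute-force all-positions oracle on random short tags
  for (k in 1:15) {
    t <- orc_rand_dna(8)
    loci <- map_tag_to_genome(t, genome)
    naive <- 0L
    for (chrom in names(genome)) {
      s <- genome[[chrom]]
      for (p in seq_len(nchar(s) - nchar(t) + 1)) {
        win <- substr(s, p, p + nchar(t) - 1)
        if (win == t) naive <- naive + 1L
        if (win == orc_revcomp(t)) naive <- naive + 1L
      }
    }
    expect_identical(nrow(loci), naive, info = t)
  }
})

test_that("precursor extraction extends 60 nt and truncates at ends", {
  genome <- c(chr1 = orc_rand_dna(1000))
  loc <- data.frame(chrom = "chr1", start = 101L, end = 122L, strand = "+")
  pc <- extract_precursor(loc, genome)
  expect_identical(nchar(pc$precursor_seq), 142L)
  expect_identical(pc$mature_offset, 61L)
  expect_identical(substr(pc$precursor_seq, 61, 82),
                   substr(genome[["chr1"]], 101, 122))
  # near the chromosome start the upstream flank is truncated
  loc2 <- data.frame(chrom = "chr1", start = 6L, end = 27L, strand = "+")
  pc2 <- extract_precursor(loc2, genome)
  expect_identical(nchar(pc2$precursor_seq), 87L)
  expect_identical(pc2$mature_offset, 6L)
  # minus strand is the reverse complement of the plus window
  loc3 <- data.frame(chrom = "chr1", start = 201L, end = 222L, strand = "-")
  pc3 <- extract_precursor(loc3, genome)
  expect_identical(pc3$precursor_seq,
                   orc_revcomp(substr(genome[["chr1"]], 141, 282)))
  expect_identical(pc3$mature_offset, 61L)
  expect_error(extract_precursor(
    data.frame(chrom = "chr1", start = 990L, end = 1011L, strand = "+"),
    genome), "bounds")
})

test_that("canonical planted hairpins pass and loop-spanning matures fail", {
  set.seed(35)
  mat <- orc_rand_dna(22)
  hp <- ovamir:::.make_hairpin(mat, 8, 1, TRUE)
  pre <- paste0(orc_rand_dna(30), hp, orc_rand_dna(30))
  ch <- call_hairpin(pre, 31, 22)
  expect_true(ch$hairpin)
  expect_identical(ch$arm, "5p")
  expect_gte(ch$scores$paired_mature, 20)
  # a "mature" centered on the terminal loop spans both arms
  ch2 <- call_hairpin(pre, 31 + 11, 22)
  expect_false(ch2$hairpin)
  # star-first layout yields a 3p arm
  hp3 <- ovamir:::.make_hairpin(mat, 8, 1, FALSE)
  pre3 <- paste0(orc_rand_dna(30), hp3, orc_rand_dna(30))
  ch3 <- call_hairpin(pre3, 31 + nchar(hp3) - 22, 22)
  expect_true(ch3$hairpin)
  expect_identical(ch3$arm, "3p")
})

test_that("novel prediction recovers planted precursors and respects contracts", {
  cfg <- sim_config(seed = 12, n_novel_hairpins = 8, genome_length = 10000)
  gt <- make_genome_with_hairpins(cfg)
  unmatched <- data.frame(sequence = gt$novel_truth$mature,
                          copy_number = 5L)
  nov <- predict_novel(unmatched, gt$genome)
  expect_gte(sum(gt$novel_truth$mature %in% nov$tag), 7)
  # flank contract
  expect_true(all(nchar(nov$precursor) <=
                    nchar(nov$tag) + 2 * 60))
  # arm naming matches the planted layout
  m <- merge(nov, gt$novel_truth, by.x = "tag", by.y = "mature")
  expect_true(all(m$arm.x == m$arm.y))
  expect_identical(nrow(predict_novel(unmatched[0, ], gt$genome)), 0L)
})

test_that("prediction is strand-symmetric", {
  cfg <- sim_config(seed = 13, n_novel_hairpins = 4, genome_length = 6000)
  gt <- make_genome_with_hairpins(cfg)
  rc_genome <- setNames(vapply(gt$genome, orc_revcomp, character(1)),
                        names(gt$genome))
  unmatched <- data.frame(sequence = gt$novel_truth$mature,
                          copy_number = 5L)
  nov1 <- predict_novel(unmatched, gt$genome)
  nov2 <- predict_novel(unmatched, rc_genome)
  expect_identical(sort(nov1$precursor), sort(nov2$precursor))
})
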
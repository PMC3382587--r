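# The synthetic-data generator: determinism, ground-truth bookkeeping, and
# detectability of every planted feature.

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 17, n_novel_hairpins = 5, genome_length = 8000,
                    library_depth = 2000, n_transcripts = 6)
  a <- make_genome_with_hairpins(cfg)
  b <- make_genome_with_hairpins(cfg)
  expect_identical(a, b)
  la <- simulate_small_rna_library(a, cfg)
  lb <- simulate_small_rna_library(b, cfg)
  expect_identical(la, lb)
  qa <- simulate_qpcr_plate(cfg)
  qb <- simulate_qpcr_plate(cfg)
  expect_identical(qa, qb)
})

test_that("planted hairpins fold back as hairpins and map uniquely", {
  cfg <- sim_config(seed = 18, n_novel_hairpins = 10, genome_length = 15000)
  gt <- make_genome_with_hairpins(cfg)
  for (h in seq_len(nrow(gt$novel_truth))) {
    tr <- gt$novel_truth[h, ]
    loci <- map_tag_to_genome(tr$mature, gt$genome)
    expect_identical(nrow(loci), 1L)
    expect_identical(loci$strand, tr$strand)
    pc <- extract_precursor(loci[1, ], gt$genome)
    expect_true(call_hairpin(pc$precursor_seq, pc$mature_offset,
                             pc$mature_len)$hairpin)
  }
  # genomic coordinates in the truth table point at the mature itself
  for (h in 1:3) {
    tr <- gt$novel_truth[h, ]
    sub <- substr(gt$genome[[tr$chrom]], tr$start, tr$end)
    expect_identical(if (tr$strand == "+") sub else orc_revcomp(sub),
                     tr$mature)
  }
})

test_that("library truth: no junk when disabled, exact copies without jitter", {
  fr <- c(known = 0.6, novel = 0.4, background = 0, junk = 0, dimer = 0,
          lowres = 0)
  cfg <- sim_config(seed = 19, library_depth = 3000, class_fractions = fr,
                    isomir_jitter_rate = 0, subst_rate = 0,
                    n_novel_hairpins = 5, genome_length = 8000)
  gt <- make_genome_with_hairpins(cfg)
  lib <- simulate_small_rna_library(gt, cfg)
  expect_identical(sum(lib$insert_truth$class == "junk"), 0L)
  # every emitted insert is an unmodified mature; collapsed counts match
  tags <- collapse_reads(vapply(lib$reads$sequence, trim_adapter,
                                character(1), adapter3 = cfg$adapter3,
                                USE.NAMES = FALSE))
  for (i in sample(nrow(lib$insert_truth), 10)) {
    tr <- lib$insert_truth[i, ]
    expect_identical(tags$copy_number[tags$sequence == tr$sequence],
                     tr$copies)
  }
  # class split approximates the configured proportions
  cc <- tapply(lib$insert_truth$copies, lib$insert_truth$class, sum)
  expect_equal(unname(cc["known"] / sum(cc)), 0.6, tolerance = 0.05)
})

test_that("length mix of mappable inserts lands near the configured mix", {
  cfg <- sim_config(seed = 20, library_depth = 20000)
  gt <- make_genome_with_hairpins(cfg)
  lib <- simulate_small_rna_library(gt, cfg)
  res <- filter_reads(lib$reads, adapter3 = cfg$adapter3)
  hist <- length_histogram(res$tags)
  # the dominant sizes are in the 20-25 nt band, as configured
  expect_gt(sum(hist$fraction[hist$length %in% 20:25]), 0.8)
})

test_that("planted target sites drive both scanners and all three modes", {
  cfg <- sim_config(seed = 21, n_transcripts = 8)
  gt <- make_genome_with_hairpins(cfg)
  genes <- make_gene_models_with_sites(gt, cfg)
  sites <- genes$sites
  expect_setequal(unique(sites$mode),
                  c("single-3UTR", "multi-miRNA-3UTR", "3UTR-plus-CDS"))
  # a planted perfect-complement 3'UTR site passes the alignment thresholds
  tr <- sites[sites$region == "3UTR", ][1, ]
  mt <- genes$models_truth[genes$models_truth$transcript == tr$gene, ]
  utr3 <- substr(genes$cdnas[[tr$gene]], mt$utr3_start, mt$utr3_end)
  mir <- genes$target_mirnas[genes$target_mirnas$name == tr$mirna, ]
  hits <- miranda_scan(mir, utr3)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$site_start <= tr$start + 3 &
                    hits$site_end >= tr$start + 18))
  # proteins translate the planted CDS exactly
  for (i in 1:3) {
    tx <- sprintf("tx%02d", i)
    mt <- genes$models_truth[genes$models_truth$transcript == tx, ]
    cds <- substr(genes$cdnas[[tx]], mt$cds_start, mt$cds_end)
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(cds))))
    expect_identical(aa, unname(genes$proteins[sprintf("prot%02d", i)]))
  }
})

test_that("qPCR plates invert exactly without noise and embed the planted fold", {
  cfg <- sim_config(seed = 22, cq_sigma = 0, dilution_sigma = 0)
  q <- simulate_qpcr_plate(cfg, targets = "m1")
  curves <- lapply(split(q$dilutions, q$dilutions$target),
                   function(d) fit_standard_curve(d$log10_quantity, d$cq))
  norm <- quantify_normalize(q$plate, curves, cfg$reference_targets)
  mu <- tapply(norm$normalized, norm$tissue, mean)
  expect_equal(unname(mu[["egg"]] / mu[["liver"]]), cfg$planted_fold,
               tolerance = 1e-6)
  # planted fold 1 gives a flat panel: one shared ANOVA letter
  cfg2 <- sim_config(seed = 23)
  q2 <- simulate_qpcr_plate(cfg2, targets = "m1", egg_fold = 1)
  curves2 <- lapply(split(q2$dilutions, q2$dilutions$target),
                    function(d) fit_standard_curve(d$log10_quantity, d$cq))
  norm2 <- quantify_normalize(q2$plate, curves2, cfg2$reference_targets)
  lt <- anova_letters(norm2$normalized, norm2$tissue)$letters
  expect_true(any(vapply(lt, function(x) grepl("a", x, fixed = TRUE),
                         logical(1))["egg"]))
  shared <- Reduce(intersect, lapply(lt, function(x)
    strsplit(x, "")[[1]]))
  expect_gte(length(shared), 1)
})

test_that("fixture files are written as plain text with a truth record", {
  cfg <- sim_config(seed = 24, n_novel_hairpins = 4, genome_length = 6000,
                    library_depth = 800, n_transcripts = 6)
  dir <- tempfile("fixtures")
  sim <- simulate_all(cfg, dir = dir)
  expect_setequal(list.files(dir),
                  c("genome.fa", "mature_known.fa", "reads.fastq",
                    "cdna.fa", "proteins.fa", "plate_cq.tsv",
                    "dilutions.tsv", "truth.json"))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(unname(nchar(genome)),
                   unname(nchar(sim$genome_truth$genome)))
  reads <- read_reads(file.path(dir, "reads.fastq"))
  expect_identical(nrow(reads), nrow(sim$library$reads))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true(all(c("novel_truth", "sites", "qpcr_truth") %in% names(tj)))
})
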
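# Dual-scanner target prediction: alignment score + duplex energy, and
# accessibility ddG.

test_that("a perfect 22-mer complement scores S = 145 under the scoring table", {
  set.seed(51)
  for (k in 1:5) {
    mir <- orc_rand_dna(22)
    al <- align_duplex(mir, orc_revcomp(mir))
    # 7 seed positions doubled: 7*5*2 + 15*5
    expect_equal(al$S, 145)
    expect_identical(al$site_start, 1L)
    expect_identical(al$site_end, 22L)
  }
  expect_equal(align_duplex("AAAAAAAA", "AAAAAAAA")$S, 0)
  expect_error(align_duplex("ACGU-", "ACGT"), "non-nucleotide")
})

test_that("alignment scores equal exhaustive trace enumeration on small pairs", {
  set.seed(52)
  for (k in 1:30) {
    mir <- orc_rand_dna(sample(6:9, 1))
    win <- orc_rand_dna(sample(8:11, 1))
    expect_equal(align_duplex(mir, win)$S, orc_best_duplex_S(mir, win),
                 tolerance = 1e-9, info = paste(mir, win))
  }
})

test_that("duplex energies: initiation-only, stacks, and worked example", {
  p <- energy_params()
  # no pairs at all -> initiation penalty only
  al <- align_duplex("AAAA", "CCCC")
  expect_equal(duplex_energy("AAAA", "CCCC", al$columns), p$duplex_init)
  # single G:C pair -> initiation + zero stacks, no AU/GU end penalty
  al1 <- align_duplex("C", "G")
  expect_equal(duplex_energy("C", "G", al1$columns), p$duplex_init)
  # worked example: fixed 8 bp duplex, hand nearest-neighbor sum
  mir <- "AAGGCCGU"            # pairs site 5'-ACGGCCUU-3'
  site <- "ACGGCCTT"
  al8 <- align_duplex(mir, site)
  # site-first pair types along the site: AU UA GC GC CG CG UA UA
  idx <- function(x) match(x, c("CG", "GC", "GU", "UG", "AU", "UA"))
  pts <- idx(c("AU", "CG", "GC", "GC", "CG", "CG", "UA", "UA"))
  hand <- p$duplex_init +
    sum(p$stacks[cbind(pts[-8], pts[-1])]) +
    2 * p$end_penalty          # both terminal pairs are A:U / U:A
  expect_equal(duplex_energy(mir, site, al8$columns), hand)
})

test_that("perfect complements beat every single-substitution site variant", {
  set.seed(53)
  for (k in 1:20) {
    mir <- orc_rand_dna(22)
    site <- orc_revcomp(mir)
    dg <- duplex_energy(mir, site, align_duplex(mir, site)$columns)
    for (p in sample(22, 6)) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(site, p, p))) {
        v <- site
        substr(v, p, p) <- b
        dgv <- duplex_energy(mir, v, align_duplex(mir, v)$columns)
        expect_gt(dgv, dg)
      }
    }
  }
})

test_that("acceptance thresholds are bit-exact at the boundaries", {
  expect_false(miranda_pass(139.9, -30))
  expect_false(miranda_pass(145, -17.0))
  expect_true(miranda_pass(145, -17.5))
  expect_true(miranda_pass(140, -17.0000001))
})

test_that("region scans find planted sites and nothing in poly-A", {
  set.seed(54)
  mir <- list(name = "m1", sequence = orc_rand_dna(22))
  region <- paste0(orc_rand_dna(80), orc_revcomp(mir$sequence),
                   orc_rand_dna(80))
  hits <- miranda_scan(mir, region)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$site_start, 81L)
  expect_identical(hits$site_end, 102L)
  expect_gte(hits$S, 140)
  expect_lt(hits$dG, -17)
  expect_identical(nrow(miranda_scan(mir, strrep("A", 120))), 0L)
})

test_that("opening energy is zero without structure and matches enumeration", {
  # a context that cannot pair at all
  expect_identical(open_energy(strrep("A", 60), 20, 30), 0)
  # constrained optimum equals brute-force enumeration on short contexts
  set.seed(55)
  for (k in 1:10) {
    ctx <- orc_rand_dna(12, prob = c(0.2, 0.3, 0.3, 0.2))
    site <- 5:7
    e_free <- orc_enum_best_fold(ctx)
    e_con <- orc_enum_best_fold(ctx, forbidden = site)
    expect_equal(fold_rna(ctx)$energy, e_free, tolerance = 1e-9, info = ctx)
    expect_equal(fold_rna(ctx, unpaired = site)$energy, e_con,
                 tolerance = 1e-9, info = ctx)
    expect_equal(open_energy(ctx, 5, 7), max(0, e_con - e_free),
                 tolerance = 1e-9, info = ctx)
  }
})

test_that("accessibility: burying a site in a stem worsens ddG", {
  set.seed(56)
  # a site over {A,C} cannot pair with itself, so the open context is
  # genuinely structure-free
  site <- orc_rand_dna(22, bases = c("A", "C"))
  mir <- list(name = "m1", sequence = orc_revcomp(site))
  # unstructured context: poly-A flanks cannot pair
  open_ctx <- paste0(strrep("A", 50), site, strrep("A", 50))
  # buried context: the site's own complement right next door forms a stem
  buried_ctx <- paste0(strrep("A", 20), orc_revcomp(site), "AAAAAA", site,
                       strrep("A", 20))
  h_open <- pita_scan(mir, open_ctx)
  h_buried <- pita_scan(mir, buried_ctx)
  expect_gte(nrow(h_open), 1L)
  expect_gte(nrow(h_buried), 1L)
  expect_equal(min(h_open$dG_open), 0)
  expect_equal(min(h_open$ddG), min(h_open$dG_duplex))
  expect_gt(min(h_buried$ddG), min(h_open$ddG))
  expect_gt(max(h_buried$dG_open), 0)
})

test_that("seed matching: planted 8-mers are found, seedless regions empty", {
  set.seed(57)
  mir <- list(name = "m1", sequence = orc_rand_dna(22))
  seed8 <- orc_revcomp(substr(mir$sequence, 2, 9))
  region <- paste0(strrep("A", 40), seed8, strrep("A", 40))
  h <- pita_scan(mir, region)
  expect_gte(nrow(h), 1L)
  expect_identical(h$seed_start[1], 41L)
  expect_identical(h$seed_len[1], 8L)
  # no seed complement anywhere
  expect_identical(nrow(pita_scan(list(name = "m", sequence = strrep("C", 22)),
                                  strrep("C", 80))), 0L)
})

test_that("consensus is the exact gene x miRNA set intersection", {
  mk <- function(genes, mirna, region = "3UTR")
    data.frame(gene = genes, region = region, mirna = mirna,
               stringsAsFactors = FALSE)
  mr <- mk(c("A", "B"), "m1")
  pt <- mk(c("B", "C"), "m1")
  cons <- intersect_targets(mr, pt)
  expect_identical(cons$gene, "B")
  # oracle: plain set intersection on keys
  expect_identical(paste(cons$gene, cons$mirna),
                   intersect(paste(mr$gene, mr$mirna),
                             paste(pt$gene, pt$mirna)))
  # commutative; empty inputs give empty output
  expect_identical(intersect_targets(pt, mr)$gene, "B")
  expect_identical(nrow(intersect_targets(mr[0, ], pt)), 0L)
  # subset property
  expect_true(all(cons$gene %in% mr$gene) && all(cons$gene %in% pt$gene))
  # region priority: 3'UTR listed before CDS
  mr2 <- rbind(mk("D", "m1", "CDS"), mk("D", "m1", "3UTR"))
  pt2 <- mk("D", "m1", "CDS")
  expect_identical(intersect_targets(mr2, pt2)$regions, "3UTR,CDS")
})

test_that("targeting modes are labelled per gene", {
  cons <- data.frame(
    gene = c("g1", "g2", "g2", "g3"),
    mirna = c("m1", "m1", "m2", "m1"),
    regions = c("3UTR", "3UTR", "3UTR", "3UTR,CDS"),
    n_miranda_sites = 1L, n_pita_sites = 1L, stringsAsFactors = FALSE)
  modes <- classify_mode(cons)
  expect_identical(modes$mode[modes$gene == "g1"], "single-3UTR")
  expect_identical(modes$mode[modes$gene == "g2"], "multi-miRNA-3UTR")
  expect_identical(modes$mode[modes$gene == "g3"], "3UTR-plus-CDS")
})
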
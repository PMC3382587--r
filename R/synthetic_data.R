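# Seeded synthetic-data generator. Every fixture the pipeline consumes is
# generated here with recorded ground truth: a toy genome with planted
# miRNA hairpins, an adapter-ligated small-RNA read library with junk and
# dimer contamination, transcripts with planted target sites covering all
# targeting modes, and a tissue-panel qPCR experiment with a planted
# egg-predominant effect. All draws are driven by the config seed, so the
# same config reproduces identical fixtures.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Synthetic study configuration
#'
#' Defaults emulate the study design at desk scale: a skewed (Zipf) tag
#' abundance distribution, mappable insert sizes of 15-26 nt peaking at
#' 22-25, a 10-tissue qPCR panel with n = 4 and a 50-fold egg-predominant
#' effect, and 100%-efficiency standard curves (slope -3.3219).
#'
#' @param seed integer seed driving every draw.
#' @param ... overrides for any default listed below.
#' @return named list of generator parameters.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome / hairpins
    n_chrom = 2, genome_length = 40000,
    n_known_mirnas = 30, n_novel_hairpins = 20,
    mature_len = 22, loop_range = c(6, 12), max_gu_wobbles = 2,
    # library
    library_depth = 50000, read_length = 36,
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    class_fractions = c(known = 0.55, novel = 0.12, background = 0.21,
                        junk = 0.08, dimer = 0.03, lowres = 0.01),
    zipf_exponent = 1.5,
    isomir_jitter_rate = 0.05, subst_rate = 0.02,
    length_mix = setNames(
      c(2, 2, 3, 4, 5, 6, 8, 18, 16, 18, 15, 3) / 100, as.character(15:26)),
    # transcripts / target sites
    n_transcripts = 30, protein_len_range = c(80, 150),
    utr5_range = c(40, 60), utr3_range = c(150, 300),
    n_target_mirnas = 3,
    # qPCR panel
    tissues = c("egg", "gill", "liver", "stomach", "kidney", "muscle",
                "heart", "intestine", "brain", "spleen"),
    n_per_tissue = 4, planted_fold = 50, cq_sigma = 0.2,
    dilution_sigma = 0.05, slope = -3.3219, intercept = 36,
    n_dilutions = 5, reference_targets = c("actb", "h2a"))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# integer counts following a Zipf law over n items summing ~ total
.zipf_counts <- function(n, total, exponent) {
  w <- (seq_len(n))^(-exponent)
  cnt <- pmax(1L, floor(w / sum(w) * total))
  cnt[sample.int(n)] # random rank assignment
}

# build a hairpin: mature + loop + star (or star-first), with GU wobbles
.make_hairpin <- function(mature, loop_len, n_wobble, mature_first) {
  star <- .chars(revcomp(mature))
  Lm <- nchar(mature)
  mch <- .chars(mature)
  eligible <- which(mch %in% c("T", "G"))
  if (n_wobble > 0 && length(eligible) > 0) {
    pos <- sample(eligible, min(n_wobble, length(eligible)))
    for (p in pos) {
      k <- Lm - p + 1 # star index pairing mature position p
      star[k] <- if (mch[p] == "T") "G" else "T"
    }
  }
  star <- paste(star, collapse = "")
  loop <- .rand_dna(loop_len)
  if (mature_first) paste0(mature, loop, star) else paste0(star, loop, mature)
}

#' Generate a toy genome with planted miRNA hairpins
#'
#' Uniform-random background chromosomes with non-overlapping planted
#' precursors: a 22 nt mature, a reverse-complement star arm carrying 0-2
#' planted G:U wobbles, a 6-12 nt loop, placed on random strands. A set of
#' known mature miRNAs (not placed in the genome) is generated alongside as
#' the known-miRNA reference. Mature uniqueness in the genome is verified.
#'
#' @param config from [sim_config()].
#' @return list with `genome` (named chromosome vector), `known_db`
#'   (data.frame `name`, `family`, `sequence`) and `novel_truth`
#'   (data.frame with mature sequence, locus, strand, arm, hairpin layout).
#' @export
make_genome_with_hairpins <- function(config = sim_config()) {
  if (config$genome_length < config$n_novel_hairpins * 200)
    stop("make_genome_with_hairpins: genome too short for requested hairpins")
  set.seed(.subseed(config$seed, 1))
  # known matures: a few let-7 paralogs plus numbered families
  known <- character(0); names_known <- character(0)
  fam_names <- c("omy-let-7a", "omy-let-7b", "omy-let-7c",
                 sprintf("omy-miR-%d-%s", 100 + seq_len(config$n_known_mirnas),
                         rep(c("5p", "3p"), length.out = config$n_known_mirnas)))
  all_seqs <- character(0)
  i <- 0
  while (length(known) < config$n_known_mirnas) {
    i <- i + 1
    len <- sample(c(20, 21, 22, 22, 22, 23, 24), 1)
    cand <- .rand_dna(len)
    if (length(all_seqs) > 0) {
      m <- .match_tags(cand, sort(all_seqs), 1L, 3L)
      if (!is.na(m$index)) next
    }
    known <- c(known, cand)
    names_known <- c(names_known, fam_names[length(known)])
    all_seqs <- c(all_seqs, cand)
  }
  known_db <- data.frame(name = names_known,
                         family = mirna_family(names_known),
                         sequence = known, stringsAsFactors = FALSE)
  # novel matures: distinct from known set and from each other
  novel <- character(0)
  while (length(novel) < config$n_novel_hairpins) {
    cand <- .rand_dna(config$mature_len)
    m <- .match_tags(cand, sort(all_seqs), 1L, 3L)
    if (!is.na(m$index)) next
    novel <- c(novel, cand)
    all_seqs <- c(all_seqs, cand)
  }
  # background chromosomes
  chrom_len <- rep(config$genome_length %/% config$n_chrom, config$n_chrom)
  genome <- setNames(vapply(chrom_len, .rand_dna, character(1)),
                     paste0("chr", seq_len(config$n_chrom)))
  # plant hairpins at non-overlapping positions (>= 100 nt apart)
  occupied <- lapply(genome, function(x) integer(0))
  rows <- list()
  for (h in seq_along(novel)) {
    mature <- novel[h]
    loop_len <- sample(seq(config$loop_range[1], config$loop_range[2]), 1)
    # >= 1 wobble keeps the star from being an exact reverse-complement hit
    n_wob <- sample(seq(1, max(1, config$max_gu_wobbles)), 1)
    mature_first <- runif(1) < 0.5
    hp <- .make_hairpin(mature, loop_len, n_wob, mature_first)
    Fh <- nchar(hp)
    strand <- sample(c("+", "-"), 1)
    insert <- if (strand == "+") hp else revcomp(hp)
    repeat {
      chrom <- sample(names(genome), 1)
      q <- sample(seq(101, nchar(genome[[chrom]]) - Fh - 100), 1)
      span <- (q - 100):(q + Fh + 100)
      if (!any(span %in% occupied[[chrom]])) break
    }
    occupied[[chrom]] <- c(occupied[[chrom]], (q - 100):(q + Fh + 100))
    substr(genome[[chrom]], q, q + Fh - 1) <- insert
    # mature position within the hairpin fragment
    a <- if (mature_first) 1L else Fh - config$mature_len + 1L
    b <- a + config$mature_len - 1L
    if (strand == "+") {
      ms <- q + a - 1L; me <- q + b - 1L
    } else {
      ms <- q + Fh - b; me <- q + Fh - a
    }
    rows[[h]] <- data.frame(
      planted_id = sprintf("planted%02d", h), mature = mature,
      chrom = chrom, start = ms, end = me, strand = strand,
      arm = if (mature_first) "5p" else "3p", loop_len = loop_len,
      n_wobble = n_wob, hairpin = hp, stringsAsFactors = FALSE)
  }
  novel_truth <- do.call(rbind, rows)
  # verify each planted mature maps to exactly one locus
  for (h in seq_len(nrow(novel_truth))) {
    loci <- map_tag_to_genome(novel_truth$mature[h], genome)
    if (nrow(loci) != 1)
      stop("make_genome_with_hairpins: planted mature not unique in genome")
  }
  list(genome = genome, known_db = known_db, novel_truth = novel_truth)
}

# apply isomiR end jitter (+/- up to 2 nt per end) to a sequence
.jitter_ends <- function(seq) {
  for (end in c(5, 3)) {
    d <- sample(-2:2, 1)
    if (d < 0) { # trim
      if (nchar(seq) + d < 15) next
      seq <- if (end == 5) substr(seq, 1 - d, nchar(seq)) else
        substr(seq, 1, nchar(seq) + d)
    } else if (d > 0) { # extend with random bases
      ext <- .rand_dna(d)
      seq <- if (end == 5) paste0(ext, seq) else paste0(seq, ext)
    }
  }
  seq
}

.substitute_one <- function(seq) {
  p <- sample(nchar(seq), 1)
  old <- substr(seq, p, p)
  substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  seq
}

#' Simulate an adapter-ligated small-RNA library
#'
#' Reads are a mixture of known matures (with optional isomiR end jitter
#' and single substitutions), planted novel matures, degradation-like
#' background inserts, junk (poly-base, two-letter, N-rich), adapter dimers
#' and low-quality records. Each insert gets the 3' adapter appended and is
#' truncated to the read length. Copy numbers follow a Zipf law.
#'
#' @param gt output of [make_genome_with_hairpins()].
#' @param config from [sim_config()].
#' @return list with `reads` (data.frame `read_id`, `sequence`, `quality`),
#'   `insert_truth` (data.frame `sequence`, `class`, `source`, `copies` of
#'   emitted inserts) and `class_counts` (reads per class).
#' @export
simulate_small_rna_library <- function(gt, config = sim_config()) {
  set.seed(.subseed(config$seed, 2))
  fr <- config$class_fractions
  D <- config$library_depth
  n_class <- setNames(round(D * fr), names(fr))
  inserts <- character(0); klass <- character(0); src <- character(0)

  emit <- function(base_seqs, counts, class, sources) {
    for (i in seq_along(base_seqs)) {
      n <- counts[i]
      if (n == 0) next
      jit <- stats::rbinom(n, 1, config$isomir_jitter_rate) == 1
      sub <- stats::rbinom(n, 1, config$subst_rate) == 1
      out <- rep(base_seqs[i], n)
      for (k in which(jit)) out[k] <- .jitter_ends(out[k])
      for (k in which(sub)) out[k] <- .substitute_one(out[k])
      inserts <<- c(inserts, out)
      klass <<- c(klass, rep(class, n))
      src <<- c(src, rep(sources[i], n))
    }
  }

  kn <- gt$known_db
  emit(kn$sequence, .zipf_counts(nrow(kn), n_class["known"],
                                 config$zipf_exponent),
       "known", kn$name)
  nv <- gt$novel_truth
  emit(nv$mature, .zipf_counts(nrow(nv), n_class["novel"],
                               config$zipf_exponent),
       "novel", nv$planted_id)
  # background: sparse degradation-like inserts at low copy numbers
  n_bg_seqs <- max(1L, n_class["background"] %/% 4L)
  bg_lens <- sample(as.integer(names(config$length_mix)), n_bg_seqs,
                    replace = TRUE, prob = config$length_mix)
  bg <- vapply(bg_lens, .rand_dna, character(1))
  bg_counts <- .zipf_counts(n_bg_seqs, n_class["background"], 1.1)
  for (i in seq_along(bg)) {
    inserts <- c(inserts, rep(bg[i], bg_counts[i]))
    klass <- c(klass, rep("background", bg_counts[i]))
    src <- c(src, rep(sprintf("bg%05d", i), bg_counts[i]))
  }
  # junk
  n_j <- n_class["junk"]
  if (n_j > 0) {
    jtypes <- sample(c("poly", "two_letter", "n_rich"), n_j, replace = TRUE)
    jk <- vapply(jtypes, function(tp) {
      len <- sample(15:30, 1)
      if (tp == "poly") {
        b <- sample(c("A", "C", "G", "T"), 1)
        mix <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        n_b <- ceiling(len * 0.85)
        paste(c(rep(b, n_b), mix[seq_len(len - n_b)]), collapse = "")
      } else if (tp == "two_letter") {
        ab <- if (runif(1) < 0.5) c("A", "C") else c("G", "T")
        paste(sample(ab, len, replace = TRUE), collapse = "")
      } else {
        s <- .chars(.rand_dna(len))
        s[sample(len, sample(3:5, 1))] <- "N"
        paste(s, collapse = "")
      }
    }, character(1), USE.NAMES = FALSE)
    inserts <- c(inserts, jk); klass <- c(klass, rep("junk", n_j))
    src <- c(src, jtypes)
  }
  # adapter dimers: empty insert
  n_d <- n_class["dimer"]
  if (n_d > 0) {
    inserts <- c(inserts, rep("", n_d))
    klass <- c(klass, rep("dimer", n_d)); src <- c(src, rep("dimer", n_d))
  }
  # low-quality records
  n_lr <- n_class["lowres"]
  lr_idx_start <- length(inserts)
  if (n_lr > 0) {
    lr <- vapply(sample(18:24, n_lr, replace = TRUE), .rand_dna, character(1))
    inserts <- c(inserts, lr)
    klass <- c(klass, rep("lowres", n_lr)); src <- c(src, rep("lowres", n_lr))
  }

  reads <- vapply(inserts, function(ins) {
    r <- paste0(ins, config$adapter3)
    while (nchar(r) < config$read_length) r <- paste0(r, .rand_dna(4))
    substr(r, 1, config$read_length)
  }, character(1), USE.NAMES = FALSE)
  qual <- rep(strrep("I", config$read_length), length(reads))
  if (n_lr > 0)
    qual[(lr_idx_start + 1):(lr_idx_start + n_lr)] <-
      strrep("#", config$read_length)

  ord <- sample(length(reads))
  reads_df <- data.frame(read_id = sprintf("read%06d", seq_along(ord)),
                         sequence = reads[ord], quality = qual[ord],
                         stringsAsFactors = FALSE)
  it <- stats::aggregate(list(copies = rep(1L, length(inserts))),
                         by = list(sequence = inserts, class = klass,
                                   source = src), FUN = sum)
  list(reads = reads_df, insert_truth = it,
       class_counts = setNames(as.integer(n_class), names(n_class)))
}

# back-translate one amino acid to a random synonymous codon
.codon_table <- function() {
  if (is.null(.ovamir_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .ovamir_env$codons <- split(names(gc), unname(gc))
  }
  .ovamir_env$codons
}

.back_translate <- function(aa) {
  ct <- .codon_table()
  paste(vapply(.chars(aa), function(a)
    sample(ct[[a]], 1), character(1), USE.NAMES = FALSE), collapse = "")
}

#' Generate transcripts with planted miRNA target sites
#'
#' Each transcript is a 40-60 nt 5'UTR, a CDS back-translated from a
#' generated protein (with stop codon), and a 150-300 nt 3'UTR. Target
#' sites are planted as perfect reverse complements of the first
#' `n_target_mirnas` planted novel matures, in configurations covering all
#' three targeting modes: single 3'UTR sites, two miRNAs in one 3'UTR, and
#' the same miRNA in both the 3'UTR and the CDS. Proteins are exact
#' translations of the final (site-carrying) CDS, so homology recovery is
#' guaranteed by construction.
#'
#' @param gt output of [make_genome_with_hairpins()].
#' @param config from [sim_config()].
#' @return list with `cdnas`, `proteins` (named vectors), `models_truth`
#'   (data.frame of true region boundaries), `sites` (planted site table:
#'   gene, mirna, region, start within region, mode) and `target_mirnas`
#'   (data.frame `name`, `sequence`).
#' @export
make_gene_models_with_sites <- function(gt, config = sim_config()) {
  set.seed(.subseed(config$seed, 3))
  nmir <- config$n_target_mirnas
  mir <- data.frame(name = paste0(gt$novel_truth$planted_id[seq_len(nmir)],
                                  "-", gt$novel_truth$arm[seq_len(nmir)]),
                    sequence = gt$novel_truth$mature[seq_len(nmir)],
                    stringsAsFactors = FALSE)
  n_tx <- config$n_transcripts
  cdnas <- character(0); proteins <- character(0)
  models <- list(); sites <- list()
  # site plan: tx1..3 single-site; tx4 multi-miRNA; tx5 3'UTR + CDS
  plan <- vector("list", n_tx)
  plan[[1]] <- list(utr3 = mir$name[1], cds = NULL, mode = "single-3UTR")
  plan[[2]] <- list(utr3 = mir$name[2], cds = NULL, mode = "single-3UTR")
  plan[[3]] <- list(utr3 = mir$name[3], cds = NULL, mode = "single-3UTR")
  plan[[4]] <- list(utr3 = mir$name[1:2], cds = NULL,
                    mode = "multi-miRNA-3UTR")
  plan[[5]] <- list(utr3 = mir$name[1], cds = mir$name[1],
                    mode = "3UTR-plus-CDS")
  for (i in seq_len(n_tx)) {
    tx <- sprintf("tx%02d", i)
    u5 <- sample(seq(config$utr5_range[1], config$utr5_range[2]), 1)
    u3 <- sample(seq(config$utr3_range[1], config$utr3_range[2]), 1)
    plen <- sample(seq(config$protein_len_range[1],
                       config$protein_len_range[2]), 1)
    aa <- paste(sample(.AA20, plen, replace = TRUE), collapse = "")
    cds <- .back_translate(aa)
    utr5 <- .rand_dna(u5)
    utr3 <- .rand_dna(u3)
    pl <- plan[[i]]
    if (!is.null(pl)) {
      pos3 <- 20L
      for (mnm in pl$utr3) {
        sseq <- revcomp(mir$sequence[mir$name == mnm])
        substr(utr3, pos3, pos3 + nchar(sseq) - 1L) <- sseq
        sites[[length(sites) + 1L]] <- data.frame(
          gene = tx, mirna = mnm, region = "3UTR", start = pos3,
          mode = pl$mode, stringsAsFactors = FALSE)
        pos3 <- pos3 + nchar(sseq) + 15L
      }
      for (mnm in pl$cds) {
        sseq <- revcomp(mir$sequence[mir$name == mnm])
        # keep the reading frame stop-free: slide until no stop codon
        for (cpos in seq(31L, nchar(cds) - nchar(sseq) - 3L, by = 1L)) {
          cand <- cds
          substr(cand, cpos, cpos + nchar(sseq) - 1L) <- sseq
          aa_cand <- suppressWarnings(as.character(Biostrings::translate(
            Biostrings::DNAString(cand))))
          if (!grepl("*", aa_cand, fixed = TRUE)) {
            cds <- cand; aa <- aa_cand
            sites[[length(sites) + 1L]] <- data.frame(
              gene = tx, mirna = mnm, region = "CDS", start = cpos,
              mode = pl$mode, stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    stopc <- sample(c("TAA", "TAG", "TGA"), 1)
    cdna <- paste0(utr5, cds, stopc, utr3)
    cdnas[tx] <- cdna
    proteins[sprintf("prot%02d", i)] <- aa
    # true boundaries: the homology match is the CDS (stop codon excluded)
    models[[tx]] <- data.frame(
      transcript = tx, utr5_start = 1L, utr5_end = u5,
      cds_start = u5 + 1L, cds_end = u5 + nchar(cds),
      utr3_start = u5 + nchar(cds) + 1L, utr3_end = nchar(cdna),
      stringsAsFactors = FALSE)
  }
  list(cdnas = cdnas, proteins = proteins,
       models_truth = `rownames<-`(do.call(rbind, models), NULL),
       sites = if (length(sites)) `rownames<-`(do.call(rbind, sites), NULL)
       else data.frame(),
       target_mirnas = mir)
}

#' Simulate a tissue-panel qPCR experiment
#'
#' True per-tissue quantities (the egg tissue multiplied by the planted
#' fold) are converted to Cq values through a fixed standard curve plus
#' Gaussian noise; reference genes are constant across tissues up to noise.
#' A 10-fold dilution series is emitted for every target for curve fitting.
#'
#' @param config from [sim_config()].
#' @param targets character vector of assay target names (default three
#'   egg-predominant miRNA assays).
#' @param egg_fold per-target planted fold in egg; recycled; default
#'   `config$planted_fold` for every target.
#' @return list with `plate` (data.frame `sample`, `tissue`, `target`,
#'   `cq`), `dilutions` (data.frame `target`, `log10_quantity`, `cq`) and
#'   `truth` (per target/tissue true quantities and folds).
#' @export
simulate_qpcr_plate <- function(config = sim_config(),
                                targets = c("mir-egg-1", "mir-egg-2",
                                            "mir-egg-3"),
                                egg_fold = NULL) {
  stopifnot(length(config$tissues) >= 2)
  set.seed(.subseed(config$seed, 4))
  if (is.null(egg_fold)) egg_fold <- config$planted_fold
  egg_fold <- rep(egg_fold, length.out = length(targets))
  refs <- config$reference_targets
  ref_q <- setNames(c(5, 20), refs)
  plate <- list(); truth <- list()
  samples <- expand.grid(rep = seq_len(config$n_per_tissue),
                         tissue = config$tissues, stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$tissue, "_", samples$rep)
  cq_of <- function(q, sigma) config$slope * log10(q) + config$intercept +
    stats::rnorm(length(q), 0, sigma)
  for (ti in seq_along(targets)) {
    q0 <- 10^stats::runif(1, -1.5, -0.5)
    for (s in seq_len(nrow(samples))) {
      q <- if (samples$tissue[s] == "egg") q0 * egg_fold[ti] else q0
      plate[[length(plate) + 1L]] <- data.frame(
        sample = samples$sample[s], tissue = samples$tissue[s],
        target = targets[ti], cq = cq_of(q, config$cq_sigma),
        stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      target = targets[ti], base_quantity = q0, egg_fold = egg_fold[ti],
      stringsAsFactors = FALSE)
  }
  for (rf in refs) {
    for (s in seq_len(nrow(samples))) {
      plate[[length(plate) + 1L]] <- data.frame(
        sample = samples$sample[s], tissue = samples$tissue[s],
        target = rf, cq = cq_of(ref_q[rf], config$cq_sigma),
        stringsAsFactors = FALSE)
    }
  }
  dil <- list()
  for (tg in c(targets, refs)) {
    lq <- -(seq_len(config$n_dilutions) - 1)
    dil[[tg]] <- data.frame(
      target = tg, log10_quantity = lq,
      cq = cq_of(10^lq, config$dilution_sigma), stringsAsFactors = FALSE)
  }
  list(plate = `rownames<-`(do.call(rbind, plate), NULL),
       dilutions = `rownames<-`(do.call(rbind, dil), NULL),
       truth = do.call(rbind, truth))
}

#' Generate the complete synthetic study
#'
#' Runs all generators under one config and optionally writes the fixture
#' files (genome.fa, reads.fastq, mature_known.fa, cdna.fa, proteins.fa,
#' plate_cq.tsv, dilutions.tsv, truth.json).
#'
#' @param config from [sim_config()].
#' @param dir optional output directory for fixture files.
#' @return list with components `genome_truth`, `library`, `genes`, `qpcr`.
#' @export
simulate_all <- function(config = sim_config(), dir = NULL) {
  gt <- make_genome_with_hairpins(config)
  lib <- simulate_small_rna_library(gt, config)
  genes <- make_gene_models_with_sites(gt, config)
  qpcr <- simulate_qpcr_plate(config,
                              targets = genes$target_mirnas$name)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(gt$genome, file.path(dir, "genome.fa"))
    write_fasta(setNames(gt$known_db$sequence, gt$known_db$name),
                file.path(dir, "mature_known.fa"))
    x <- Biostrings::DNAStringSet(lib$reads$sequence)
    names(x) <- lib$reads$read_id
    Biostrings::writeXStringSet(
      x, file.path(dir, "reads.fastq"), format = "fastq",
      qualities = Biostrings::BStringSet(lib$reads$quality))
    write_fasta(genes$cdnas, file.path(dir, "cdna.fa"))
    aaset <- Biostrings::AAStringSet(genes$proteins)
    Biostrings::writeXStringSet(aaset, file.path(dir, "proteins.fa"))
    utils::write.table(qpcr$plate, file.path(dir, "plate_cq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qpcr$dilutions, file.path(dir, "dilutions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(novel_truth = gt$novel_truth, insert_truth = lib$insert_truth,
           models_truth = genes$models_truth, sites = genes$sites,
           qpcr_truth = qpcr$truth),
      file.path(dir, "truth.json"), dataframe = "rows")
  }
  list(genome_truth = gt, library = lib, genes = genes, qpcr = qpcr,
       config = config)
}
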
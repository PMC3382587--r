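# Novel miRNA prediction: tags that match no known mature are mapped to a
# reference genome, the hit is extended 60 nt in both directions, the
# extension is folded, and the fold is screened with stem-loop (hairpin)
# criteria. Coordinates are 1-based inclusive.

#' Map a tag to a genome on both strands
#'
#' @param sequence tag sequence.
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @param max_mismatch substitutions tolerated (default 0, exact match).
#' @return data.frame of loci: `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`; ordered by (chrom, start, strand). Zero rows when unmapped.
#' @export
map_tag_to_genome <- function(sequence, genome, max_mismatch = 0) {
  genome <- .as_genome(genome)
  out <- list()
  pat_f <- Biostrings::DNAString(sequence)
  pat_r <- Biostrings::reverseComplement(pat_f)
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (std in c("+", "-")) {
      pat <- if (std == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (length(m) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = std,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  genome
}

#' Extract a precursor candidate around a genomic locus
#'
#' Returns the genome window extended `flank` nt on both sides of the locus
#' (truncated at chromosome ends), on the locus strand, together with the
#' 1-based position of the mature tag within it.
#'
#' @param locus one-row data.frame (`chrom`, `start`, `end`, `strand`).
#' @param genome named character vector of chromosomes.
#' @param flank extension on each side, default 60 nt.
#' @return list with `precursor_seq`, `mature_offset` (1-based start of the
#'   mature within the precursor), `mature_len`, and the locus fields.
#' @export
extract_precursor <- function(locus, genome, flank = 60) {
  genome <- .as_genome(genome)
  chrom_seq <- genome[[locus$chrom]]
  if (is.null(chrom_seq)) stop("extract_precursor: unknown chromosome")
  L <- nchar(chrom_seq)
  if (locus$start < 1 || locus$end > L || locus$start > locus$end)
    stop("extract_precursor: locus outside chromosome bounds")
  ws <- as.integer(max(1, locus$start - flank))
  we <- as.integer(min(L, locus$end + flank))
  win <- substr(chrom_seq, ws, we)
  if (locus$strand == "-") {
    win <- revcomp(win)
    offset <- as.integer(we - locus$end + 1)
  } else {
    offset <- as.integer(locus$start - ws + 1)
  }
  list(precursor_seq = win, mature_offset = offset,
       mature_len = as.integer(locus$end - locus$start + 1),
       chrom = locus$chrom, start = ws, end = we, strand = locus$strand)
}

#' Default hairpin-calling criteria
#'
#' @param min_paired_mature minimum mature bases that must be paired.
#' @param loop_min,loop_max accepted terminal loop size range (nt).
#' @param energy_max maximum (i.e. least negative) fold energy, kcal/mol.
#' @param min_dominance the "single dominant stem-loop" rule: the
#'   mature:star duplex must hold at least this many times as many base
#'   pairs as the largest stem-loop elsewhere in the window (1.2 by
#'   default). Competing stems are only walked across bulges of up to
#'   `stem_bulge_max` unpaired bases, so sloppy chains of short helices in
#'   random flank sequence do not count as one long stem.
#' @param stem_bulge_max largest interior loop (total unpaired bases) a
#'   contiguous stem may contain.
#' @return named list of criteria.
#' @export
hairpin_criteria <- function(min_paired_mature = 14, loop_min = 3,
                             loop_max = 20, energy_max = -18,
                             min_dominance = 1.2, stem_bulge_max = 2) {
  list(min_paired_mature = min_paired_mature, loop_min = loop_min,
       loop_max = loop_max, energy_max = energy_max,
       min_dominance = min_dominance, stem_bulge_max = stem_bulge_max)
}

# stem-loop decomposition of a partner vector: for each hairpin loop, walk
# outward through stacked/bulged pairs until a multiloop, the exterior, or
# an interior loop larger than max_gap unpaired bases is reached (precursor
# stems tolerate small bulges only). Returns a data.frame of stems.
.find_stems <- function(partner, max_gap = 2) {
  n <- length(partner)
  opens <- which(partner > seq_len(n))
  stems <- list()
  for (i in opens) {
    j <- partner[i]
    if (j - i >= 2 && all(partner[(i + 1):(j - 1)] == 0)) {
      # hairpin loop closed by (i, j); walk outward
      a <- i; b <- j; npairs <- 1L
      repeat {
        # nearest paired base 5' of a
        a2 <- a - 1L
        while (a2 >= 1 && partner[a2] == 0) a2 <- a2 - 1L
        if (a2 < 1 || partner[a2] <= b) break
        b2 <- partner[a2]
        # region between must be unpaired for this to be the same stem
        if (b2 > b + 1 && any(partner[(b + 1):(b2 - 1)] != 0)) break
        if ((a - a2 - 1L) + (b2 - b - 1L) > max_gap) break
        a <- a2; b <- b2; npairs <- npairs + 1L
      }
      stems[[length(stems) + 1L]] <- data.frame(
        outer5 = a, outer3 = b, loop5 = i, loop3 = j,
        loop_len = j - i - 1L, n_pairs = npairs)
    }
  }
  if (length(stems) == 0) {
    return(data.frame(outer5 = integer(0), outer3 = integer(0),
                      loop5 = integer(0), loop3 = integer(0),
                      loop_len = integer(0), n_pairs = integer(0)))
  }
  do.call(rbind, stems)
}

#' Screen a precursor candidate for a miRNA-like hairpin
#'
#' The minimum-energy fold of the precursor is decomposed into stem-loops
#' (helices walked across bulges of at most `stem_bulge_max` unpaired
#' bases); the mature's stem is the one holding most of its paired bases.
#' The verdict is TRUE when all of the mature's in-stem pairs lie on a
#' single arm of that stem (a mature spanning the terminal loop fails), at
#' least `min_paired_mature` mature bases pair within the stem, the stem's
#' terminal loop is `loop_min`-`loop_max` nt, the stem dominates every
#' stem-loop outside its extent (pair-count ratio `min_dominance`), and the
#' fold energy is at or below `energy_max`.
#'
#' @param precursor_seq precursor sequence (from [extract_precursor()]).
#' @param mature_offset,mature_len 1-based position and length of the mature
#'   within the precursor.
#' @param criteria from [hairpin_criteria()].
#' @param fold optional precomputed [fold_rna()] result for the precursor.
#' @return list with `hairpin` (verdict), `arm` ("5p"/"3p" or NA), `scores`
#'   (per-criterion values) and `fold`.
#' @export
call_hairpin <- function(precursor_seq, mature_offset, mature_len,
                         criteria = hairpin_criteria(), fold = NULL) {
  if (is.null(fold)) fold <- fold_rna(precursor_seq)
  partner <- fold$partner
  ms <- mature_offset
  me <- mature_offset + mature_len - 1L
  mat_pos <- ms:me
  stems <- .find_stems(partner, max_gap = criteria$stem_bulge_max)
  arm <- NA_character_
  paired_in_stem <- 0L
  dominance <- 0
  loop_len <- NA_integer_
  loop_ok <- FALSE
  spans_loop <- FALSE
  if (nrow(stems) > 0) {
    # mature pairs on each arm of each stem (paired positions inside a
    # walked stem's arm always pair within that stem)
    p5 <- vapply(seq_len(nrow(stems)), function(k) {
      sel <- mat_pos >= stems$outer5[k] & mat_pos <= stems$loop5[k]
      sum(partner[mat_pos[sel]] > 0)
    }, integer(1))
    p3 <- vapply(seq_len(nrow(stems)), function(k) {
      sel <- mat_pos >= stems$loop3[k] & mat_pos <= stems$outer3[k]
      sum(partner[mat_pos[sel]] > 0)
    }, integer(1))
    k <- which.max(p5 + p3)
    if (p5[k] + p3[k] > 0) {
      spans_loop <- p5[k] > 0 && p3[k] > 0
      if (!spans_loop) {
        arm <- if (p5[k] > 0) "5p" else "3p"
        paired_in_stem <- p5[k] + p3[k]
        loop_len <- stems$loop_len[k]
        loop_ok <- loop_len >= criteria$loop_min &&
          loop_len <= criteria$loop_max
        disjoint <- stems$outer3 < stems$outer5[k] |
          stems$outer5 > stems$outer3[k]
        dominance <- stems$n_pairs[k] / max(stems$n_pairs[disjoint], 1)
      }
    }
  }
  verdict <- !is.na(arm) && loop_ok &&
    paired_in_stem >= criteria$min_paired_mature &&
    dominance >= criteria$min_dominance &&
    fold$energy <= criteria$energy_max
  list(hairpin = verdict, arm = arm,
       scores = list(paired_mature = paired_in_stem, loop_len = loop_len,
                     dominance = dominance, energy = fold$energy,
                     on_one_arm = !is.na(arm), spans_loop = spans_loop),
       fold = fold)
}

#' Predict novel miRNAs from unmatched tags
#'
#' For every tag with no known-miRNA assignment: map to the genome, extend
#' each locus by `flank` nt on both sides, fold the extension and keep
#' candidates passing [call_hairpin()]. Candidates with identical precursor
#' sequences (repeated genome regions) are collapsed, and survivors are
#' named `nov{serial}-5p`/`-3p` by the arm carrying the mature.
#'
#' @param unmatched data.frame with `sequence`, `copy_number` (the unmatched
#'   output of [match_known()]).
#' @param genome named character vector of chromosomes.
#' @param flank extension length, default 60.
#' @param criteria hairpin criteria, see [hairpin_criteria()].
#' @param max_mismatch genome-mapping mismatch tolerance (default 0).
#' @param params energy model for folding.
#' @return data.frame of accepted candidates: `name`, `tag`, `copy_number`,
#'   `chrom`, `start`, `end`, `strand`, `precursor`, `mature_offset`,
#'   `dot_bracket`, `energy`, `arm`, `paired_mature`, `loop_len`,
#'   `dominance`.
#' @export
predict_novel <- function(unmatched, genome, flank = 60,
                          criteria = hairpin_criteria(), max_mismatch = 0,
                          params = energy_params()) {
  genome <- .as_genome(genome)
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(unmatched))) {
    tag <- unmatched$sequence[i]
    loci <- map_tag_to_genome(tag, genome, max_mismatch = max_mismatch)
    for (k in seq_len(nrow(loci))) {
      pc <- extract_precursor(loci[k, ], genome, flank = flank)
      if (pc$precursor_seq %in% seen) next
      fold <- fold_rna(pc$precursor_seq, params = params)
      ch <- call_hairpin(pc$precursor_seq, pc$mature_offset, pc$mature_len,
                         criteria = criteria, fold = fold)
      if (!ch$hairpin) next
      seen <- c(seen, pc$precursor_seq)
      rows[[length(rows) + 1L]] <- data.frame(
        tag = tag, copy_number = unmatched$copy_number[i],
        chrom = pc$chrom, start = pc$start, end = pc$end,
        strand = pc$strand, precursor = pc$precursor_seq,
        mature_offset = pc$mature_offset,
        dot_bracket = fold$dot_bracket, energy = fold$energy,
        arm = ch$arm, paired_mature = ch$scores$paired_mature,
        loop_len = ch$scores$loop_len, dominance = ch$scores$dominance,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(name = character(0), tag = character(0),
                      copy_number = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), precursor = character(0),
                      mature_offset = integer(0), dot_bracket = character(0),
                      energy = numeric(0), arm = character(0),
                      paired_mature = integer(0), loop_len = integer(0),
                      dominance = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- cbind(name = sprintf("nov%d-%s", seq_len(nrow(out)), out$arm), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
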
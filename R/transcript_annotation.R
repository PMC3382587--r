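# Approximate UTR/CDS partitioning of transcript cDNAs by translated
# homology: a desk-scale six-frame ungapped seeded search against a protein
# reference (BLOSUM62, word size 6, low-complexity query masking, ungapped
# Karlin-Altschul E-values), followed by the fixed partition rule: the
# homology match is the approximate coding region, the 60 nt upstream of it
# the approximate 5'UTR, and everything downstream the approximate 3'UTR.

# ungapped Karlin-Altschul parameters for BLOSUM62
.KA_LAMBDA <- 0.3176
.KA_K <- 0.134

.blosum62 <- function() {
  if (is.null(.ovamir_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ovamir_env$blosum62 <- e$BLOSUM62
  }
  .ovamir_env$blosum62
}

.aa_score <- function(mat, a, b) {
  if (a %in% rownames(mat) && b %in% colnames(mat)) mat[a, b] else -4
}

#' Mask low-complexity amino-acid segments
#'
#' Windowed Shannon-entropy filter: every window of `window` residues whose
#' composition entropy is below `threshold` bits is replaced by `X`
#' (excluded from seeding). An approximation of the usual query filter.
#'
#' @param aa amino-acid string.
#' @param window window size in residues.
#' @param threshold entropy threshold in bits.
#' @return masked amino-acid string.
#' @export
mask_low_complexity <- function(aa, window = 12, threshold = 2.2) {
  ch <- .chars(aa)
  n <- length(ch)
  if (n < window) return(aa)
  mask <- logical(n)
  for (i in seq_len(n - window + 1)) {
    if (.entropy(ch[i:(i + window - 1)]) < threshold)
      mask[i:(i + window - 1)] <- TRUE
  }
  ch[mask] <- "X"
  paste(ch, collapse = "")
}

# translate one frame; returns aa string ('*' for stops, 'X' for fuzzy)
.translate_frame <- function(cdna, frame) {
  s <- if (frame > 0) cdna else revcomp(cdna)
  off <- abs(frame)
  sub <- substr(s, off, nchar(s))
  usable <- nchar(sub) - nchar(sub) %% 3
  if (usable < 3) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(sub, 1, usable)), if.fuzzy.codon = "X")))
}

# ungapped x-drop extension of a word seed; returns extended HSP
.extend_seed <- function(qa, sa, qpos, spos, word_size, mat, xdrop = 20) {
  score <- 0
  for (k in 0:(word_size - 1))
    score <- score + .aa_score(mat, substr(qa, qpos + k, qpos + k),
                               substr(sa, spos + k, spos + k))
  qs <- qpos; qe <- qpos + word_size - 1
  ss <- spos; se <- spos + word_size - 1
  # right
  cur <- score; best <- score; bq <- qe; bs <- se
  i <- qe + 1; j <- se + 1
  while (i <= nchar(qa) && j <= nchar(sa)) {
    a <- substr(qa, i, i)
    if (a == "*") break
    cur <- cur + .aa_score(mat, a, substr(sa, j, j))
    if (cur > best) { best <- cur; bq <- i; bs <- j }
    if (cur < best - xdrop) break
    i <- i + 1; j <- j + 1
  }
  qe <- bq; se <- bs; score <- best
  # left
  cur <- score; best <- score; bq <- qs; bs <- ss
  i <- qs - 1; j <- ss - 1
  while (i >= 1 && j >= 1) {
    a <- substr(qa, i, i)
    if (a == "*") break
    cur <- cur + .aa_score(mat, a, substr(sa, j, j))
    if (cur > best) { best <- cur; bq <- i; bs <- j }
    if (cur < best - xdrop) break
    i <- i - 1; j <- j - 1
  }
  list(q_start = bq, q_end = qe, s_start = bs, s_end = se, score = best)
}

#' Six-frame translated homology search of a cDNA against proteins
#'
#' Seeds on exact `word_size`-residue words (after low-complexity masking of
#' the translated query), extends each seed without gaps under BLOSUM62 with
#' an X-drop rule, and reports the best hit per protein and frame that meets
#' the E-value and shorter-sequence coverage cutoffs. E-values use ungapped
#' Karlin-Altschul statistics.
#'
#' @param cdna cDNA sequence (one string).
#' @param proteins named character vector of amino-acid sequences.
#' @param word_size seed word length in residues.
#' @param evalue_max E-value cutoff (default 10).
#' @param min_shorter_coverage minimum fraction of the shorter of
#'   query/subject covered by the match (default 0.60).
#' @param mask apply low-complexity masking before seeding.
#' @param xdrop extension termination parameter (bits of raw score).
#' @return data.frame of matches: `protein_id`, `frame` (1..3, -1..-3),
#'   `nt_start`, `nt_end` (1-based inclusive on the forward cDNA),
#'   `aligned_aa`, `score`, `bits`, `evalue`, `shorter_coverage`.
#' @export
translated_search <- function(cdna, proteins, word_size = 6,
                              evalue_max = 10, min_shorter_coverage = 0.60,
                              mask = TRUE, xdrop = 20) {
  cdna <- as_dna(cdna)
  empty <- data.frame(protein_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      aligned_aa = integer(0), score = numeric(0),
                      bits = numeric(0), evalue = numeric(0),
                      shorter_coverage = numeric(0), stringsAsFactors = FALSE)
  if (nchar(cdna) < 3 * word_size) {
    warning("translated_search: cDNA shorter than 3*word_size; no search")
    return(empty)
  }
  stopifnot(length(proteins) > 0)
  mat <- .blosum62()
  # subject word index
  idx <- new.env(parent = emptyenv())
  for (p in seq_along(proteins)) {
    sa <- proteins[[p]]
    if (nchar(sa) < word_size) next
    for (pos in seq_len(nchar(sa) - word_size + 1)) {
      w <- substr(sa, pos, pos + word_size - 1)
      idx[[w]] <- rbind(idx[[w]], c(p, pos))
    }
  }
  m_aa <- nchar(cdna) %/% 3
  n_db <- sum(nchar(proteins))
  L <- nchar(cdna)
  hits <- list()
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    qa <- .translate_frame(cdna, frame)
    if (!nzchar(qa)) next
    qa_seed <- if (mask) mask_low_complexity(qa) else qa
    best_by_diag <- new.env(parent = emptyenv())
    nq <- nchar(qa_seed)
    if (nq < word_size) next
    for (qpos in seq_len(nq - word_size + 1)) {
      w <- substr(qa_seed, qpos, qpos + word_size - 1)
      if (grepl("[X*]", w)) next
      locs <- idx[[w]]
      if (is.null(locs)) next
      for (r in seq_len(nrow(locs))) {
        p <- locs[r, 1]; spos <- locs[r, 2]
        key <- paste0(p, "_", qpos - spos)
        prev <- best_by_diag[[key]]
        # skip seeds inside an HSP already extended on this diagonal
        if (!is.null(prev) && qpos >= prev$q_start && qpos <= prev$q_end)
          next
        h <- .extend_seed(qa, proteins[[p]], qpos, spos, word_size, mat,
                          xdrop)
        if (is.null(prev) || h$score > prev$score) best_by_diag[[key]] <- h
      }
    }
    # best HSP per protein in this frame
    keys <- ls(best_by_diag)
    if (length(keys) == 0) next
    byp <- list()
    for (key in keys) {
      p <- as.integer(sub("_.*$", "", key))
      h <- best_by_diag[[key]]
      if (is.null(byp[[as.character(p)]]) ||
          h$score > byp[[as.character(p)]]$score)
        byp[[as.character(p)]] <- c(h, protein = p)
    }
    for (h in byp) {
      alen <- h$q_end - h$q_start + 1
      p <- h$protein
      cov <- alen / min(m_aa, nchar(proteins[[p]]))
      ev <- .KA_K * m_aa * n_db * exp(-.KA_LAMBDA * h$score)
      if (ev > evalue_max || cov < min_shorter_coverage) next
      off <- abs(frame)
      nt_s <- off + 3 * (h$q_start - 1)
      nt_e <- off + 3 * h$q_end - 1
      if (frame < 0) { tmp <- nt_s; nt_s <- L - nt_e + 1; nt_e <- L - tmp + 1 }
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = names(proteins)[p], frame = frame,
        nt_start = nt_s, nt_end = nt_e, aligned_aa = alen,
        score = h$score,
        bits = (.KA_LAMBDA * h$score - log(.KA_K)) / log(2),
        evalue = ev, shorter_coverage = cov, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Pick the homolog among multiple matches
#'
#' The match with the greatest aligned length wins; ties are broken by
#' higher score, then lower E-value, then protein id.
#'
#' @param matches data.frame from [translated_search()].
#' @return one-row data.frame, or NULL when `matches` is empty.
#' @export
select_homolog <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(NULL)
  o <- order(-matches$aligned_aa, -matches$score, matches$evalue,
             matches$protein_id)
  matches[o[1], , drop = FALSE]
}

#' Partition a cDNA into approximate 5'UTR / CDS / 3'UTR
#'
#' The homology match region is the approximate coding region; the 60 nt
#' immediately upstream are the approximate 5'UTR (typical 5'UTRs run
#' 60-90 nt) and everything downstream of the match is the approximate
#' 3'UTR. For reverse-frame matches the model is built on the reverse
#' complement of the cDNA and flagged.
#'
#' @param cdna cDNA sequence.
#' @param match one-row match (from [select_homolog()]).
#' @param transcript_id id recorded in the output.
#' @return data.frame with `transcript`, `region` ("5UTR","CDS","3UTR"),
#'   `start`, `end` (1-based inclusive; empty regions omitted), and a
#'   `revcomp` attribute flagging reverse-frame models.
#' @export
partition_transcript <- function(cdna, match, transcript_id = "tx") {
  L <- nchar(cdna)
  s <- match$nt_start; e <- match$nt_end
  if (s < 1 || e > L || s > e)
    stop("partition_transcript: match outside cDNA bounds")
  rc <- match$frame < 0
  if (rc) { tmp <- s; s <- L - e + 1; e <- L - tmp + 1 } # coords on revcomp
  rows <- list()
  if (s > 1)
    rows$five <- data.frame(transcript = transcript_id, region = "5UTR",
                            start = max(1, s - 60), end = s - 1)
  rows$cds <- data.frame(transcript = transcript_id, region = "CDS",
                         start = s, end = e)
  if (e < L)
    rows$three <- data.frame(transcript = transcript_id, region = "3UTR",
                             start = e + 1, end = L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "revcomp") <- rc
  out
}

#' Annotate a set of transcripts against a protein reference
#'
#' Runs [translated_search()] + [select_homolog()] + [partition_transcript()]
#' per transcript.
#'
#' @param cdnas named character vector of cDNA sequences.
#' @param proteins named character vector of protein sequences.
#' @param ... passed to [translated_search()].
#' @return list with `models` (region table over all transcripts with a
#'   homolog; columns `transcript`, `region`, `start`, `end`, `protein`,
#'   `frame`) and `unmatched` (transcript ids with no acceptable homolog).
#' @export
annotate_transcripts <- function(cdnas, proteins, ...) {
  models <- list()
  unmatched <- character(0)
  for (tx in names(cdnas)) {
    m <- translated_search(cdnas[[tx]], proteins, ...)
    best <- select_homolog(m)
    if (is.null(best)) { unmatched <- c(unmatched, tx); next }
    gm <- partition_transcript(cdnas[[tx]], best, transcript_id = tx)
    gm$protein <- best$protein_id
    gm$frame <- best$frame
    models[[tx]] <- gm
  }
  models <- if (length(models)) do.call(rbind, models) else
    data.frame(transcript = character(0), region = character(0),
               start = integer(0), end = integer(0),
               protein = character(0), frame = integer(0))
  rownames(models) <- NULL
  list(models = models, unmatched = unmatched)
}

#' Extract region sequences from gene models
#'
#' @param cdnas named character vector of cDNAs.
#' @param models region table from [annotate_transcripts()].
#' @return named list (`5UTR`, `CDS`, `3UTR`) of named character vectors.
#' @export
region_sequences <- function(cdnas, models) {
  out <- list()
  for (rt in c("5UTR", "CDS", "3UTR")) {
    rows <- models[models$region == rt, , drop = FALSE]
    seqs <- character(0)
    for (i in seq_len(nrow(rows))) {
      tx <- rows$transcript[i]
      seqs[tx] <- substr(cdnas[[tx]], rows$start[i], rows$end[i])
    }
    out[[rt]] <- seqs
  }
  out
}
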
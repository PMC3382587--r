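# Independent oracles used by the tests. These deliberately re-implement
# the checked quantities with different (usually brute-force) algorithms so
# that agreement is informative.

orc_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

orc_rand_dna <- function(n, bases = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

orc_revcomp <- function(s) {
  paste(rev(orc_chars(chartr("ACGT", "TGCA", s))), collapse = "")
}

# ---- folding: exhaustive enumeration of nested structures ----------------

orc_can_pair <- function(a, b) {
  paste0(chartr("T", "U", a), chartr("T", "U", b)) %in%
    c("CG", "GC", "GU", "UG", "AU", "UA")
}

# enumerate every nested structure (min loop 3) and return the minimum
# energy under the package's own structure scorer; independent of the DP.
orc_enum_best_fold <- function(seq, forbidden = integer(0),
                               params = energy_params()) {
  s <- orc_chars(seq)
  n <- length(s)
  best <- 0
  rec <- function(partner, pos) {
    if (pos > n) {
      e <- structure_energy(seq, partner, params)
      if (e < best) best <<- e
      return(invisible())
    }
    if (partner[pos] != 0) {
      rec(partner, pos + 1)
      return(invisible())
    }
    rec(partner, pos + 1) # leave pos unpaired
    if (pos %in% forbidden) return(invisible())
    for (j in seq_len(n)) {
      if (j <= pos + 3 || partner[j] != 0 || j %in% forbidden) next
      if (!orc_can_pair(s[pos], s[j])) next
      crossing <- FALSE
      for (i2 in seq_len(n)) {
        j2 <- partner[i2]
        if (j2 > i2 &&
            ((pos < i2 && j > i2 && j < j2) ||
             (pos > i2 && pos < j2 && j > j2))) { crossing <- TRUE; break }
      }
      if (crossing) next
      p2 <- partner
      p2[pos] <- j; p2[j] <- pos
      rec(p2, pos + 1)
    }
  }
  rec(integer(n), 1)
  best
}

# ---- known-miRNA matching: exhaustive Hamming search ---------------------

# best (mismatches, |offset|, name) assignment of one tag over a db,
# scanning every offset in -max_off..max_off; overhangs (up to max_off per
# end) are not counted. Returns NULL when nothing is within max_mm.
orc_match_one <- function(tag, db_seqs, db_names, max_mm = 1, max_off = 3) {
  tc <- orc_chars(tag)
  lt <- length(tc)
  ord <- order(db_names)
  best <- NULL
  for (d in ord) {
    mc <- orc_chars(db_seqs[d])
    lm <- length(mc)
    for (o in -max_off:max_off) {
      if ((o + lt) - lm > max_off) next
      from <- max(1, 1 - o); to <- min(lt, lm - o)
      if (to < from) next
      mm <- sum(tc[from:to] != mc[(from:to) + o])
      if (mm > max_mm) next
      if (is.null(best) || mm < best$mm ||
          (mm == best$mm && abs(o) < abs(best$off))) {
        best <- list(name = db_names[d], mm = mm, off = o)
      }
    }
  }
  best
}

# ---- duplex alignment: memoized exhaustive trace search ------------------

# best local complementarity alignment score; recursion over alignment
# moves with affine gap states, memoized. Mirrors the scoring semantics
# (pair scores weighted at miRNA 5' positions, gaps unweighted).
orc_best_duplex_S <- function(mirna, window, scoring = duplex_scoring()) {
  m <- nchar(mirna); w <- nchar(window)
  mr <- rev(orc_chars(mirna)) # 3'->5'
  wn <- orc_chars(window)
  pair_score <- function(i, j) {
    pos5 <- m - (i - 1)
    a <- mr[i]; b <- wn[j]
    key <- paste0(chartr("T", "U", b), chartr("T", "U", a))
    sc <- if (key %in% c("CG", "GC", "AU", "UA")) scoring$wc_score
    else if (key %in% c("GU", "UG")) scoring$gu_score
    else scoring$mm_score
    if (pos5 >= scoring$w5_from && pos5 <= scoring$w5_to)
      sc * scoring$w5_factor else sc
  }
  memo <- new.env(parent = emptyenv())
  cont <- function(i, j, last) {
    if (i > m || j > w) return(0)
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0 # stop here
    best <- max(best, pair_score(i, j) + cont(i + 1, j + 1, "p"))
    gm <- if (last == "gm") scoring$gap_extend else scoring$gap_open
    best <- max(best, gm + cont(i + 1, j, "gm"))
    gw <- if (last == "gw") scoring$gap_extend else scoring$gap_open
    best <- max(best, gw + cont(i, j + 1, "gw"))
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(w)) {
    best <- max(best, pair_score(i, j) + cont(i + 1, j + 1, "p"))
  }
  best
}

# ---- rank statistics ------------------------------------------------------

# tie-corrected Kruskal-Wallis H from the textbook formula
orc_kw_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gs <- split(r, groups)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(gs, function(x) length(x) * mean(x)^2, numeric(1))) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# one-way ANOVA F from explicit sums of squares
orc_anova_F <- function(values, groups) {
  gs <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(gs, function(x) length(x) * (mean(x) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(gs, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- length(gs) - 1
  dfw <- length(values) - length(gs)
  (ssb / dfb) / (ssw / dfw)
}

# ---- misc -----------------------------------------------------------------

# dinucleotide shuffle (non-overlapping dinucleotide permutation)
orc_dinuc_shuffle <- function(seq) {
  n <- nchar(seq)
  idx <- seq(1, n - 1, by = 2)
  parts <- vapply(idx, function(i) substr(seq, i, i + 1), character(1))
  out <- paste(sample(parts), collapse = "")
  if (nchar(out) < n) out <- paste0(out, substr(seq, n, n))
  out
}

# independent single-rule read-category rescan used against FilterReport.
# Applies each rule in the documented order to the raw reads.
orc_rescan_categories <- function(reads, adapter3, min_quality = 20,
                                  min_copy = 3, min_len = 15, max_len = 26) {
  n <- nrow(reads)
  cat_of <- rep(NA_character_, n)
  ins <- character(n)
  for (i in seq_len(n)) {
    sq <- reads$sequence[i]
    if (grepl("[^ACGTN]", sq)) { cat_of[i] <- "invalid"; next }
    if (!is.na(reads$quality[i]) &&
        mean(utf8ToInt(reads$quality[i]) - 33) < min_quality) {
      cat_of[i] <- "low_resolution"; next
    }
    ins[i] <- trim_adapter(sq, adapter3)
    if (ins[i] == "") { cat_of[i] <- "adapter_dimer"; next }
  }
  open <- is.na(cat_of)
  counts <- table(ins[open])
  for (i in which(open)) {
    sq <- ins[i]
    ch <- orc_chars(sq)
    tab <- table(factor(ch, levels = c("A", "C", "G", "T", "N")))
    if (max(tab[c("A", "C", "G", "T")]) / nchar(sq) >= 0.8 ||
        tab["N"] >= 3 ||
        all(ch %in% c("A", "C")) || all(ch %in% c("G", "T"))) {
      cat_of[i] <- "junk"
    } else if (tab["N"] >= 1) {
      cat_of[i] <- "n_content"
    } else if (nchar(sq) < min_len || nchar(sq) > max_len) {
      cat_of[i] <- "length"
    } else if (counts[[sq]] < min_copy) {
      cat_of[i] <- "copy_number"
    } else cat_of[i] <- "survivor"
  }
  table(cat_of)
}
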
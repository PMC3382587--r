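# Dual-algorithm miRNA target prediction. Scanner 1 (alignment style):
# local complementarity alignment score S with a 5'-seed weighting plus
# nearest-neighbor duplex free energy, accepted when S >= 140 and
# dG < -17 kcal/mol. Scanner 2 (accessibility style): seed-anchored sites
# scored by ddG = dG_duplex + dG_open, where dG_open is the energetic cost
# of unpairing the site in its folded mRNA context. Genes predicted by both
# scanners form the consensus target set.

#' Duplex alignment scoring parameters
#'
#' @param wc_score,gu_score,mm_score per-pair scores for Watson-Crick,
#'   G:U wobble and mismatched columns.
#' @param gap_open,gap_extend affine gap penalties.
#' @param w5_factor,w5_from,w5_to weighting factor applied to pair scores at
#'   miRNA 5'-end positions `w5_from`..`w5_to` (the seed region).
#' @return named list.
#' @export
duplex_scoring <- function(wc_score = 5, gu_score = 1, mm_score = -3,
                           gap_open = -9, gap_extend = -4,
                           w5_factor = 2, w5_from = 2, w5_to = 8) {
  list(wc_score = wc_score, gu_score = gu_score, mm_score = mm_score,
       gap_open = gap_open, gap_extend = gap_extend,
       w5_factor = w5_factor, w5_from = w5_from, w5_to = w5_to)
}

#' Best local miRNA:site complementarity alignment in a window
#'
#' Smith-Waterman alignment of the miRNA (antiparallel, 3' end against the
#' window 5' end) with per-pair complementarity scores and affine gaps; pair
#' scores at miRNA positions 2-8 are doubled by default.
#'
#' @param mirna_seq miRNA sequence (5'->3', DNA or RNA).
#' @param window target window sequence (5'->3').
#' @param scoring from [duplex_scoring()].
#' @return list with `S` (alignment score, >= 0), `site_start`, `site_end`
#'   (1-based inclusive window coordinates; NA when S = 0), and `columns`
#'   (data.frame `mirna_pos`, `site_pos`, NA for gap columns, ordered along
#'   the window).
#' @export
align_duplex <- function(mirna_seq, window, scoring = duplex_scoring()) {
  mirna_seq <- as_dna(mirna_seq); window <- as_dna(window)
  if (!.is_dna(mirna_seq) || !.is_dna(window))
    stop("align_duplex: non-nucleotide characters")
  r <- .sw_duplex(mirna_seq, window, scoring$wc_score, scoring$gu_score,
                  scoring$mm_score, scoring$gap_open, scoring$gap_extend,
                  scoring$w5_factor, as.integer(scoring$w5_from),
                  as.integer(scoring$w5_to))
  cols <- data.frame(mirna_pos = r$mirna_col + 1L,
                     site_pos = r$window_col + 1L)
  sp <- if (nrow(cols) == 0 || all(is.na(cols$site_pos))) c(NA, NA)
  else range(cols$site_pos, na.rm = TRUE)
  list(S = r$score, site_start = sp[1], site_end = sp[2], columns = cols)
}

#' Duplex free energy of an aligned miRNA:site hybrid
#'
#' Nearest-neighbor sum over consecutive stacked pairs from the package
#' stacking table, plus a duplex initiation penalty, AU/GU helix end
#' penalties, and a linear penalty for each internal loop/bulge (mismatch or
#' gap region) between helices. More negative is more stable.
#'
#' @param mirna_seq,site_seq the two strands (site 5'->3'); `site_seq` is
#'   the window the alignment columns refer to.
#' @param columns alignment columns from [align_duplex()].
#' @param params energy model from [energy_params()].
#' @return dG in kcal/mol.
#' @export
duplex_energy <- function(mirna_seq, site_seq, columns,
                          params = energy_params()) {
  mirna_seq <- as_dna(mirna_seq); site_seq <- as_dna(site_seq)
  mch <- .chars(mirna_seq); sch <- .chars(site_seq)
  dG <- params$duplex_init
  if (nrow(columns) == 0) return(dG)
  # paired columns: both positions present and a legal pair
  pt <- rep(NA_integer_, nrow(columns))
  for (k in seq_len(nrow(columns))) {
    mp <- columns$mirna_pos[k]; sp <- columns$site_pos[k]
    if (!is.na(mp) && !is.na(sp))
      pt[k] <- .pair_type(sch[sp], mch[mp])
  }
  paired <- which(!is.na(pt))
  if (length(paired) == 0) return(dG)
  for (w in seq_len(length(paired) - 1)) {
    k1 <- paired[w]; k2 <- paired[w + 1]
    contiguous <- columns$site_pos[k2] == columns$site_pos[k1] + 1 &&
      columns$mirna_pos[k2] == columns$mirna_pos[k1] - 1
    if (contiguous) {
      dG <- dG + params$stacks[pt[k1], pt[k2]]
    } else {
      u <- (columns$site_pos[k2] - columns$site_pos[k1] - 1) +
        (columns$mirna_pos[k1] - columns$mirna_pos[k2] - 1)
      dG <- dG + params$loop_a + params$loop_b * u
    }
  }
  for (endk in c(paired[1], paired[length(paired)])) {
    if (pt[endk] %in% 3:6) dG <- dG + params$end_penalty  # GU/UG/AU/UA end
  }
  dG
}

#' Acceptance rule for alignment-scanner sites
#'
#' Bit-exact thresholds: the score must satisfy `S >= S_min` (inclusive) and
#' the duplex energy `dG < dG_max` (strict).
#'
#' @param S alignment score.
#' @param dG duplex free energy, kcal/mol.
#' @param S_min,dG_max thresholds (defaults 140 and -17).
#' @return logical.
#' @export
miranda_pass <- function(S, dG, S_min = 140, dG_max = -17) {
  S >= S_min & dG < dG_max
}

#' Scan a region with the alignment-score/duplex-energy rule
#'
#' Slides overlapping windows across the region, keeps the best local
#' alignment per window, scores duplex energies and retains non-overlapping
#' sites passing [miranda_pass()] (greedy by descending S).
#'
#' @param mirna named list or one-row data.frame with `name` and `sequence`,
#'   or a single named character element.
#' @param region_seq region sequence.
#' @param S_min,dG_max acceptance thresholds.
#' @param scoring,params scoring and energy model parameters.
#' @param window_slack extra window length beyond the miRNA length.
#' @param step window step.
#' @return data.frame of sites: `mirna`, `site_start`, `site_end`, `S`,
#'   `dG`.
#' @export
miranda_scan <- function(mirna, region_seq, S_min = 140, dG_max = -17,
                         scoring = duplex_scoring(),
                         params = energy_params(),
                         window_slack = 10, step = 5) {
  nm <- if (!is.null(mirna$name)) mirna$name else names(mirna)
  ms <- as_dna(if (!is.null(mirna$sequence)) mirna$sequence else mirna[[1]])
  L <- nchar(region_seq)
  wlen <- nchar(ms) + window_slack
  starts <- unique(pmin(seq(1, max(1, L), by = step), max(1, L - wlen + 1)))
  cand <- list()
  for (ws in starts) {
    win <- substr(region_seq, ws, min(L, ws + wlen - 1))
    if (nchar(win) < nchar(ms) - 5) next
    al <- align_duplex(ms, win, scoring)
    if (al$S < S_min || is.na(al$site_start)) next
    dG <- duplex_energy(ms, win, al$columns, params)
    if (!miranda_pass(al$S, dG, S_min, dG_max)) next
    key <- paste(ws + al$site_start - 1, ws + al$site_end - 1)
    if (!is.null(cand[[key]]) && cand[[key]]$S >= al$S) next
    cand[[key]] <- list(start = ws + al$site_start - 1,
                        end = ws + al$site_end - 1, S = al$S, dG = dG)
  }
  if (length(cand) == 0) {
    return(data.frame(mirna = character(0), site_start = integer(0),
                      site_end = integer(0), S = numeric(0),
                      dG = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(cand, as.data.frame))
  df <- df[order(-df$S, df$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df))
  occupied <- integer(0)
  for (i in seq_len(nrow(df))) {
    span <- df$start[i]:df$end[i]
    if (!any(span %in% occupied)) { keep[i] <- TRUE; occupied <- c(occupied, span) }
  }
  df <- df[keep, , drop = FALSE]
  out <- data.frame(mirna = nm, site_start = as.integer(df$start),
                    site_end = as.integer(df$end),
                    S = df$S, dG = df$dG, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$site_start), , drop = FALSE]
}

#' Opening energy of a target site in its mRNA context
#'
#' dG_open is the free-energy cost of making the site single-stranded:
#' the optimal fold energy of the local context with the site constrained
#' unpaired, minus the unconstrained optimal fold energy. Non-negative by
#' construction.
#'
#' @param region_seq region sequence.
#' @param site_start,site_end 1-based inclusive site interval.
#' @param context_flank context taken on each side of the site (default
#'   70 nt), truncated at region ends.
#' @param params energy model.
#' @return dG_open in kcal/mol (>= 0).
#' @export
open_energy <- function(region_seq, site_start, site_end,
                        context_flank = 70, params = energy_params()) {
  L <- nchar(region_seq)
  stopifnot(site_start >= 1, site_end <= L, site_start <= site_end)
  cs <- max(1, site_start - context_flank)
  ce <- min(L, site_end + context_flank)
  ctx <- substr(region_seq, cs, ce)
  site_local <- (site_start - cs + 1):(site_end - cs + 1)
  e_free <- fold_rna(ctx, params = params)$energy
  e_open <- fold_rna(ctx, unpaired = site_local, params = params)$energy
  max(0, e_open - e_free)
}

#' Scan a region with the accessibility (seed + ddG) rule
#'
#' Finds seed matches of length 8, 7 or 6 starting at miRNA position 2
#' (perfect Watson-Crick; a single G:U wobble is tolerated in 8-mers only),
#' then scores each site as ddG = dG_duplex + dG_open over the full-miRNA
#' pairing window. All sites are reported unless `ddG_max` is set;
#' overlapping sites are resolved greedily by ascending ddG.
#'
#' @param mirna named list/one-row data.frame with `name`, `sequence`.
#' @param region_seq region sequence.
#' @param ddG_max optional cutoff; sites with ddG above it are dropped.
#' @param context_flank accessibility context, see [open_energy()].
#' @param scoring,params scoring and energy parameters.
#' @return data.frame: `mirna`, `seed_start`, `seed_len`, `site_start`,
#'   `site_end`, `dG_duplex`, `dG_open`, `ddG`.
#' @export
pita_scan <- function(mirna, region_seq, ddG_max = NULL, context_flank = 70,
                      scoring = duplex_scoring(), params = energy_params()) {
  nm <- if (!is.null(mirna$name)) mirna$name else names(mirna)
  ms <- as_dna(if (!is.null(mirna$sequence)) mirna$sequence else mirna[[1]])
  mch <- .chars(ms)
  m <- length(mch)
  rch <- .chars(as_dna(region_seq))
  L <- length(rch)
  empty <- data.frame(mirna = character(0), seed_start = integer(0),
                      seed_len = integer(0), site_start = integer(0),
                      site_end = integer(0), dG_duplex = numeric(0),
                      dG_open = numeric(0), ddG = numeric(0),
                      stringsAsFactors = FALSE)
  hits <- list()
  for (p in seq_len(L)) {
    found <- 0L
    for (len in c(8L, 7L, 6L)) {
      if (p + len - 1L > L) next
      gu <- 0L; ok <- TRUE
      for (k in seq_len(len)) {
        # miRNA position k+1 pairs site position p + len - k
        pt <- .pair_type(rch[p + len - k], mch[k + 1])
        if (is.na(pt)) { ok <- FALSE; break }
        if (pt %in% c(3L, 4L)) gu <- gu + 1L  # GU/UG wobble
      }
      if (!ok) next
      if (gu > 0L && !(len == 8L && gu <= 1L)) next
      found <- len
      break
    }
    if (found == 0L) next
    # full-miRNA pairing window: miRNA 5' end sits at the site 3' end
    w_end <- min(L, p + found)
    w_start <- max(1L, p + found + 1L - m - 3L)
    win <- substr(region_seq, w_start, w_end)
    al <- align_duplex(ms, win, scoring)
    dG_dup <- duplex_energy(ms, win, al$columns, params)
    dG_op <- open_energy(region_seq, w_start, w_end,
                         context_flank = context_flank, params = params)
    hits[[length(hits) + 1L]] <- data.frame(
      mirna = nm, seed_start = p, seed_len = found,
      site_start = w_start, site_end = w_end,
      dG_duplex = dG_dup, dG_open = dG_op, ddG = dG_dup + dG_op,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(empty)
  df <- do.call(rbind, hits)
  if (!is.null(ddG_max)) df <- df[df$ddG <= ddG_max, , drop = FALSE]
  if (nrow(df) == 0) return(empty)
  df <- df[order(df$ddG, df$site_start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df))
  occupied <- integer(0)
  for (i in seq_len(nrow(df))) {
    span <- df$site_start[i]:df$site_end[i]
    if (!any(span %in% occupied)) { keep[i] <- TRUE; occupied <- c(occupied, span) }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$site_start), , drop = FALSE]
}

#' Scan all gene-model regions with both scanners
#'
#' @param mirnas data.frame with `name`, `sequence` (one row per miRNA).
#' @param regions named list of region sequence vectors, as produced by
#'   [region_sequences()] (`5UTR`, `CDS`, `3UTR`, each named by transcript).
#' @param S_min,dG_max alignment-scanner thresholds.
#' @param ddG_max optional accessibility cutoff.
#' @param ... passed to the scanners (`scoring`, `params`).
#' @return list of two data.frames, `miranda` and `pita`, each with `gene`
#'   and `region` columns prepended to the scanner output.
#' @export
scan_targets <- function(mirnas, regions, S_min = 140, dG_max = -17,
                         ddG_max = NULL, ...) {
  mir_rows <- split(mirnas, seq_len(nrow(mirnas)))
  mr <- list(); pt <- list()
  for (rt in c("3UTR", "CDS", "5UTR")) {
    seqs <- regions[[rt]]
    for (gene in names(seqs)) {
      for (mir in mir_rows) {
        h1 <- miranda_scan(mir, seqs[[gene]], S_min = S_min,
                           dG_max = dG_max, ...)
        if (nrow(h1) > 0)
          mr[[length(mr) + 1L]] <- cbind(gene = gene, region = rt, h1,
                                         stringsAsFactors = FALSE)
        h2 <- pita_scan(mir, seqs[[gene]], ddG_max = ddG_max, ...)
        if (nrow(h2) > 0)
          pt[[length(pt) + 1L]] <- cbind(gene = gene, region = rt, h2,
                                         stringsAsFactors = FALSE)
      }
    }
  }
  empty_m <- data.frame(gene = character(0), region = character(0),
                        mirna = character(0), stringsAsFactors = FALSE)
  list(miranda = if (length(mr)) `rownames<-`(do.call(rbind, mr), NULL)
       else empty_m,
       pita = if (length(pt)) `rownames<-`(do.call(rbind, pt), NULL)
       else empty_m)
}

#' Consensus targets: genes predicted by both scanners
#'
#' A gene x miRNA pair is a consensus target when both scanners report at
#' least one site for it in the gene (any region). Regions are reported with
#' 3'UTR priority, then CDS, then 5'UTR.
#'
#' @param miranda_hits,pita_hits data.frames from [scan_targets()].
#' @return data.frame with `gene`, `mirna`, `regions` (comma-joined, in
#'   priority order), `n_miranda_sites`, `n_pita_sites`.
#' @export
intersect_targets <- function(miranda_hits, pita_hits) {
  key <- function(df) paste(df$gene, df$mirna, sep = "\r")
  common <- intersect(unique(key(miranda_hits)), unique(key(pita_hits)))
  if (length(common) == 0) {
    return(data.frame(gene = character(0), mirna = character(0),
                      regions = character(0), n_miranda_sites = integer(0),
                      n_pita_sites = integer(0), stringsAsFactors = FALSE))
  }
  prio <- c("3UTR" = 1, "CDS" = 2, "5UTR" = 3)
  rows <- lapply(sort(common), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    mh <- miranda_hits[key(miranda_hits) == k, , drop = FALSE]
    ph <- pita_hits[key(pita_hits) == k, , drop = FALSE]
    regs <- union(mh$region, ph$region)
    regs <- regs[order(prio[regs])]
    data.frame(gene = parts[1], mirna = parts[2],
               regions = paste(regs, collapse = ","),
               n_miranda_sites = nrow(mh), n_pita_sites = nrow(ph),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify targeting modes per gene
#'
#' Labels each consensus gene with every mode it exhibits:
#' `single-3UTR` (exactly one miRNA with 3'UTR sites and no other mode),
#' `multi-miRNA-3UTR` (two or more distinct miRNAs with 3'UTR sites) and
#' `3UTR-plus-CDS` (the same miRNA hits both the 3'UTR and the CDS).
#'
#' @param consensus data.frame from [intersect_targets()].
#' @return data.frame with `gene` and `mode` (one row per gene-mode pair).
#' @export
classify_mode <- function(consensus) {
  out <- list()
  for (g in unique(consensus$gene)) {
    sub <- consensus[consensus$gene == g, , drop = FALSE]
    reglist <- strsplit(sub$regions, ",", fixed = TRUE)
    has3 <- vapply(reglist, function(r) "3UTR" %in% r, logical(1))
    modes <- character(0)
    if (sum(has3) >= 2) modes <- c(modes, "multi-miRNA-3UTR")
    both <- vapply(reglist, function(r) all(c("3UTR", "CDS") %in% r),
                   logical(1))
    if (any(both)) modes <- c(modes, "3UTR-plus-CDS")
    if (sum(has3) == 1 && length(modes) == 0)
      modes <- "single-3UTR"
    for (m in modes)
      out[[length(out) + 1L]] <- data.frame(gene = g, mode = m,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), mode = character(0),
                      stringsAsFactors = FALSE))
  }
  `rownames<-`(do.call(rbind, out), NULL)
}
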
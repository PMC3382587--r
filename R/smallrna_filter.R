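# Read cleaning and collapsing: the "impurity" screen. Raw reads are adapter
# trimmed, junk/low-quality records removed, survivors collapsed to unique
# tags with copy numbers and filtered on length, copy number and an optional
# exclusion database. Every input read is accounted for in exactly one
# FilterReport category or as a survivor.

#' Trim ligation adapters from a small-RNA read
#'
#' The 3' adapter is located as the longest read suffix matching a prefix of
#' `adapter3` (minimum overlap `min_overlap`, at most `max_mismatch`
#' substitutions; the leftmost acceptable start wins). An optional 5' adapter
#' is trimmed the same way, anchored at the read prefix. Reads carrying no
#' adapter are returned unchanged (insert-only dialect) unless
#' `require_adapter` is set.
#'
#' @param sequence read sequence (A/C/G/T/N).
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 optional 5' adapter sequence.
#' @param min_overlap minimum adapter overlap to trigger trimming.
#' @param max_mismatch substitutions tolerated in the overlap.
#' @param require_adapter if TRUE, reads without a 3' adapter hit return NA.
#' @return the trimmed insert; `""` signals an adapter dimer.
#' @export
trim_adapter <- function(sequence, adapter3, adapter5 = NULL,
                         min_overlap = 6, max_mismatch = 1,
                         require_adapter = FALSE) {
  stopifnot(nchar(adapter3) > 0)
  if (!.is_dna(sequence))
    stop("trim_adapter: non-ACGTN characters in read: ", sequence)
  rd <- .chars(sequence)
  n <- length(rd)
  if (!is.null(adapter5) && nzchar(adapter5)) {
    a5 <- .chars(adapter5)
    # longest read prefix matching an adapter5 suffix
    best <- 0L
    ov_max <- min(n, length(a5))
    if (ov_max >= min_overlap) {
      for (ov in seq(ov_max, min_overlap)) {
        mm <- sum(rd[seq_len(ov)] != a5[seq(length(a5) - ov + 1, length(a5))])
        if (mm <= max_mismatch) { best <- ov; break }
      }
    }
    if (best > 0L) { rd <- rd[-seq_len(best)]; n <- length(rd) }
    if (n == 0L) return("")
  }
  a3 <- .chars(adapter3)
  hit <- NA_integer_
  for (i in seq_len(n)) {
    ov <- min(n - i + 1L, length(a3))
    if (ov < min_overlap) break
    mm <- sum(rd[seq(i, i + ov - 1L)] != a3[seq_len(ov)])
    if (mm <= max_mismatch) { hit <- i; break }
  }
  if (is.na(hit)) {
    if (require_adapter) return(NA_character_)
    return(paste(rd, collapse = ""))
  }
  if (hit == 1L) return("")
  paste(rd[seq_len(hit - 1L)], collapse = "")
}

#' Junk-sequence screen
#'
#' A sequence is junk when any single base makes up >= 80\% of its length,
#' it contains >= 3 N characters, or its alphabet is a subset of \{A,C\} or
#' of \{G,T\}. Rules are evaluated in that order and the first hit is
#' reported.
#'
#' @param sequence non-empty nucleotide string.
#' @return list with `junk` (logical) and `reason` (one of
#'   "single_base_80", "n_rich", "only_AC", "only_GT", or NA).
#' @export
is_junk <- function(sequence) {
  stopifnot(nchar(sequence) > 0)
  ch <- .chars(sequence)
  n <- length(ch)
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"), N = sum(ch == "N"))
  if (any(counts[c("A", "C", "G", "T")] / n >= 0.8))
    return(list(junk = TRUE, reason = "single_base_80"))
  if (counts["N"] >= 3)
    return(list(junk = TRUE, reason = "n_rich"))
  present <- names(counts)[counts > 0]
  if (all(present %in% c("A", "C")))
    return(list(junk = TRUE, reason = "only_AC"))
  if (all(present %in% c("G", "T")))
    return(list(junk = TRUE, reason = "only_GT"))
  list(junk = FALSE, reason = NA_character_)
}

#' Collapse trimmed inserts to unique tags
#'
#' @param inserts character vector of adapter-trimmed insert sequences.
#' @return data.frame with `sequence` and `copy_number`, ordered by
#'   decreasing copy number then sequence; the copy numbers sum to
#'   `length(inserts)`.
#' @export
collapse_reads <- function(inserts) {
  if (length(inserts) == 0) {
    return(data.frame(sequence = character(0), copy_number = integer(0),
                      stringsAsFactors = FALSE))
  }
  tb <- table(inserts)
  out <- data.frame(sequence = names(tb),
                    copy_number = as.integer(tb),
                    stringsAsFactors = FALSE)
  out[order(-out$copy_number, out$sequence), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# classify one tag against the tag-level filters; returns category or NA
.tag_category <- function(sequence, copy_number, min_copy, min_len, max_len,
                          exclusion_db) {
  jk <- is_junk(sequence)
  if (jk$junk) return("junk")
  if (grepl("N", sequence, fixed = TRUE)) return("n_content")
  len <- nchar(sequence)
  if (len < min_len || len > max_len) return("length")
  if (!is.null(exclusion_db) && length(exclusion_db) > 0) {
    hit <- any(vapply(exclusion_db, function(db)
      sequence == db || grepl(sequence, db, fixed = TRUE), logical(1)))
    if (hit) return("exclusion_db")
  }
  if (copy_number < min_copy) return("copy_number")
  NA_character_
}

#' Apply the impurity filters to collapsed tags
#'
#' Tags are screened in a fixed order (junk, residual N content, length,
#' exclusion database, copy number), so the copy-number rule is applied only
#' to tags that survive every sequence-level rule. Counts in the report are
#' copy-number weighted (reads), and reconcile exactly with the input.
#'
#' @param tags data.frame with `sequence` and `copy_number` (from
#'   [collapse_reads()]).
#' @param min_copy minimum copy number (default 3: tags seen fewer than 3
#'   times are discarded).
#' @param min_len,max_len retained length range, default 15-26 nt.
#' @param exclusion_db optional character vector of sequences (e.g. mRNA,
#'   RFam, Repbase entries); tags equal to, or contained in, any entry are
#'   removed.
#' @return list with `tags` (survivors) and `report` (named integer vector
#'   of read counts per category plus `surviving_reads`, `surviving_tags`,
#'   `input_reads`).
#' @export
apply_filters <- function(tags, min_copy = 3, min_len = 15, max_len = 26,
                          exclusion_db = NULL) {
  if (min_len > max_len) stop("apply_filters: min_len > max_len")
  tags$copy_number <- as.integer(tags$copy_number)
  cats <- c("junk", "n_content", "length", "exclusion_db", "copy_number")
  counts <- setNames(integer(length(cats)), cats)
  keep <- logical(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    cat_i <- .tag_category(tags$sequence[i], tags$copy_number[i],
                           min_copy, min_len, max_len, exclusion_db)
    if (is.na(cat_i)) keep[i] <- TRUE
    else counts[cat_i] <- counts[cat_i] + tags$copy_number[i]
  }
  survivors <- tags[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  report <- c(counts,
              surviving_reads = sum(survivors$copy_number),
              surviving_tags = nrow(survivors),
              input_reads = sum(tags$copy_number))
  list(tags = survivors, report = report)
}

#' Full read-level impurity screen
#'
#' Drives the complete cleaning stage on raw reads: character validation,
#' optional low-resolution (quality) screen, adapter trimming, collapsing,
#' and the tag-level filters of [apply_filters()]. The returned report
#' accounts for every input read exactly once.
#'
#' @param reads data.frame with `sequence` and optional `quality`
#'   (Phred+33), as returned by [read_reads()]; a bare character vector is
#'   also accepted.
#' @param adapter3 3' adapter sequence.
#' @param adapter5 optional 5' adapter.
#' @param min_quality mean Phred quality below which a read is discarded as
#'   low-resolution (only when qualities are present); set NA to disable.
#' @param ... passed to [apply_filters()] (`min_copy`, `min_len`, `max_len`,
#'   `exclusion_db`).
#' @param min_overlap,max_mismatch adapter matching tolerance.
#' @return list with `tags` (surviving unique tags), `report` (read counts:
#'   `invalid`, `low_resolution`, `adapter_dimer`, the [apply_filters()]
#'   categories, survivors and totals).
#' @export
filter_reads <- function(reads, adapter3, adapter5 = NULL, min_quality = 20,
                         min_overlap = 6, max_mismatch = 1, ...) {
  if (is.character(reads))
    reads <- data.frame(sequence = reads, quality = NA_character_,
                        stringsAsFactors = FALSE)
  n_in <- nrow(reads)
  valid <- !grepl("[^ACGTN]", reads$sequence)
  n_invalid <- sum(!valid)
  reads <- reads[valid, , drop = FALSE]

  n_lowres <- 0L
  if (!is.na(min_quality) && "quality" %in% names(reads) &&
      any(!is.na(reads$quality))) {
    mq <- vapply(reads$quality, function(q) {
      if (is.na(q)) return(Inf)
      mean(as.integer(charToRaw(q)) - 33L)
    }, numeric(1), USE.NAMES = FALSE)
    low <- mq < min_quality
    n_lowres <- sum(low)
    reads <- reads[!low, , drop = FALSE]
  }

  inserts <- vapply(reads$sequence, trim_adapter, character(1),
                    adapter3 = adapter3, adapter5 = adapter5,
                    min_overlap = min_overlap, max_mismatch = max_mismatch,
                    USE.NAMES = FALSE)
  dimer <- !nzchar(inserts)
  n_dimer <- sum(dimer)
  tags <- collapse_reads(inserts[!dimer])
  flt <- apply_filters(tags, ...)
  report <- c(input_reads = n_in, invalid = n_invalid,
              low_resolution = n_lowres, adapter_dimer = n_dimer,
              flt$report[c("junk", "n_content", "length", "exclusion_db",
                           "copy_number", "surviving_reads",
                           "surviving_tags")])
  list(tags = flt$tags, report = report)
}

#' Copy-number weighted length histogram of tags
#'
#' @param tags data.frame with `sequence`, `copy_number`.
#' @return data.frame with `length`, `reads` and `fraction` (fractions sum
#'   to 1); zero rows for empty input.
#' @export
length_histogram <- function(tags) {
  if (nrow(tags) == 0) {
    return(data.frame(length = integer(0), reads = integer(0),
                      fraction = numeric(0)))
  }
  len <- nchar(tags$sequence)
  agg <- tapply(tags$copy_number, len, sum)
  out <- data.frame(length = as.integer(names(agg)),
                    reads = as.integer(agg))
  out$fraction <- out$reads / sum(out$reads)
  out[order(out$length), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Write collapsed tags as FASTA
#'
#' Headers use the common collapsed-FASTA dialect `tag{serial}_x{copies}`.
#'
#' @param tags data.frame with `sequence`, `copy_number`.
#' @param path output FASTA path.
#' @export
write_tag_fasta <- function(tags, path) {
  seqs <- tags$sequence
  names(seqs) <- sprintf("tag%d_x%d", seq_along(seqs), tags$copy_number)
  write_fasta(seqs, path)
}

#' Read a collapsed-tag FASTA written by [write_tag_fasta()]
#'
#' @param path FASTA path with `_x{copies}` headers.
#' @return tags data.frame.
#' @export
read_tag_fasta <- function(path) {
  seqs <- read_fasta(path)
  copies <- as.integer(sub("^.*_x(\\d+)$", "\\1", names(seqs)))
  data.frame(sequence = unname(seqs), copy_number = copies,
             stringsAsFactors = FALSE)
}

#' Write a filter report as TSV and/or JSON
#'
#' @param report named vector from [filter_reads()] or [apply_filters()].
#' @param tsv,json optional output paths.
#' @export
write_filter_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    df <- data.frame(category = names(report), reads = as.integer(report))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(as.list(report), json, auto_unbox = TRUE)
  }
  invisible(report)
}
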
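# Assignment of filtered tags to known mature miRNAs. The match rule is
# deterministic: ungapped alignment with terminal offsets of up to 3 nt and
# at most one substitution in the overlap. Tag bases overhanging the mature
# ends (isomiR length variants) are soft-clipped within the offset allowance
# and not counted as mismatches.

#' Derive a miRNA family name from a mature miRNA name
#'
#' Strips the species prefix (e.g. "omy-", "dre-"), the arm suffix
#' ("-5p"/"-3p"), a trailing duplicate-locus number ("miR-133-1") and
#' trailing paralog letters ("let-7a" -> "let-7"), pooling paralogs and arms
#' into one family as abundance figures conventionally do.
#'
#' @param name character vector of mature miRNA names.
#' @param mapping optional named character vector of explicit overrides
#'   (names = mature names, values = family names).
#' @return character vector of family names.
#' @export
mirna_family <- function(name, mapping = NULL) {
  fam <- name
  if (!is.null(mapping)) {
    hit <- fam %in% names(mapping)
    fam[hit] <- mapping[fam[hit]]
    if (all(hit)) return(fam)
    idx <- !hit
  } else idx <- rep(TRUE, length(fam))
  x <- fam[idx]
  x <- sub("^[A-Za-z]{3,4}-(?=(miR|mir|let|lin|ban))", "", x,
           perl = TRUE)  # species code
  x <- sub("-(5p|3p)$", "", x)             # arm
  x <- sub("^(.*\\d[a-z]*)-\\d+$", "\\1", x)  # duplicate locus suffix
  x <- sub("(?<=\\d)[a-z]+$", "", x, perl = TRUE)  # paralog letters
  fam[idx] <- x
  fam
}

#' Read a mature miRNA FASTA (miRBase dialect)
#'
#' @param path FASTA file; U is normalized to T.
#' @return data.frame with `name`, `family`, `sequence`.
#' @export
read_mature_fasta <- function(path) {
  seqs <- read_fasta(path)
  data.frame(name = names(seqs), family = mirna_family(names(seqs)),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Match unique tags against known mature miRNAs
#'
#' Each tag is aligned ungapped to every mature at terminal offsets of up to
#' `max_offset` nt on either end; the best assignment minimizes (mismatches,
#' |offset|, mature name). Tags with no alignment at `max_mismatch` or fewer
#' substitutions are returned as unmatched and feed the novel-miRNA stage.
#'
#' @param tags data.frame with `sequence` and `copy_number`.
#' @param db data.frame with `name`, `sequence` (and optionally `family`),
#'   e.g. from [read_mature_fasta()]; sequences must be DNA (U -> T).
#' @param max_mismatch maximum substitutions in the overlap (default 1,
#'   i.e. fewer than 2 mismatching bases).
#' @param max_offset maximum terminal offset / overhang per end.
#' @return list with `assignments` (tag, copies, mature, family, mismatches,
#'   offset) and `unmatched` (subset of `tags`). Every tag appears in
#'   exactly one of the two.
#' @export
match_known <- function(tags, db, max_mismatch = 1, max_offset = 3) {
  if (nrow(db) == 0) {
    warning("match_known: empty mature miRNA database; all tags unmatched")
    return(list(assignments = data.frame(), unmatched = tags))
  }
  if (is.null(db$family)) db$family <- mirna_family(db$name)
  db <- db[order(db$name), , drop = FALSE]
  m <- .match_tags(tags$sequence, db$sequence,
                   as.integer(max_mismatch), as.integer(max_offset))
  hit <- !is.na(m$index)
  assignments <- data.frame(
    tag = tags$sequence[hit],
    copies = tags$copy_number[hit],
    mature = db$name[m$index[hit]],
    family = db$family[m$index[hit]],
    mismatches = m$mismatches[hit],
    offset = m$offset[hit],
    stringsAsFactors = FALSE)
  list(assignments = assignments,
       unmatched = `rownames<-`(tags[!hit, , drop = FALSE], NULL))
}

#' Family-level abundance profile of known-miRNA assignments
#'
#' Pools copy-number weighted read counts by family and ranks families by
#' abundance; the attribute `top_cumulative` carries the cumulative fraction
#' of the `top_k` most abundant families.
#'
#' @param assignments data.frame from [match_known()].
#' @param top_k how many leading families the cumulative fraction covers.
#' @return data.frame with `family`, `read_count`, `fraction` (summing to
#'   1), ranked by decreasing read count.
#' @export
summarize_families <- function(assignments, top_k = 10) {
  if (nrow(assignments) == 0) {
    out <- data.frame(family = character(0), read_count = integer(0),
                      fraction = numeric(0))
    attr(out, "top_cumulative") <- NA_real_
    return(out)
  }
  agg <- tapply(assignments$copies, assignments$family, sum)
  out <- data.frame(family = names(agg), read_count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out$fraction <- out$read_count / sum(out$read_count)
  attr(out, "top_cumulative") <-
    sum(out$fraction[seq_len(min(top_k, nrow(out)))])
  out
}
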
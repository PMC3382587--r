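# Shared low-level helpers. Sequences are handled as plain uppercase DNA
# character strings throughout (U is normalized to T on input); folding and
# hybridization treat T as U.

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Normalize RNA/DNA input to uppercase DNA
#'
#' @param x character vector; U is converted to T.
#' @return uppercase DNA character vector.
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# split a string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.is_dna <- function(x) !grepl("[^ACGTN]", x)

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; U is normalized to T
#' and names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as_dna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read small-RNA reads from FASTQ or FASTA
#'
#' @param path reads file; format is inferred from the extension
#'   (`.fastq`/`.fq` vs anything else).
#' @return data.frame with `read_id`, `sequence` and (FASTQ only) `quality`
#'   columns.
#' @export
read_reads <- function(path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  if (fastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(read_id = names(x),
               sequence = toupper(as.character(x)),
               quality = as.character(S4Vectors::mcols(x)$qualities),
               stringsAsFactors = FALSE)
  } else {
    x <- Biostrings::readBStringSet(path)
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               sequence = as_dna(as.character(x)),
               quality = NA_character_,
               stringsAsFactors = FALSE)
  }
}

# geometric mean
.geomean <- function(x) exp(mean(log(x)))

# Shannon entropy (bits) of a character vector
.entropy <- function(chars) {
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# deterministic seed derivation for sub-generators; stays < 2^31
.subseed <- function(seed, k) (as.integer(seed) + 1000L * k) %% 2147483647L
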
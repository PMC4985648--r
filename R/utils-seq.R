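# Low-level nucleotide utilities shared across the package.

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

check_alphabet <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("sequence must be a single non-empty character string")
  if (!grepl("^[ACGTN]+$", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  invisible(seq)
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar over A,C,G,T,N.
#' @return character scalar.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Split a nucleotide string into codons
#' @param seq character scalar; trailing bases beyond the last full codon are dropped.
#' @return character vector of codons.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character())
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Codons containing N (or any non-ACGT base) translate to X; X never matches stop.
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

translate_nt <- function(seq) {
  paste(translate_codons(split_codons(seq)), collapse = "")
}

is_stop_codon <- function(codons) codons %in% STOP_CODONS

# Left-normalize (5'-shift) an indel to its 5'-most equivalent placement on the
# reference, the same convention used for variant normalization. `ref` is a
# character vector of single bases. Deletions: start = first deleted ref
# position. Insertions: pos = the ref position the insertion precedes, seq =
# inserted bases.
normalize_deletion <- function(ref, start, len) {
  while (start > 1L && ref[start - 1L] == ref[start + len - 1L]) start <- start - 1L
  start
}

normalize_insertion <- function(ref, pos, ins) {
  ins <- strsplit(ins, "")[[1]]
  L <- length(ins)
  while (pos > 1L && ref[pos - 1L] == ins[L]) {
    ins <- c(ref[pos - 1L], ins[-L])
    pos <- pos - 1L
  }
  list(pos = pos, seq = paste(ins, collapse = ""))
}
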
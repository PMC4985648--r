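# Intact-ortholog reference profiles used by the intact filter and the
# pseudogene caller.

#' Construct an intact-OR reference profile
#'
#' @param locus locus identifier.
#' @param cds intact coding sequence: starts with ATG, ends with a stop codon,
#'   length divisible by 3, no internal stop codons.
#' @param tm_intervals data.frame with columns `start`, `end`: 1-based
#'   inclusive codon intervals of the seven transmembrane helices on the
#'   reference protein; defaults to canonical OR helix positions scaled to the
#'   protein length.
#' @param species source species of the reference sequence.
#' @return object of class `or_reference`.
#' @export
reference_profile <- function(locus, cds, tm_intervals = NULL, species = NA_character_) {
  cds <- toupper(cds)
  check_alphabet(cds)
  if (nchar(cds) %% 3L != 0L) stop("reference CDS length not divisible by 3")
  cods <- split_codons(cds)
  if (cods[1] != "ATG") stop("reference CDS must start with ATG")
  aa <- translate_codons(cods)
  if (aa[length(aa)] != "*") stop("reference CDS must end with a stop codon")
  if (any(aa[-length(aa)] == "*")) stop("reference CDS has internal stop codons")
  protein <- paste(aa[-length(aa)], collapse = "")
  n_aa <- length(aa) - 1L
  if (is.null(tm_intervals)) tm_intervals <- default_tm_intervals(n_aa)
  tm_intervals <- as.data.frame(tm_intervals)
  stopifnot(all(c("start", "end") %in% names(tm_intervals)))
  tm_intervals <- tm_intervals[order(tm_intervals$start), , drop = FALSE]
  if (any(tm_intervals$end < tm_intervals$start) ||
      any(tm_intervals$start < 1) || any(tm_intervals$end > n_aa))
    stop("tm_intervals out of range")
  if (nrow(tm_intervals) > 1 &&
      any(tm_intervals$start[-1] <= tm_intervals$end[-nrow(tm_intervals)]))
    stop("tm_intervals overlap")
  structure(list(locus = locus, cds = cds, protein = protein,
                 n_codons = length(cods), tm_intervals = tm_intervals,
                 species = species),
            class = "or_reference")
}

#' Canonical transmembrane helix intervals for an OR protein
#'
#' Seven-helix positions typical of a ~310-codon olfactory receptor, rescaled
#' linearly to the supplied protein length.
#'
#' @param n_aa protein length in amino acids (stop excluded).
#' @return data.frame with columns `tm_index`, `start`, `end` (1-based codons).
#' @export
default_tm_intervals <- function(n_aa = 309L) {
  base <- data.frame(
    tm_index = 1:7,
    start = c(26L, 58L, 93L, 136L, 196L, 236L, 269L),
    end   = c(49L, 80L, 115L, 158L, 219L, 258L, 291L))
  sc <- n_aa / 309
  out <- data.frame(tm_index = base$tm_index,
                    start = pmax(1L, as.integer(round(base$start * sc))),
                    end = pmin(n_aa, as.integer(round(base$end * sc))))
  out
}

#' Read transmembrane intervals from a TSV file
#'
#' File format: columns `locus`, `tm_index`, `start_codon`, `end_codon`.
#'
#' @param path file path.
#' @return named list (by locus) of data.frames with columns `start`, `end`.
#' @export
read_tm_intervals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "start_codon", "end_codon") %in% names(df)))
  split(data.frame(start = df$start_codon, end = df$end_codon),
        df$locus)
}
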
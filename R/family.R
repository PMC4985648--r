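# OR gene family and Class (I vs II) assignment by best alignment against a
# user-supplied exemplar panel. A simplified stand-in for profile-HMM
# scanning: the best-scoring global protein alignment decides the family.

#' Class of an OR gene family
#'
#' Families 51-56 form Class I (receptors assumed to detect water-borne
#' molecules); families 1-14 form Class II (air-borne compounds).
#'
#' @param family integer family id(s).
#' @return character vector of "I", "II", or NA.
#' @export
or_class <- function(family) {
  ifelse(family %in% 51:56, "I", ifelse(family %in% 1:14, "II", NA_character_))
}

#' Read a family exemplar panel from a protein FASTA
#'
#' Headers must carry a `family:<n>` tag.
#'
#' @param path FASTA file of exemplar protein sequences.
#' @return data.frame with columns `id`, `family`, `class`, `protein`.
#' @export
read_family_panel <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- names(x)
  fam <- regmatches(ids, regexpr("family:[0-9]+", ids))
  if (length(fam) != length(ids)) stop("every panel header needs a family:<n> tag")
  fam <- as.integer(sub("family:", "", fam))
  data.frame(id = sub("\\s.*$", "", ids), family = fam, class = or_class(fam),
             protein = as.character(x), stringsAsFactors = FALSE)
}

#' Assign an OR protein to a gene family and Class
#'
#' Globally aligns the query against every exemplar (BLOSUM62, gap open 10,
#' extend 1) and returns the family of the highest-scoring exemplar; ties are
#' broken by the lowest family id.
#'
#' @param query_protein amino-acid string.
#' @param panel data.frame as returned by [read_family_panel()] (columns
#'   `family`, `protein`).
#' @return list with `family`, `class`, `score`.
#' @export
assign_family <- function(query_protein, panel) {
  if (!is.character(query_protein) || !nzchar(query_protein))
    stop("empty query protein")
  if (!is.data.frame(panel) || nrow(panel) == 0L) stop("empty exemplar panel")
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(panel$protein),
    Biostrings::AAString(query_protein),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  best <- which(scores == max(scores))
  fam <- min(panel$family[best])
  list(family = fam, class = or_class(fam), score = max(scores))
}
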
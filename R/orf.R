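# Identification of full-length intact OR genes: six-frame ORF scan followed
# by length and transmembrane-gap filters against an intact reference.

#' Find all maximal ATG-to-stop open reading frames in six frames
#'
#' Scans the three forward frames of the input and the three frames of its
#' reverse complement. Every ATG that is followed by an in-frame stop codon
#' yields one ORF running to the first such stop. Codons containing N
#' translate to X and never match ATG or a stop.
#'
#' @param seq character scalar over A,C,G,T,N (or a one-row data.frame with a
#'   `seq` column).
#' @return data.frame with columns `frame` (0-2 forward, 3-5 on the reverse
#'   complement), `start`, `end` (0-based half-open nucleotide coordinates in
#'   the orientation of the scanned strand; `end` includes the stop codon),
#'   `aa_length`, `translation`; sorted by decreasing `aa_length`, ties by
#'   frame then start.
#' @export
find_orfs <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  seq <- toupper(seq)
  check_alphabet(seq)
  if (nchar(seq) < 6L) stop("sequence shorter than 6 nt")
  strands <- c(seq, revcomp(seq))
  frame <- start <- end <- aa_length <- integer(0)
  translation <- character(0)
  for (s in 0:1) {
    str <- strands[s + 1L]
    for (f in 0:2) {
      ncod <- (nchar(str) - f) %/% 3L
      if (ncod < 2L) next
      pos <- f + 3L * seq_len(ncod)
      cods <- substring(str, pos - 2L, pos)
      stops <- which(is_stop_codon(cods))
      if (!length(stops)) next
      for (a in which(cods == "ATG")) {
        st <- stops[stops > a]
        if (!length(st)) next
        st <- st[1L]
        frame <- c(frame, 3L * s + f)
        start <- c(start, f + 3L * (a - 1L))
        end <- c(end, f + 3L * st)
        aa_length <- c(aa_length, st - a)
        translation <- c(translation,
                         paste(translate_codons(cods[a:(st - 1L)]), collapse = ""))
      }
    }
  }
  res <- data.frame(frame = frame, start = start, end = end,
                    aa_length = aa_length, translation = translation,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$aa_length, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter criteria for intact OR classification
#'
#' @param min_aa_exclusive ORFs must be strictly longer than this many amino
#'   acids (default 250).
#' @param max_tm_gap_aa largest tolerated deletion gap, in amino acids, that
#'   overlaps a transmembrane interval (default 4; gaps of 5 or more reject).
#' @return object of class `or_filter_criteria`.
#' @export
filter_criteria <- function(min_aa_exclusive = 250L, max_tm_gap_aa = 4L) {
  stopifnot(min_aa_exclusive >= 0L, max_tm_gap_aa >= 0L)
  structure(list(min_aa_exclusive = as.integer(min_aa_exclusive),
                 max_tm_gap_aa = as.integer(max_tm_gap_aa)),
            class = "or_filter_criteria")
}

#' Decide whether a candidate ORF is a full-length intact OR
#'
#' Rejects an ORF if it is not strictly longer than `min_aa_exclusive` amino
#' acids, or if a global protein alignment to the intact reference shows a
#' deletion gap of more than `max_tm_gap_aa` consecutive amino acids
#' overlapping any transmembrane interval. All failing reasons are reported,
#' not just the first.
#'
#' @param orf one row of [find_orfs()] output (or any list with `aa_length`
#'   and `translation`).
#' @param reference an [reference_profile()].
#' @param criteria an [filter_criteria()].
#' @return list with `verdict` ("intact"/"rejected") and `reasons` (character
#'   vector, empty iff intact).
#' @export
filter_intact <- function(orf, reference, criteria = filter_criteria()) {
  if (is.null(reference)) stop("missing reference profile")
  reasons <- character()
  if (orf$aa_length <= criteria$min_aa_exclusive) reasons <- c(reasons, "too_short")
  qv <- strsplit(orf$translation, "")[[1]]
  rv <- strsplit(reference$protein, "")[[1]]
  if (length(qv) == length(rv) && mean(qv == rv) >= 0.7) {
    # equal length at high identity: the optimal global alignment is gapless,
    # so no deletion gap can overlap a transmembrane interval
    return(list(verdict = if (length(reasons)) "rejected" else "intact",
                reasons = reasons))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(orf$translation),
    Biostrings::AAString(reference$protein),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  rpos <- cumsum(sub != "-")
  r <- rle(pat == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tm <- reference$tm_intervals
  for (k in which(r$values & r$lengths > criteria$max_tm_gap_aa)) {
    # deletion gap on the query side, in reference aa coordinates
    g1 <- rpos[starts[k]]; g2 <- rpos[ends[k]]
    if (any(tm$start <= g2 & tm$end >= g1)) {
      reasons <- c(reasons, "tm_gap")
      break
    }
  }
  list(verdict = if (length(reasons)) "rejected" else "intact", reasons = reasons)
}

#' Classify candidate sequences as intact OR genes
#'
#' For each candidate: scan six frames for ORFs, take the longest, and apply
#' [filter_intact()] against the reference profile of its locus. Sequences
#' with no ORF at all are rejected with reason `no_orf`.
#'
#' @param seqs data.frame with columns `id`, `species`, `locus`, `seq`.
#' @param references a single [reference_profile()] or a named list of
#'   profiles keyed by locus.
#' @param criteria an [filter_criteria()].
#' @param min_identity optional protein-identity prefilter in \[0,1\]: ORFs
#'   whose global alignment identity to the reference falls below it are
#'   rejected with reason `low_identity`. Off (NULL) by default.
#' @return data.frame with columns `id`, `species`, `locus`, `verdict`,
#'   `reasons` (comma-joined), `aa_length`, `frame`.
#' @export
identify_intact <- function(seqs, references, criteria = filter_criteria(),
                            min_identity = NULL) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  get_ref <- function(locus) {
    if (inherits(references, "or_reference")) return(references)
    r <- references[[locus]]
    if (is.null(r)) stop("no reference profile for locus ", locus)
    r
  }
  n <- nrow(seqs)
  verdict <- reasons_v <- character(n)
  aa_len <- frame <- rep(NA_integer_, n)
  has_sp <- "species" %in% names(seqs); has_lo <- "locus" %in% names(seqs)
  for (i in seq_len(n)) {
    orfs <- find_orfs(seqs$seq[i])
    if (nrow(orfs) == 0L) {
      verdict[i] <- "rejected"; reasons_v[i] <- "no_orf"
      next
    }
    orf <- orfs[1L, ]
    ref <- get_ref(if (has_lo) seqs$locus[i] else NA)
    dec <- filter_intact(orf, ref, criteria)
    reasons <- dec$reasons
    if (!is.null(min_identity)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(orf$translation), Biostrings::AAString(ref$protein),
        type = "global", substitutionMatrix = blosum62(),
        gapOpening = 10, gapExtension = 1)
      if (Biostrings::pid(pa, type = "PID1") / 100 < min_identity)
        reasons <- c(reasons, "low_identity")
    }
    verdict[i] <- if (length(reasons)) "rejected" else "intact"
    reasons_v[i] <- paste(reasons, collapse = ",")
    aa_len[i] <- orf$aa_length; frame[i] <- orf$frame
  }
  data.frame(id = seqs$id,
             species = if (has_sp) seqs$species else NA_character_,
             locus = if (has_lo) seqs$locus else NA_character_,
             verdict = verdict, reasons = reasons_v,
             aa_length = aa_len, frame = frame, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
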
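# Codon-aware pseudogene calling: ORF-disrupting mutations (premature stop
# codons, frameshifting indels) in a query relative to an intact ortholog
# reference.

default_nt_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = 8, gap_extend = 2)
}

nt_submat <- function(scoring) {
  key <- paste0("nt_", scoring$match, "_", scoring$mismatch)
  if (is.null(.pkg_cache[[key]]))
    .pkg_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  .pkg_cache[[key]]
}

#' Call ORF-disrupting mutations in a query against an intact reference
#'
#' Computes a global (or semiglobal, for partial gene segments) nucleotide
#' alignment with affine gap penalties, projects it onto reference codons, and
#' reports: every insertion/deletion (frameshifting iff its length is not a
#' multiple of 3, each left-normalized to its 5'-most equivalent placement)
#' and every premature stop codon read in the query's own running frame - the
#' frame implied by the cumulative indel offset - so stops induced by an
#' upstream frameshift are reported too. In-frame indels are recorded but do
#' not by themselves make the sequence a pseudogene.
#'
#' @param query character scalar, or a one-row data.frame with columns `seq`
#'   and optionally `id`, `species`.
#' @param reference an [reference_profile()].
#' @param min_identity minimum aligned nucleotide identity in \[0,1\] below
#'   which orthology is suspect: the report is flagged `low_confidence` with a
#'   warning (default 0.5).
#' @param partial if TRUE the query is a gene segment: a semiglobal (ends-free)
#'   alignment is used so missing flanks are not counted as deletions.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return object of class `or_disruption_report`: list with `query`,
#'   `species`, `locus`, `disruptions` (data.frame `kind`, `ref_codon`,
#'   `length_nt`, `query_pos` in reference order), `status` ("intact" or
#'   "pseudogene"), `first_disruption_fraction`, `frame_restored`,
#'   `identity`, `low_confidence`, `n_codons`.
#' @export
call_disruptions <- function(query, reference, min_identity = 0.5,
                             partial = FALSE, scoring = default_nt_scoring()) {
  id <- NA_character_; species <- NA_character_
  if (is.data.frame(query)) {
    id <- as.character(query$id[1] %||% NA)
    species <- as.character(query$species[1] %||% NA)
    query <- query$seq[1]
  }
  query <- toupper(query)
  check_alphabet(query)
  stopifnot(inherits(reference, "or_reference"))
  refv <- strsplit(reference$cds, "")[[1]]
  ncod <- reference$n_codons
  qv <- strsplit(query, "")[[1]]
  mm_run <- 0L
  if (length(qv) == length(refv)) {
    r0 <- rle(qv == refv)
    mm_run <- if (any(!r0$values)) max(r0$lengths[!r0$values]) else 0L
  }
  if (!partial && length(qv) == length(refv) && mean(qv == refv) >= 0.7 &&
      mm_run <= 4L && identical(scoring, default_nt_scoring())) {
    # equal-length, high-identity query with no long mismatch run: the
    # optimal affine-gap alignment is gapless (a compensating gap pair costs
    # 2*(open+extend) = 20 and can only pay against >= 5 repaired
    # mismatches), so skip the dynamic program
    pat <- qv; sub <- refv; s0 <- 1L; q0 <- 1L
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(reference$cds),
      type = if (partial) "overlap" else "global",
      substitutionMatrix = nt_submat(scoring),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    s0 <- Biostrings::start(Biostrings::subject(pa))
    q0 <- Biostrings::start(Biostrings::pattern(pa))
  }

  # identity over all alignment columns, gap columns counted as differences
  both <- pat != "-" & sub != "-"
  identity <- if (length(pat)) sum(pat == sub & both) / length(pat) else 0
  low_confidence <- identity < min_identity
  if (low_confidence)
    warning(sprintf("query %s: aligned identity %.2f below %.2f; orthology suspect",
                    id, identity, min_identity))

  # reference nt position at/just before each alignment column
  rpos <- cumsum(sub != "-") + (s0 - 1L)
  # query nt count consumed up to and including each column
  qcum <- cumsum(pat != "-")

  kinds <- integer(0)
  dis <- list()
  # --- indels ---
  state <- ifelse(sub == "-", "I", ifelse(pat == "-", "D", "M"))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "M") next
    i <- starts[k]; j <- ends[k]; L <- j - i + 1L
    if (r$values[k] == "D") {
      p <- normalize_deletion(refv, rpos[i], L)
      dis[[length(dis) + 1L]] <- data.frame(
        kind = "deletion", ref_codon = (p - 1L) %/% 3L + 1L, length_nt = L,
        query_pos = (q0 - 1L) + qcum[i], ref_nt = p, stringsAsFactors = FALSE)
    } else {
      ins <- paste(pat[i:j], collapse = "")
      nrm <- normalize_insertion(refv, rpos[i] + 1L, ins)
      dis[[length(dis) + 1L]] <- data.frame(
        kind = "insertion", ref_codon = (nrm$pos - 1L) %/% 3L + 1L, length_nt = L,
        query_pos = (q0 - 1L) + qcum[i] - 1L, ref_nt = nrm$pos,
        stringsAsFactors = FALSE)
    }
  }
  # --- premature stops in the query's running frame ---
  qcols <- which(pat != "-")
  qchars <- pat[qcols]
  # phase offset so query codon boundaries mirror reference codon boundaries
  # at the 5' end of the aligned region (0 for a global alignment)
  ph <- (s0 - 1L) %% 3L
  ncodq <- (length(qchars) - ((3L - ph) %% 3L)) %/% 3L
  if (ncodq > 0L) {
    first_idx <- ((3L - ph) %% 3L) + 3L * (seq_len(ncodq) - 1L) + 1L
    cod <- paste0(qchars[first_idx], qchars[first_idx + 1L], qchars[first_idx + 2L])
    stops <- which(is_stop_codon(cod))
    for (sidx in stops) {
      col <- qcols[first_idx[sidx]]
      rc <- (rpos[col] - 1L) %/% 3L + 1L
      if (rc >= ncod || rpos[col] < 1L) next  # the reference's own stop codon
      dis[[length(dis) + 1L]] <- data.frame(
        kind = "nonsense", ref_codon = rc, length_nt = 0L,
        query_pos = (q0 - 1L) + first_idx[sidx] - 1L, ref_nt = rpos[col],
        stringsAsFactors = FALSE)
    }
  }

  if (length(dis)) {
    d <- do.call(rbind, dis)
    d <- d[order(d$ref_codon, d$query_pos), , drop = FALSE]
    rownames(d) <- NULL
  } else {
    d <- data.frame(kind = character(), ref_codon = integer(),
                    length_nt = integer(), query_pos = integer(),
                    ref_nt = integer())
  }
  disruptive <- d$kind == "nonsense" | (d$kind != "nonsense" & d$length_nt %% 3L != 0L)
  status <- if (any(disruptive)) "pseudogene" else "intact"
  fs <- d$kind != "nonsense" & d$length_nt %% 3L != 0L
  net <- sum(d$length_nt[d$kind == "insertion"]) - sum(d$length_nt[d$kind == "deletion"])
  frame_restored <- any(fs) && net %% 3L == 0L
  first_frac <- if (any(disruptive)) min(d$ref_codon[disruptive]) / ncod else NA_real_

  structure(list(query = id, species = species, locus = reference$locus,
                 disruptions = d[, c("kind", "ref_codon", "length_nt", "query_pos")],
                 status = status, first_disruption_fraction = first_frac,
                 frame_restored = frame_restored, identity = identity,
                 low_confidence = low_confidence, n_codons = ncod),
            class = "or_disruption_report")
}

#' @export
print.or_disruption_report <- function(x, ...) {
  cat(sprintf("Disruption report: %s (locus %s, %s)\n",
              x$query, x$locus, x$status))
  if (nrow(x$disruptions)) print(x$disruptions) else cat("  no disruptions\n")
  invisible(x)
}

#' Classify where along the gene the first ORF disruption falls
#'
#' @param report an [call_disruptions()] report.
#' @param threshold_fraction disruptions before this fraction of the reference
#'   codon count are "five_prime", the rest "three_prime" (default 0.5).
#' @return "five_prime", "three_prime", or "none" for an intact report.
#' @export
classify_terminal_position <- function(report, threshold_fraction = 0.5) {
  if (report$status == "intact") return("none")
  if (report$first_disruption_fraction < threshold_fraction) "five_prime" else "three_prime"
}
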
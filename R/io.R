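# FASTA and TSV readers/writers tying the pipeline stages together.

#' Read OR sequences from a FASTA file
#'
#' Header fields are `|`-delimited: the part before the first `|` is the
#' species, the second field (when present) the locus. CRLF files parse
#' identically to LF files.
#'
#' @param path FASTA file.
#' @param source provenance tag stored on each record (default "genome").
#' @return data.frame with columns `id`, `species`, `locus`, `seq`, `source`.
#' @export
read_or_fasta <- function(path, source = "genome") {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(id = character(), species = character(),
                      locus = character(), seq = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty)
  }
  txt <- readLines(path)
  txt <- sub("\r$", "", txt)
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  x <- Biostrings::readDNAStringSet(tf)
  if (length(x) == 0L) {
    warning("no records in FASTA file: ", path)
    return(empty)
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(id = ids,
             species = unname(vapply(parts, `[`, character(1), 1L)),
             locus = unname(vapply(parts, function(p)
               if (length(p) >= 2L) p[2L] else NA_character_, character(1))),
             seq = unname(toupper(as.character(x))), source = source,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write OR sequences to a FASTA file
#'
#' Headers are the record ids (conventionally `species|locus`), sequence
#' lines wrapped at 60 columns; round-trips through [read_or_fasta()].
#'
#' @param seqs data.frame with columns `id` and `seq`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_or_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  if (anyDuplicated(seqs$id)) stop("duplicate sequence ids")
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a species-to-group table
#'
#' TSV with columns `species` and `group`.
#'
#' @param path file path.
#' @return named character vector species -> group.
#' @export
read_group_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "group") %in% names(df)))
  stats::setNames(df$group, df$species)
}

#' Flatten disruption reports to long-format tables
#'
#' @param reports list of [call_disruptions()] reports.
#' @return list with `summary` (one row per query: `query`, `species`,
#'   `locus`, `status`, `n_disruptions`, `first_fraction`, `frame_restored`,
#'   `low_confidence`) and `events` (one row per disruption).
#' @export
reports_as_tables <- function(reports) {
  summary <- do.call(rbind, lapply(reports, function(r) data.frame(
    query = r$query, species = r$species, locus = r$locus, status = r$status,
    n_disruptions = nrow(r$disruptions),
    first_fraction = r$first_disruption_fraction,
    frame_restored = r$frame_restored, low_confidence = r$low_confidence,
    stringsAsFactors = FALSE)))
  events <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$disruptions) == 0L) return(NULL)
    cbind(query = r$query, species = r$species, locus = r$locus,
          r$disruptions, stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(query = character(), species = character(),
                         locus = character(), kind = character(),
                         ref_codon = integer(), length_nt = integer(),
                         query_pos = integer(), stringsAsFactors = FALSE)
  rownames(summary) <- rownames(events) <- NULL
  list(summary = summary, events = events)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
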
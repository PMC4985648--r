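# Shared disruptions across species and Dollo-style ancestral-loss inference
# on a species tree.

# internal: long-format disruption events from a list of reports
reports_to_events <- function(reports) {
  locus <- unique(vapply(reports, function(r) r$locus, character(1)))
  if (length(locus) != 1L) stop("reports span multiple loci: ",
                                paste(locus, collapse = ", "))
  rows <- lapply(reports, function(r) {
    if (nrow(r$disruptions) == 0L) return(NULL)
    cbind(species = r$species, r$disruptions, stringsAsFactors = FALSE)
  })
  list(locus = locus, events = do.call(rbind, rows))
}

# internal: cluster events of one (kind, length) by position; single-linkage
# with gap <= tolerance
cluster_positions <- function(pos, tolerance) {
  o <- order(pos)
  brk <- c(0L, cumsum(diff(pos[o]) > tolerance))
  split(o, brk)
}

#' Find disruptions shared across species at homologous positions
#'
#' Two disruptions match when they have the same kind, the same length (for
#' indels), and reference codon positions differing by at most
#' `tolerance_codons` (single-linkage clustering; default 0 = exact match).
#' Maximal species sets are reported per signature.
#'
#' @param reports list of [call_disruptions()] reports for one locus, one per
#'   species.
#' @param tolerance_codons allowed reference-codon offset between matching
#'   disruptions.
#' @param min_species smallest species set reported (default 2; 1 also
#'   returns species-private signatures).
#' @return data.frame with columns `locus`, `kind`, `ref_codon` (5'-most
#'   position in the cluster), `length_nt`, `n_species`, `species`
#'   (comma-joined, sorted).
#' @export
find_shared_disruptions <- function(reports, tolerance_codons = 0L,
                                    min_species = 2L) {
  le <- reports_to_events(reports)
  ev <- le$events
  out <- data.frame(locus = character(), kind = character(),
                    ref_codon = integer(), length_nt = integer(),
                    n_species = integer(), species = character(),
                    stringsAsFactors = FALSE)
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  for (key in unique(paste(ev$kind, ev$length_nt))) {
    sel <- ev[paste(ev$kind, ev$length_nt) == key, , drop = FALSE]
    for (cl in cluster_positions(sel$ref_codon, tolerance_codons)) {
      sp <- sort(unique(sel$species[cl]))
      if (length(sp) < min_species) next
      out <- rbind(out, data.frame(
        locus = le$locus, kind = sel$kind[cl[1]],
        ref_codon = min(sel$ref_codon[cl]), length_nt = sel$length_nt[cl[1]],
        n_species = length(sp), species = paste(sp, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$ref_codon, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer ancestral pseudogenization events on a species tree
#'
#' Dollo-style single-origin rule: each shared ORF-disrupting signature
#' (nonsense or frameshifting indel) is assigned to the stem branch of the
#' most recent common ancestor of its carriers; species-private disruptions
#' are assigned to terminal branches. A locus is called ancestrally
#' pseudogenized for a clade when at least one shared disruptive signature
#' maps to the clade's stem. A shared in-frame deletion of at least
#' `weak_min_deletion_nt` whose clade species are all pseudogenes yields a
#' separate "ancestral (weak evidence)" flag; it never counts as a strict
#' call.
#'
#' @param shared output of [find_shared_disruptions()] for one locus.
#' @param reports the per-species [call_disruptions()] reports for the locus.
#' @param tree rooted species tree (`phylo`); internal node labels name stem
#'   branches.
#' @param aliases optional named character vector mapping sequenced species to
#'   the species named in the tree (e.g. congener substitutes).
#' @param tolerance_codons as in [find_shared_disruptions()]; used to match
#'   private events against shared signatures.
#' @param weak_min_deletion_nt minimum shared in-frame deletion length for the
#'   weak-evidence rule (default 12).
#' @return data.frame with columns `locus`, `branch`, `kind`, `ref_codon`,
#'   `length_nt`, `n_species`, `species`, `evidence` in
#'   {"strict", "weak", "shared_inframe", "terminal"}; attribute `loss_calls`
#'   summarizes per-branch calls (`locus`, `branch`, `call` in
#'   {"ancestral", "ancestral_weak", "terminal"}).
#' @export
infer_ancestral_loss <- function(shared, reports, tree, aliases = NULL,
                                 tolerance_codons = 0L,
                                 weak_min_deletion_nt = 12L) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  nn <- node_names(tree)
  unalias <- function(sp) {
    if (is.null(aliases)) return(sp)
    ifelse(sp %in% names(aliases), unname(aliases[sp]), sp)
  }
  status <- vapply(reports, function(r) r$status, character(1))
  names(status) <- unalias(vapply(reports, function(r) r$species, character(1)))
  le <- reports_to_events(reports)
  locus <- le$locus

  rows <- list()
  add <- function(branch, kind, ref_codon, length_nt, sp, evidence) {
    rows[[length(rows) + 1L]] <<- data.frame(
      locus = locus, branch = branch, kind = kind, ref_codon = ref_codon,
      length_nt = length_nt, n_species = length(sp),
      species = paste(sort(sp), collapse = ","), evidence = evidence,
      stringsAsFactors = FALSE)
  }

  if (!is.null(shared) && nrow(shared)) {
    for (k in seq_len(nrow(shared))) {
      s <- shared[k, ]
      carriers <- unalias(strsplit(s$species, ",")[[1]])
      missing <- setdiff(carriers, tree$tip.label)
      if (length(missing))
        stop("carrier species absent from the species tree: ",
             paste(missing, collapse = ", "))
      mrca <- ape::getMRCA(tree, unique(carriers))
      branch <- nn[mrca]
      disruptive <- s$kind == "nonsense" || s$length_nt %% 3L != 0L
      if (disruptive) {
        add(branch, s$kind, s$ref_codon, s$length_nt, carriers, "strict")
      } else if (s$kind == "deletion" && s$length_nt >= weak_min_deletion_nt) {
        clade_sp <- tree$tip.label[phangorn::Descendants(tree, mrca, "tips")[[1]]]
        observed <- intersect(clade_sp, names(status))
        weak_ok <- length(observed) > 0L && all(status[observed] == "pseudogene")
        add(branch, s$kind, s$ref_codon, s$length_nt, carriers,
            if (weak_ok) "weak" else "shared_inframe")
      } else {
        add(branch, s$kind, s$ref_codon, s$length_nt, carriers, "shared_inframe")
      }
    }
  }

  # species-private disruptive events -> terminal branches
  ev <- le$events
  if (!is.null(ev) && nrow(ev)) {
    disr <- ev[ev$kind == "nonsense" | ev$length_nt %% 3L != 0L, , drop = FALSE]
    for (k in seq_len(nrow(disr))) {
      e <- disr[k, ]
      sp <- unalias(e$species)
      in_shared <- FALSE
      if (!is.null(shared) && nrow(shared)) {
        cand <- shared[shared$kind == e$kind & shared$length_nt == e$length_nt &
                         abs(shared$ref_codon - e$ref_codon) <= tolerance_codons +
                         0L, , drop = FALSE]
        in_shared <- any(vapply(cand$species, function(ss)
          sp %in% unalias(strsplit(ss, ",")[[1]]), logical(1)))
      }
      if (in_shared) next
      if (!sp %in% tree$tip.label)
        stop("species absent from the species tree: ", sp)
      add(sp, e$kind, e$ref_codon, e$length_nt, sp, "terminal")
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), branch = character(), kind = character(),
               ref_codon = integer(), length_nt = integer(),
               n_species = integer(), species = character(),
               evidence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  calls <- unique(data.frame(
    locus = out$locus, branch = out$branch,
    call = c(strict = "ancestral", weak = "ancestral_weak",
             shared_inframe = NA_character_, terminal = "terminal")[out$evidence],
    stringsAsFactors = FALSE))
  calls <- calls[!is.na(calls$call), , drop = FALSE]
  rownames(calls) <- NULL
  attr(out, "loss_calls") <- calls
  out
}
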
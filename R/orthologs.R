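# One-to-one ortholog group extraction from support-annotated gene trees,
# plus a neighbor-joining + bootstrap tree builder for self-contained runs.

#' Criteria defining a putative one-to-one ortholog group
#'
#' @param min_support_exclusive clades qualify only with support strictly
#'   greater than this (default 85, on a 0-100 scale).
#' @param max_copies_per_species maximum gene copies per species inside the
#'   clade (default 1, i.e. single-copy).
#' @param min_species minimum number of distinct species (default 4).
#' @return object of class `or_ortholog_criteria`.
#' @export
ortholog_criteria <- function(min_support_exclusive = 85,
                              max_copies_per_species = 1L,
                              min_species = 4L) {
  stopifnot(min_species >= 2L, max_copies_per_species >= 1L)
  structure(list(min_support_exclusive = min_support_exclusive,
                 max_copies_per_species = as.integer(max_copies_per_species),
                 min_species = as.integer(min_species)),
            class = "or_ortholog_criteria")
}

#' Extract maximal one-to-one ortholog clades from a gene tree
#'
#' A clade qualifies when its node support is strictly greater than
#' `min_support_exclusive`, no species contributes more than
#' `max_copies_per_species` genes, and at least `min_species` distinct species
#' are present. Only maximal qualifying clades are returned (no returned clade
#' nests inside another), numbered by pre-order appearance on the tree.
#' Supports on a 0-1 scale (Bayesian posteriors) are rescaled to 0-100 before
#' comparison.
#'
#' @param tree `phylo` gene tree; node labels hold the support of the clade
#'   below each node.
#' @param species named character vector mapping leaf names to species;
#'   defaults to the part of each leaf name before the first `|`.
#' @param criteria an [ortholog_criteria()].
#' @param outgroup optional leaf name used to root an unrooted tree; if the
#'   tree is unrooted and no outgroup is given, midpoint rooting is applied
#'   (set `midpoint = FALSE` to make that an error instead).
#' @param midpoint allow midpoint rooting as a fallback (default TRUE).
#' @return list of class `or_ortholog_groups`; each element has `group_id`,
#'   `node`, `support`, and `members` (data.frame `leaf`, `species`, `gene`).
#' @export
extract_ortholog_clades <- function(tree, species = NULL,
                                    criteria = ortholog_criteria(),
                                    outgroup = NULL, midpoint = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) stop("outgroup not found among leaves")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  } else if (!ape::is.rooted(tree)) {
    if (!midpoint) stop("unrooted tree: supply an outgroup or allow midpoint rooting")
    tree <- phangorn::midpoint(tree)
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names")
  if (is.null(species))
    species <- stats::setNames(sub("\\|.*$", "", tree$tip.label), tree$tip.label)
  if (!all(tree$tip.label %in% names(species)))
    stop("species map does not cover every leaf")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (length(sup) && all(is.na(sup) | (sup >= 0 & sup <= 1)) &&
      any(!is.na(sup) & sup > 0))
    sup <- sup * 100
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("node supports outside [0, 100]")
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_below <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), "tips")
  groups <- list()
  visit <- function(node) {
    idx <- node - ntip
    s <- if (length(sup) >= idx) sup[idx] else NA_real_
    leaves <- tree$tip.label[tips_below[[idx]]]
    sp <- unname(species[leaves])
    if (!is.na(s) && s > criteria$min_support_exclusive &&
        max(table(sp)) <= criteria$max_copies_per_species &&
        length(unique(sp)) >= criteria$min_species) {
      groups[[length(groups) + 1L]] <<- list(
        node = node, support = s,
        members = data.frame(leaf = leaves, species = sp,
                             gene = sub("^[^|]*\\|?", "", leaves),
                             stringsAsFactors = FALSE))
      return(invisible())
    }
    for (ch in kids[[as.character(node)]])
      if (ch > ntip) visit(ch)
    invisible()
  }
  visit(ntip + 1L)
  for (i in seq_along(groups)) groups[[i]]$group_id <- i
  structure(groups, class = "or_ortholog_groups")
}

#' @export
as.data.frame.or_ortholog_groups <- function(x, ...) {
  if (!length(x))
    return(data.frame(group_id = integer(), support = numeric(),
                      species = character(), gene = character(),
                      leaf = character()))
  do.call(rbind, lapply(x, function(g)
    data.frame(group_id = g$group_id, support = g$support,
               species = g$members$species, gene = g$members$gene,
               leaf = g$members$leaf, stringsAsFactors = FALSE)))
}

#' Neighbor-joining gene tree with site-resampling bootstrap supports
#'
#' Plumbing tree builder for self-contained synthetic runs (it stands in for
#' external ML/Bayesian inference, which this package does not perform).
#' Distances are p-distances with pairwise deletion of gapped/ambiguous
#' sites; supports are the percentage of bootstrap replicates (columns
#' resampled with replacement) containing each bipartition.
#'
#' @param aln named character vector of equal-length aligned nucleotide
#'   sequences, or a character matrix (rows = taxa).
#' @param n_bootstrap number of replicates; 0 leaves supports absent.
#' @param seed integer seed controlling the resampling.
#' @return unrooted `phylo`; `node.label` holds supports (0-100) when
#'   `n_bootstrap > 0`.
#' @export
build_gene_tree <- function(aln, n_bootstrap = 100L, seed = 1L) {
  if (is.character(aln) && is.null(dim(aln))) {
    if (is.null(names(aln))) stop("sequences must be named")
    if (length(unique(nchar(aln))) != 1L) stop("sequences must be aligned (equal length)")
    if (nchar(aln[1]) == 0L) stop("alignment width is zero")
    m <- do.call(rbind, strsplit(tolower(aln), ""))
    rownames(m) <- names(aln)
  } else {
    m <- aln
  }
  if (nrow(m) < 3L) stop("need at least 3 sequences")
  if (anyDuplicated(rownames(m))) stop("duplicate sequence names")
  bin <- ape::as.DNAbin(m)
  pdist <- function(x) ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE)
  d <- pdist(bin)
  if (any(!is.finite(d)))
    stop("undefined pairwise distance (no overlapping resolved sites)")
  tr <- ape::nj(d)
  if (n_bootstrap > 0L) {
    set.seed(seed)
    bp <- suppressWarnings(
      ape::boot.phylo(tr, bin, FUN = function(x) ape::nj(pdist(x)),
                      B = n_bootstrap, quiet = TRUE))
    # the root bipartition (all taxa) is present in every replicate; with 3
    # taxa it is the only internal node and boot.phylo cannot score it
    if (length(bp) < tr$Nnode) bp <- c(bp, rep(NA_real_, tr$Nnode - length(bp)))
    if (is.na(bp[1])) bp[1] <- n_bootstrap
    tr$node.label <- as.character(round(100 * bp / n_bootstrap))
  }
  tr
}
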
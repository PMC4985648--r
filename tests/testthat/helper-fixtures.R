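# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

SENSE <- setdiff(
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

# random intact CDS: ATG + sense codons + TAA, n_codons total
random_cds <- function(n_codons = 310L) {
  paste(c("ATG", sample(SENSE, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

codon_at <- function(seq, i) substr(seq, 3L * (i - 1L) + 1L, 3L * i)

set_codon <- function(seq, i, codon) {
  paste0(substr(seq, 1L, 3L * (i - 1L)), codon, substr(seq, 3L * i + 1L, nchar(seq)))
}

# delete len nt starting at the first base of codon i
delete_at <- function(seq, i, len) {
  p <- 3L * (i - 1L) + 1L
  paste0(substr(seq, 1L, p - 1L), substr(seq, p + len, nchar(seq)))
}

# insert `ins` immediately before the first base of codon i
insert_at <- function(seq, i, ins) {
  p <- 3L * (i - 1L) + 1L
  paste0(substr(seq, 1L, p - 1L), ins, substr(seq, p, nchar(seq)))
}

# substitutions at a given per-site probability that never touch a stop
# codon's frame-aligned triplet and never create one
mutate_sites <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  for (i in which(runif(n) < p)) {
    if (i <= 3L || i > n - 3L) next
    c0 <- (i - 1L) %/% 3L
    cod <- ch[(3L * c0 + 1L):(3L * c0 + 3L)]
    if (paste(cod, collapse = "") %in% c("TAA", "TAG", "TGA")) next
    off <- i - 3L * c0
    for (b in sample(setdiff(c("A", "C", "G", "T"), ch[i]))) {
      cod2 <- cod; cod2[off] <- b
      if (!paste(cod2, collapse = "") %in% c("TAA", "TAG", "TGA")) {
        ch[i] <- b
        break
      }
    }
  }
  paste(ch, collapse = "")
}

# a random gene tree whose tips are "sp<i>|g<j>" with random supports,
# for oracle comparisons
random_labelled_tree <- function(n_tips, n_species) {
  tr <- ape::rtree(n_tips)
  sp <- sample(seq_len(n_species), n_tips, replace = TRUE)
  tr$tip.label <- paste0("sp", sp, "|g", seq_len(n_tips))
  tr$node.label <- as.character(sample(c(NA, 0:100), tr$Nnode, replace = TRUE))
  tr
}

# independent brute-force enumeration of maximal qualifying clades: test
# every internal node, then drop nodes nested inside another qualifying node
oracle_ortholog_leafsets <- function(tree, crit) {
  ntip <- ape::Ntip(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  qual <- c()
  for (nd in nodes) {
    tips <- tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
    sp <- sub("\\|.*$", "", tips)
    s <- sup[nd - ntip]
    if (!is.na(s) && s > crit$min_support_exclusive &&
        max(table(sp)) <= crit$max_copies_per_species &&
        length(unique(sp)) >= crit$min_species)
      qual <- c(qual, nd)
  }
  keep <- qual
  for (nd in qual) {
    anc <- phangorn::Ancestors(tree, nd, "all")
    if (any(anc %in% qual)) keep <- setdiff(keep, nd)
  }
  lapply(keep, function(nd)
    sort(tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]))
}

# two-species tree for shared-disruption fixtures
two_penguin_tree <- function() {
  ape::read.tree(text = "((emperor_penguin:1,adelie_penguin:1)penguins:1,northern_fulmar:2)root;")
}

# build a disruption report by calling the package on a constructed query
report_for <- function(seq, ref, species, id = species) {
  r <- call_disruptions(data.frame(id = id, species = species, seq = seq,
                                   stringsAsFactors = FALSE), ref)
  r
}
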
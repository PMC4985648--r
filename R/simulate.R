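# Synthetic OR-repertoire simulator: OR-like single-exon coding sequences
# evolved along a species tree with planted, branch-specific ORF disruptions
# and known truth labels.

#' The eight waterbird species of the study design
#'
#' Two penguins plus six non-penguin waterbirds, with genome sequencing
#' coverages used to parameterize coverage-dependent gene absence.
#'
#' @return data.frame with columns `species`, `coverage`, `group`.
#' @export
waterbird_species <- function() {
  data.frame(
    species = c("emperor_penguin", "adelie_penguin", "northern_fulmar",
                "crested_ibis", "little_egret", "great_cormorant",
                "dalmatian_pelican", "red_throated_loon"),
    coverage = c(60, 60, 33, 105, 74, 24, 34, 33),
    group = c("penguin", "penguin", rep("waterbird", 6)),
    stringsAsFactors = FALSE)
}

#' The accepted waterbird species tree
#'
#' Rooted eight-species topology (loon sister to the rest; penguins sister to
#' the fulmar; the four Pelecaniformes as the remaining clade), ultrametric
#' with unit root-to-tip depth. Internal nodes are named so that branches can
#' be addressed by their child node (e.g. `penguins` for the penguin stem).
#'
#' @return an `ape::phylo` object with `node.label` set.
#' @export
waterbird_tree <- function() {
  txt <- paste0(
    "(red_throated_loon:1,(((emperor_penguin:0.25,adelie_penguin:0.25)",
    "penguins:0.35,northern_fulmar:0.6)austrodyptornithes:0.2,",
    "(crested_ibis:0.7,(little_egret:0.6,(dalmatian_pelican:0.5,",
    "great_cormorant:0.5)sulae:0.1)egret_clade:0.1)pelecaniformes:0.1)",
    "core_waterbirds:0.2)root;")
  ape::read.tree(text = txt)
}

#' Default per-species probability that a locus is unrecoverable
#'
#' Mimics coverage-dependent missingness in draft genomes: lower-coverage
#' assemblies drop loci more often. Set to min(5/coverage, 0.25).
#'
#' @return named numeric vector over the eight species.
#' @export
default_absence_prob <- function() {
  sp <- waterbird_species()
  stats::setNames(pmin(5 / sp$coverage, 0.25), sp$species)
}

#' Default planted-disruption plan
#'
#' Mirrors the lineage-restricted disruption layout of the study system:
#' eight loci disrupted on the penguin stem branch (OR3: 2-bp deletion +
#' 2-bp insertion; OR4: nonsense; OR7: two nonsense + 10-bp deletion; OR9:
#' 2-bp deletion near the 3' end; OR13, OR22: nonsense; OR19: 12-bp in-frame
#' deletion on the stem with species-private nonsense mutations ahead of it;
#' OR25: 1-bp insertion), and three independent terminal-branch events in
#' non-penguins (OR10, OR16 in the northern fulmar; OR25 in the red-throated
#' loon). Planted nonsense codons always lie 5' of any same-lineage
#' frameshifting indel so that they remain stop codons in the derived reading
#' frame.
#'
#' @return data.frame with columns `locus`, `branch`, `event`
#'   (nonsense/deletion/insertion), `length_nt`, `codon_position`.
#' @export
default_disruption_plan <- function() {
  p <- function(locus, branch, event, length_nt, codon_position)
    data.frame(locus = locus, branch = branch, event = event,
               length_nt = length_nt, codon_position = codon_position,
               stringsAsFactors = FALSE)
  rbind(
    p("OR3", "penguins", "deletion", 2L, 57L),
    p("OR3", "penguins", "insertion", 2L, 130L),
    p("OR4", "penguins", "nonsense", 0L, 45L),
    p("OR7", "penguins", "nonsense", 0L, 60L),
    p("OR7", "penguins", "nonsense", 0L, 120L),
    p("OR7", "penguins", "deletion", 10L, 200L),
    p("OR9", "penguins", "deletion", 2L, 280L),
    p("OR13", "penguins", "nonsense", 0L, 35L),
    p("OR19", "emperor_penguin", "nonsense", 0L, 40L),
    p("OR19", "adelie_penguin", "nonsense", 0L, 70L),
    p("OR19", "penguins", "deletion", 12L, 150L),
    p("OR22", "penguins", "nonsense", 0L, 90L),
    p("OR25", "penguins", "insertion", 1L, 100L),
    p("OR10", "northern_fulmar", "nonsense", 0L, 55L),
    p("OR16", "northern_fulmar", "deletion", 1L, 88L),
    p("OR25", "red_throated_loon", "nonsense", 0L, 50L))
}

#' Simulation configuration
#'
#' @param species_tree rooted `phylo` with branch lengths; internal node
#'   labels name branches for the disruption plan.
#' @param n_loci number of one-to-one orthologous loci to simulate.
#' @param codon_length total codons per coding sequence including the ATG
#'   start and the terminal stop; must exceed 250 so that undisrupted genes
#'   pass the intact filter.
#' @param substitution_rate expected substitutions per site per unit branch
#'   length (Jukes-Cantor-like; stop codons are never created or destroyed by
#'   background substitution).
#' @param disruption_plan data.frame as in [default_disruption_plan()];
#'   branches are species-tree tip or node labels.
#' @param absence_prob per-species probability in \[0,1\] that a locus is
#'   unrecoverable (scalar or named vector over tips).
#' @param seed integer random seed.
#' @return object of class `or_sim_config`.
#' @export
sim_config <- function(species_tree = waterbird_tree(), n_loci = 29L,
                       codon_length = 310L, substitution_rate = 0.05,
                       disruption_plan = default_disruption_plan(),
                       absence_prob = default_absence_prob(), seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"), ape::is.rooted(species_tree))
  if (ape::Ntip(species_tree) < 2L) stop("species tree must have >= 2 leaves")
  n_loci <- as.integer(n_loci); codon_length <- as.integer(codon_length)
  stopifnot(n_loci >= 1L)
  if (codon_length <= 250L)
    stop("codon_length must exceed 250 or intact loci would fail the length filter")
  if (substitution_rate < 0) stop("substitution_rate must be >= 0")
  tips <- species_tree$tip.label
  if (length(absence_prob) == 1L && is.null(names(absence_prob)))
    absence_prob <- stats::setNames(rep(absence_prob, length(tips)), tips)
  if (!all(tips %in% names(absence_prob)))
    stop("absence_prob must cover every species in the tree")
  absence_prob <- absence_prob[tips]
  if (any(absence_prob < 0 | absence_prob > 1)) stop("absence_prob must lie in [0,1]")
  plan <- as.data.frame(disruption_plan)
  if (nrow(plan)) {
    stopifnot(all(c("locus", "branch", "event", "length_nt", "codon_position")
                  %in% names(plan)))
    branches <- c(tips, species_tree$node.label)
    bad <- setdiff(unique(plan$branch), branches)
    if (length(bad)) stop("unknown branch in disruption_plan: ",
                          paste(bad, collapse = ", "))
    if (!all(plan$event %in% c("nonsense", "deletion", "insertion")))
      stop("disruption events must be nonsense, deletion or insertion")
    if (any(plan$event != "nonsense" & plan$length_nt < 1L))
      stop("indel events need length_nt >= 1")
    if (any(plan$codon_position < 2L | plan$codon_position > codon_length - 1L))
      stop("codon_position must lie in [2, codon_length - 1]")
    if (any(plan$event == "deletion" &
            3L * (plan$codon_position - 1L) + plan$length_nt > 3L * (codon_length - 1L)))
      stop("deletion runs into the terminal stop codon")
  }
  structure(list(species_tree = species_tree, n_loci = n_loci,
                 codon_length = codon_length,
                 substitution_rate = substitution_rate,
                 disruption_plan = plan, absence_prob = absence_prob,
                 seed = as.integer(seed)),
            class = "or_sim_config")
}

# internal: node names (tips then internal), synthesizing labels where empty
node_names <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl <- ifelse(nzchar(nl), nl, paste0("node", ape::Ntip(tree) + seq_len(tree$Nnode)))
  c(tree$tip.label, nl)
}

# internal: mutate a codon-framed sequence (character vector) with per-site
# probability p; never creates or destroys a stop codon in the ancestral
# frame; the start codon and terminal stop are exempt.
mutate_cds <- function(chars, p) {
  n <- length(chars)
  if (p <= 0) return(chars)
  hits <- which(stats::runif(n) < p)
  hits <- hits[hits > 3L & hits <= n - 3L]
  for (i in hits) {
    c0 <- (i - 1L) %/% 3L
    cod <- chars[(3L * c0 + 1L):(3L * c0 + 3L)]
    if (is_stop_codon(paste(cod, collapse = ""))) next  # protect planted stops
    off <- i - 3L * c0
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    ok <- vapply(alt, function(b) {
      cod2 <- cod; cod2[off] <- b
      !is_stop_codon(paste(cod2, collapse = ""))
    }, logical(1))
    alt <- alt[ok]
    if (length(alt)) chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

# internal: realize tip sequence by replaying indel events (ancestral
# coordinates) on the mutated ancestral-frame sequence
apply_indels <- function(chars, events) {
  if (is.null(events) || nrow(events) == 0L) return(paste(chars, collapse = ""))
  keep <- rep(TRUE, length(chars))
  ins_at <- rep("", length(chars) + 1L)  # ins_at[p]: inserted before position p
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    p0 <- 3L * (ev$codon_position - 1L) + 1L
    if (ev$event == "deletion") {
      keep[p0:(p0 + ev$length_nt - 1L)] <- FALSE
    } else if (ev$event == "insertion") {
      ins_at[p0] <- paste0(ins_at[p0], ev$ins_seq)
    }
  }
  out <- character(0)
  for (p in seq_along(chars)) {
    if (nzchar(ins_at[p])) out <- c(out, strsplit(ins_at[p], "")[[1]])
    if (keep[p]) out <- c(out, chars[p])
  }
  if (nzchar(ins_at[length(chars) + 1L]))
    out <- c(out, strsplit(ins_at[length(chars) + 1L], "")[[1]])
  paste(out, collapse = "")
}

#' Simulate an OR repertoire along a species tree
#'
#' Each locus starts from a random intact coding sequence (ATG start, sense
#' codons, TAA stop) at the root and evolves by Jukes-Cantor-like
#' substitution along branches; proposed substitutions that would create an
#' in-frame stop are resampled, and existing (planted) stop codons are never
#' reverted. Planned disruptions are applied on their branch and inherited by
#' all descendant leaves; inserted bases and nonsense codons are drawn once
#' per branch so shared events are identical across carriers. Finally each
#' (species, locus) is dropped with the species' absence probability.
#'
#' @param config an [sim_config()].
#' @return object of class `or_simulation`: list with `sequences` (data.frame
#'   `id`, `species`, `locus`, `seq`, `source`), `gene_trees` (per-locus
#'   species tree pruned to non-absent species), `truth` (list with `status` -
#'   data.frame `species`, `locus`, `status` in intact/pseudogene/absent - and
#'   `events` - planted events with realized, left-normalized reference
#'   coordinates and the branch they occurred on), and `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "or_sim_config"))
  set.seed(config$seed)
  tree <- ape::reorder.phylo(config$species_tree, "cladewise")
  nn <- node_names(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  loci <- paste0("OR", seq_len(config$n_loci))
  plan <- config$disruption_plan
  nt_len <- 3L * config$codon_length

  seq_rows <- list(); status_rows <- list(); event_rows <- list()
  gene_trees <- stats::setNames(vector("list", length(loci)), loci)

  for (locus in loci) {
    root_cds <- c("A", "T", "G",
                  unlist(strsplit(sample(SENSE_CODONS, config$codon_length - 2L,
                                         replace = TRUE), "")),
                  "T", "A", "A")
    refv <- root_cds  # ancestral reference for truth coordinates
    node_seq <- vector("list", ntip + tree$Nnode)
    node_ev <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- root_cds
    lplan <- plan[plan$locus == locus, , drop = FALSE]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
      bl <- tree$edge.length[e]
      chars <- mutate_cds(node_seq[[par]], config$substitution_rate * bl)
      ev_here <- lplan[lplan$branch == nn[chd], , drop = FALSE]
      acc <- node_ev[[par]]
      if (nrow(ev_here)) {
        for (k in seq_len(nrow(ev_here))) {
          ev <- ev_here[k, ]
          p0 <- 3L * (ev$codon_position - 1L) + 1L
          ins_seq <- ""
          if (ev$event == "nonsense") {
            chars[p0:(p0 + 2L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
            real_nt <- p0
          } else if (ev$event == "deletion") {
            real_nt <- normalize_deletion(refv, p0, ev$length_nt)
          } else {
            ins_seq <- paste(sample(c("A", "C", "G", "T"), ev$length_nt,
                                    replace = TRUE), collapse = "")
            real_nt <- normalize_insertion(refv, p0, ins_seq)$pos
          }
          rec <- data.frame(locus = locus, branch = nn[chd], event = ev$event,
                            codon_position = ev$codon_position,
                            length_nt = ev$length_nt,
                            ref_codon = (real_nt - 1L) %/% 3L + 1L,
                            ref_nt = real_nt, ins_seq = ins_seq,
                            stringsAsFactors = FALSE)
          acc <- rbind(acc, rec)
          event_rows[[length(event_rows) + 1L]] <- rec
        }
      }
      node_seq[[chd]] <- chars
      node_ev[chd] <- list(acc)
    }
    absent <- stats::runif(ntip) < config$absence_prob[tree$tip.label]
    for (t in seq_len(ntip)) {
      sp <- tree$tip.label[t]
      ev <- node_ev[[t]]
      disruptive <- !is.null(ev) &&
        any(ev$event == "nonsense" | ev$length_nt %% 3L != 0L)
      st <- if (absent[t]) "absent" else if (disruptive) "pseudogene" else "intact"
      status_rows[[length(status_rows) + 1L]] <-
        data.frame(species = sp, locus = locus, status = st,
                   stringsAsFactors = FALSE)
      if (!absent[t]) {
        seq_rows[[length(seq_rows) + 1L]] <- data.frame(
          id = paste(sp, locus, sep = "|"), species = sp, locus = locus,
          seq = apply_indels(node_seq[[t]], ev), source = "synthetic",
          stringsAsFactors = FALSE)
      }
    }
    present <- tree$tip.label[!absent]
    gene_trees[[locus]] <- if (length(present) >= 2L)
      ape::keep.tip(tree, present) else NULL
  }

  events <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(locus = character(), branch = character(), event = character(),
               codon_position = integer(), length_nt = integer(),
               ref_codon = integer(), ref_nt = integer(), ins_seq = character())
  # deduplicate (an event is planted once per branch even with several carriers)
  events <- unique(events)
  rownames(events) <- NULL
  structure(list(sequences = do.call(rbind, seq_rows),
                 gene_trees = gene_trees,
                 truth = list(status = do.call(rbind, status_rows),
                              events = events),
                 config = config),
            class = "or_simulation")
}

#' Write a simulated repertoire to disk
#'
#' One FASTA per species (headers `species|locus`), per-locus true gene trees
#' as newick, truth labels as TSV, and the configuration (scalars + plan) as
#' JSON.
#'
#' @param sim an [simulate_repertoire()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "or_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (sp in unique(sim$sequences$species)) {
    f <- file.path(dir, paste0(sp, ".fasta"))
    write_or_fasta(sim$sequences[sim$sequences$species == sp, ], f)
    files <- c(files, f)
  }
  tr <- Filter(Negate(is.null), sim$gene_trees)
  if (length(tr)) {
    f <- file.path(dir, "gene_trees.nwk")
    ape::write.tree(do.call(c, lapply(tr, list)) |> (\(x) {
      class(x) <- "multiPhylo"; names(x) <- names(tr); x })(), file = f)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth_labels.tsv")
  utils::write.table(sim$truth$status, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "config.json")
  cfg <- sim$config
  jsonlite::write_json(list(n_loci = cfg$n_loci, codon_length = cfg$codon_length,
                            substitution_rate = cfg$substitution_rate,
                            absence_prob = as.list(cfg$absence_prob),
                            seed = cfg$seed,
                            disruption_plan = cfg$disruption_plan),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
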
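test_that("zero rate, empty plan, no absence: identical intact sequences", {
  cfg <- sim_config(substitution_rate = 0, n_loci = 3,
                    disruption_plan = default_disruption_plan()[0, ],
                    absence_prob = 0, seed = 5)
  sim <- simulate_repertoire(cfg)
  expect_equal(nrow(sim$sequences), 3 * 8)
  for (locus in paste0("OR", 1:3)) {
    s <- sim$sequences$seq[sim$sequences$locus == locus]
    expect_equal(length(unique(s)), 1L)
  }
  expect_true(all(sim$truth$status$status == "intact"))
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("same config and seed produce byte-identical FASTA output", {
  cfg <- sim_config(n_loci = 4, seed = 99)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_repertoire(cfg), d1)
  write_simulation(simulate_repertoire(cfg), d2)
  for (f in list.files(d1, pattern = "fasta$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a stem-branch deletion appears in all descendants at the homologous position", {
  plan <- data.frame(locus = "OR1", branch = "penguins", event = "deletion",
                     length_nt = 2L, codon_position = 57L)
  cfg <- sim_config(substitution_rate = 0, n_loci = 1, disruption_plan = plan,
                    absence_prob = 0, seed = 8)
  sim <- simulate_repertoire(cfg)
  st <- sim$truth$status
  expect_setequal(st$species[st$status == "pseudogene"],
                  c("emperor_penguin", "adelie_penguin"))
  peng <- sim$sequences[sim$sequences$species %in%
                          c("emperor_penguin", "adelie_penguin"), ]
  expect_equal(length(unique(peng$seq)), 1L)
  expect_equal(unique(nchar(peng$seq)), 3L * 310L - 2L)
  # re-derive the disruption against an intact relative: exact recovery
  ref <- reference_profile("OR1", sim$sequences$seq[
    sim$sequences$species == "northern_fulmar"])
  r <- call_disruptions(peng$seq[1], ref)
  expect_equal(r$status, "pseudogene")
  del <- r$disruptions[r$disruptions$kind == "deletion", ]
  expect_equal(del$ref_codon, sim$truth$events$ref_codon)
  expect_equal(del$length_nt, 2L)
})

test_that("planted events are recovered exactly at zero substitution rate", {
  cfg <- sim_config(substitution_rate = 0, absence_prob = 0, seed = 13)
  sim <- simulate_repertoire(cfg)
  refs <- lapply(split(sim$sequences, sim$sequences$locus), function(s) {
    fu <- s$seq[s$species == "crested_ibis"]
    reference_profile(s$locus[1], fu)
  })
  ev <- sim$truth$events
  tree <- cfg$species_tree
  for (locus in unique(ev$locus)) {
    for (sp in c("emperor_penguin", "adelie_penguin", "northern_fulmar",
                 "red_throated_loon")) {
      row <- sim$sequences[sim$sequences$species == sp &
                             sim$sequences$locus == locus, ]
      r <- call_disruptions(row, refs[[locus]])
      # events on the path to this species
      carriers <- ev[ev$locus == locus, ]
      onpath <- vapply(seq_len(nrow(carriers)), function(k) {
        br <- carriers$branch[k]
        if (br == sp) return(TRUE)
        if (br %in% tree$tip.label) return(FALSE)
        nd <- which(orloss:::node_names(tree) == br)
        sp %in% tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
      }, logical(1))
      carriers <- carriers[onpath, , drop = FALSE]
      for (k in seq_len(nrow(carriers))) {
        e <- carriers[k, ]
        kind <- if (e$event == "nonsense") "nonsense" else e$event
        hit <- r$disruptions[r$disruptions$kind == kind &
                               r$disruptions$ref_codon == e$ref_codon &
                               r$disruptions$length_nt == e$length_nt, ]
        expect_gte(nrow(hit), 1L)
      }
      truth_status <- sim$truth$status
      expect_equal(r$status, truth_status$status[truth_status$species == sp &
                                                   truth_status$locus == locus])
    }
  }
})

test_that("without planted disruptions no sequence has internal stops", {
  cfg <- sim_config(substitution_rate = 0.08, n_loci = 5,
                    disruption_plan = default_disruption_plan()[0, ],
                    absence_prob = 0, seed = 17)
  sim <- simulate_repertoire(cfg)
  for (s in sim$sequences$seq) {
    aa <- strsplit(orloss:::translate_nt(s), "")[[1]]
    expect_false(any(aa[-length(aa)] == "*"))
    expect_equal(aa[length(aa)], "*")
    expect_equal(substr(s, 1, 3), "ATG")
  }
})

test_that("absence counts follow the per-species probability (binomial bounds)", {
  # 100 seeds, one species with absence_prob 0.15 over 29 loci
  n_absent <- integer(100)
  for (s in 1:100) {
    cfg <- sim_config(substitution_rate = 0, n_loci = 29,
                      disruption_plan = default_disruption_plan()[0, ],
                      absence_prob = 0.15, seed = 1000 + s)
    sim <- simulate_repertoire(cfg)
    st <- sim$truth$status
    n_absent[s] <- sum(st$status == "absent" & st$species == "great_cormorant")
  }
  n <- 100 * 29
  total <- sum(n_absent)
  bounds <- qbinom(c(0.005, 0.995), n, 0.15)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("configuration errors are caught", {
  expect_error(sim_config(codon_length = 250), "exceed 250")
  expect_error(sim_config(substitution_rate = -1), "substitution_rate")
  expect_error(sim_config(absence_prob = 1.5), "\\[0,1\\]")
  bad_plan <- data.frame(locus = "OR1", branch = "nope", event = "nonsense",
                         length_nt = 0L, codon_position = 10L)
  expect_error(sim_config(disruption_plan = bad_plan), "unknown branch")
  bad_pos <- data.frame(locus = "OR1", branch = "penguins", event = "nonsense",
                        length_nt = 0L, codon_position = 310L)
  expect_error(sim_config(disruption_plan = bad_pos), "codon_position")
})
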
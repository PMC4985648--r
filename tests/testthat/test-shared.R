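test_that("a deletion shared by both penguins yields one shared event", {
  set.seed(31)
  ref <- reference_profile("OR9", random_cds(310L))
  q <- delete_at(ref$cds, 57L, 2L)
  reps <- list(report_for(q, ref, "emperor_penguin"),
               report_for(q, ref, "adelie_penguin"),
               report_for(ref$cds, ref, "northern_fulmar"))
  sh <- find_shared_disruptions(reps)
  del <- sh[sh$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$n_species, 2L)
  expect_equal(del$species, "adelie_penguin,emperor_penguin")
})

test_that("positions differing beyond the tolerance do not match", {
  set.seed(32)
  ref <- reference_profile("OR1", random_cds(310L))
  r1 <- report_for(set_codon(ref$cds, 40L, "TAA"), ref, "spA")
  r2 <- report_for(set_codon(ref$cds, 90L, "TAA"), ref, "spB")
  expect_equal(nrow(find_shared_disruptions(list(r1, r2))), 0L)
  # generous tolerance merges them
  sh <- find_shared_disruptions(list(r1, r2), tolerance_codons = 60L)
  expect_equal(nrow(sh), 1L)
  expect_error(find_shared_disruptions(list(
    r1, report_for(ref$cds, reference_profile("OR2", ref$cds), "spC"))),
    "multiple loci")
})

test_that("shared events equal a brute-force pairwise-intersection oracle", {
  set.seed(33)
  ref <- reference_profile("OR1", random_cds(310L))
  for (trial in 1:15) {
    species <- paste0("sp", 1:5)
    # plant random nonsense mutations, some at shared positions
    planted <- lapply(species, function(s) {
      k <- sample(0:3, 1)
      sort(sample(c(20L, 50L, 80L, 120L, 200L, 250L), k))
    })
    reps <- Map(function(s, pos) {
      q <- ref$cds
      for (p in pos) q <- set_codon(q, p, "TAA")
      report_for(q, ref, s)
    }, species, planted)
    sh <- find_shared_disruptions(unname(reps))
    # oracle: positions carried by >= 2 species
    tally <- table(unlist(planted))
    want <- sort(as.integer(names(tally)[tally >= 2]))
    expect_equal(sort(sh$ref_codon), want, info = trial)
    for (k in seq_len(nrow(sh))) {
      carriers <- species[vapply(planted, function(p) sh$ref_codon[k] %in% p,
                                 logical(1))]
      expect_equal(sh$species[k], paste(sort(carriers), collapse = ","))
    }
  }
})

test_that("shared penguin disruptions map to the penguin stem branch", {
  set.seed(34)
  ref <- reference_profile("OR9", random_cds(310L))
  tree <- waterbird_tree()
  q <- delete_at(ref$cds, 57L, 2L)
  reps <- list(report_for(q, ref, "emperor_penguin"),
               report_for(q, ref, "adelie_penguin"),
               report_for(ref$cds, ref, "northern_fulmar"),
               report_for(ref$cds, ref, "red_throated_loon"))
  sh <- find_shared_disruptions(reps)
  loss <- infer_ancestral_loss(sh, reps, tree)
  strict <- loss[loss$evidence == "strict", ]
  expect_equal(unique(strict$branch), "penguins")
  calls <- attr(loss, "loss_calls")
  expect_true(any(calls$branch == "penguins" & calls$call == "ancestral"))
})

test_that("species-private disruptions land on terminal branches", {
  set.seed(35)
  ref <- reference_profile("OR25", random_cds(310L))
  tree <- waterbird_tree()
  reps <- list(report_for(set_codon(ref$cds, 50L, "TGA"), ref, "red_throated_loon"),
               report_for(ref$cds, ref, "emperor_penguin"),
               report_for(ref$cds, ref, "northern_fulmar"))
  sh <- find_shared_disruptions(reps)
  expect_equal(nrow(sh), 0L)
  loss <- infer_ancestral_loss(sh, reps, tree)
  expect_equal(loss$evidence, "terminal")
  expect_equal(loss$branch, "red_throated_loon")
  calls <- attr(loss, "loss_calls")
  expect_equal(calls$call, "terminal")
})

test_that("congener aliases are applied before tree lookup", {
  set.seed(36)
  ref <- reference_profile("OR4", random_cds(310L))
  tree <- waterbird_tree()
  q <- set_codon(ref$cds, 45L, "TAA")
  reps <- list(report_for(q, ref, "king_penguin"),
               report_for(q, ref, "chinstrap_penguin"),
               report_for(ref$cds, ref, "crested_ibis"))
  sh <- find_shared_disruptions(reps)
  aliases <- c(king_penguin = "emperor_penguin",
               chinstrap_penguin = "adelie_penguin")
  expect_error(infer_ancestral_loss(sh, reps, tree), "absent from the species tree")
  loss <- infer_ancestral_loss(sh, reps, tree, aliases = aliases)
  expect_equal(loss$branch[loss$evidence == "strict"], "penguins")
})

test_that("the weak-evidence rule needs a long in-frame deletion and all-pseudogene carriers", {
  set.seed(37)
  ref <- reference_profile("OR19", random_cds(310L))
  tree <- waterbird_tree()
  mk <- function(extra_stop) {
    q <- delete_at(ref$cds, 150L, 12L)
    if (!is.na(extra_stop)) q <- set_codon(q, extra_stop, "TAA")
    q
  }
  # both penguins: shared 12-bp in-frame deletion + private nonsense each
  reps <- list(report_for(mk(40L), ref, "emperor_penguin"),
               report_for(mk(70L), ref, "adelie_penguin"),
               report_for(ref$cds, ref, "northern_fulmar"))
  sh <- find_shared_disruptions(reps)
  loss <- infer_ancestral_loss(sh, reps, tree)
  expect_true(any(loss$evidence == "weak" & loss$branch == "penguins"))
  expect_false(any(loss$evidence == "strict" & loss$branch == "penguins"))
  calls <- attr(loss, "loss_calls")
  expect_true(any(calls$call == "ancestral_weak"))
  expect_false(any(calls$call == "ancestral"))
  # without the private disruptions the carriers are intact: no weak call
  reps2 <- list(report_for(mk(NA), ref, "emperor_penguin"),
                report_for(mk(NA), ref, "adelie_penguin"),
                report_for(ref$cds, ref, "northern_fulmar"))
  sh2 <- find_shared_disruptions(reps2)
  loss2 <- infer_ancestral_loss(sh2, reps2, tree)
  expect_false(any(loss2$evidence == "weak"))
})

test_that("inference is invariant to the order species are supplied", {
  set.seed(38)
  ref <- reference_profile("OR3", random_cds(310L))
  tree <- waterbird_tree()
  q <- delete_at(ref$cds, 57L, 2L)
  reps <- list(report_for(q, ref, "emperor_penguin"),
               report_for(q, ref, "adelie_penguin"),
               report_for(ref$cds, ref, "crested_ibis"))
  sh1 <- find_shared_disruptions(reps)
  sh2 <- find_shared_disruptions(rev(reps))
  expect_equal(sh1, sh2)
  l1 <- infer_ancestral_loss(sh1, reps, tree)
  l2 <- infer_ancestral_loss(sh2, rev(reps), tree)
  expect_equal(l1[order(l1$branch, l1$ref_codon), ],
               l2[order(l2$branch, l2$ref_codon), ], ignore_attr = TRUE)
})
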
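test_that("identical query is intact with an empty disruption list", {
  set.seed(10)
  ref <- reference_profile("L", random_cds(310L))
  r <- call_disruptions(ref$cds, ref)
  expect_equal(r$status, "intact")
  expect_equal(nrow(r$disruptions), 0L)
  expect_true(is.na(r$first_disruption_fraction))
  expect_false(r$frame_restored)
})

test_that("a 2-bp deletion is reported at its codon and calls a pseudogene", {
  set.seed(12)
  ref <- reference_profile("L", random_cds(310L))
  # make the deletion unambiguous: preceding base differs from the deleted run end
  q <- delete_at(ref$cds, 10L, 2L)
  r <- call_disruptions(q, ref)
  dels <- r$disruptions[r$disruptions$kind == "deletion", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$length_nt, 2L)
  nrm <- orloss:::normalize_deletion(strsplit(ref$cds, "")[[1]], 28L, 2L)
  expect_equal(dels$ref_codon, (nrm - 1L) %/% 3L + 1L)
  expect_equal(r$status, "pseudogene")
  # frameshift-induced premature stops downstream are reported as nonsense
  expect_true(all(r$disruptions$kind[r$disruptions$kind != "deletion"] == "nonsense"))
})

test_that("compensating 2-bp deletion + 2-bp insertion restores the frame", {
  set.seed(13)
  ref <- reference_profile("L", random_cds(310L))
  q <- delete_at(ref$cds, 10L, 2L)
  q <- insert_at(q, 40L, "GT")  # coordinates pre-shift by the deletion are fine here
  r <- call_disruptions(q, ref)
  expect_equal(r$status, "pseudogene")
  expect_true(r$frame_restored)
  kinds <- r$disruptions$kind
  expect_true("deletion" %in% kinds && "insertion" %in% kinds)
  # downstream of the restoring insertion the frame is clean again: no
  # nonsense calls beyond the compensated window
  ns <- r$disruptions[r$disruptions$kind == "nonsense", ]
  if (nrow(ns)) expect_true(all(ns$ref_codon <= 41L))
})

test_that("single planted edits are recovered exactly (enumerated oracle)", {
  set.seed(14)
  ref <- reference_profile("L", random_cds(310L))
  refv <- strsplit(ref$cds, "")[[1]]
  for (i in 1:100) {
    kind <- sample(c("nonsense", "deletion", "insertion"), 1)
    cpos <- sample(2:309, 1)
    if (kind == "nonsense") {
      q <- set_codon(ref$cds, cpos, sample(c("TAA", "TAG", "TGA"), 1))
      want <- c(kind = "nonsense", ref_codon = cpos, length_nt = 0L)
    } else if (kind == "deletion") {
      len <- sample(c(1L, 2L, 4L, 10L), 1)
      if (3 * (cpos - 1) + len > 927) next
      q <- delete_at(ref$cds, cpos, len)
      p <- orloss:::normalize_deletion(refv, 3L * (cpos - 1L) + 1L, len)
      want <- c(kind = "deletion", ref_codon = (p - 1L) %/% 3L + 1L, length_nt = len)
    } else {
      len <- sample(c(1L, 2L, 5L), 1)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      q <- insert_at(ref$cds, cpos, ins)
      p <- orloss:::normalize_insertion(refv, 3L * (cpos - 1L) + 1L, ins)$pos
      want <- c(kind = "insertion", ref_codon = (p - 1L) %/% 3L + 1L, length_nt = len)
    }
    r <- call_disruptions(q, ref)
    hit <- r$disruptions[r$disruptions$kind == want["kind"] &
                           r$disruptions$length_nt == as.integer(want["length_nt"]), ]
    expect_equal(nrow(hit), 1L, info = paste(i, kind, cpos))
    expect_equal(hit$ref_codon, as.integer(want["ref_codon"]),
                 info = paste(i, kind, cpos))
    expect_equal(r$status, "pseudogene")
  }
})

test_that("in-frame indels alone never call a pseudogene", {
  set.seed(15)
  ref <- reference_profile("L", random_cds(310L))
  q <- delete_at(ref$cds, 100L, 3L)
  r <- call_disruptions(q, ref)
  expect_equal(r$status, "intact")
  expect_equal(r$disruptions$kind, "deletion")
  q2 <- insert_at(ref$cds, 100L, "GGGTTT")
  r2 <- call_disruptions(q2, ref)
  expect_equal(r2$status, "intact")
})

test_that("status is invariant to synonymous substitutions", {
  set.seed(16)
  ref <- reference_profile("L", random_cds(310L))
  gc <- Biostrings::GENETIC_CODE
  q <- ref$cds
  n_swapped <- 0
  for (cpos in sample(2:309, 60)) {
    cod <- codon_at(q, cpos)
    syn <- setdiff(names(gc)[gc == gc[[cod]]], cod)
    if (length(syn)) { q <- set_codon(q, cpos, sample(syn, 1)); n_swapped <- n_swapped + 1 }
  }
  expect_gt(n_swapped, 10)
  r <- call_disruptions(q, ref)
  expect_equal(r$status, "intact")
  expect_equal(nrow(r$disruptions), 0L)
})

test_that("partial gene segments are not charged for missing flanks", {
  set.seed(17)
  ref <- reference_profile("L", random_cds(310L))
  seg <- substr(ref$cds, 301, 1200)  # 900-bp amplicon starting at codon 101
  r <- call_disruptions(seg, ref, partial = TRUE)
  expect_equal(r$status, "intact")
  expect_equal(nrow(r$disruptions), 0L)
  # a nonsense inside the segment is still found at the right codon
  seg2 <- substr(set_codon(ref$cds, 150L, "TGA"), 301, 1200)
  r2 <- call_disruptions(seg2, ref, partial = TRUE)
  expect_equal(r2$status, "pseudogene")
  expect_true(any(r2$disruptions$kind == "nonsense" &
                    r2$disruptions$ref_codon == 150L))
})

test_that("low-identity queries are flagged, not fabricated", {
  set.seed(18)
  ref <- reference_profile("L", random_cds(310L))
  unrelated <- random_cds(310L)
  expect_warning(r <- call_disruptions(unrelated, ref), "orthology suspect")
  expect_true(r$low_confidence)
  expect_error(call_disruptions("", ref))
})

test_that("terminal position classification follows the threshold fraction", {
  set.seed(19)
  ref <- reference_profile("L", random_cds(310L))
  r5 <- call_disruptions(set_codon(ref$cds, 10L, "TAA"), ref)
  expect_equal(classify_terminal_position(r5), "five_prime")
  expect_equal(r5$first_disruption_fraction, 10 / 310)
  r3 <- call_disruptions(set_codon(ref$cds, 300L, "TGA"), ref)
  expect_equal(classify_terminal_position(r3), "three_prime")
  rid <- call_disruptions(ref$cds, ref)
  expect_equal(classify_terminal_position(rid), "none")
})
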
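# dNSAF scoring, fold-change filtering, intersection and pooling.

makeCounts <- function(ids, lengths, counts, sample = "bait1", replicate = 1L,
                       shared = NULL) {
  SpectralCounts(
    proteins = data.frame(protein_id = ids, length = lengths),
    uniqueCounts = data.frame(protein_id = ids, sample = sample,
                              replicate = replicate, count = counts),
    sharedCounts = shared)
}

test_that("dNSAF reproduces the shared-peptide distribution formula", {
  sc <- makeCounts(c("A", "B"), c(100, 200), c(4, 6),
                   shared = data.frame(peptide_id = "pep1", sample = "bait1",
                                       replicate = 1L, count = 10,
                                       sharers = "A;B"))
  d <- computeDnsaf(sc, "bait1")
  expect_equal(d@table$dSpC, c(8, 12))
  expect_equal(d@table$dNSAF, c(4 / 7, 3 / 7), tolerance = 1e-12)
  # distribution conserves total counts: sum dSpC = sum uSpC + sum sSpC
  expect_equal(sum(d@table$dSpC), 4 + 6 + 10)
  # single protein, all counts unique -> dNSAF = 1
  one <- computeDnsaf(makeCounts("A", 500, 7), "bait1")
  expect_equal(one@table$dNSAF, 1)
  # all sharers with zero unique counts split the peptide equally
  sc0 <- makeCounts(c("A", "B", "C"), c(100, 100, 300), c(0, 0, 9),
                    shared = data.frame(peptide_id = "p", sample = "bait1",
                                        replicate = 1L, count = 6,
                                        sharers = "A;B"))
  d0 <- computeDnsaf(sc0, "bait1")
  expect_equal(d0@table$dSpC, c(3, 3, 9))
})

test_that("per-sample dNSAF sums to one and errors are informative", {
  sim <- simulateSpectralCounts(coipSimConfig(seed = 19L))
  for (s in c(sim$groundTruth$baits, "IgG")) {
    d <- computeDnsaf(sim$counts, s)
    expect_lt(abs(sum(d@table$dNSAF) - 1), 1e-9)
    expect_true(all(d@table$dNSAF >= 0))
  }
  expect_error(computeDnsaf(sim$counts, "nope"), "absent")
  zero <- makeCounts(c("A", "B"), c(100, 100), c(0, 0))
  expect_error(computeDnsaf(zero, "bait1"), "all-zero")
})

test_that("distributing shared counts conserves totals on simulated tables", {
  sim <- simulateSpectralCounts(coipSimConfig(sharedPeptideFraction = 0.3,
                                              seed = 23L))
  sc <- sim$counts
  for (r in 1:2) {
    d <- computeDnsaf(sc, "bait2", combine = r)
    u <- sc@uniqueCounts
    s <- sc@sharedCounts
    tot <- sum(u$count[u$sample == "bait2" & u$replicate == r]) +
      sum(s$count[s$sample == "bait2" & s$replicate == r])
    expect_equal(sum(d@table$dSpC), tot, tolerance = 1e-9)
  }
})

test_that("fold-change filtering removes FC <= 1 and keeps bait-only proteins", {
  mk <- function(vals, sample) {
    d <- computeDnsaf(makeCounts(LETTERS[1:6], rep(300, 6), vals, sample), sample)
  }
  bait <- mk(c(10, 10, 30, 0, 5, 5), "bait1")
  ctl <- mk(c(10, 20, 10, 10, 0, 5), "IgG")
  kept <- foldChangeFilter(bait, ctl)
  # brute-force per-protein ratio check
  bv <- dnsafValues(bait); cv <- dnsafValues(ctl)
  expectKeep <- names(bv)[bv > 0 & (cv[names(bv)] == 0 | bv / cv[names(bv)] > 1)]
  expect_setequal(candidateIds(kept), expectKeep)
  # equal dNSAF -> FC exactly 1 -> removed; "not greater than 1" is exclusive
  same <- mk(c(1, 2, 3, 4, 5, 6), "bait1")
  same2 <- mk(c(1, 2, 3, 4, 5, 6), "IgG")
  expect_length(candidateIds(foldChangeFilter(same, same2)), 0L)
  # detected only in bait -> infinite fold change, kept first
  expect_true("E" %in% candidateIds(kept))
  expect_equal(unname(kept@scores[candidateIds(kept) == "E"]), Inf)
})

test_that("intersection and Venn regions match brute-force enumeration", {
  l1 <- CandidateList(c("A", "B", "C"))
  l2 <- CandidateList(c("B", "C", "D"))
  l3 <- CandidateList(c("C", "E"))
  out <- intersectCandidates(list(x = l1, y = l2, z = l3))
  expect_identical(candidateIds(out$candidates), "C")
  expect_identical(out$venn[["x"]], 1L)          # A
  expect_identical(out$venn[["x&y"]], 1L)        # B
  expect_identical(out$venn[["x&y&z"]], 1L)      # C
  expect_identical(out$venn[["y"]], 1L)          # D
  expect_identical(out$venn[["z"]], 1L)          # E
  expect_identical(out$venn[["x&z"]], 0L)
  expect_identical(sum(out$venn), 5L)
  # identical lists: intersection = the list, exclusive regions empty
  outSame <- intersectCandidates(list(a = l1, b = l1, c = l1))
  expect_identical(candidateIds(outSame$candidates), candidateIds(l1))
  expect_identical(outSame$venn[["a&b&c"]], 3L)
  expect_identical(sum(outSame$venn) - outSame$venn[["a&b&c"]], 0L)
  # disjoint lists
  outDisj <- intersectCandidates(list(a = CandidateList("A"),
                                      b = CandidateList("B")))
  expect_length(candidateIds(outDisj$candidates), 0L)
  expect_error(intersectCandidates(list(l1)), ">= 2")
})

test_that("pooling takes the annotated union and warns on missing annotations", {
  l1 <- CandidateList(c("A", "B"))
  l2 <- CandidateList(c("B", "C"))
  ann <- c(A = FALSE, B = TRUE, C = TRUE)
  expect_identical(candidateIds(poolCandidates(list(l1, l2), ann)), c("B", "C"))
  # one list, all annotated true -> identity
  allTrue <- c(A = TRUE, B = TRUE)
  expect_identical(candidateIds(poolCandidates(list(l1), allTrue)), c("A", "B"))
  expect_warning(poolCandidates(list(l2), allTrue), "missing")
  # simulated three-bait run with fixed membrane labels
  sim <- simulateSpectralCounts(coipSimConfig(seed = 31L))
  igg <- computeDnsaf(sim$counts, "IgG")
  lists <- lapply(sim$groundTruth$baits, function(b)
    foldChangeFilter(computeDnsaf(sim$counts, b), igg))
  ids <- sim$counts@proteins$protein_id
  membrane <- setNames(seq_along(ids) %% 3 == 0, ids)
  pooled <- poolCandidates(lists, membrane)
  unionIds <- unique(unlist(lapply(lists, candidateIds)))
  expect_setequal(candidateIds(pooled),
                  intersect(unionIds, names(which(membrane))))
  # pool restricted to annotation contains the annotated intersection
  inter <- intersectCandidates(setNames(lists, sim$groundTruth$baits))
  expect_true(all(intersect(candidateIds(inter$candidates),
                            names(which(membrane))) %in% candidateIds(pooled)))
})

test_that("recall of true interactors does not fall as enrichment rises", {
  recall <- vapply(c(2, 5, 10), function(enr) {
    sim <- simulateSpectralCounts(coipSimConfig(baitEnrichment = enr,
                                                sharedPeptideFraction = 0,
                                                seed = 37L))
    igg <- computeDnsaf(sim$counts, "IgG")
    kept <- candidateIds(foldChangeFilter(computeDnsaf(sim$counts, "bait1"), igg))
    truth <- names(which(sim$groundTruth$interactor))
    mean(truth %in% kept)
  }, 0)
  expect_true(all(diff(recall) >= 0))
  expect_equal(recall[3], 1)
})
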
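test_that("a candidate identical to one parent is a single full segment", {
  set.seed(139)
  p <- paste0("M", rand_protein(150))
  dec <- decomposeChimera(p, c(parent = p))
  expect_equal(nrow(dec$segments), 1L)
  s <- dec$segments
  expect_equal(s$identity, 1)
  expect_equal(c(s$cand_start, s$cand_end), c(1L, 151L))
  expect_equal(c(s$parent_start, s$parent_end), c(1L, 151L))
})

test_that("synthetic fusions decompose at the planted breakpoints", {
  # exact case: no indels, no tails beyond the fused regions
  fus <- simFusion(149, candLength = 300, breakpoint = 180,
                   junctionOverlap = 0, parent1Tail = 0, parent2Head = 0,
                   nIndels = 0, nMismatches = 0)
  dec <- decomposeChimera(fus$candidate, fus$parents)
  seg <- dec$segments
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$parent_id, c("parentA", "parentB"))
  expect_equal(c(seg$cand_start[1], seg$cand_end[1]), c(1, 180))
  expect_equal(c(seg$cand_start[2], seg$cand_end[2]), c(181, 300))
  expect_equal(c(seg$parent_start[2], seg$parent_end[2]), c(1, 120))
  expect_equal(seg$insertions, c(0L, 0L))
  expect_equal(seg$identity, c(1, 1))
})

test_that("junction homology appears as overlapping segments", {
  fus <- simFusion(151, junctionOverlap = 6, parent1Tail = 0,
                   parent2Head = 0)
  dec <- decomposeChimera(fus$candidate, fus$parents)
  seg <- dec$segments
  expect_equal(nrow(seg), 2L)
  overlap <- seg$cand_end[1] - seg$cand_start[2] + 1L
  expect_equal(overlap, 6L)
})

test_that("planted indels in the N segment are reported as insertions", {
  for (sd in c(157, 163)) {
    fus <- simFusion(sd, nIndels = 2, nMismatches = 1)
    dec <- decomposeChimera(fus$candidate, fus$parents)
    seg <- dec$segments
    expect_equal(nrow(seg), 2L)
    segA <- seg[seg$parent_id == "parentA", ]
    expect_equal(segA$insertions, 2L)
    expect_lte(abs(segA$cand_end - fus$truth$breakpoint), 2)
    segB <- seg[seg$parent_id == "parentB", ]
    expect_equal(segB$cand_start, fus$truth$p2_cand_range[1])
    # the single planted mismatch sits at the terminus: the aligned core
    # may stop just short of it
    expect_gte(segB$cand_end, fus$truth$p2_cand_range[2] - 1L)
  }
})

test_that("no qualifying parent yields an empty decomposition with notice", {
  set.seed(167)
  cand <- paste0("M", rand_protein(100))
  junk <- paste0("M", rand_protein(100))
  expect_message(dec <- decomposeChimera(cand, c(p = junk)),
                 "no parental segment")
  expect_equal(nrow(dec$segments), 0L)
})

test_that("domains lift through segments, junctions and gaps correctly", {
  fus <- simFusion(173, candLength = 300, breakpoint = 180,
                   junctionOverlap = 6, parent1Tail = 30, parent2Head = 20,
                   nIndels = 0, nMismatches = 0)
  dec <- decomposeChimera(fus$candidate, fus$parents)
  doms <- data.frame(
    parent_id = c("parentA", "parentA", "parentB", "parentB"),
    name = c("inside", "junction", "junction", "orphan"),
    start = c(50, 170, 21, 200),
    end = c(90, 180, 40, 220))
  # parentB positions 21..40 correspond to candidate 175..194
  lift <- liftDomains(dec, doms)
  inside <- lift[lift$name == "inside", ]
  expect_equal(c(inside$cand_start, inside$cand_end), c(50, 90))
  expect_equal(inside$parents, "parentA")
  junction <- lift[lift$name == "junction", ]
  expect_equal(junction$parents, "parentA,parentB")
  expect_equal(c(junction$cand_start, junction$cand_end), c(170, 194))
  orphan <- lift[lift$name == "orphan", ]
  expect_true(is.na(orphan$cand_start))    # beyond parentB's aligned range
})

test_that("round-trip: lifted coordinates equal planted ones without indels", {
  fus <- simFusion(179, candLength = 250, breakpoint = 150,
                   junctionOverlap = 0, parent1Tail = 0, parent2Head = 0)
  dec <- decomposeChimera(fus$candidate, fus$parents)
  doms <- data.frame(parent_id = c("parentA", "parentB"),
                     name = c("d1", "d2"), start = c(10, 5),
                     end = c(60, 50))
  lift <- liftDomains(dec, doms)
  expect_equal(c(lift$cand_start[lift$name == "d1"],
                 lift$cand_end[lift$name == "d1"]), c(10, 60))
  # parentB position p corresponds to candidate 150 + p
  expect_equal(c(lift$cand_start[lift$name == "d2"],
                 lift$cand_end[lift$name == "d2"]), c(155, 200))
  expect_equal(lift$mapped_frac, c(1, 1))
})

test_that("segment indel counts agree with their alignment columns", {
  fus <- simFusion(181, nIndels = 3, nMismatches = 0)
  dec <- decomposeChimera(fus$candidate, fus$parents)
  for (i in seq_len(nrow(dec$segments))) {
    cols <- dec$alignments[[i]]
    expect_equal(dec$segments$insertions[i], sum(cols$parent_pos == 0L))
    expect_equal(dec$segments$deletions[i], sum(cols$cand_pos == 0L))
  }
})
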
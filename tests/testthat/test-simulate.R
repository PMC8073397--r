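test_that("generators are pure functions of the seed", {
  a <- simPanel(seed = 227, backboneLen = 5000, nPanel = 2,
                mssSpec = list(list(length = 300, presentIn = 1L)))
  b <- simPanel(seed = 227, backboneLen = 5000, nPanel = 2,
                mssSpec = list(list(length = 300, presentIn = 1L)))
  expect_identical(genomeSeq(a$query), genomeSeq(b$query))
  expect_identical(lapply(a$panel, genomeSeq), lapply(b$panel, genomeSeq))
  expect_identical(a$truth, b$truth)

  f1 <- simFusion(229); f2 <- simFusion(229)
  expect_identical(f1, f2)

  s1 <- simBulkseq(seed = 233, nSnps = 100)
  s2 <- simBulkseq(seed = 233, nSnps = 100)
  expect_identical(s1$counts, s2$counts)
  # and the global RNG stream is left untouched
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(simBulkseq(seed = 5, nSnps = 10)); y <- runif(1)
  expect_identical(x, y)
})

test_that("an empty MSS spec gives identical genomes", {
  sim <- simPanel(seed = 239, backboneLen = 4000, nPanel = 3)
  expect_true(all(vapply(sim$panel, genomeSeq, character(1)) ==
                  genomeSeq(sim$query)))
})

test_that("truth coordinates address the emitted sequences", {
  sim <- simPanel(seed = 241, backboneLen = 2e4, nPanel = 3,
                  mssSpec = list(
                    list(length = 400, presentIn = c(2), duplicate = TRUE),
                    list(length = 500, presentIn = integer(),
                         orf = list(aaLength = 80, tm = TRUE))),
                  repeatSpec = list(list(length = 1200)))
  qs <- genomeSeq(sim$query)
  for (tr in sim$truth$mss) {
    seg <- substr(qs, tr$start, tr$end)
    expect_equal(nchar(seg), tr$length)
    if (!is.null(tr$dup_start))
      expect_equal(substr(qs, tr$dup_start, tr$dup_start + tr$length - 1),
                   seg)
    # present panel genomes contain the segment verbatim, absent do not
    for (g in seq_along(sim$panel)) {
      hit <- grepl(seg, genomeSeq(sim$panel[[g]]), fixed = TRUE)
      expect_equal(hit, g %in% tr$presentIn)
    }
  }
  orf <- sim$truth$orfs[[1]]
  nt <- substr(qs, orf$start, orf$end)
  expect_equal(substr(nt, 1, 3), "ATG")
  aa <- translateCodons(nt)
  expect_equal(nchar(aa), orf$aa_length + 1L)
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("[*X]", substr(aa, 1, nchar(aa) - 1L)))
  rep1 <- sim$truth$repeats[[1]]
  expect_equal(substr(qs, rep1$copy_start, rep1$copy_start + rep1$length - 1),
               substr(genomeSeq(sim$backbone), rep1$src_start,
                      rep1$src_start + rep1$length - 1))
})

test_that("planted ORFs carry a transmembrane core when requested", {
  sim <- simPanel(seed = 251, backboneLen = 1e4, nPanel = 2,
                  mssSpec = list(list(length = 500, presentIn = integer(),
                                      orf = list(aaLength = 90, tm = TRUE))))
  orf <- sim$truth$orfs[[1]]
  aa <- translateCodons(substr(genomeSeq(sim$query), orf$start, orf$end))
  aa <- substr(aa, 1, nchar(aa) - 1L)
  expect_gt(nrow(predictTm(aa)), 0L)
})

test_that("fusion truths are respected by construction", {
  fus <- simFusion(257, candLength = 280, breakpoint = 170,
                   junctionOverlap = 5, nIndels = 2, nMismatches = 1)
  tr <- fus$truth
  expect_equal(nchar(fus$candidate), 280L)
  # the parent-2 region matches the candidate except the terminal edit
  p2 <- fus$parents[["parentB"]]
  expect_equal(substr(fus$candidate, 166, 279),
               substr(p2, tr$p2_parent_range[1],
                      tr$p2_parent_range[2] - 1L))
  expect_false(substr(fus$candidate, 280, 280) ==
               substr(p2, tr$p2_parent_range[2], tr$p2_parent_range[2]))
})

test_that("bulk simulation has the planted expectation structure", {
  nullSim <- simBulkseq(seed = 263, nSnps = 800, effect = 0)
  st <- snpStats(nullSim$counts)
  expect_lt(abs(mean(st$delta, na.rm = TRUE)), 0.02)

  fixed <- simBulkseq(seed = 269, nSnps = 400, recombRate = 0,
                      depthModel = "fixed")
  stf <- snpStats(fixed$counts)
  # no recombination, complete selection: delta is exactly 1 everywhere
  expect_true(all(stf$delta == 1))
})
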
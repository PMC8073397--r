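# Small panels keep these fast; the full-scale planted-truth recovery
# runs in the acceptance suite.

test_that("coverage profiles mark homologous positions", {
  set.seed(109)
  q <- mitoGenome("q", rand_dna(5000))
  expect_true(all(coverageProfile(q, q)))

  unrelated <- mitoGenome("u", rand_dna(5000))
  expect_false(any(coverageProfile(q, unrelated)))

  ins <- rand_dna(500)
  qs <- genomeSeq(q)
  withIns <- mitoGenome("qi", paste0(substr(qs, 1, 2500), ins,
                                     substr(qs, 2501, 5000)))
  cov <- coverageProfile(withIns, q)
  runs <- which(!cov)
  expect_gte(min(runs), 2500 - 20)
  expect_lte(max(runs), 3001 + 20)
  expect_gte(sum(!cov), 460)
})

test_that("a panel equal to the query yields no MSS", {
  set.seed(113)
  q <- mitoGenome("q", rand_dna(8000))
  mss <- detectMss(q, list(mitoGenome("p", genomeSeq(q))))
  expect_equal(nrow(mssRecords(mss)), 0L)
})

test_that("planted segments are recovered with correct presence vectors", {
  sim <- simPanel(seed = 127, backboneLen = 2e4, nPanel = 4,
                  mssSpec = list(
                    list(length = 400, presentIn = integer()),
                    list(length = 600, presentIn = c(1, 3)),
                    list(length = 300, presentIn = c(2))))
  mss <- detectMss(sim$query, sim$panel)
  rec <- mssRecords(mss)
  expect_equal(nrow(rec), 3L)
  pm <- presenceMatrix(mss)
  expect_true(all(pm[, "query"]))
  for (i in 1:3) {
    tr <- sim$truth$mss[[i]]
    j <- which(abs(rec$start - tr$start) <= 50)
    expect_length(j, 1L)
    expect_lte(abs(rec$end[j] - tr$end), 50)
    expect_equal(unname(pm[j, -1]), seq_len(4) %in% tr$presentIn)
  }
  # ids are M1..Mn in coordinate order
  expect_equal(rec$id, paste0("M", seq_len(nrow(rec))))
  expect_true(all(diff(rec$start) > 0))
})

test_that("a duplicated planted segment is counted as two copies", {
  sim <- simPanel(seed = 131, backboneLen = 2e4, nPanel = 3,
                  mssSpec = list(
                    list(length = 500, presentIn = integer(),
                         duplicate = TRUE),
                    list(length = 400, presentIn = c(1))))
  mss <- detectMss(sim$query, sim$panel)
  rec <- mssRecords(mss)
  dupRec <- findMssDuplicates(mss)
  # both loci of the duplicated segment detected, both with copies = 2
  expect_equal(nrow(dupRec), 2L)
  expect_true(all(dupRec$copies == 2L))
  # the single-copy segment is not flagged
  single <- rec[!rec$id %in% dupRec$id, ]
  expect_true(all(single$copies == 1L))
})

test_that("records marked absent have no qualifying coverage (self-consistency)", {
  sim <- simPanel(seed = 137, backboneLen = 2e4, nPanel = 3,
                  mssSpec = list(list(length = 500, presentIn = c(2))))
  mss <- detectMss(sim$query, sim$panel)
  rec <- mssRecords(mss)
  pm <- presenceMatrix(mss)
  for (r in seq_len(nrow(rec))) {
    for (j in which(!pm[r, -1])) {
      cov <- coverageProfile(sim$query, sim$panel[[j]])
      frac <- mean(cov[rec$start[r]:rec$end[r]])
      expect_lt(frac, 0.8)
    }
  }
  # merged MSS intervals are disjoint
  if (nrow(rec) > 1)
    expect_true(all(rec$start[-1] > rec$end[-nrow(rec)]))
})

test_that("ORF/MSS overlap annotation is wrap-aware", {
  orfs <- data.frame(orf_id = c("o1", "o2", "o3"),
                     start = c(100, 950, 400),
                     end = c(220, 50, 450))   # o2 wraps a 1000 bp genome
  rec <- data.frame(id = c("M1", "M2"), start = c(200, 990),
                    end = c(320, 1000), length = c(121, 11),
                    copies = c(1L, 1L))
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
                 dimnames = list(rec$id, c("q", "p")))
  mss <- new("MssSet", records = rec, presence = pres, query = "q",
             params = list())
  ov <- annotateMssOverlaps(orfs, mss, genomeLength = 1000)
  expect_equal(ov$o1, "M1")
  expect_equal(ov$o2, "M2")        # via the wrap
  expect_equal(ov$o3, character(0))
})

test_that("an ORF spanning two adjacent MSSs reports both ids", {
  rec <- data.frame(id = c("M23", "M24"), start = c(100, 301),
                    end = c(300, 500), length = c(201, 200),
                    copies = c(1L, 1L))
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
                 dimnames = list(rec$id, c("q", "p")))
  mss <- new("MssSet", records = rec, presence = pres, query = "q",
             params = list())
  orfs <- data.frame(orf_id = "orf312_1", start = 250, end = 420)
  expect_equal(annotateMssOverlaps(orfs, mss, 1000)[[1]], c("M23", "M24"))
})
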
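# End-to-end screen on small synthetic panels (the full-scale run lives
# in the acceptance suite).

.screen_sim <- function(seed = 271) {
  simPanel(seed = seed, backboneLen = 1.5e4, nPanel = 2,
           mssSpec = list(
             list(length = 500, presentIn = 1:2),
             list(length = 600, presentIn = integer(),
                  orf = list(aaLength = 85, tm = TRUE))),
           cleanOrfs = TRUE)
}

test_that("screening a genome against itself leaves no candidates", {
  set.seed(277)
  g <- mitoGenome("q", rand_dna(12000))
  cfg <- screenConfig(g, reference = g, panel = list())
  rep <- runScreen(cfg)
  expect_gt(nrow(rep@orfs), 0L)
  expect_true(all(rep@orfs$discarded))
  expect_equal(nrow(candidates(rep)), 0L)
})

test_that("a planted novel TM-bearing ORF inside an MSS is the sole candidate", {
  sim <- .screen_sim()
  cfg <- screenConfig(sim$query, reference = sim$backbone,
                      panel = sim$panel, requireMssOverlap = TRUE)
  rep <- runScreen(cfg)
  cand <- candidates(rep)
  tr <- sim$truth$orfs[[1]]
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, tr$start)
  expect_equal(cand$end, tr$end)
  expect_equal(cand$aa_length, tr$aa_length)
  expect_true(cand$has_tm)
  expect_true(nzchar(cand$mss_ids))
})

test_that("removing a required filter never decreases the candidate count", {
  sim <- .screen_sim(281)
  base <- runScreen(screenConfig(sim$query, sim$backbone, sim$panel,
                                 requireTm = TRUE,
                                 requireMssOverlap = TRUE))
  noTm <- runScreen(screenConfig(sim$query, sim$backbone, sim$panel,
                                 requireTm = FALSE,
                                 requireMssOverlap = TRUE))
  noMss <- runScreen(screenConfig(sim$query, sim$backbone, sim$panel,
                                  requireTm = TRUE,
                                  requireMssOverlap = FALSE))
  expect_gte(nrow(candidates(noTm)), nrow(candidates(base)))
  expect_gte(nrow(candidates(noMss)), nrow(candidates(base)))
})

test_that("every threshold that affects output appears in the provenance", {
  sim <- .screen_sim()
  rep <- runScreen(screenConfig(sim$query, sim$backbone, sim$panel))
  pv <- screenParams(rep)
  for (key in c("minCodons", "identityDiscard", "discardCoverage",
                "evalueMax", "requireTm", "requireMssOverlap", "tmWindow",
                "tmThreshold", "minMssLen", "mergeGap", "presenceFrac",
                "identityMin", "align", "seed", "version"))
    expect_true(key %in% names(pv), label = paste("provenance has", key))
})

test_that("report files are stable, complete and byte-identical on rerun", {
  sim <- .screen_sim()
  rep <- runScreen(screenConfig(sim$query, sim$backbone, sim$panel))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- renderReports(rep, d1)
  f2 <- renderReports(rep, d2)
  expect_setequal(basename(f1),
                  c("orfs.tsv", "candidates.tsv", "mss.tsv",
                    "presence_matrix.tsv", "tm_segments.tsv",
                    "report.json"))
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("rerun identical:", nm))
  js <- jsonlite::read_json(f1[["report"]])
  expect_true(all(c("provenance", "log", "candidates") %in% names(js)))
})

test_that("an empty screen still renders header-only files", {
  set.seed(283)
  g <- mitoGenome("q", rand_dna(9000))
  rep <- runScreen(screenConfig(g, g))
  d <- withr::local_tempdir()
  f <- renderReports(rep, d)
  expect_equal(readLines(f[["candidates"]])[1],
               "id\tstart\tend\tstrand\ttype\tattributes")
  expect_equal(length(readLines(f[["candidates"]])), 1L)
})
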
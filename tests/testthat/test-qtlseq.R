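test_that("the SNP-index follows alt/(ref+alt) with a depth floor", {
  expect_equal(snpIndex(5, 5), 0.5)
  expect_equal(snpIndex(0, 10), 1.0)
  expect_equal(snpIndex(10, 0), 0.0)
  expect_true(is.na(snpIndex(4, 5)))          # depth 9 < 10: flagged
  expect_equal(snpIndex(c(5, 2), c(5, 3)), c(0.5, NA_real_))
})

test_that("delta is antisymmetric and bounded", {
  sim <- simBulkseq(seed = 191, nSnps = 300)
  st <- snpStats(sim$counts)
  expect_true(all(abs(st$delta) <= 1, na.rm = TRUE))
  swapped <- sim$counts
  names(swapped) <- sub("bulk1", "bulkX", names(swapped))
  names(swapped) <- sub("bulk2", "bulk1", names(swapped))
  names(swapped) <- sub("bulkX", "bulk2", names(swapped))
  st2 <- snpStats(swapped)
  expect_equal(st$delta, -st2$delta)
})

test_that("window means follow the plain averaging oracle", {
  sim <- simBulkseq(seed = 193, nSnps = 500, chromLen = 5e6,
                    qtlPos = 2.5e6)
  st <- snpStats(sim$counts)
  w <- deltaWindows(st, windowBp = 1e6, stepBp = 2e5)
  want <- oracle_window_means(st, w$start, 1e6)
  expect_equal(w$mean_delta, want)
  expect_true(all(w$n_snps[is.na(w$mean_delta)] == 0))
})

test_that("identical bulks give zero deltas and empty QTL calls", {
  set.seed(197)
  n <- 200
  pos <- sort(sample.int(4e6, n))
  ref <- rbinom(n, 30, .5); alt <- 30 - ref
  tab <- data.frame(chrom = "c1", pos = pos,
                    ref_count_bulk1 = ref, alt_count_bulk1 = alt,
                    ref_count_bulk2 = ref, alt_count_bulk2 = alt)
  st <- snpStats(tab)
  expect_true(all(st$delta == 0, na.rm = TRUE))
  w <- attachConfidence(deltaWindows(st, 1e6, 2e5), nSims = 1000,
                        seed = 1)
  expect_equal(nrow(callQtl(w)), 0L)
})

test_that("a single extreme SNP dominates its window", {
  tab <- data.frame(chrom = "c1", pos = c(100, 3e6),
                    ref_count_bulk1 = c(0, 10), alt_count_bulk1 = c(20, 10),
                    ref_count_bulk2 = c(20, 10), alt_count_bulk2 = c(0, 10))
  w <- deltaWindows(snpStats(tab), windowBp = 1e6, stepBp = 1e6)
  expect_equal(w$mean_delta[1], 1.0)
  expect_equal(w$n_snps[1], 1L)
})

test_that("null bands are symmetric, seeded and tighten with depth", {
  b1 <- nullConfidence(c(30, 100), nSims = 4000, seed = 7)
  b2 <- nullConfidence(c(30, 100), nSims = 4000, seed = 7)
  expect_identical(b1, b2)                        # determinism under seed
  expect_lt(abs(b1$ci95_lo[1] + b1$ci95_hi[1]), 0.05)  # symmetry
  expect_lt(b1$ci95_hi[2], b1$ci95_hi[1])         # deeper: narrower
  expect_true(all(b1$ci99_hi >= b1$ci95_hi))
  # wide-depth, large-bulk limit approaches zero width
  b3 <- nullConfidence(5000, bulkSize = 2000, nSims = 4000, seed = 7)
  expect_lt(b3$ci95_hi, 0.05)
})

test_that("a planted restorer locus is localized; two loci give two calls", {
  sim <- simBulkseq(seed = 199)
  w <- attachConfidence(deltaWindows(snpStats(sim$counts)),
                        nSims = 2000, seed = 3)
  q <- callQtl(w)
  expect_equal(nrow(q), 1L)
  expect_true(q$start <= sim$truth$qtl_pos && sim$truth$qtl_pos <= q$end)
  expect_lte(abs(q$peak_mid - sim$truth$qtl_pos), 2e6)

  sim2 <- simBulkseq(seed = 211, chromLen = 2e7, qtlPos = 1e7,
                     chrom = "chr02")
  both <- rbind(sim$counts, sim2$counts)
  w2 <- attachConfidence(deltaWindows(snpStats(both)), nSims = 2000,
                         seed = 3)
  q2 <- callQtl(w2)
  expect_equal(sort(unique(q2$chrom)), c("chr02", "chr10"))
})

test_that("effect-free simulation stays inside the bands nearly everywhere", {
  sim <- simBulkseq(seed = 223, effect = 0)
  w <- attachConfidence(deltaWindows(snpStats(sim$counts)),
                        nSims = 2000, seed = 5)
  q <- callQtl(w)
  # isolated noise windows may poke out; no broad signal
  expect_lte(sum(q$n_windows), 40)
})
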
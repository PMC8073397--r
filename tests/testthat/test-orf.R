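test_that("translation follows the standard code with N and stop handling", {
  expect_equal(translateCodons("ATGTAA"), "M*")
  expect_equal(translateCodons("ATGANT"), "MX")
  expect_error(translateCodons("ATGTA"), "divisible")
  set.seed(23)
  nt <- rand_dna(300)
  expect_equal(translateCodons(nt),
               as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                                  no.init.codon = TRUE)))
})

.orf_of <- function(naa) paste0("ATG", strrep("GCT", naa - 1L), "TAA")

test_that("the codon threshold is an exact boundary", {
  pad <- "CCTTCCTTCC"  # no ATG, no stop in any frame needed: flanks
  g70 <- mitoGenome("x", paste0(pad, .orf_of(70), pad), circular = FALSE)
  g69 <- mitoGenome("x", paste0(pad, .orf_of(69), pad), circular = FALSE)
  expect_equal(nrow(findOrfs(g70, 70)), 1L)
  expect_equal(findOrfs(g70, 70)$aa_length, 70L)
  expect_equal(nrow(findOrfs(g69, 70)), 0L)
})

test_that("a reverse-strand ORF spanning 939 nt encodes 312 aa", {
  set.seed(41)
  orf <- rand_orf(312)                   # 312 aa + stop = 939 nt
  expect_equal(nchar(orf), 939)
  # an in-frame stop upstream of the ATG pins the ORF start
  g <- mitoGenome("x", paste0(rand_dna(500), revComp(paste0("TAA", orf)),
                              rand_dna(497)), circular = FALSE)
  res <- findOrfs(g, 300)
  res <- res[res$strand == -1L, ]
  expect_equal(nrow(res), 1L)
  expect_equal(res$aa_length, 312L)
  expect_equal(res$end - res$start + 1L, 939L)
  expect_equal(c(res$start, res$end), c(501L, 1439L))
})

test_that("ORFs wrapping the circular origin are reported once", {
  set.seed(43)
  orf <- paste0("TAA", .orf_of(80))  # in-frame stop marks the ORF start
  # place the ORF so it spans the origin: last 103 nt then the remainder
  tailPart <- substr(orf, 1, 103)
  headPart <- substr(orf, 104, nchar(orf))
  g <- mitoGenome("c", paste0(headPart, rand_dna(2000), tailPart))
  res <- findOrfs(g, 80)
  res <- res[res$aa_seq == paste0("M", strrep("A", 79)), ]
  expect_equal(nrow(res), 1L)
  expect_true(res$wraps)
  expect_equal(res$start, nchar(genomeSeq(g)) - 100L + 1L)
  expect_equal(intervalLength(res$start, res$end, genomeLength(g)),
               nchar(orf) - 3L)
})

test_that("N codons terminate ORFs without yielding one across them", {
  g <- mitoGenome("n", paste0("ATG", strrep("GCT", 40), "ANT",
                              strrep("GCT", 40), "TAA"), circular = FALSE)
  expect_equal(nrow(findOrfs(g, 40)), 0L)
})

test_that("the scanner agrees with a brute-force six-frame oracle", {
  set.seed(47)
  for (circ in c(TRUE, FALSE)) {
    s <- rand_dna(3000)
    got <- findOrfs(mitoGenome("g", s, circ), 25)
    want <- oracle_orfs(s, circ, 25)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, unname(want[, "start"]))
    expect_equal(got$end, unname(want[, "end"]))
    expect_equal(got$strand, unname(want[, "strand"]))
    expect_equal(got$aa_length, unname(want[, "aa"]))
  }
})

test_that("rotating the origin permutes coordinates but not proteins", {
  set.seed(53)
  s <- rand_dna(2500)
  rot <- paste0(substr(s, 1001, 2500), substr(s, 1, 1000))
  a <- findOrfs(mitoGenome("a", s), 25)
  b <- findOrfs(mitoGenome("b", rot), 25)
  expect_equal(sort(a$aa_seq), sort(b$aa_seq))
})

test_that("reported ORFs never contain an internal stop", {
  set.seed(59)
  s <- rand_dna(4000)
  res <- findOrfs(mitoGenome("g", s), 25)
  expect_gt(nrow(res), 0L)
  expect_false(any(grepl("[*X]", res$aa_seq)))
  expect_true(all(substr(res$aa_seq, 1, 1) == "M"))
  expect_true(all(res$aa_length == nchar(res$aa_seq)))
})
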
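test_that("chord distance has its closed form on binary profiles", {
  const <- 2 * sqrt(2) / pi
  m <- cbind(a = c(TRUE, FALSE, TRUE), b = c(TRUE, FALSE, TRUE))
  expect_equal(cseDistance(m)["a", "b"], 0)

  for (L in c(1, 5, 40)) {          # all loci differ: constant distance
    m2 <- cbind(a = rep(TRUE, L), b = rep(FALSE, L))
    expect_equal(cseDistance(m2)["a", "b"], const)
  }
  expect_equal(const, 0.9003163, tolerance = 1e-6)

  m3 <- cbind(a = rep(TRUE, 10), b = c(rep(FALSE, 3), rep(TRUE, 7)))
  expect_equal(cseDistance(m3)["a", "b"], 0.3 * const)

  expect_error(cseDistance(matrix(logical(), 0, 2)), "locus")
})

test_that("chord distance is a metric on binary profiles", {
  set.seed(71)
  m <- matrix(sample(c(TRUE, FALSE), 60, TRUE), nrow = 12,
              dimnames = list(NULL, paste0("g", 1:5)))
  d <- cseDistance(m)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # identity of indiscernibles
  ident <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)
  for (r in seq_len(nrow(ident)))
    expect_equal(m[, ident[r, 1]], m[, ident[r, 2]])
})

test_that("UPGMA reproduces the hand-computed example and is deterministic", {
  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(newickString(upgmaTree(d)),
               "((A:0.1,B:0.1):0.2,C:0.3);")

  # all distances equal: merge order fixed by the lexicographic tie rule
  d2 <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d2) <- 0
  expect_equal(newickString(upgmaTree(d2)),
               newickString(upgmaTree(d2[c(3, 1, 4, 2), c(3, 1, 4, 2)])))
  expect_match(newickString(upgmaTree(d2)), "\\(a:0\\.2,b:0\\.2\\)")
})

test_that("UPGMA agrees with a naive average-of-leaf-pairs oracle", {
  set.seed(73)
  for (rep in 1:20) {
    n <- 5
    x <- matrix(runif(n * n), n)
    d <- (x + t(x)) / 2
    diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("t", 1:n)
    expect_equal(newickString(upgmaTree(d)), oracle_upgma_newick(d))
  }
})

test_that("emitted Newick round-trips through an independent parser", {
  skip_if_not_installed("ape")
  set.seed(79)
  x <- matrix(runif(36), 6)
  d <- (x + t(x)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:6)
  tr <- upgmaTree(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, paste0("g", 1:6))
  # ultrametric with every root-to-leaf depth equal to the tree height
  depths <- ape::node.depth.edgelength(ph)[seq_len(6)]
  expect_equal(depths, rep(tr$height, 6), tolerance = 1e-6)
  # topology matches an independent UPGMA implementation
  skip_if_not_installed("phangorn")
  ph2 <- phangorn::upgma(as.dist(d))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ph), ape::unroot(ph2))), 0)
})

test_that("labels with spaces are quoted in Newick output", {
  d <- matrix(c(0, .3, .3, 0), 2,
              dimnames = list(c("tip one", "b"), c("tip one", "b")))
  s <- newickString(upgmaTree(d))
  expect_match(s, "'tip one'", fixed = TRUE)
})

test_that("UPGMA recovers a planted nesting of shared insertions", {
  # presence profiles with a known nesting: (((q,p1),p2),p3)
  m <- rbind(c(TRUE, TRUE, FALSE, FALSE),   # q,p1 only
             c(TRUE, TRUE, TRUE, FALSE),    # shared by q,p1,p2
             c(TRUE, TRUE, TRUE, FALSE),
             c(TRUE, TRUE, TRUE, FALSE))
  colnames(m) <- c("q", "p1", "p2", "p3")
  tr <- upgmaTree(cseDistance(m))
  expect_true(isMonophyletic(tr, c("q", "p1")))
  expect_true(isMonophyletic(tr, c("q", "p1", "p2")))
})
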
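test_that("NJ recovers the 4-taxon additive example with exact lengths", {
  # additive matrix of ((A:1,B:2):1,(C:1,D:3))
  m <- matrix(c(0, 3, 3, 5,
                3, 0, 4, 6,
                3, 4, 0, 4,
                5, 6, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(m)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, LETTERS[1:4])
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:3):0);")
  expect_identical(rf_distance(tr, truth), 0L)
  # exact branch lengths: compare leaf-to-leaf path lengths
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]],
               m, tolerance = 1e-8)
})

test_that("three taxa resolve by the closed three-point formulas", {
  m <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c")))
  tr <- neighbor_joining(m)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 9)
  expect_equal(d["b", "c"], 10)
  # (ab + ac - bc) / 2 = 2 on the a edge
  expect_equal(sort(tr$edge.length), sort(c(2, 3, 7)))
})

test_that("an equidistant matrix yields a star-like tree", {
  n <- 5L
  m <- matrix(1, n, n); diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  tr <- neighbor_joining(m)
  expect_setequal(tr$tip.label, letters[1:n])
  # internal branches all zero
  internal <- tr$edge[, 2L] > length(tr$tip.label)
  expect_equal(unname(tr$edge.length[internal]), rep(0, sum(internal)))
})

test_that("NJ and BioNJ exactly recover random additive matrices", {
  for (s in 1:20) {
    case <- random_additive_case(sample(5:8, 1L), seed = 1000 + s)
    for (fn in list(neighbor_joining, bionj)) {
      tr <- fn(case$matrix)
      expect_identical(rf_distance(tr, case$tree), 0L)
      expect_equal(ape::cophenetic.phylo(tr)[rownames(case$matrix),
                                             colnames(case$matrix)],
                   case$matrix, tolerance = 1e-6)
    }
  }
})

test_that("package NJ/BioNJ topologies agree with the ape implementations", {
  # independent cross-check on noisy (non-additive) matrices
  for (s in 1:5) {
    case <- random_additive_case(7L, seed = 2000 + s)
    set.seed(s)
    noise <- matrix(runif(49, 0, 0.05), 7, 7)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    m <- case$matrix + noise
    expect_identical(rf_distance(neighbor_joining(m),
                                 ape::nj(stats::as.dist(m))), 0L)
    expect_identical(rf_distance(bionj(m),
                                 ape::bionj(stats::as.dist(m))), 0L)
  }
})

test_that("perturbed matrices still give valid binary trees", {
  case <- random_additive_case(8L, seed = 3000)
  set.seed(3000)
  noise <- matrix(runif(64, 0, 0.2), 8, 8)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  for (fn in list(neighbor_joining, bionj)) {
    tr <- fn(case$matrix + noise)
    expect_setequal(tr$tip.label, rownames(case$matrix))
    expect_true(all(tr$edge.length >= 0))  # negatives clamped
  }
})

test_that("malformed matrices are rejected", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3.5, 0), 3, 3)
  expect_error(neighbor_joining(m), "not symmetric")
  m2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(neighbor_joining(m2), "at least 3")
  m3 <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(m3), "NA")
})

test_that("Newick serialization round-trips exactly", {
  txt <- "(A:1,B:2,(C:1,D:3):1);"
  tr <- from_newick(txt)
  expect_identical(to_newick(tr), txt)
  tr2 <- from_newick(to_newick(tr))
  expect_identical(rf_distance(tr, tr2), 0L)
  expect_identical(tr2$edge.length, tr$edge.length)
  f <- withr::local_tempfile(fileext = ".nwk")
  to_newick(tr, f)
  expect_identical(to_newick(from_newick(f)), txt)
  expect_error(from_newick("(A:1,(B:2);"), "unbalanced")
  expect_error(from_newick("(A:1,A:2,B:1);"), "duplicate leaf")
})

test_that("RF distance behaves like a metric on tree space", {
  t1 <- from_newick("((A,B),(C,D));")
  t2 <- from_newick("((A,C),(B,D));")
  expect_identical(rf_distance(t1, t1), 0L)
  expect_identical(rf_distance(t1, t2), 2L)
  expect_identical(rf_distance(t1, t2), rf_distance(t2, t1))
  set.seed(4000)
  for (r in 1:5) {
    trees <- lapply(1:3, function(i) ape::rtree(8L, tip.label = letters[1:8]))
    d12 <- rf_distance(trees[[1L]], trees[[2L]])
    d13 <- rf_distance(trees[[1L]], trees[[3L]])
    d23 <- rf_distance(trees[[2L]], trees[[3L]])
    expect_lte(d13, d12 + d23)  # triangle inequality
  }
  expect_error(rf_distance(t1, from_newick("((A,B),(C,E));")),
               "leaf sets differ")
})
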
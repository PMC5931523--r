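test_that("synthetic root proteomes honor their contract", {
  p <- synth_root_proteome(100L, 300L, seed = 1)
  expect_identical(length(p$id), 100L)
  expect_true(all(nchar(p$seq) >= 40L))
  expect_false(anyDuplicated(p$id) > 0)
  # determinism
  q <- synth_root_proteome(100L, 300L, seed = 1)
  expect_identical(p, q)
  # law of large numbers on the stated log-normal length model
  big <- synth_root_proteome(1000L, 300L, seed = 2)
  expect_lt(abs(mean(nchar(big$seq)) - 300) / 300, 0.15)
})

test_that("mutation changes exactly the requested number of positions", {
  set.seed(2)
  p <- tiny_proteome(12L, 90L, "mut")
  expect_identical(mutate_proteome(p, 0)$seq, p$seq)
  q <- mutate_proteome(p, 0.25, seed = 3)
  expect_identical(q$id, p$id)
  expect_identical(nchar(q$seq), nchar(p$seq))
  orig <- strsplit(paste(p$seq, collapse = ""), "")[[1L]]
  mut <- strsplit(paste(q$seq, collapse = ""), "")[[1L]]
  changed <- sum(orig != mut)
  k <- round(0.25 * total_residues(p))
  # k positions redrawn; each keeps its letter with probability 1/20
  expect_lte(changed, k)
  expect_gt(changed, k * 0.85)
})

test_that("one mutation round changes ~ fraction * 19/20 of residues", {
  set.seed(4)
  p <- tiny_proteome(25L, 400L, "m1")  # 10,000 residues
  N <- total_residues(p)
  for (f in c(0.2, 1)) {
    q <- mutate_proteome(p, f)
    orig <- strsplit(paste(p$seq, collapse = ""), "")[[1L]]
    mut <- strsplit(paste(q$seq, collapse = ""), "")[[1L]]
    obs <- mean(orig != mut)
    expected <- f * 19 / 20
    sigma <- sqrt(expected * (1 - expected) / N)
    expect_lt(abs(obs - expected), 4 * sigma + 1e-9)
  }
  # exclude_self draws from the 19 other residues: all selected sites change
  q19 <- mutate_proteome(p, 1, exclude_self = TRUE)
  expect_true(all(strsplit(paste(p$seq, collapse = ""), "")[[1L]] !=
                    strsplit(paste(q19$seq, collapse = ""), "")[[1L]]))
})

test_that("lineage evolution is reproducible and correctly shaped", {
  root <- synth_root_proteome(20L, 80L, seed = 5)
  rec <- evolve_lineages(root, 3L, 0.2, seed = 6)
  expect_identical(length(rec$leaves), 8L)
  expect_identical(sort(names(rec$leaves)), sort(rec$true_tree$tip.label))
  expect_true(ape::is.binary(rec$true_tree))
  # every leaf sits at depth = generations in the true tree
  depths <- ape::node.depth.edgelength(rec$true_tree)[
    seq_along(rec$true_tree$tip.label)]
  expect_equal(unname(depths), rep(3, 8))
  rec2 <- evolve_lineages(root, 3L, 0.2, seed = 6)
  expect_identical(rec$leaves, rec2$leaves)  # bit-reproducible
})

test_that("one generation diverges children by ~ fraction * 19/20", {
  root <- synth_root_proteome(25L, 400L, seed = 7)
  rec <- evolve_lineages(root, 1L, 0.2, seed = 8)
  N <- total_residues(root)
  for (leaf in rec$leaves) {
    orig <- strsplit(paste(root$seq, collapse = ""), "")[[1L]]
    mut <- strsplit(paste(leaf$seq, collapse = ""), "")[[1L]]
    obs <- mean(orig != mut)
    expected <- 0.2 * 19 / 20
    sigma <- sqrt(expected * (1 - expected) / N)
    expect_lt(abs(obs - expected), 4 * sigma)
  }
})

test_that("MRCA generations decode from leaf paths and match the tree", {
  root <- synth_root_proteome(15L, 60L, seed = 9)
  rec <- evolve_lineages(root, 5L, 0.1, seed = 10)
  expect_identical(mrca_generation("n00000", "n00001", rec), 5L)  # siblings
  expect_identical(mrca_generation("n00000", "n10000", rec), 1L)  # root split
  expect_error(mrca_generation("n00000", "nXXXXX", rec), "unknown leaf")
  # oracle: depth of the MRCA node in the stored true tree, all leaf pairs
  tr <- rec$true_tree
  depth <- ape::node.depth.edgelength(tr)
  pairs <- utils::combn(names(rec$leaves), 2L)
  for (k in sample(ncol(pairs), 60L)) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    mrca_node <- ape::getMRCA(tr, c(a, b))
    expect_identical(mrca_generation(a, b, rec),
                     as.integer(round(depth[mrca_node])) + 1L)
  }
})

test_that("lateral gene transfer replaces exactly the requested genes", {
  root <- synth_root_proteome(100L, 60L, seed = 11)
  rec <- evolve_lineages(root, 2L, 0.2, seed = 12)
  donor <- rec$leaves[["n00"]]
  recip <- rec$leaves[["n11"]]
  r0 <- inject_lgt(donor, recip, 0, seed = 13)
  expect_identical(r0$proteome$seq, recip$seq)
  r <- inject_lgt(donor, recip, 0.5, seed = 14)
  expect_identical(length(r$event$transferred_ids), 50L)
  expect_identical(length(r$proteome$id), length(recip$id))  # size conserved
  expect_identical(r$proteome$seq[r$event$positions],
                   donor$seq[r$event$positions])
  untouched <- setdiff(seq_along(recip$id), r$event$positions)
  expect_identical(r$proteome$seq[untouched], recip$seq[untouched])
  # additive mode appends under fresh IDs
  ra <- inject_lgt(donor, recip, 0.3, seed = 15, mode = "add")
  expect_identical(length(ra$proteome$id), 130L)
  expect_false(anyDuplicated(ra$proteome$id) > 0)
})
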
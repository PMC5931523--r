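test_that("pair distance is one minus the mean of the two slopes", {
  mk <- function(s, src, tgt) {
    f <- fit_T_slope(data.frame(x = c(-100, -50), y = s * c(-100, -50)))
    f$source <- src; f$target <- tgt
    f
  }
  expect_equal(pair_distance(mk(0.9, "a", "b"), mk(0.7, "b", "a")), 0.2)
  expect_equal(pair_distance(mk(1, "a", "b"), mk(1, "b", "a")), 0)
  expect_equal(pair_distance(mk(0, "a", "b"), mk(0, "b", "a")), 1)
  expect_error(pair_distance(mk(0.9, "a", "b"), mk(0.7, "c", "a")),
               "not the two directions")
})

test_that("identical proteomes are at distance exactly zero", {
  X <- tiny_proteome(8L, 60L, "z1", seed = 81)
  X2 <- X; X2$organism_id <- "z2"
  X3 <- X; X3$organism_id <- "z3"
  dm <- distance_matrix(list(X, X2, X3))
  m <- as.matrix(dm)
  expect_equal(max(abs(m)), 0)
  expect_identical(attr(dm, "kind"), "raw_D")
})

test_that("distance matrices are symmetric, zero-diagonal, and in [0, 1]", {
  set.seed(82)
  X <- tiny_proteome(8L, 60L, "m0")
  Y <- mutate_proteome(X, 0.3); Y$organism_id <- "m1"
  Z <- mutate_proteome(Y, 0.3); Z$organism_id <- "m2"
  dm <- distance_matrix(list(X, Y, Z))
  m <- as.matrix(dm)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(m >= 0 & m <= 1))
  sl <- attr(dm, "slopes")
  expect_identical(nrow(sl), 6L)  # both directions of all 3 pairs
  expect_true(all(sl$slope >= 0 & sl$slope <= 1))
})

test_that("D grows monotonically with cumulative mutation load", {
  for (s in 1:3) {
    set.seed(s)
    X <- tiny_proteome(10L, 80L, "base")
    one <- mutate_proteome(X, 0.1); one$organism_id <- "one"
    five <- one
    for (k in 2:5) five <- mutate_proteome(five, 0.1)
    five$organism_id <- "five"
    dm <- as.matrix(distance_matrix(list(X, one, five)))
    expect_lt(dm["base", "one"], dm["base", "five"])
  }
})

test_that("reciprocal mode fits on a subset of the directional points", {
  set.seed(83)
  X <- tiny_proteome(10L, 60L, "r0")
  Y <- mutate_proteome(X, 0.45); Y$organism_id <- "r1"
  Z <- mutate_proteome(X, 0.45); Z$organism_id <- "r2"
  dir_m <- distance_matrix(list(X, Y, Z), mode = "directional")
  rec_m <- distance_matrix(list(X, Y, Z), mode = "reciprocal")
  sd_ <- attr(dir_m, "slopes")
  sr <- attr(rec_m, "slopes")
  key <- paste(sd_$source, sd_$target)
  expect_identical(key, paste(sr$source, sr$target))
  expect_true(all(sr$n_points <= sd_$n_points))
  expect_identical(attr(rec_m, "kind"), "reciprocal_D")
})

test_that("PHYLIP square matrices round-trip", {
  set.seed(84)
  m <- matrix(runif(16), 4, 4)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(c("alpha", "beta", "gamma", "delta"),
                      c("alpha", "beta", "gamma", "delta"))
  f <- withr::local_tempfile(fileext = ".phy")
  write_phylip(m, f)
  m2 <- read_phylip(f)
  expect_identical(rownames(m2), rownames(m))
  expect_equal(m2, m, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dimnames(m2), dimnames(m))
})

test_that("degenerate proteomes are rejected with the organism named", {
  # 80 single-alanine proteins: every self-score is 4, so every self
  # E-value is K * 1 * 80 * exp(-lambda * 4) = 1.13 >= 1 -> no eligible point
  bad <- proteome(setNames(rep("A", 80), sprintf("s%02d", 1:80)), "shorty")
  X <- tiny_proteome(8L, 60L, "okA", seed = 85)
  Y <- tiny_proteome(8L, 60L, "okB", seed = 86)
  expect_error(distance_matrix(list(bad, X, Y)), "shorty")
})
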
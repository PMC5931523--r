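test_that("self-search yields E = E_best on every row", {
  X <- tiny_proteome(8L, 50L, "selfy", seed = 11)
  tab <- directed_best_hits(X, X)
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$target_id, tab$query_id)
  expect_equal(tab$evalue, tab$self_best)
  expect_true(all(tab$self_best <= tab$evalue))
})

test_that("E_best <= E holds for all rows against a diverged target", {
  set.seed(12)
  X <- tiny_proteome(8L, 60L, "qx")
  Y <- mutate_proteome(X, 0.6)
  Y$organism_id <- "qy"
  tab <- directed_best_hits(X, Y)
  expect_identical(nrow(tab), length(X$id))
  expect_true(all(tab$self_best <= tab$evalue))
  expect_true(all(tab$evalue >= search_params()$e_floor &
                    tab$evalue <= search_params()$e_ceiling))
})

test_that("deeply mutated targets produce rows at the E ceiling", {
  set.seed(13)
  X <- tiny_proteome(12L, 45L, "deepx")
  Y <- X
  for (k in 1:6) Y <- mutate_proteome(Y, 0.2)
  Y$organism_id <- "deepy"
  tab <- directed_best_hits(X, Y)
  # near-ceiling E-values (around 10^1) for a sizable share of short queries
  expect_gt(sum(tab$evalue > 1e-3), 0)
})

test_that("ties go to the lexicographically smallest target ID", {
  X <- proteome(c(q = "MKVLAWGHE"), "tx")
  Y <- proteome(c(zz = "MKVLAWGHE", aa = "MKVLAWGHE", mm = "WWWW"), "ty")
  tab <- directed_best_hits(X, Y)
  expect_identical(tab$target_id, "aa")
})

test_that("queries with no detectable hit get the ceiling and no target", {
  # q2 is a G homopolymer and the targets contain no G (G scores <= 0
  # against every other residue), so its best attainable score is 0 and its
  # pre-clamp E-value K*m*n exceeds the ceiling: a guaranteed no-hit.
  set.seed(61)
  q1 <- paste(sample(setdiff(aa20, "G"), 60, replace = TRUE), collapse = "")
  X <- proteome(c(q1 = q1, q2 = strrep("G", 60)), "nx")
  Y <- proteome(c(t1 = q1, t2 = strrep("A", 300)), "ny")
  tab <- directed_best_hits(X, Y)
  expect_identical(tab$target_id[1L], "t1")
  expect_true(is.na(tab$target_id[2L]))
  expect_identical(tab$evalue[2L], search_params()$e_ceiling)
  empty <- structure(list(organism_id = "e", id = character(),
                          seq = character()), class = "proteome")
  expect_error(directed_best_hits(X, empty), "empty")
})

test_that("reciprocal flags follow the reverse search", {
  X <- tiny_proteome(6L, 50L, "rx", seed = 21)
  Y <- mutate_proteome(X, 0.3)
  Y$organism_id <- "ry"
  xy <- directed_best_hits(X, Y)
  yx <- directed_best_hits(Y, X)
  fl <- reciprocal_flag(xy, yx)
  back <- setNames(yx$target_id, yx$query_id)
  manual <- !is.na(fl$target_id) & back[fl$target_id] == fl$query_id
  expect_identical(fl$reciprocal, unname(manual))
  # self tables: everything reciprocal
  xx <- directed_best_hits(X, X)
  expect_true(all(reciprocal_flag(xx, xx)$reciprocal))
  # mismatched pair is an error
  expect_error(reciprocal_flag(xy, xy), "not the two directions")
})

test_that("reciprocal flags disagree when the reverse search moves on", {
  # y5 prefers x2 even though x1's best hit is y5
  X <- proteome(c(x1 = "MKVLAWGHEDR", x2 = "MKVLAWGHEDRNQSTPIY"), "fx")
  Y <- proteome(c(y5 = "MKVLAWGHEDRNQSTPIY"), "fy")
  xy <- directed_best_hits(X, Y)
  yx <- directed_best_hits(Y, X)
  fl <- reciprocal_flag(xy, yx)
  expect_identical(fl$reciprocal, c(FALSE, TRUE))
})

test_that("tabular import selects best rows, clamps, and fills no-hits", {
  X <- tiny_proteome(3L, 40L, "px", seed = 31)
  Y <- tiny_proteome(4L, 40L, "py", seed = 32)
  f <- withr::local_tempfile(fileext = ".tsv")
  row <- function(q, s, e, bits)
    paste(q, s, "45.0", "40", "20", "1", "1", "40", "1", "40", e, bits,
          sep = "\t")
  writeLines(c(row("p01", "p02", "1e-50", 180),
               row("p01", "p01", "1e-30", 120),
               row("p02", "p03", "0.0", 300)), f)
  tab <- parse_tabular_hits(f, X, Y)
  expect_identical(tab$query_id, X$id)
  expect_identical(tab$target_id[1:2], c("p02", "p03"))
  expect_identical(tab$evalue[1L], 1e-50)
  expect_identical(tab$evalue[2L], search_params()$e_floor)  # 0.0 clamped
  expect_true(is.na(tab$target_id[3L]))                      # fill rule
  expect_identical(tab$evalue[3L], search_params()$e_ceiling)
})

test_that("tabular import rejects malformed rows and unknown queries", {
  X <- tiny_proteome(2L, 40L, "ex", seed = 41)
  Y <- tiny_proteome(2L, 40L, "ey", seed = 42)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p01\tp02\t1e-5", f)
  expect_error(parse_tabular_hits(f, X, Y), "line 1.*12")
  writeLines(paste(c("nope", "p01", rep("0", 8), "1e-5", "50"),
                   collapse = "\t"), f)
  expect_error(parse_tabular_hits(f, X, Y), "query ID.*nope")
})

test_that("internal results exported as TSV re-import to the same best hits", {
  X <- tiny_proteome(5L, 50L, "wx", seed = 51)
  Y <- mutate_proteome(X, 0.25)
  Y$organism_id <- "wy"
  tab <- directed_best_hits(X, Y)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(tab, f)
  tab2 <- parse_tabular_hits(f, X, Y)
  expect_identical(tab2$target_id, tab$target_id)
  expect_equal(log10(tab2$evalue), log10(tab$evalue), tolerance = 0.01)
})
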
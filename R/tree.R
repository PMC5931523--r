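# Distance-matrix tree reconstruction: neighbor joining and BioNJ, with
# deterministic tie-breaking (smallest row-index pair) and negative branch
# estimates clamped to zero with the deficit absorbed into the sibling edge.
# ape::nj / ape::bionj are used only as independent cross-checks in tests.

.check_dist_input <- function(m) {
  if (inherits(m, "proteome_dist")) m <- as.matrix.proteome_dist(m)
  if (inherits(m, "dist")) m <- as.matrix(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("t", seq_len(nrow(m))),
                        paste0("t", seq_len(nrow(m))))
  if (any(!is.finite(m))) stop("distance matrix contains NA/NaN/Inf entries")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal is not zero")
  m
}

# Shared agglomeration; `bionj` switches on the variance-weighted reduction
# (Gascuel 1997), otherwise the classical NJ reduction (lambda = 1/2).
.agglomerate <- function(d, bionj = FALSE) {
  labs <- rownames(d)
  frag <- labs
  v <- d  # variance estimates; only used by BioNJ
  fmt <- function(x) sprintf("%.8g", x)
  while (nrow(d) > 3L) {
    n <- nrow(d)
    S <- rowSums(d)
    q <- (n - 2) * d - outer(S, S, "+")
    diag(q) <- Inf
    # deterministic argmin: smallest (i, j) index pair among exact ties
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    bi <- d[i, j] / 2 + (S[i] - S[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    lam <- 0.5
    if (bionj) {
      denom <- 2 * (n - 2) * v[i, j]
      if (denom > 0) {
        k <- setdiff(seq_len(n), c(i, j))
        lam <- 0.5 + sum(v[j, k] - v[i, k]) / denom
        lam <- min(max(lam, 0), 1)
      }
    }
    k <- setdiff(seq_len(n), c(i, j))
    du <- lam * (d[i, k] - bi) + (1 - lam) * (d[j, k] - bj)
    vu <- lam * v[i, k] + (1 - lam) * v[j, k] - lam * (1 - lam) * v[i, j]
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":",
                      fmt(bj), ")")
    keep <- setdiff(seq_len(n), j)
    d <- d[keep, keep, drop = FALSE]
    v <- v[keep, keep, drop = FALSE]
    frag <- frag[keep]
    i2 <- match(i, keep)
    kpos <- match(k, keep)
    d[i2, kpos] <- d[kpos, i2] <- pmax(du, 0)
    v[i2, kpos] <- v[kpos, i2] <- pmax(vu, 0)
    d[i2, i2] <- v[i2, i2] <- 0
    frag[i2] <- newfrag
  }
  # closed three-point resolution
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(ba, bb, bc), 0)
  nwk <- paste0("(", frag[1], ":", fmt(b[1]), ",", frag[2], ":", fmt(b[2]),
                ",", frag[3], ":", fmt(b[3]), ");")
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Saitou & Nei), deterministic given the matrix
#' (ties broken by the smallest row-index pair). Negative branch-length
#' estimates are clamped to zero with the deficit absorbed into the sibling
#' edge, so the path length between the joined pair is preserved. Exactly
#' recovers the generating tree from any additive matrix.
#'
#' @param m a `proteome_dist`, symmetric matrix, or `dist`.
#' @return an unrooted `phylo` tree (ape) with branch lengths in the units
#'   of the input matrix.
#' @export
neighbor_joining <- function(m) .agglomerate(.check_dist_input(m), bionj = FALSE)

#' BioNJ tree from a distance matrix
#'
#' BioNJ agglomeration (Gascuel 1997): as NJ, but each join uses the
#' variance-weighted reduction whose weight lambda minimizes the variance
#' of the reduced matrix. Identical to NJ on exactly additive matrices;
#' typically more accurate on noisy ones.
#'
#' @inheritParams neighbor_joining
#' @return an unrooted `phylo` tree.
#' @export
bionj <- function(m) .agglomerate(.check_dist_input(m), bionj = TRUE)

#' Serialize a tree as Newick
#'
#' @param t a `phylo` tree.
#' @param path optional file path; when given the Newick string is also
#'   written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "phylo"))
  s <- ape::write.tree(t)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string or file
#'
#' Round-trips with [to_newick()] preserving topology, labels, and branch
#' lengths. Unbalanced parentheses or duplicate leaf labels are errors.
#'
#' @param text Newick string, or a path to a file containing one.
#' @return a `phylo` tree.
#' @export
from_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("(", text, fixed = TRUE) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  if (lengths(regmatches(text, gregexpr("(", text, fixed = TRUE))) !=
      lengths(regmatches(text, gregexpr(")", text, fixed = TRUE))))
    stop("unbalanced parentheses in Newick string")
  t <- tryCatch(ape::read.tree(text = text), error = function(e)
    stop("invalid Newick: ", conditionMessage(e)))
  if (is.null(t)) stop("invalid Newick string")
  if (anyDuplicated(t$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(t$tip.label[duplicated(t$tip.label)]), collapse = ", "))
  t
}

#' Robinson-Foulds distance between two trees
#'
#' The number of bipartitions present in exactly one of the two unrooted
#' trees (unweighted). Zero means identical unrooted topologies.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) || length(only2))
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ", "), "}, only in second: {",
         paste(only2, collapse = ", "), "}")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}
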
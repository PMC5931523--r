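# Independent oracles and fixture builders used across the suite.

# Plain O(mn) affine-gap Smith-Waterman, written independently of the
# compiled engine (full DP matrices, no striping). A gap of length k costs
# gap_open + k * gap_extend.
sw_oracle <- function(a, b, smat = prophy:::score_matrix("BLOSUM62"),
                      go = 11, ge = 1) {
  A <- strsplit(toupper(a), "")[[1L]]
  B <- strsplit(toupper(b), "")[[1L]]
  m <- length(A)
  n <- length(B)
  if (m == 0L || n == 0L) return(0L)
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)
  F <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0
  for (i in 2L:(m + 1L)) {
    for (j in 2L:(n + 1L)) {
      E[i, j] <- max(E[i, j - 1L] - ge, H[i, j - 1L] - go - ge)
      F[i, j] <- max(F[i - 1L, j] - ge, H[i - 1L, j] - go - ge)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + smat[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  as.integer(best)
}

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# Small random proteome for unit tests (lighter than the full generator).
tiny_proteome <- function(n = 10L, len = 60L, id = "toy", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) random_aa(len), character(1))
  proteome(setNames(seqs, sprintf("p%02d", seq_len(n))), id)
}

# Random binary tree with positive branch lengths and its additive
# distance matrix (leaf-to-leaf path lengths), computed via ape's cophenetic
# distances -- an independent route from the package's NJ/BioNJ code.
random_additive_case <- function(n_taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 2))
  m <- ape::cophenetic.phylo(tr)
  m <- m[order(rownames(m)), order(colnames(m))]
  list(tree = tr, matrix = m)
}
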
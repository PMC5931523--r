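#' Search and scoring parameters
#'
#' Bundles the scoring scheme used by the internal local-alignment search
#' engine and the Karlin-Altschul E-value statistics applied to its raw
#' scores. The defaults are the conventional gapped BLOSUM62 parameters
#' (gap open 11, gap extend 1) with the matching Karlin-Altschul constants
#' lambda = 0.267 and K = 0.041. E-values are clamped into
#' `[e_floor, e_ceiling]` so that their logarithms stay finite; the ceiling
#' (default 10) is also the conventional reporting cutoff below which a hit
#' is considered detectable at all.
#'
#' @param substitution_matrix name of a standard substitution matrix shipped
#'   with Biostrings ("BLOSUM62", "BLOSUM45", "BLOSUM50", "BLOSUM80",
#'   "BLOSUM100", "PAM250", "PAM30", "PAM40", "PAM70", "PAM120").
#' @param gap_open positive integer gap-opening penalty; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @param gap_extend positive integer gap-extension penalty.
#' @param lambda positive Karlin-Altschul scale parameter.
#' @param K positive Karlin-Altschul search-space constant.
#' @param e_ceiling maximum reported E-value; queries whose best hit exceeds
#'   it are recorded as no-hit rows at the ceiling.
#' @param e_floor minimum reported E-value (E = 0 reports are clamped here).
#' @return an object of class `search_params`.
#' @examples
#' p <- search_params()
#' p$lambda
#' @export
search_params <- function(substitution_matrix = "BLOSUM62",
                          gap_open = 11L, gap_extend = 1L,
                          lambda = 0.267, K = 0.041,
                          e_ceiling = 10, e_floor = 1e-180) {
  stopifnot(is.character(substitution_matrix), length(substitution_matrix) == 1L)
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open <= 0L || gap_extend <= 0L)
    stop("gap penalties must be positive integers")
  if (!(lambda > 0) || !(K > 0))
    stop("lambda and K must be positive")
  if (!(e_floor < 1 && 1 < e_ceiling))
    stop("need e_floor < 1 < e_ceiling")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K,
                 e_ceiling = e_ceiling, e_floor = e_floor),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat("Search parameters:", x$substitution_matrix,
      sprintf("gap %d/%d, lambda %.3f, K %.3f, E in [%.3g, %.3g]\n",
              x$gap_open, x$gap_extend, x$lambda, x$K, x$e_floor, x$e_ceiling))
  invisible(x)
}

# 20 standard residues in the row order of the Biostrings matrices, then the
# tolerated ambiguity/rare codes. Ambiguity codes score at the mismatch
# floor of the matrix (see score_matrix()).
.aa_standard <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.aa_extra <- c("B", "Z", "X", "J", "U", "O")
.aa_alphabet <- c(.aa_standard, .aa_extra)

#' Integer substitution matrix over the package alphabet
#'
#' Expands a named Biostrings substitution matrix to the 26-letter package
#' alphabet (20 standard residues plus B, Z, X, J, U, O). Ambiguity and rare
#' codes score at the mismatch floor of the matrix (its minimum entry, -4
#' for BLOSUM62) against everything, including themselves.
#'
#' @param name matrix name, e.g. "BLOSUM62".
#' @return integer matrix with dimnames equal to the package alphabet.
#' @keywords internal
score_matrix <- function(name = "BLOSUM62") {
  key <- paste0("smat_", name)
  cached <- .prophy_env[[key]]
  if (!is.null(cached)) return(cached)
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || is.null(e[[name]]))
    stop("unknown substitution matrix: ", name)
  base <- e[[name]][.aa_standard, .aa_standard]
  floorv <- min(base)
  k <- length(.aa_alphabet)
  full <- matrix(as.integer(floorv), k, k,
                 dimnames = list(.aa_alphabet, .aa_alphabet))
  full[.aa_standard, .aa_standard] <- as.integer(base)
  .prophy_env[[key]] <- full
  full
}

.alphabet_string <- function() paste(.aa_alphabet, collapse = "")
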
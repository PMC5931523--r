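#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under an affine gap model in which a gap of
#' length k costs `gap_open + k * gap_extend`. The score is non-negative by
#' construction (the empty alignment scores 0). Backed by a compiled engine
#' (SSE2-striped where available, plain dynamic programming otherwise).
#'
#' @param a,b `proteome` entries (lists with a `seq` element), single
#'   sequences as character strings, or a `proteome` of length 1.
#' @param params a [search_params()] object.
#' @return integer alignment score.
#' @examples
#' local_align_score("AAAA", "AAAA")  # 4 x BLOSUM62 A/A = 16
#' @export
local_align_score <- function(a, b, params = search_params()) {
  a <- .as_sequence(a)
  b <- .as_sequence(b)
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  smat <- score_matrix(params$substitution_matrix)
  cpp_sw_pair(a, b, smat, .alphabet_string(), params$gap_open,
              params$gap_extend)
}

.as_sequence <- function(x) {
  if (inherits(x, "proteome")) {
    if (length(x$seq) != 1L)
      stop("expected a single sequence, got a proteome of length ",
           length(x$seq))
    return(x$seq)
  }
  if (is.list(x) && !is.null(x$seq)) return(as.character(x$seq)[1L])
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Karlin-Altschul E-value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`, the expected number of chance
#' local alignments at least this good between a length-m query and a
#' length-n target database, then clamped into `[e_floor, e_ceiling]`
#' (set `clamp = FALSE` for the raw value). Raw sequence lengths are used;
#' no effective-length correction is applied.
#'
#' @param score integer alignment score(s).
#' @param m residues in the query.
#' @param n residues in the target database.
#' @param params a [search_params()] object.
#' @param clamp clamp into `[e_floor, e_ceiling]`? Default `TRUE`.
#' @return numeric E-value(s).
#' @examples
#' karlin_altschul_evalue(100, 300, 300)  # about 9.4e-9
#' @export
karlin_altschul_evalue <- function(score, m, n, params = search_params(),
                                   clamp = TRUE) {
  stopifnot(all(m >= 1), all(n >= 1))
  e <- params$K * as.numeric(m) * as.numeric(n) *
    exp(-params$lambda * as.numeric(score))
  if (clamp) e <- pmin(pmax(e, params$e_floor), params$e_ceiling)
  e
}
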
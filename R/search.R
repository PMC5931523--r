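# Directed best-hit search: for each query ORF of X, the E-value of its
# best-matched ORF in Y, plus the self-search best E-value E_best and a
# reciprocal flag filled in later by reciprocal_flag().

#' Self-search best E-values for a proteome
#'
#' E_best for every ORF: the E-value of the ORF aligned against itself,
#' with the organism's own total residue count as the database size. In a
#' full self-search the best-matched pair is the pair of identical ORFs, so
#' the self-alignment provides the same value without the all-vs-all cost.
#'
#' @param p a `proteome`.
#' @param params a [search_params()] object.
#' @return named numeric vector of clamped E-values, one per ORF.
#' @export
self_best_evalues <- function(p, params = search_params()) {
  stopifnot(inherits(p, "proteome"))
  smat <- score_matrix(params$substitution_matrix)
  sc <- cpp_sw_self(p$seq, smat, .alphabet_string(), params$gap_open,
                    params$gap_extend)
  setNames(karlin_altschul_evalue(sc, nchar(p$seq), total_residues(p), params),
           p$id)
}

.best_hit_core <- function(X, Y, params, self_e) {
  smat <- score_matrix(params$substitution_matrix)
  sc <- cpp_sw_all(X$seq, Y$seq, smat, .alphabet_string(), params$gap_open,
                   params$gap_extend)
  best_score <- integer(length(X$id))
  best_id <- character(length(X$id))
  for (i in seq_along(X$id)) {
    s <- sc[i, ]
    mx <- max(s)
    cand <- which(s == mx)
    # ties: E and raw score tie together (m, n fixed per query), so the
    # remaining rule is the lexicographically smallest target ID
    best_id[i] <- min(Y$id[cand])
    best_score[i] <- mx
  }
  e_raw <- karlin_altschul_evalue(best_score, nchar(X$seq), total_residues(Y),
                                  params, clamp = FALSE)
  nohit <- e_raw > params$e_ceiling
  e <- pmin(pmax(e_raw, params$e_floor), params$e_ceiling)
  e[nohit] <- params$e_ceiling
  best_id[nohit] <- NA_character_
  best_score[nohit] <- NA_integer_
  # E_best <= E must hold after clamping (self is the best possible target);
  # guard against pathological database-size mismatches
  if (!is.null(names(self_e))) self_e <- self_e[X$id]
  eb <- pmin(unname(self_e), e)
  df <- data.frame(query_id = X$id, target_id = best_id, evalue = e,
                   score = best_score, self_best = eb,
                   reciprocal = NA, stringsAsFactors = FALSE)
  structure(df, source = X$organism_id, target = Y$organism_id,
            class = c("best_hit_table", "data.frame"))
}

#' Directed best hits of one proteome against another
#'
#' For each query ORF of `X`, the single best-matched ORF of `Y` by smallest
#' E-value (ties broken by highest raw score, then lexicographically
#' smallest target ID). Queries whose best pre-clamp E-value exceeds the
#' ceiling are recorded as no-hit rows with an absent target and
#' `evalue = e_ceiling`. `E_best` comes from the self-search of `X`.
#'
#' @param X query `proteome`.
#' @param Y target `proteome`.
#' @param params a [search_params()] object.
#' @param self_e optional precomputed [self_best_evalues()] of `X` (cache).
#' @return a `best_hit_table` data frame with one row per ORF of `X` and
#'   columns `query_id`, `target_id`, `evalue`, `score`, `self_best`,
#'   `reciprocal`; attributes `source` and `target` carry the organism IDs.
#' @export
directed_best_hits <- function(X, Y, params = search_params(), self_e = NULL) {
  stopifnot(inherits(X, "proteome"), inherits(Y, "proteome"))
  if (length(X$id) == 0L || length(Y$id) == 0L)
    stop("empty proteome")
  if (is.null(self_e)) self_e <- self_best_evalues(X, params)
  .best_hit_core(X, Y, params, self_e)
}

#' Flag reciprocal best-hit pairs
#'
#' A row of the X -> Y table is reciprocal when the reverse search of its
#' target gives back the original query: `table_yx[target_id] == query_id`.
#' No-hit rows are never reciprocal.
#'
#' @param table_xy,table_yx `best_hit_table`s for the two directions of the
#'   same organism pair.
#' @return `table_xy` with its `reciprocal` column filled in.
#' @export
reciprocal_flag <- function(table_xy, table_yx) {
  stopifnot(inherits(table_xy, "best_hit_table"),
            inherits(table_yx, "best_hit_table"))
  if (!identical(attr(table_xy, "source"), attr(table_yx, "target")) ||
      !identical(attr(table_xy, "target"), attr(table_yx, "source")))
    stop("tables are not the two directions of the same organism pair: ",
         attr(table_xy, "source"), "->", attr(table_xy, "target"), " vs ",
         attr(table_yx, "source"), "->", attr(table_yx, "target"))
  back <- setNames(table_yx$target_id, table_yx$query_id)
  rec <- !is.na(table_xy$target_id) &
    !is.na(back[table_xy$target_id]) &
    back[table_xy$target_id] == table_xy$query_id
  table_xy$reciprocal <- unname(rec)
  table_xy
}

#' Parse precomputed tabular search results into a best-hit table
#'
#' Reads the standard 12-column tab-separated search-result layout (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, evalue, bitscore), selects the best row per
#' query (smallest E-value, then largest bit score, then lexicographically
#' smallest subject), clamps `E = 0` entries to `e_floor`, and fills in
#' queries of `X` absent from the file as no-hit rows. `E_best` is computed
#' internally from the self-search of `X`.
#'
#' @param path path to the tabular file.
#' @param X query `proteome` (row per ORF of `X` guaranteed).
#' @param Y target `proteome`.
#' @param params a [search_params()] object.
#' @param self_e optional precomputed [self_best_evalues()] of `X`.
#' @return a `best_hit_table`, as for [directed_best_hits()].
#' @export
parse_tabular_hits <- function(path, X, Y, params = search_params(),
                               self_e = NULL) {
  stopifnot(inherits(X, "proteome"), inherits(Y, "proteome"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    bad <- which(nf != 12L)
    if (length(bad))
      stop("line ", bad[1L], ": expected 12 tab-separated columns, found ",
           nf[bad[1L]])
  }
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    qid <- vapply(f, `[[`, "", 1L)
    sid <- vapply(f, `[[`, "", 2L)
    ev <- as.numeric(vapply(f, `[[`, "", 11L))
    bits <- as.numeric(vapply(f, `[[`, "", 12L))
    unknown_q <- setdiff(qid, X$id)
    if (length(unknown_q))
      stop("query ID(s) not in proteome '", X$organism_id, "': ",
           paste(unknown_q, collapse = ", "))
    unknown_s <- setdiff(sid, Y$id)
    if (length(unknown_s))
      stop("subject ID(s) not in proteome '", Y$organism_id, "': ",
           paste(unknown_s, collapse = ", "))
    if (anyNA(ev)) stop("non-numeric evalue field")
    ev <- pmin(pmax(ev, params$e_floor), params$e_ceiling)
    ord <- order(qid, ev, -bits, sid)
    keep <- !duplicated(qid[ord])
    pick <- ord[keep]
    hit <- setNames(seq_along(pick), qid[pick])
  } else {
    pick <- integer(0)
    hit <- setNames(integer(0), character(0))
    sid <- character(0)
    ev <- numeric(0)
    bits <- numeric(0)
  }
  if (is.null(self_e)) self_e <- self_best_evalues(X, params)
  idx <- unname(hit[X$id])
  target_id <- ifelse(is.na(idx), NA_character_, sid[pick][idx])
  evalue <- unname(ifelse(is.na(idx), params$e_ceiling, ev[pick][idx]))
  eb <- pmin(unname(self_e[X$id]), evalue)
  df <- data.frame(query_id = X$id, target_id = target_id, evalue = evalue,
                   score = NA_integer_, self_best = eb, reciprocal = NA,
                   stringsAsFactors = FALSE)
  structure(df, source = X$organism_id, target = Y$organism_id,
            class = c("best_hit_table", "data.frame"))
}

#' Export a best-hit table in the 12-column tabular layout
#'
#' Columns not tracked by the internal engine (identities, alignment
#' coordinates) are written as 0; the bit score is derived from the raw
#' score as `(lambda * S - ln K) / ln 2`. [parse_tabular_hits()] recovers
#' the same best hits from the output.
#'
#' @param table a `best_hit_table` produced by [directed_best_hits()].
#' @param path output file path.
#' @param params the [search_params()] used for the search.
#' @return invisibly, `path`.
#' @export
write_hits_tsv <- function(table, path, params = search_params()) {
  stopifnot(inherits(table, "best_hit_table"))
  hit <- table[!is.na(table$target_id), , drop = FALSE]
  bits <- ifelse(is.na(hit$score), 0,
                 round((params$lambda * hit$score - log(params$K)) / log(2), 1))
  out <- data.frame(hit$query_id, hit$target_id, 0, 0, 0, 0, 0, 0, 0, 0,
                    sprintf("%.3g", hit$evalue), bits)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
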
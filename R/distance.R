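# Symmetric whole-proteome distances: D = 1 - (T_xy + T_yx) / 2.

#' Symmetric distance from the two directed slopes of a pair
#'
#' `D = 1 - (T_xy + T_yx) / 2`, in \[0, 1\] because both slopes are.
#'
#' @param t_xy,t_yx `tslope` fits for the two directions of the same
#'   unordered organism pair.
#' @return numeric distance D.
#' @examples
#' pts <- function(s) data.frame(x = c(-100, -50), y = s * c(-100, -50))
#' pair_distance(fit_T_slope(pts(0.9)), fit_T_slope(pts(0.7)))  # 0.2
#' @export
pair_distance <- function(t_xy, t_yx) {
  stopifnot(inherits(t_xy, "tslope"), inherits(t_yx, "tslope"))
  if (!is.na(t_xy$source) && !is.na(t_yx$source) &&
      !(identical(t_xy$source, t_yx$target) &&
        identical(t_xy$target, t_yx$source)))
    stop("slopes are not the two directions of one pair: ",
         t_xy$source, "->", t_xy$target, " vs ", t_yx$source, "->", t_yx$target)
  1 - (t_xy$slope + t_yx$slope) / 2
}

# One unordered pair: both directed tables, optional reciprocal filtering,
# slopes and D. `self_x`/`self_y` are cached self-search E-value vectors.
.slope_pair <- function(X, Y, params, self_x, self_y,
                        mode = "directional", collect_tables = FALSE) {
  txy_tab <- .best_hit_core(X, Y, params, self_x)
  tyx_tab <- .best_hit_core(Y, X, params, self_y)
  if (mode == "reciprocal") {
    txy_tab <- reciprocal_flag(txy_tab, tyx_tab)
    tyx_tab <- reciprocal_flag(tyx_tab, txy_tab)
    t_xy <- fit_T_slope(txy_tab, params = params, reciprocal_only = TRUE)
    t_yx <- fit_T_slope(tyx_tab, params = params, reciprocal_only = TRUE)
  } else {
    t_xy <- fit_T_slope(txy_tab, params = params)
    t_yx <- fit_T_slope(tyx_tab, params = params)
  }
  out <- list(t_xy = t_xy, t_yx = t_yx, D = pair_distance(t_xy, t_yx))
  if (collect_tables) out$tables <- list(xy = txy_tab, yx = tyx_tab)
  out
}

.check_self_eligible <- function(proteomes, params, self_list) {
  for (p in proteomes) {
    eb <- self_list[[p$organism_id]]
    if (!any(eb < 1))
      stop("proteome '", p$organism_id,
           "' has zero eligible self-hits (all E_best >= 1)")
  }
}

#' Whole-proteome distance matrix
#'
#' Computes the symmetric matrix of D over a collection of proteomes. In
#' `directional` mode every best-hit pair enters the slope fits; in
#' `reciprocal` mode only pairs confirmed by the reverse search do (a
#' subset, reproducing the classical reciprocal-best-hit restriction).
#' Self-search E-values are computed once per organism and reused across
#' all pairs.
#'
#' @param proteomes list of `proteome` objects (at least 3) with unique
#'   organism IDs.
#' @param mode `"directional"` (default) or `"reciprocal"`.
#' @param params a [search_params()] object.
#' @param correct apply a saturation correction? Requires `curve`.
#' @param curve a [build_saturation_curve()] result when `correct = TRUE`.
#' @param verbose print per-pair progress.
#' @return an object of class `proteome_dist`: a symmetric numeric matrix
#'   with zero diagonal, a `kind` attribute (`"raw_D"`, `"reciprocal_D"` or
#'   `"corrected_C"`), and a `slopes` attribute containing the directed
#'   slope table. Supports `print()`, `plot()` and `as.matrix()`;
#'   `stats::as.dist(as.matrix(x))` feeds the tree builders.
#' @export
distance_matrix <- function(proteomes, mode = c("directional", "reciprocal"),
                            params = search_params(), correct = FALSE,
                            curve = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.list(proteomes), length(proteomes) >= 3L)
  stopifnot(all(vapply(proteomes, inherits, TRUE, "proteome")))
  ids <- vapply(proteomes, `[[`, "", "organism_id")
  if (anyDuplicated(ids))
    stop("duplicate organism ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(proteomes) <- ids
  self_list <- lapply(proteomes, self_best_evalues, params = params)
  .check_self_eligible(proteomes, params, self_list)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  slopes <- vector("list", n * (n - 1L))
  s_i <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (verbose)
        message("pair ", ids[i], " <-> ", ids[j])
      sp <- .slope_pair(proteomes[[i]], proteomes[[j]], params,
                        self_list[[i]], self_list[[j]], mode)
      m[i, j] <- m[j, i] <- sp$D
      slopes[[s_i <- s_i + 1L]] <- .slope_row(sp$t_xy)
      slopes[[s_i <- s_i + 1L]] <- .slope_row(sp$t_yx)
    }
  }
  slopes <- do.call(rbind, slopes)
  kind <- if (mode == "reciprocal") "reciprocal_D" else "raw_D"
  out <- structure(m, kind = kind, slopes = slopes, class = "proteome_dist")
  if (correct) {
    if (is.null(curve)) stop("correct = TRUE requires a saturation curve")
    out <- correct_matrix(out, curve)
  }
  out
}

.slope_row <- function(ts) {
  data.frame(source = ts$source, target = ts$target, slope = ts$slope,
             n_points = ts$n_points, n_nohit = ts$n_nohit,
             stringsAsFactors = FALSE)
}

#' @export
print.proteome_dist <- function(x, ...) {
  cat(sprintf("Whole-proteome distance matrix (%s), %d organisms\n",
              attr(x, "kind"), nrow(x)))
  print(round(as.matrix.proteome_dist(x), 4), ...)
  invisible(x)
}

#' @export
#' @method as.matrix proteome_dist
as.matrix.proteome_dist <- function(x, ...) {
  y <- unclass(x)
  attr(y, "kind") <- NULL
  attr(y, "slopes") <- NULL
  y
}

#' @export
#' @method plot proteome_dist
plot.proteome_dist <- function(x, ...) {
  m <- as.matrix.proteome_dist(x)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s distances", attr(x, "kind")), ...)
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param m a `proteome_dist` or plain symmetric matrix with dimnames.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_phylip <- function(m, path) {
  mm <- if (inherits(m, "proteome_dist")) as.matrix.proteome_dist(m) else m
  stopifnot(is.matrix(mm), !is.null(rownames(mm)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(mm)), con)
  for (i in seq_len(nrow(mm)))
    writeLines(paste(formatC(rownames(mm)[i], width = -10),
                     paste(sprintf("%.6f", mm[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  f <- strsplit(trimws(lines[1L + seq_len(n)]), "\\s+")
  ids <- vapply(f, `[[`, "", 1L)
  vals <- lapply(f, function(z) as.numeric(z[-1L]))
  if (any(lengths(vals) != n)) stop("malformed PHYLIP matrix: wrong row length")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a distance matrix as TSV
#' @param m a `proteome_dist` or matrix.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  mm <- if (inherits(m, "proteome_dist")) as.matrix.proteome_dist(m) else m
  write.table(mm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
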
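# The per-gene T ratio and the directed average T, estimated as the slope
# of an origin-constrained least-squares line through the
# (log10 E_best, log10 E) point cloud of one directed search.

#' Per-gene T ratios from E-values
#'
#' For a best-hit pair, `T = log10(E) / log10(E_best)`, clamped into
#' \[0, 1\]. T is 1 when the query and its best match are identical
#' (E = E_best) and approaches 0 as homology becomes undetectable. Queries
#' with `E_best >= 1` carry no usable signal (their own self-match is not
#' better than chance) and are marked ineligible rather than raising an
#' error.
#'
#' @param E clamped E-value(s) of the best hit.
#' @param E_best clamped self-search E-value(s).
#' @param params a [search_params()] object (used to flag no-hit points at
#'   the ceiling).
#' @return data frame of T points with columns `x` (log10 E_best),
#'   `y` (log10 E), `t` (clamped ratio), `eligible`, `nohit`.
#' @examples
#' compute_T(1e-50, 1e-100)$t  # 0.5
#' @export
compute_T <- function(E, E_best, params = search_params()) {
  stopifnot(length(E) == length(E_best))
  x <- log10(E_best)
  y <- log10(E)
  t <- pmin(pmax(y / x, 0), 1)
  eligible <- x < 0
  t[!eligible] <- NA_real_
  data.frame(x = x, y = y, t = t, eligible = eligible,
             nohit = E >= params$e_ceiling)
}

#' Directed average T from an origin-constrained least-squares fit
#'
#' Fits a straight line through the origin to the point cloud of one
#' directed search: x = log10(E_best), y = log10(E) with y clamped at 0 so
#' that no-hit queries enter as (x, 0). The closed-form slope is
#' `sum(x * y) / sum(x^2)`, clamped into \[0, 1\]; it is the directed
#' average T for the pair. A 14-bin profile of mean y by equal-width bins
#' of x is attached as a linearity diagnostic; it never alters the fit.
#'
#' @param points a `best_hit_table` (from [directed_best_hits()] or
#'   [parse_tabular_hits()]), or a data frame of T points as produced by
#'   [compute_T()]. For a best-hit table with its `reciprocal` column
#'   filled, `reciprocal_only = TRUE` restricts the fit to reciprocal rows.
#' @param n_bins number of equal-width diagnostic bins (default 14).
#' @param params a [search_params()] object.
#' @param reciprocal_only use only reciprocal rows of a best-hit table.
#' @return an object of class `tslope` with elements `slope` (the directed
#'   average T), `n_points`, `n_nohit`, `bin_profile`, `points`, `source`,
#'   `target`. Supports `print()`, `coef()`, `summary()`, `predict()`,
#'   `residuals()` and `plot()`.
#' @examples
#' pts <- data.frame(x = c(-100, -60), y = c(-50, -30))
#' coef(fit_T_slope(pts))  # 0.5
#' @export
fit_T_slope <- function(points, n_bins = 14L, params = search_params(),
                        reciprocal_only = FALSE) {
  src <- tgt <- NA_character_
  if (inherits(points, "best_hit_table")) {
    src <- attr(points, "source")
    tgt <- attr(points, "target")
    if (reciprocal_only) {
      if (all(is.na(points$reciprocal)))
        stop("reciprocal flags not set; call reciprocal_flag() first")
      points <- points[!is.na(points$reciprocal) & points$reciprocal, ,
                       drop = FALSE]
    }
    points <- compute_T(points$evalue, points$self_best, params)
  }
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (is.null(points$eligible)) points$eligible <- points$x < 0
  if (is.null(points$nohit)) points$nohit <- FALSE
  pts <- points[points$eligible, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("no eligible points (all E_best >= 1); proteome too degenerate")
  x <- pts$x
  y <- pmin(pts$y, 0)
  slope <- sum(x * y) / sum(x * x)
  slope <- min(max(slope, 0), 1)
  bin_profile <- .bin_profile(x, y, n_bins)
  structure(list(slope = slope, n_points = nrow(pts),
                 n_nohit = sum(pts$nohit), bin_profile = bin_profile,
                 points = data.frame(x = x, y = y),
                 source = src, target = tgt),
            class = "tslope")
}

.bin_profile <- function(x, y, n_bins) {
  rng <- range(x)
  if (diff(rng) == 0) {
    return(data.frame(bin = 1L, x_mid = rng[1L], n = length(x),
                      mean_y = mean(y)))
  }
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(bin = seq_len(n_bins),
             x_mid = (br[-1L] + br[-(n_bins + 1L)]) / 2,
             n = tabulate(bin, n_bins),
             mean_y = vapply(seq_len(n_bins), function(b) {
               if (any(bin == b)) mean(y[bin == b]) else NA_real_
             }, numeric(1)))
}

#' @export
print.tslope <- function(x, ...) {
  dir <- if (!is.na(x$source)) sprintf(" %s -> %s", x$source, x$target) else ""
  cat(sprintf("Directed average T%s: slope %.4f (%d points, %d no-hit)\n",
              dir, x$slope, x$n_points, x$n_nohit))
  invisible(x)
}

#' @export
#' @method coef tslope
coef.tslope <- function(object, ...) c(slope = object$slope)

#' @export
#' @method summary tslope
summary.tslope <- function(object, ...) {
  r <- residuals(object)
  structure(list(slope = object$slope, n_points = object$n_points,
                 n_nohit = object$n_nohit, rmse = sqrt(mean(r^2)),
                 bin_profile = object$bin_profile,
                 source = object$source, target = object$target),
            class = "summary.tslope")
}

#' @export
print.summary.tslope <- function(x, ...) {
  dir <- if (!is.na(x$source)) sprintf(" %s -> %s", x$source, x$target) else ""
  cat(sprintf("Origin-constrained fit%s\n", dir))
  cat(sprintf("  slope (average T): %.4f\n", x$slope))
  cat(sprintf("  points: %d (%d no-hit)   RMSE: %.2f\n",
              x$n_points, x$n_nohit, x$rmse))
  cat("  bin profile (mean log10 E by log10 E_best bin):\n")
  print(x$bin_profile, row.names = FALSE)
  invisible(x)
}

#' @export
predict.tslope <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$x else
    if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  object$slope * x
}

#' @export
#' @method residuals tslope
residuals.tslope <- function(object, ...) {
  object$points$y - object$slope * object$points$x
}

#' @export
#' @method plot tslope
plot.tslope <- function(x, ...) {
  plot(x$points$x, x$points$y,
       xlab = "log10 E_best", ylab = "log10 E",
       pch = 16, cex = 0.5, col = "grey30", ...)
  graphics::abline(0, x$slope, col = "red", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("slope (avg T) = %.3f", x$slope))
  invisible(x)
}
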
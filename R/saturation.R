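# Saturation correction: D compresses as substitutions saturate; a curve of
# mean D against cumulative simulated mutation rounds linearizes it.

#' Build a saturation curve by cumulative simulated mutation
#'
#' Mutates a reference proteome cumulatively (default 10% of residues per
#' round, uniform replacement) and records D(reference, mutant) at every
#' round, averaged over replicate mutation chains. Isotonic regression
#' enforces monotonicity, and the piecewise-linear inverse of the resulting
#' curve maps a distance D to a corrected distance C in units of mutation
#' rounds. Beyond the grid the inverse extrapolates flat and results are
#' flagged unreliable.
#'
#' @param reference a `proteome` standing in for the organism on which the
#'   curve is calibrated.
#' @param per_gen_fraction fraction of residues mutated per round
#'   (default 0.1).
#' @param max_generations number of cumulative rounds (>= 2).
#' @param replicates number of independent mutation chains averaged.
#' @param seed optional RNG seed for reproducibility.
#' @param params a [search_params()] object.
#' @return an object of class `saturation_curve` with elements
#'   `generations` (0..max), `mean_D` (raw means), `mean_D_iso` (isotonic),
#'   `per_gen_fraction`, `replicates`. Supports `print()` and `plot()`.
#' @export
build_saturation_curve <- function(reference, per_gen_fraction = 0.1,
                                   max_generations = 16L, replicates = 3L,
                                   seed = NULL, params = search_params()) {
  stopifnot(inherits(reference, "proteome"), max_generations >= 2L,
            replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  self_ref <- self_best_evalues(reference, params)
  G <- as.integer(max_generations)
  d <- matrix(0, nrow = G + 1L, ncol = replicates)
  for (r in seq_len(replicates)) {
    cur <- reference
    for (g in seq_len(G)) {
      cur <- mutate_proteome(cur, per_gen_fraction)
      cur$organism_id <- sprintf("%s_m%d_%d", reference$organism_id, g, r)
      sp <- .slope_pair(reference, cur, params, self_ref,
                        self_best_evalues(cur, params))
      d[g + 1L, r] <- sp$D
    }
  }
  mean_D <- rowMeans(d)
  iso <- isoreg(0:G, mean_D)$yf
  structure(list(generations = 0:G, mean_D = mean_D, mean_D_iso = iso,
                 per_gen_fraction = per_gen_fraction,
                 replicates = replicates,
                 reference_id = reference$organism_id),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf(paste0("Saturation curve: %d rounds at %.0f%% mutation/round ",
                     "(%d replicate chains, reference '%s')\n"),
              max(x$generations), 100 * x$per_gen_fraction, x$replicates,
              x$reference_id))
  print(data.frame(generation = x$generations, mean_D = round(x$mean_D, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
#' @method plot saturation_curve
plot.saturation_curve <- function(x, ...) {
  plot(x$generations, x$mean_D, type = "p", pch = 16,
       xlab = sprintf("mutation rounds (%.0f%%/round)",
                      100 * x$per_gen_fraction),
       ylab = "mean D", ...)
  graphics::lines(x$generations, x$mean_D_iso, col = "red")
  invisible(x)
}

#' Saturation-corrected distance C
#'
#' Maps a raw distance D through the inverse of the saturation curve,
#' giving C in units of mutation rounds of the curve. Values beyond the
#' approximately linear range (D > 0.85) or beyond the curve grid are
#' returned with an `unreliable` flag attribute.
#'
#' @param D numeric distance(s) in \[0, 1\].
#' @param curve a [build_saturation_curve()] result.
#' @param reliable_max D above this bound is flagged unreliable
#'   (default 0.85, the bound of the approximately linear regime).
#' @return numeric C value(s) with a logical attribute `unreliable`.
#' @export
correct_distance <- function(D, curve, reliable_max = 0.85) {
  stopifnot(inherits(curve, "saturation_curve"), all(D >= 0), all(D <= 1))
  C <- approx(x = curve$mean_D_iso, y = curve$generations, xout = D,
              ties = mean, rule = 2)$y
  structure(C, unreliable = D > pmin(reliable_max, max(curve$mean_D_iso)))
}

#' Apply a saturation correction to a whole distance matrix
#'
#' @param m a `proteome_dist` of kind `raw_D` or `reciprocal_D`.
#' @param curve a [build_saturation_curve()] result.
#' @param reliable_max passed to [correct_distance()].
#' @return a `proteome_dist` of kind `corrected_C`; entries flagged
#'   unreliable are recorded in the `unreliable` attribute.
#' @export
correct_matrix <- function(m, curve, reliable_max = 0.85) {
  stopifnot(inherits(m, "proteome_dist"))
  v <- correct_distance(as.vector(unclass(m)), curve, reliable_max)
  out <- matrix(as.numeric(v), nrow(m), ncol(m), dimnames = dimnames(m))
  diag(out) <- 0
  structure(out, kind = "corrected_C", slopes = attr(m, "slopes"),
            unreliable = matrix(attr(v, "unreliable"), nrow(m), ncol(m),
                                dimnames = dimnames(m)),
            class = "proteome_dist")
}
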
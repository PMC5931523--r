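# End-to-end orchestration: proteomes -> best hits -> T slopes -> D/C
# matrix -> tree, plus the two named validation recipes that rerun the
# in-silico evolution experiments at desk scale.

#' Run the whole-proteome phylogeny pipeline
#'
#' Reads proteome FASTA files, computes the distance matrix, builds the
#' tree, and writes all intermediate artifacts plus a JSON manifest into
#' `out_dir`. All inputs are validated before anything is written, so a
#' malformed input leaves no partial outputs behind. Deterministic given
#' identical inputs, config and seed.
#'
#' @param proteome_paths character vector of FASTA paths, or a single
#'   directory containing `.fa`/`.faa`/`.fasta` files.
#' @param out_dir output directory (created; must not be an existing
#'   non-empty directory).
#' @param mode `"directional"` or `"reciprocal"`.
#' @param params a [search_params()] object.
#' @param tree_method `"bionj"` (default) or `"nj"`.
#' @param correct_saturation apply a saturation correction; the curve is
#'   built from the first proteome with `curve_generations` rounds.
#' @param curve_generations,curve_replicates saturation-curve settings.
#' @param seed RNG seed recorded in the manifest and used for the
#'   saturation curve (the rest of the pipeline is deterministic).
#' @param write_hits write per-pair best-hit TSVs (12-column layout).
#' @param verbose print per-pair progress.
#' @return invisibly, the output directory; side effects: `hits/*.tsv`,
#'   `slopes.tsv`, `matrix.phy`, `matrix.tsv`, `tree.nwk`,
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(proteome_paths, out_dir,
                         mode = c("directional", "reciprocal"),
                         params = search_params(),
                         tree_method = c("bionj", "nj"),
                         correct_saturation = FALSE,
                         curve_generations = 16L, curve_replicates = 2L,
                         seed = 1L, write_hits = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  tree_method <- match.arg(tree_method)
  if (length(proteome_paths) == 1L && dir.exists(proteome_paths))
    proteome_paths <- list.files(proteome_paths, full.names = TRUE,
                                 pattern = "\\.(fa|faa|fasta)$")
  if (length(proteome_paths) < 3L)
    stop("need at least 3 input proteomes, got ", length(proteome_paths))
  proteomes <- lapply(proteome_paths, function(f)
    tryCatch(read_fasta(f), error = function(e)
      stop("stage read_fasta, file '", f, "': ", conditionMessage(e),
           call. = FALSE)))
  ids <- vapply(proteomes, `[[`, "", "organism_id")
  names(proteomes) <- ids
  self_list <- lapply(proteomes, self_best_evalues, params = params)
  .check_self_eligible(proteomes, params, self_list)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  slopes <- list()
  tables <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (verbose) message("pair ", ids[i], " <-> ", ids[j])
      sp <- tryCatch(
        .slope_pair(proteomes[[i]], proteomes[[j]], params,
                    self_list[[i]], self_list[[j]], mode,
                    collect_tables = write_hits),
        error = function(e)
          stop("stage distances, pair ", ids[i], " <-> ", ids[j], ": ",
               conditionMessage(e), call. = FALSE))
      m[i, j] <- m[j, i] <- sp$D
      slopes <- c(slopes, list(.slope_row(sp$t_xy)), list(.slope_row(sp$t_yx)))
      if (write_hits) {
        tables[[paste0(ids[i], "__", ids[j])]] <- sp$tables$xy
        tables[[paste0(ids[j], "__", ids[i])]] <- sp$tables$yx
      }
    }
  }
  slopes <- do.call(rbind, slopes)
  kind <- if (mode == "reciprocal") "reciprocal_D" else "raw_D"
  dm <- structure(m, kind = kind, slopes = slopes, class = "proteome_dist")
  curve <- NULL
  if (correct_saturation) {
    curve <- build_saturation_curve(proteomes[[1L]],
                                    max_generations = curve_generations,
                                    replicates = curve_replicates,
                                    seed = seed, params = params)
    dm <- correct_matrix(dm, curve)
  }
  tree <- tryCatch(
    if (tree_method == "bionj") bionj(dm) else neighbor_joining(dm),
    error = function(e)
      stop("stage tree: ", conditionMessage(e), call. = FALSE))

  # computation done; now write everything
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (write_hits) {
    dir.create(file.path(out_dir, "hits"), showWarnings = FALSE)
    for (nm in names(tables))
      write_hits_tsv(tables[[nm]], file.path(out_dir, "hits",
                                             paste0(nm, ".tsv")), params)
  }
  write.table(slopes, file.path(out_dir, "slopes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_phylip(dm, file.path(out_dir, "matrix.phy"))
  write_matrix_tsv(dm, file.path(out_dir, "matrix.tsv"))
  to_newick(tree, file.path(out_dir, "tree.nwk"))
  manifest <- list(
    config = list(mode = mode, tree_method = tree_method,
                  correct_saturation = correct_saturation,
                  params = unclass(params), seed = seed),
    inputs = data.frame(path = as.character(proteome_paths),
                        organism_id = ids,
                        md5 = unname(tools::md5sum(proteome_paths)),
                        stringsAsFactors = FALSE),
    outputs = local({
      fs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
      fs <- fs[basename(fs) != "manifest.json"]
      data.frame(file = sub(paste0("^", out_dir, "/?"), "", fs),
                 md5 = unname(tools::md5sum(fs)), stringsAsFactors = FALSE)
    }),
    package_version = as.character(utils::packageVersion("prophy")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Rerun the in-silico evolution validation at desk scale
#'
#' Generates a synthetic root proteome, evolves a balanced clade, and
#' evaluates the average-similarity method against the known truth: the
#' Robinson-Foulds distance of the reconstructed tree to the true tree
#' (when `build_tree = TRUE`), and a table of D against the MRCA
#' generation for sampled leaf pairs.
#'
#' @param n_proteins,mean_length synthetic root proteome size.
#' @param generations,fraction clade depth and per-generation mutation
#'   fraction (defaults 5 and 0.2).
#' @param seed RNG seed; derived seeds are used for the root, the
#'   evolution, and the pair sampling.
#' @param pairs_per_depth leaf pairs sampled per MRCA generation for the
#'   D table (0 to skip).
#' @param build_tree reconstruct the full tree and report RF to the truth
#'   (quadratic in leaf count; default only up to 16 leaves).
#' @param tree_method `"bionj"` or `"nj"`.
#' @param params a [search_params()] object.
#' @return an object of class `prophy_validation`: list with `rf`
#'   (RF distance or NA), `d_table` (leaf_a, leaf_b, mrca_generation, D),
#'   `config`. `write_report()` serializes it as JSON.
#' @export
recipe_insilico_validation <- function(n_proteins = 100L, mean_length = 300L,
                                       generations = 5L, fraction = 0.2,
                                       seed = 1L, pairs_per_depth = 10L,
                                       build_tree = generations <= 4L,
                                       tree_method = c("bionj", "nj"),
                                       params = search_params()) {
  tree_method <- match.arg(tree_method)
  root <- synth_root_proteome(n_proteins, mean_length, seed = seed)
  rec <- evolve_lineages(root, generations, fraction, seed = seed + 1L)
  leaves <- rec$leaves
  self_list <- lapply(leaves, self_best_evalues, params = params)
  rf <- NA_integer_
  if (build_tree) {
    ids <- names(leaves)
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L))
      for (j in seq((i + 1L), n)) {
        sp <- .slope_pair(leaves[[i]], leaves[[j]], params,
                          self_list[[i]], self_list[[j]])
        m[i, j] <- m[j, i] <- sp$D
      }
    tree <- if (tree_method == "bionj") bionj(m) else neighbor_joining(m)
    rf <- rf_distance(tree, rec$true_tree)
  }
  d_table <- NULL
  if (pairs_per_depth > 0L) {
    set.seed(seed + 2L)
    ids <- names(leaves)
    pairs <- t(utils::combn(ids, 2L))
    depth <- apply(pairs, 1L, function(p)
      mrca_generation(p[1L], p[2L], rec))
    rows <- list()
    for (g in sort(unique(depth))) {
      cand <- which(depth == g)
      take <- cand[sample.int(length(cand), min(pairs_per_depth,
                                                length(cand)))]
      for (ix in take) {
        a <- pairs[ix, 1L]; b <- pairs[ix, 2L]
        sp <- .slope_pair(leaves[[a]], leaves[[b]], params,
                          self_list[[a]], self_list[[b]])
        rows <- c(rows, list(data.frame(leaf_a = a, leaf_b = b,
                                        mrca_generation = g, D = sp$D,
                                        stringsAsFactors = FALSE)))
      }
    }
    d_table <- do.call(rbind, rows)
  }
  structure(list(rf = rf, d_table = d_table,
                 config = list(n_proteins = n_proteins,
                               mean_length = mean_length,
                               generations = generations,
                               fraction = fraction, seed = seed,
                               pairs_per_depth = pairs_per_depth,
                               tree_method = tree_method)),
            class = "prophy_validation")
}

#' @export
print.prophy_validation <- function(x, ...) {
  cat("In-silico evolution validation\n")
  cfg <- x$config
  cat(sprintf("  clade: %d generations at %.0f%% mutation, root %d x %d aa\n",
              cfg$generations, 100 * cfg$fraction, cfg$n_proteins,
              cfg$mean_length))
  if (!is.na(x$rf))
    cat(sprintf("  RF distance to true tree: %d\n", x$rf))
  if (!is.null(x$d_table)) {
    agg <- stats::aggregate(D ~ mrca_generation, x$d_table,
                            function(z) c(min = min(z), max = max(z)))
    cat("  D by MRCA generation (min / max over sampled pairs):\n")
    for (r in seq_len(nrow(agg)))
      cat(sprintf("    generation %d: %.3f / %.3f\n",
                  agg$mrca_generation[r], agg$D[r, "min"], agg$D[r, "max"]))
  }
  invisible(x)
}

#' Rerun the lateral-gene-transfer robustness experiment
#'
#' Simulates a balanced clade, then for each transfer fraction copies that
#' fraction of randomly selected genes from a donor leaf into a recipient
#' leaf (replacement mode), rebuilds the distance matrix and tree, and
#' records the Robinson-Foulds distance to the true tree. Only pairs
#' involving the recipient are recomputed per fraction; all others are
#' cached from the baseline. The default donor/recipient are the first
#' leaves of the two halves of the root split (maximally divergent
#' descendants).
#'
#' @param fractions transfer fractions to test (default 0.1..0.5).
#' @param seed RNG seed.
#' @param n_proteins,mean_length synthetic root proteome size.
#' @param generations,per_gen_fraction clade depth (default 3, 8 leaves)
#'   and mutation fraction per generation (default 0.2).
#' @param donor,recipient leaf IDs; defaults described above.
#' @param tree_method `"bionj"` or `"nj"`.
#' @param params a [search_params()] object.
#' @return an object of class `prophy_lgt_report`: list with `table`
#'   (fraction, rf; fraction 0 is the unperturbed baseline), `events`,
#'   `config`.
#' @export
recipe_lgt_robustness <- function(fractions = seq(0.1, 0.5, by = 0.1),
                                  seed = 1L, n_proteins = 100L,
                                  mean_length = 300L, generations = 3L,
                                  per_gen_fraction = 0.2,
                                  donor = NULL, recipient = NULL,
                                  tree_method = c("bionj", "nj"),
                                  params = search_params()) {
  tree_method <- match.arg(tree_method)
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  root <- synth_root_proteome(n_proteins, mean_length, seed = seed)
  rec <- evolve_lineages(root, generations, per_gen_fraction,
                         seed = seed + 1L)
  leaves <- rec$leaves
  ids <- names(leaves)
  if (is.null(donor)) donor <- ids[startsWith(ids, "n0")][1L]
  if (is.null(recipient)) recipient <- ids[startsWith(ids, "n1")][1L]
  stopifnot(donor %in% ids, recipient %in% ids, donor != recipient)
  self_list <- lapply(leaves, self_best_evalues, params = params)
  n <- length(ids)
  base <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n)) {
      sp <- .slope_pair(leaves[[i]], leaves[[j]], params,
                        self_list[[i]], self_list[[j]])
      base[i, j] <- base[j, i] <- sp$D
    }
  build <- function(m) if (tree_method == "bionj") bionj(m) else
    neighbor_joining(m)
  rf0 <- rf_distance(build(base), rec$true_tree)
  out <- data.frame(fraction = 0, rf = rf0)
  events <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    lgt <- inject_lgt(leaves[[donor]], leaves[[recipient]], f,
                      seed = seed + 100L + fi)
    events[[fi]] <- lgt$event
    pert <- lgt$proteome
    self_pert <- self_best_evalues(pert, params)
    m <- base
    for (other in setdiff(ids, recipient)) {
      sp <- .slope_pair(pert, leaves[[other]], params,
                        self_pert, self_list[[other]])
      m[recipient, other] <- m[other, recipient] <- sp$D
    }
    out <- rbind(out, data.frame(fraction = f,
                                 rf = rf_distance(build(m), rec$true_tree)))
  }
  structure(list(table = out, events = events,
                 config = list(seed = seed, n_proteins = n_proteins,
                               mean_length = mean_length,
                               generations = generations,
                               per_gen_fraction = per_gen_fraction,
                               donor = donor, recipient = recipient,
                               tree_method = tree_method)),
            class = "prophy_lgt_report")
}

#' @export
print.prophy_lgt_report <- function(x, ...) {
  cat(sprintf("LGT robustness: donor %s -> recipient %s (%d-leaf clade)\n",
              x$config$donor, x$config$recipient,
              2L^x$config$generations))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a validation or LGT report as JSON
#'
#' @param report a `prophy_validation` or `prophy_lgt_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, c("prophy_validation", "prophy_lgt_report")))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
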
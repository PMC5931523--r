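# In-silico proteome evolution: synthetic root proteomes, per-generation
# fractional residue mutation, balanced bifurcating lineages with a known
# true tree, and lateral gene transfer.

# Robinson & Robinson (1991) background amino-acid frequencies.
.aa_background <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364,
                    C = 0.01925, Q = 0.04264, E = 0.06295, G = 0.07377,
                    H = 0.02199, I = 0.05142, L = 0.09019, K = 0.05744,
                    M = 0.02243, F = 0.03856, P = 0.05203, S = 0.07120,
                    T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Generate a synthetic root proteome
#'
#' Sequences are drawn i.i.d. from standard background amino-acid
#' frequencies (Robinson-Robinson); lengths are log-normal around
#' `mean_length` (floored at 40 residues). Deterministic given `seed`.
#' Used as the ancestral genome of the in-silico evolution experiments, in
#' place of a downloaded bacterial proteome.
#'
#' @param n_proteins number of proteins (>= 10).
#' @param mean_length mean sequence length in residues.
#' @param seed optional RNG seed.
#' @param sdlog log-scale standard deviation of the length distribution
#'   (default 0.35, a realistic spread for bacterial ORF lengths).
#' @param organism_id organism ID of the generated proteome.
#' @return a `proteome`.
#' @export
synth_root_proteome <- function(n_proteins, mean_length = 300L, seed = NULL,
                                sdlog = 0.35, organism_id = "root") {
  stopifnot(n_proteins >= 10L, mean_length >= 40L)
  if (!is.null(seed)) set.seed(seed)
  meanlog <- log(mean_length) - sdlog^2 / 2
  lens <- pmax(40L, as.integer(round(stats::rlnorm(n_proteins, meanlog, sdlog))))
  seqs <- vapply(lens, function(L)
    paste(sample(names(.aa_background), L, replace = TRUE,
                 prob = .aa_background), collapse = ""), character(1))
  proteome(setNames(seqs, sprintf("g%04d", seq_len(n_proteins))), organism_id)
}

#' Mutate a fixed fraction of proteome residues
#'
#' Selects exactly `round(fraction * total_residues)` positions uniformly
#' without replacement across the whole proteome (no per-protein quota) and
#' replaces each selected residue with a draw uniform over the 20 standard
#' amino acids. Self-replacement is allowed, so the expected fraction of
#' residues actually changed in one round is `fraction * 19/20`. Gene
#' count, IDs and lengths are invariant.
#'
#' @param p a `proteome`.
#' @param fraction fraction of residues to mutate, in \[0, 1\].
#' @param seed optional RNG seed; by default the current RNG stream is used
#'   (so callers can seed once for a whole experiment).
#' @param exclude_self if `TRUE`, replacements are drawn uniformly from the
#'   19 other residues instead (expected changed fraction = `fraction`).
#' @return the mutated `proteome`.
#' @export
mutate_proteome <- function(p, fraction, seed = NULL, exclude_self = FALSE) {
  stopifnot(inherits(p, "proteome"), fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- total_residues(p)
  k <- round(fraction * N)
  if (k == 0) return(p)
  idx <- sort(sample.int(N, k))
  lens <- nchar(p$seq)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  pi <- findInterval(idx, starts)
  pos <- idx - starts[pi] + 1L
  aa20 <- names(.aa_background)
  res <- sample(aa20, k, replace = TRUE)
  for (u in unique(pi)) {
    sel <- pi == u
    ch <- strsplit(p$seq[u], "", fixed = TRUE)[[1L]]
    if (exclude_self) {
      cur <- ch[pos[sel]]
      r <- res[sel]
      redo <- r == cur
      while (any(redo)) {
        r[redo] <- sample(aa20, sum(redo), replace = TRUE)
        redo <- r == cur
      }
      ch[pos[sel]] <- r
    } else {
      ch[pos[sel]] <- res[sel]
    }
    p$seq[u] <- paste(ch, collapse = "")
  }
  p
}

#' Evolve balanced bifurcating lineages from a root proteome
#'
#' Every node spawns two children, each independently mutated by
#' `per_gen_fraction`; after `generations` rounds the `2^generations` leaf
#' proteomes are returned together with the true genealogy (a rooted,
#' fully balanced binary tree with unit branch lengths per generation).
#' Leaf IDs encode the lineage path as a bit string (`n01101`: first split
#' side 0, second split side 1, ...), so the generation of any pair's most
#' recent common ancestor can be read off the common prefix. Fully
#' reproducible given `seed`.
#'
#' @param root a `proteome`.
#' @param generations number of bifurcating generations (>= 1).
#' @param per_gen_fraction fraction of residues mutated per generation.
#' @param seed optional RNG seed.
#' @return an object of class `lineage_record` with elements `root`,
#'   `leaves` (named list of proteomes), `true_tree` (an `ape` phylo),
#'   `generations`, `per_gen_fraction`.
#' @export
evolve_lineages <- function(root, generations, per_gen_fraction, seed = NULL) {
  stopifnot(inherits(root, "proteome"), generations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  generations <- as.integer(generations)
  leaves <- vector("list", 2L^generations)
  n_leaf <- 0L
  descend <- function(p, path) {
    if (nchar(path) == generations) {
      p$organism_id <- paste0("n", path)
      n_leaf <<- n_leaf + 1L
      leaves[[n_leaf]] <<- p
      return(invisible(NULL))
    }
    for (b in c("0", "1"))
      descend(mutate_proteome(p, per_gen_fraction), paste0(path, b))
  }
  # depth-first, branch 0 before branch 1: deterministic RNG consumption
  for (b in c("0", "1")) descend(mutate_proteome(root, per_gen_fraction), b)
  names(leaves) <- vapply(leaves, `[[`, "", "organism_id")
  nwk <- local({
    build <- function(path, d) {
      if (d == generations) return(paste0("n", path, ":1"))
      paste0("(", build(paste0(path, "0"), d + 1L), ",",
             build(paste0(path, "1"), d + 1L), "):1")
    }
    paste0("(", build("0", 1L), ",", build("1", 1L), ");")
  })
  structure(list(root = root, leaves = leaves,
                 true_tree = ape::read.tree(text = nwk),
                 generations = generations,
                 per_gen_fraction = per_gen_fraction),
            class = "lineage_record")
}

#' @export
print.lineage_record <- function(x, ...) {
  cat(sprintf(paste0("Lineage record: %d generations at %.0f%% mutation, ",
                     "%d leaves of %d proteins\n"),
              x$generations, 100 * x$per_gen_fraction, length(x$leaves),
              length(x$root$id)))
  invisible(x)
}

#' Generation of the most recent common ancestor of two leaves
#'
#' Returns the split index (1 = first split at the root, `generations` =
#' the final split producing siblings) of the most recent common ancestor
#' of two leaves of a `lineage_record`, decoded from the common prefix of
#' their lineage-path IDs.
#'
#' @param leaf_a,leaf_b leaf organism IDs.
#' @param record a `lineage_record`.
#' @return integer MRCA generation in `1..generations`.
#' @export
mrca_generation <- function(leaf_a, leaf_b, record) {
  stopifnot(inherits(record, "lineage_record"))
  for (l in c(leaf_a, leaf_b))
    if (!l %in% names(record$leaves)) stop("unknown leaf: ", l)
  if (leaf_a == leaf_b) stop("leaves must be distinct")
  a <- strsplit(sub("^n", "", leaf_a), "")[[1L]]
  b <- strsplit(sub("^n", "", leaf_b), "")[[1L]]
  p <- 0L
  for (k in seq_along(a)) {
    if (a[k] == b[k]) p <- p + 1L else break
  }
  p + 1L
}

#' Inject a lateral gene transfer event
#'
#' Copies `round(fraction * gene count)` randomly selected donor genes into
#' the recipient. In the default `replace` mode each transferred gene
#' replaces the recipient gene at the same index position (genome size
#' conserved; the recipient keeps its own protein IDs). In `add` mode the
#' transferred genes are appended under `lgt.`-prefixed IDs (genome grows).
#'
#' @param donor,recipient `proteome`s; `replace` mode requires equal gene
#'   counts (as for leaves of one simulated clade).
#' @param fraction fraction of donor genes to transfer, in \[0, 1\].
#' @param seed optional RNG seed.
#' @param mode `"replace"` (default) or `"add"`.
#' @return list with elements `proteome` (the modified recipient) and
#'   `event` (donor, recipient, fraction, mode, transferred donor gene IDs
#'   and their index positions).
#' @export
inject_lgt <- function(donor, recipient, fraction, seed = NULL,
                       mode = c("replace", "add")) {
  mode <- match.arg(mode)
  stopifnot(inherits(donor, "proteome"), inherits(recipient, "proteome"),
            fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction * length(donor$id))
  idx <- if (k > 0) sort(sample.int(length(donor$id), k)) else integer(0)
  if (mode == "replace") {
    if (length(donor$id) != length(recipient$id))
      stop("replace mode requires equal gene counts (donor ",
           length(donor$id), ", recipient ", length(recipient$id), ")")
    recipient$seq[idx] <- donor$seq[idx]
  } else if (k > 0) {
    new_ids <- paste0("lgt.", donor$organism_id, ".", donor$id[idx])
    recipient$seq <- c(recipient$seq, donor$seq[idx])
    recipient$id <- c(recipient$id, new_ids)
  }
  event <- list(donor = donor$organism_id, recipient = recipient$organism_id,
                fraction = fraction, mode = mode,
                transferred_ids = donor$id[idx], positions = idx)
  list(proteome = recipient, event = event)
}
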
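#' Construct a proteome
#'
#' A proteome is the ordered set of ORF amino-acid sequences of one
#' organism. Sequences are uppercased and validated against the IUPAC
#' amino-acid alphabet (B, Z, X and the rare J, U, O are tolerated; they are
#' scored at the mismatch floor during alignment). `*` stop characters are
#' stripped with a warning.
#'
#' @param sequences named character vector of amino-acid sequences; names
#'   are the protein IDs and must be unique.
#' @param organism_id single string identifying the organism.
#' @return an object of class `proteome` with elements `organism_id`, `id`,
#'   and `seq`.
#' @examples
#' p <- proteome(c(a = "MKV", b = "MA"), "toy")
#' total_residues(p)
#' @export
proteome <- function(sequences, organism_id) {
  stopifnot(is.character(sequences), is.character(organism_id),
            length(organism_id) == 1L, nzchar(organism_id))
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must be named with protein IDs")
  if (anyDuplicated(ids))
    stop("duplicate protein ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(sequences)
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  if (any(nchar(seqs) < 1L))
    stop("zero-length sequence(s): ",
         paste(ids[nchar(seqs) < 1L], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(.aa_alphabet, collapse = "")), seqs)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  structure(list(organism_id = organism_id,
                 id = unname(ids), seq = unname(seqs)),
            class = "proteome")
}

#' Total residue count of a proteome
#'
#' Always recomputed from the sequences, never trusted from a file.
#'
#' @param p a `proteome`.
#' @return integer, the sum of sequence lengths.
#' @export
total_residues <- function(p) {
  stopifnot(inherits(p, "proteome"))
  sum(nchar(p$seq))
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s': %d proteins, %d residues\n",
              x$organism_id, length(x$id), total_residues(x)))
  invisible(x)
}

#' @export
length.proteome <- function(x) length(x$id)

#' Read a proteome from a multi-FASTA amino-acid file
#'
#' One `proteome` per file, one protein per FASTA record, record order
#' preserved. The protein ID is the first whitespace-delimited token of the
#' header. The organism ID defaults to the file basename without extension.
#'
#' @param path path to a FASTA file.
#' @param organism_id optional organism ID overriding the filename default.
#' @return a `proteome`.
#' @export
read_fasta <- function(path, organism_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate record ID(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(aa)
  nuc <- sum(nchar(gsub("[^ACGTNacgtn]", "", seqs)))
  if (nuc >= 0.95 * sum(nchar(seqs)))
    warning("sequences in ", path, " look like nucleotides (>= 95% ACGTN)")
  if (is.null(organism_id))
    organism_id <- sub("\\.[^.]*$", "", basename(path))
  proteome(setNames(seqs, ids), organism_id)
}

#' Write a proteome as 60-column wrapped FASTA
#'
#' `read_fasta()` inverts it exactly on (id, sequence) pairs.
#'
#' @param p a `proteome`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(p, path) {
  stopifnot(inherits(p, "proteome"))
  if (length(p$id) == 0L) stop("refusing to write an empty proteome")
  aa <- Biostrings::AAStringSet(setNames(p$seq, p$id))
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}
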
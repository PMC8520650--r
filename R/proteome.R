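#' Simulate a background proteome
#'
#' Draws protein sequences i.i.d. from a residue composition over the twenty
#' standard amino acids. The result stands in for a reference proteome (e.g.
#' the mouse proteome used as a motif background) in synthetic studies.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer vector `c(min, max)` of sequence lengths in
#'   residues; `min` must be >= 15 so every site admits a full 15-mer window.
#' @param aa_frequencies Named numeric vector of residue frequencies over (a
#'   subset of) the twenty standard amino acids, summing to 1 within 1e-6.
#'   Defaults to the uniform composition.
#' @param seed Optional integer seed; identical seeds give identical proteomes.
#' @return A tibble with columns `accession` and `sequence`.
#' @examples
#' simulate_proteome(3, c(20, 30), seed = 1)
#' @export
simulate_proteome <- function(n_proteins = 1000L,
                              length_range = c(100L, 500L),
                              aa_frequencies = NULL,
                              seed = NULL) {
  if (n_proteins < 1) phos_abort("n_proteins must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] < 15 || length_range[2] < length_range[1]) {
    phos_abort("length_range must be c(min, max) with min >= 15")
  }
  aa <- aa_alphabet()
  if (is.null(aa_frequencies)) {
    aa_frequencies <- setNames(rep(1 / 20, 20), aa)
  }
  bad <- setdiff(names(aa_frequencies), aa)
  if (length(bad) > 0 || is.null(names(aa_frequencies))) {
    phos_abort("aa_frequencies must be named with standard one-letter residue codes")
  }
  if (abs(sum(aa_frequencies) - 1) > 1e-6) {
    phos_abort("aa_frequencies must sum to 1 (got %.8f)", sum(aa_frequencies))
  }

  with_seed_if(seed, {
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n_proteins)
    } else {
      sample(seq(length_range[1], length_range[2]), n_proteins, replace = TRUE)
    }
    residues <- sample(names(aa_frequencies), sum(lens), replace = TRUE,
                       prob = aa_frequencies)
    seqs <- vapply(split(residues, rep(seq_len(n_proteins), lens)),
                   paste0, character(1), collapse = "")
    tibble::tibble(
      accession = sprintf("SYNP%04d", seq_len(n_proteins)),
      sequence = unname(seqs)
    )
  })
}

#' Read or write a proteome FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] returning/accepting the tibble
#' representation used throughout the package.
#'
#' @param path FASTA file path.
#' @return `read_proteome()`: a tibble with `accession`, `sequence`.
#' @export
read_proteome <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  tibble::tibble(accession = names(s), sequence = unname(as.character(s)))
}

#' @rdname read_proteome
#' @param proteome Tibble with columns `accession`, `sequence`.
#' @export
write_proteome <- function(proteome, path) {
  stopifnot_cols(proteome, c("accession", "sequence"), "proteome")
  set <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$accession))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Enumerate phospho-acceptor residues of a proteome
#'
#' @param proteome Tibble with `accession`, `sequence`.
#' @param residues Residues to locate; defaults to the phospho-acceptors S/T/Y.
#' @return Tibble with columns `protein`, `residue`, `position` (1-based).
#' @export
proteome_sites <- function(proteome, residues = c("S", "T", "Y")) {
  stopifnot_cols(proteome, c("accession", "sequence"), "proteome")
  pat <- paste0("[", paste(residues, collapse = ""), "]")
  locs <- stringr::str_locate_all(proteome$sequence, pat)
  n <- vapply(locs, nrow, integer(1))
  pos <- unlist(lapply(locs, function(m) m[, 1L]), use.names = FALSE)
  prot <- rep(proteome$accession, n)
  res <- stringr::str_sub(rep(proteome$sequence, n), pos, pos)
  tibble::tibble(protein = prot, residue = res, position = as.integer(pos))
}
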
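#' Extract 15-residue sequence windows around phosphosites
#'
#' Returns the proteome context from -7 to +7 around each site, with the
#' central residue lowercased (s/t/y) and positions beyond the protein's ends
#' padded with `_`.
#'
#' @param sites Tibble with `protein`, `residue`, `position`.
#' @param proteome Proteome tibble (`accession`, `sequence`).
#' @param flank Residues on each side of the site (7 gives the standard
#'   15-mer).
#' @return `sites` with a `window` character column added.
#' @examples
#' prot <- tibble::tibble(accession = "P1", sequence = "MKSPQRSTYAAATTT")
#' extract_windows(tibble::tibble(protein = "P1", residue = "S",
#'                                position = 3L), prot)
#' @export
extract_windows <- function(sites, proteome, flank = 7L) {
  stopifnot_cols(sites, c("protein", "residue", "position"), "sites")
  stopifnot_cols(proteome, c("accession", "sequence"), "proteome")
  seqs <- setNames(proteome$sequence, proteome$accession)
  missing <- setdiff(sites$protein, names(seqs))
  if (length(missing) > 0) {
    phos_abort("site protein(s) absent from proteome: %s",
               paste(head(missing, 3), collapse = ", "))
  }
  if (nrow(sites) == 0) return(dplyr::mutate(sites, window = character(0)))
  seq <- seqs[sites$protein]
  at <- substr(seq, sites$position, sites$position)
  bad <- at != sites$residue
  if (any(bad)) {
    i <- which(bad)[1]
    phos_abort("residue mismatch at %s position %d: proteome has %s, site says %s",
               sites$protein[i], sites$position[i], at[i], sites$residue[i])
  }
  pad <- strrep("_", flank)
  padded <- paste0(pad, seq, pad)
  win <- substr(padded, sites$position, sites$position + 2L * flank)
  substr(win, flank + 1L, flank + 1L) <- tolower(sites$residue)
  dplyr::mutate(sites, window = unname(win))
}
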
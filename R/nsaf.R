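#' Spectral counts per protein
#'
#' Counts distinct PSMs per protein accession across all experiments. By
#' default only the non-phosphorylated population contributes, matching the
#' use of the non-enriched proteome for abundance estimation.
#'
#' @param psms PSM tibble.
#' @param include_phospho Also count phosphorylated PSMs.
#' @return Tibble `protein`, `spectral_count`.
#' @export
spectral_counts <- function(psms, include_phospho = FALSE) {
  stopifnot_cols(psms, c("psm_id", "protein", "population"), "psms")
  df <- if (include_phospho) psms else dplyr::filter(psms, .data$population == "nonphospho")
  df |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(spectral_count = dplyr::n_distinct(.data$psm_id),
                     .groups = "drop")
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Relative protein abundance from spectral counts: the spectral abundance
#' factor of a protein is its PSM count divided by its length in residues;
#' NSAF divides each SAF by the sum of SAFs over all detected proteins, so
#' NSAF values sum to 1.
#'
#' @param counts Tibble `protein`, `spectral_count` (see [spectral_counts()]),
#'   with counts >= 1 for every detected protein.
#' @param proteome Proteome tibble (`accession`, `sequence`) or a named
#'   numeric vector of protein lengths.
#' @return Tibble `protein`, `spectral_count`, `length`, `saf`, `nsaf`,
#'   sorted by decreasing `nsaf`.
#' @examples
#' counts <- tibble::tibble(protein = c("A", "B"), spectral_count = c(10, 20))
#' compute_nsaf(counts, c(A = 100, B = 200))
#' @export
compute_nsaf <- function(counts, proteome) {
  stopifnot_cols(counts, c("protein", "spectral_count"), "counts")
  lengths <- if (is.numeric(proteome)) {
    proteome
  } else {
    stopifnot_cols(proteome, c("accession", "sequence"), "proteome")
    setNames(nchar(proteome$sequence), proteome$accession)
  }
  missing <- setdiff(counts$protein, names(lengths))
  if (length(missing) > 0) {
    phos_abort("no protein length available for accession(s): %s",
               paste(head(missing, 3), collapse = ", "))
  }
  if (any(counts$spectral_count < 1)) {
    phos_abort("spectral counts of detected proteins must be >= 1")
  }
  len <- unname(lengths[counts$protein])
  if (any(len <= 0)) phos_abort("protein lengths must be positive")
  counts |>
    dplyr::mutate(
      length = as.integer(len),
      saf = .data$spectral_count / .data$length,
      nsaf = .data$saf / sum(.data$saf)
    ) |>
    dplyr::arrange(dplyr::desc(.data$nsaf))
}
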
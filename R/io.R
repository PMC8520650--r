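#' Read and write the pipeline's tab-separated tables
#'
#' PSM tables carry one row per peptide-spectrum match with columns `psm_id`,
#' `experiment_id`, `peptide`, `protein`, `site_positions` (semicolon-joined
#' residue+position strings such as `S727`, empty for non-phospho PSMs),
#' `population` (`nonphospho`/`mono`/`multi`) and one numeric intensity column
#' per channel. Designs, annotations and quantification tables are plain TSV
#' with header rows.
#'
#' @param path File path.
#' @return The corresponding tibble.
#' @export
read_psm_table <- function(path) {
  psms <- readr::read_tsv(path, col_types = readr::cols(
    psm_id = readr::col_character(),
    experiment_id = readr::col_character(),
    peptide = readr::col_character(),
    protein = readr::col_character(),
    site_positions = readr::col_character(),
    population = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_psm_table(psms)
}

#' @rdname read_psm_table
#' @param psms PSM tibble.
#' @export
write_psm_table <- function(psms, path) {
  validate_psm_table(psms)
  readr::write_tsv(psms, path)
  invisible(path)
}

#' Validate PSM-table invariants
#'
#' Checks that the population label agrees with the number of localized sites
#' (nonphospho: none; mono: one; multi: two or more) and that every PSM has a
#' positive intensity in at least one channel.
#'
#' @param psms PSM tibble.
#' @param proteome Optional proteome tibble; when given, every site's residue
#'   is checked against the sequence at its position.
#' @return The PSM tibble, invisibly usable in a pipe; errors otherwise.
#' @export
validate_psm_table <- function(psms, proteome = NULL) {
  stopifnot_cols(psms, c("psm_id", "experiment_id", "peptide", "protein",
                         "site_positions", "population"), "psms")
  n_sites <- ifelse(is.na(psms$site_positions) | psms$site_positions == "", 0L,
                    stringr::str_count(psms$site_positions, ";") + 1L)
  expected <- dplyr::case_when(
    psms$population == "nonphospho" ~ n_sites == 0L,
    psms$population == "mono" ~ n_sites == 1L,
    psms$population == "multi" ~ n_sites >= 2L,
    TRUE ~ FALSE
  )
  if (!all(expected)) {
    i <- which(!expected)[1]
    phos_abort("PSM %s: population '%s' inconsistent with %d localized site(s)",
               psms$psm_id[i], psms$population[i], n_sites[i])
  }
  meta <- c("psm_id", "experiment_id", "peptide", "protein", "site_positions",
            "population")
  intensity_cols <- setdiff(names(psms), meta)
  if (length(intensity_cols) == 0) phos_abort("PSM table has no intensity columns")
  mx <- as.matrix(psms[intensity_cols])
  if (any(mx < 0, na.rm = TRUE)) phos_abort("negative reporter intensities")
  if (any(rowSums(mx > 0, na.rm = TRUE) == 0)) {
    phos_abort("PSM(s) without any positive channel intensity")
  }
  if (!is.null(proteome)) {
    phos <- psms[n_sites > 0, c("psm_id", "protein", "site_positions")]
    parsed <- parse_site_string(phos$site_positions)
    sites <- tibble::tibble(protein = phos$protein[parsed$.row],
                            residue = parsed$residue,
                            position = parsed$position) |>
      dplyr::distinct()
    extract_windows(sites, proteome)  # errors on any mismatch
  }
  invisible(psms)
}

#' @rdname read_psm_table
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot_cols(raw, c("kinase_accession", "site", "effect"), "annotations")
  parsed <- parse_site_string(raw$site)
  tibble::tibble(
    kinase = raw$kinase_accession,
    residue = parsed$residue,
    position = parsed$position,
    effect = raw$effect
  )
}

#' @rdname read_psm_table
#' @param annotations Annotation tibble (`kinase`, `residue`, `position`,
#'   `effect`).
#' @export
write_annotations <- function(annotations, path) {
  stopifnot_cols(annotations, c("kinase", "residue", "position", "effect"),
                 "annotations")
  readr::write_tsv(
    tibble::tibble(
      kinase_accession = annotations$kinase,
      site = format_site(annotations$residue, annotations$position),
      effect = annotations$effect
    ),
    path
  )
  invisible(path)
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits the proteome FASTA, PSM TSV, design TSV, annotation TSV and a
#' ground-truth TSV of planted site fold changes into a directory. Re-reading
#' with the package's readers is lossless.
#'
#' @param study A `phos_study` ([simulate_phospho_study()]).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "phos_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome(study$proteome, file.path(dir, "proteome.fasta"))
  write_psm_table(study$psms, file.path(dir, "psms.tsv"))
  write_design(study$design, file.path(dir, "design.tsv"))
  if (!is.null(study$annotations)) {
    write_annotations(study$annotations, file.path(dir, "annotations.tsv"))
  }
  readr::write_tsv(study$truth$detected_sites, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
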
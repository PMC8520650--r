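#' Default 4-plex duplicate-experiment design
#'
#' Two labelling experiments with four isobaric channels each: two reference
#' channels (the first of which is the ratio denominator) and two treated
#' channels. This mirrors a study run with n = 2 per genotype per run, ratios
#' formed against the untreated/reference condition.
#'
#' @param n_experiments Number of duplicate labelling experiments.
#' @param channels Channel labels (column names of the PSM intensity columns).
#' @param reference,treatment Sample labels for the reference and treated
#'   conditions. Sample labels name conditions, so replicates of the same
#'   condition share a label and are pooled during aggregation.
#' @param n_reference_channels How many of the channels carry the reference
#'   condition (the first one is the denominator).
#' @return A design tibble with columns `experiment_id`, `channel`,
#'   `sample_label`, `is_denominator`.
#' @examples
#' default_design()
#' @export
default_design <- function(n_experiments = 2L,
                           channels = c("114", "115", "116", "117"),
                           reference = "WT",
                           treatment = "IFN",
                           n_reference_channels = 2L) {
  stopifnot(n_reference_channels >= 1, n_reference_channels < length(channels))
  labels <- c(rep(reference, n_reference_channels),
              rep(treatment, length(channels) - n_reference_channels))
  purrr::map_dfr(seq_len(n_experiments), function(e) {
    tibble::tibble(
      experiment_id = sprintf("exp%d", e),
      channel = channels,
      sample_label = labels,
      is_denominator = seq_along(channels) == 1L
    )
  })
}

#' Validate an experimental-design table
#'
#' Checks the design invariants: exactly one denominator channel per
#' experiment and channel labels unique within an experiment.
#'
#' @param design Design tibble (`experiment_id`, `channel`, `sample_label`,
#'   `is_denominator`).
#' @return The design, invisibly; errors otherwise.
#' @export
validate_design <- function(design) {
  stopifnot_cols(design, c("experiment_id", "channel", "sample_label", "is_denominator"),
                 "design")
  chk <- design |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(
      n_den = sum(.data$is_denominator),
      dup = anyDuplicated(.data$channel) > 0,
      .groups = "drop"
    )
  bad_den <- chk$experiment_id[chk$n_den != 1]
  if (length(bad_den) > 0) {
    phos_abort("experiment(s) without exactly one denominator channel: %s",
               paste(bad_den, collapse = ", "))
  }
  if (any(chk$dup)) {
    phos_abort("duplicated channel labels within experiment(s): %s",
               paste(chk$experiment_id[chk$dup], collapse = ", "))
  }
  invisible(design)
}

#' @rdname read_psm_table
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    experiment_id = readr::col_character(),
    channel = readr::col_character(),
    sample_label = readr::col_character(),
    is_denominator = readr::col_logical()
  ))
  validate_design(d)
  d
}

#' @rdname read_psm_table
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  readr::write_tsv(design, path)
  invisible(path)
}
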
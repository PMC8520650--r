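#' PhosphoSitePlus-weighted kinase activity scores
#'
#' For each kinase with at least one significant annotated regulatory site,
#' the activity score is the PSM-weighted, direction-signed average of the
#' combined log2 fold changes of its significant annotated sites:
#' `score = sum(L_s * n_s * d_s) / sum(n_s)` with `L_s` the site's combined
#' log2 fold change, `n_s` its total PSM count and `d_s` +1 for
#' "activity, induced" or -1 for "activity, inhibited". The score is on the
#' log2-fold-change scale; kinases are called increased at
#' `score >= threshold`, decreased at `score <= -threshold`, else unchanged.
#' The default threshold 0.53 is the published constant for a 1.5-fold change
#' in activity.
#'
#' Annotated sites that were not detected are ignored for scoring and counted
#' in the coverage summary (attribute `"coverage"`), as are kinases with no
#' significant annotated site.
#'
#' @param site_quant Flagged phosphosite quantification tibble
#'   ([quantify_psms()] at level `"phosphosite"`), restricted to a single
#'   contrast sample.
#' @param annotations Regulatory-site annotation tibble with columns
#'   `kinase`, `residue`, `position`, `effect` (effect exactly
#'   `"activity, induced"` or `"activity, inhibited"`).
#' @param threshold Call threshold on the score magnitude.
#' @return Tibble `kinase`, `score`, `n_sites`, `n_psms`, `call`
#'   (increased/decreased/unchanged), with a coverage summary attached as
#'   attribute `"coverage"`.
#' @export
activity_scores <- function(site_quant, annotations, threshold = 0.53) {
  stopifnot_cols(site_quant, c("protein", "residue", "position", "z", "log2fc",
                               "n_psms", "significant"), "site_quant")
  stopifnot_cols(annotations, c("kinase", "residue", "position", "effect"),
                 "annotations")
  bad <- setdiff(unique(annotations$effect),
                 c("activity, induced", "activity, inhibited"))
  if (length(bad) > 0) {
    phos_abort("invalid effect value(s): %s", paste(bad, collapse = "; "))
  }
  if (length(unique(site_quant$sample_label %||% "x")) > 1) {
    phos_abort("site_quant spans multiple contrast samples; filter to one")
  }
  joined <- annotations |>
    dplyr::left_join(
      site_quant |>
        dplyr::select("protein", "residue", "position", "z", "log2fc",
                      "n_psms", "significant"),
      by = c(kinase = "protein", "residue", "position")
    ) |>
    dplyr::mutate(detected = !is.na(.data$z))

  scores <- joined |>
    dplyr::filter(.data$detected, .data$significant) |>
    dplyr::mutate(d = ifelse(.data$effect == "activity, induced", 1, -1)) |>
    dplyr::group_by(.data$kinase) |>
    dplyr::summarise(
      score = sum(.data$log2fc * .data$n_psms * .data$d) / sum(.data$n_psms),
      n_sites = dplyr::n(),
      n_psms = sum(.data$n_psms),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      call = dplyr::case_when(
        .data$score >= threshold ~ "increased",
        .data$score <= -threshold ~ "decreased",
        TRUE ~ "unchanged"
      )
    ) |>
    dplyr::arrange(dplyr::desc(abs(.data$score)))

  coverage <- joined |>
    dplyr::group_by(.data$kinase) |>
    dplyr::summarise(
      n_annotated = dplyr::n(),
      n_detected = sum(.data$detected),
      n_significant = sum(.data$significant, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(scored = .data$kinase %in% scores$kinase)
  attr(scores, "coverage") <- coverage
  attr(scores, "threshold") <- threshold
  scores
}

#' Consensus substrate motifs of the major kinase families
#'
#' The proline-directed MAPK/CDK motifs (sP and sP...K), the acidophilic
#' casein-kinase motif (s.E) and the basophilic CaMK motif (R..s).
#'
#' @return Tibble `family`, `pattern`.
#' @export
phos_family_patterns <- function() {
  tibble::tibble(
    family = c("MAPK/CDK", "MAPK/CDK", "CK", "CaMK"),
    pattern = c("sP", "sP...K", "s.E", "R..s")
  )
}

#' Link phosphopeptides to kinase families by consensus-motif matching
#'
#' A phosphopeptide is linked to a family when any of its sites' windows
#' matches one of the family's consensus patterns.
#'
#' @param peptide_windows Tibble with columns `peptide`, `site_positions` and
#'   `window` (one row per site of each phosphopeptide).
#' @param family_patterns Tibble `family`, `pattern`
#'   ([phos_family_patterns()]).
#' @return Link tibble `peptide`, `site_positions`, `family` (distinct).
#' @export
build_family_links <- function(peptide_windows, family_patterns = phos_family_patterns()) {
  stopifnot_cols(peptide_windows, c("peptide", "site_positions", "window"),
                 "peptide_windows")
  stopifnot_cols(family_patterns, c("family", "pattern"), "family_patterns")
  purrr::map_dfr(seq_len(nrow(family_patterns)), function(i) {
    hit <- match_pattern(peptide_windows$window, family_patterns$pattern[i])
    peptide_windows[hit, c("peptide", "site_positions")] |>
      dplyr::mutate(family = family_patterns$family[i])
  }) |>
    dplyr::distinct()
}

#' Percentage of a kinase family's substrates that are upregulated
#'
#' For each kinase family, the number of upregulated linked phosphopeptides
#' is normalized to the total number of detected phosphopeptides linked to
#' that family. A final `(unmatched)` row reports upregulated peptides with
#' no family link as a percentage of all upregulated peptides.
#'
#' @param peptides Tibble of detected phosphopeptides with columns `peptide`,
#'   `site_positions` and a logical `upregulated`.
#' @param links Link tibble `peptide`, `site_positions`, `family`
#'   ([build_family_links()]).
#' @return Tibble `family`, `n_upregulated`, `n_total`, `percentage`, ordered
#'   by decreasing percentage with the `(unmatched)` row last.
#' @export
family_percentages <- function(peptides, links) {
  stopifnot_cols(peptides, c("peptide", "site_positions", "upregulated"),
                 "peptides")
  key <- c("peptide", "site_positions")
  peptides <- dplyr::distinct(peptides, dplyr::across(dplyr::all_of(key)),
                              .keep_all = TRUE)
  per_family <- if (nrow(links) > 0) {
    peptides |>
      dplyr::inner_join(dplyr::distinct(links), by = key,
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(
        n_upregulated = sum(.data$upregulated),
        n_total = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(percentage = 100 * .data$n_upregulated / .data$n_total) |>
      dplyr::arrange(dplyr::desc(.data$percentage))
  } else {
    tibble::tibble(family = character(), n_upregulated = integer(),
                   n_total = integer(), percentage = numeric())
  }
  up <- dplyr::filter(peptides, .data$upregulated)
  linked_keys <- if (nrow(links) > 0) {
    dplyr::distinct(links[, key])
  } else {
    tibble::tibble(peptide = character(), site_positions = character())
  }
  n_up_unmatched <- nrow(dplyr::anti_join(up, linked_keys, by = key))
  unmatched <- tibble::tibble(
    family = "(unmatched)",
    n_upregulated = n_up_unmatched,
    n_total = nrow(up),
    percentage = if (nrow(up) > 0) 100 * n_up_unmatched / nrow(up) else 0
  )
  dplyr::bind_rows(per_family, unmatched)
}
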
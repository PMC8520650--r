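#' Assemble a validated pipeline configuration
#'
#' Inputs may be in-memory tibbles or file paths (FASTA for the proteome, TSV
#' otherwise); paths are read when the pipeline runs. All thresholds must be
#' positive.
#'
#' @param psms PSM table or TSV path.
#' @param design Design table or TSV path.
#' @param proteome Proteome tibble or FASTA path.
#' @param annotations Kinase regulatory-site annotations (tibble/TSV path) or
#'   `NULL` to skip activity scoring.
#' @param family_patterns Kinase-family consensus motifs
#'   ([phos_family_patterns()]).
#' @param bin_size,robust z-scoring parameters ([assign_zscores()]).
#' @param z_phospho,z_protein,fc_threshold,min_protein_psms Significance
#'   thresholds ([call_significance()]).
#' @param activity_threshold Kinase activity call threshold
#'   ([activity_scores()]).
#' @param motif_p_threshold,motif_min_occurrences,motif_center Motif-search
#'   parameters ([motif_enrichment()]).
#' @param motif_background `"proteome"` (all S/T/Y windows of the proteome)
#'   or `"detected"` (windows of detected phosphosites).
#' @param contrast Sample label to analyse against the denominator; defaults
#'   to the single non-reference label of the design.
#' @param out_dir Directory for TSV outputs, or `NULL` to skip writing.
#' @return A list of class `phosflow_config`.
#' @export
pipeline_config <- function(psms, design, proteome, annotations = NULL,
                            family_patterns = phos_family_patterns(),
                            bin_size = 300L, robust = TRUE,
                            z_phospho = 1, z_protein = 1.96,
                            fc_threshold = 1.5, min_protein_psms = 5L,
                            activity_threshold = 0.53,
                            motif_p_threshold = 1e-6,
                            motif_min_occurrences = 20L,
                            motif_center = "each",
                            motif_background = c("proteome", "detected"),
                            contrast = NULL, out_dir = NULL) {
  motif_background <- match.arg(motif_background)
  thresholds <- c(bin_size = bin_size, z_phospho = z_phospho,
                  z_protein = z_protein, fc_threshold = fc_threshold,
                  min_protein_psms = min_protein_psms,
                  activity_threshold = activity_threshold,
                  motif_p_threshold = motif_p_threshold,
                  motif_min_occurrences = motif_min_occurrences)
  if (any(thresholds <= 0)) {
    phos_abort("all thresholds must be positive; offending: %s",
               paste(names(thresholds)[thresholds <= 0], collapse = ", "))
  }
  for (x in list(psms, design, proteome, annotations)) {
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      phos_abort("input file does not exist: %s", x)
    }
  }
  structure(
    list(psms = psms, design = design, proteome = proteome,
         annotations = annotations, family_patterns = family_patterns,
         bin_size = as.integer(bin_size), robust = isTRUE(robust),
         z_phospho = z_phospho, z_protein = z_protein,
         fc_threshold = fc_threshold,
         min_protein_psms = as.integer(min_protein_psms),
         activity_threshold = activity_threshold,
         motif_p_threshold = motif_p_threshold,
         motif_min_occurrences = as.integer(motif_min_occurrences),
         motif_center = motif_center, motif_background = motif_background,
         contrast = contrast, out_dir = out_dir),
    class = "phosflow_config"
  )
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML holds file paths under `inputs:` (`psms`, `design`, `proteome`,
#' optionally `annotations`) and any [pipeline_config()] parameter under
#' `params:`. Relative paths resolve against the YAML's directory.
#'
#' @param path YAML configuration file.
#' @return A `phosflow_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  inputs <- lapply(cfg$inputs, resolve)
  do.call(pipeline_config, c(inputs, cfg$params))
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full quantification and kinase-inference pipeline
#'
#' Orchestrates the whole chain: channel normalization, ratios, intensity-
#' ranked z-scores, aggregation and significance calls at phosphosite,
#' phosphopeptide and protein level, NSAF protein abundance, motif
#' enrichment of upregulated-site windows, kinase-family substrate
#' percentages and kinase activity scores, plus a descriptive principal-
#' component summary of per-channel fold-change vectors. Deterministic given
#' its inputs.
#'
#' @param config A `phosflow_config` ([pipeline_config()]) or YAML path.
#' @return An object of class `phosflow_run`: quantification tibbles under
#'   `$quant`, plus `$nsaf`, `$motifs`, `$families`, `$activity`, `$pca`,
#'   `$report` and the echoed `$config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "phosflow_config"))
  psms <- resolve_input(config$psms, read_psm_table)
  design <- resolve_input(config$design, read_design)
  proteome <- resolve_input(config$proteome, read_proteome)
  annotations <- resolve_input(config$annotations, read_annotations)
  validate_design(design)
  validate_psm_table(psms)

  message("phosflow: normalizing channels")
  scaled <- normalize_channels(psms, design)
  scale_factors <- attr(scaled, "scale_factors")
  message("phosflow: computing ratios and z-scores")
  ratios <- compute_ratios(scaled, design)
  n_dropped <- attr(ratios, "n_dropped")
  ratios <- assign_zscores(ratios, bin_size = config$bin_size,
                           robust = config$robust)
  bin_diagnostics <- attr(ratios, "bin_diagnostics")

  message("phosflow: aggregating and calling significance")
  quant <- list(
    phosphosite = aggregate_quant(ratios, "phosphosite") |>
      call_significance("phosphosite", z_threshold = config$z_phospho,
                        fc_threshold = config$fc_threshold),
    phosphopeptide = aggregate_quant(ratios, "phosphopeptide") |>
      call_significance("phosphopeptide", z_threshold = config$z_phospho,
                        fc_threshold = config$fc_threshold),
    protein = aggregate_quant(ratios, "protein") |>
      call_significance("protein", z_threshold = config$z_protein,
                        fc_threshold = config$fc_threshold,
                        min_psms = config$min_protein_psms)
  )

  ref_labels <- design$sample_label[design$is_denominator]
  contrast <- config$contrast %||% {
    lab <- sort(setdiff(unique(design$sample_label), ref_labels))
    if (length(lab) > 1) {
      message(sprintf("phosflow: multiple contrast labels; using '%s'", lab[1]))
    }
    lab[1]
  }

  site_quant <- dplyr::filter(quant$phosphosite, .data$sample_label == contrast)
  pep_quant <- dplyr::filter(quant$phosphopeptide, .data$sample_label == contrast)

  message("phosflow: NSAF protein abundance")
  nsaf <- compute_nsaf(spectral_counts(psms), proteome)

  message("phosflow: motif enrichment")
  up_sites <- dplyr::filter(site_quant, .data$regulated, .data$log2fc > 0)
  fg <- extract_windows(
    up_sites[, c("protein", "residue", "position")], proteome
  )$window
  bg <- if (config$motif_background == "proteome") {
    extract_windows(proteome_sites(proteome), proteome)$window
  } else {
    extract_windows(
      dplyr::distinct(site_quant[, c("protein", "residue", "position")]),
      proteome
    )$window
  }
  motifs <- motif_enrichment(fg, bg,
                             p_threshold = config$motif_p_threshold,
                             min_occurrences = config$motif_min_occurrences,
                             center = config$motif_center)

  message("phosflow: kinase-family substrate percentages")
  pep_sites <- {
    parsed <- parse_site_string(pep_quant$site_positions)
    tibble::tibble(
      peptide = pep_quant$peptide[parsed$.row],
      site_positions = pep_quant$site_positions[parsed$.row],
      protein = NA_character_, residue = parsed$residue,
      position = parsed$position
    )
  }
  # recover protein accessions for peptide sites from the phospho PSMs
  pep_sites$protein <- psms$protein[match(
    paste(pep_sites$peptide, pep_sites$site_positions),
    paste(psms$peptide, psms$site_positions)
  )]
  pep_windows <- extract_windows(pep_sites[!is.na(pep_sites$protein), ], proteome)
  links <- build_family_links(pep_windows, config$family_patterns)
  families <- family_percentages(
    pep_quant |>
      dplyr::mutate(upregulated = .data$regulated & .data$log2fc > 0) |>
      dplyr::select("peptide", "site_positions", "upregulated"),
    links
  )

  activity <- NULL
  if (!is.null(annotations)) {
    message("phosflow: kinase activity scores")
    activity <- activity_scores(site_quant, annotations,
                                threshold = config$activity_threshold)
  }

  pca <- fold_change_pca(ratios)

  counts <- purrr::map_dfr(names(quant), function(lv) {
    q <- dplyr::filter(quant[[lv]], .data$sample_label == contrast)
    tibble::tibble(level = lv, n_detected = nrow(q),
                   n_significant = sum(q$significant),
                   n_regulated = sum(q$regulated))
  })

  report <- list(
    contrast = contrast,
    counts = counts,
    scale_factors = scale_factors,
    n_dropped_psms = n_dropped,
    n_degenerate_bins = attr(ratios, "n_degenerate_bins"),
    bin_diagnostics = bin_diagnostics,
    thresholds = list(z_phospho = config$z_phospho,
                      z_protein = config$z_protein,
                      fc_threshold = config$fc_threshold,
                      min_protein_psms = config$min_protein_psms,
                      activity_threshold = config$activity_threshold),
    activity_coverage = if (!is.null(activity)) attr(activity, "coverage")
  )

  run <- structure(
    list(quant = quant, nsaf = nsaf, motifs = motifs, families = families,
         activity = activity, pca = pca, report = report, config = config),
    class = "phosflow_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# descriptive PCA of per-channel phosphosite fold-change vectors
fold_change_pca <- function(ratios) {
  df <- ratios |>
    dplyr::filter(!.data$is_denominator, .data$population != "nonphospho")
  if (nrow(df) == 0) return(NULL)
  parsed <- parse_site_string(df$site_positions)
  df <- df[parsed$.row, ]
  df$site <- paste0(df$protein, "-", parsed$residue, parsed$position)
  wide <- df |>
    dplyr::group_by(.data$experiment_id, .data$channel, .data$sample_label,
                    .data$site) |>
    dplyr::summarise(log2fc = median(.data$log2_ratio), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "site", values_from = "log2fc",
                       values_fill = 0)
  if (nrow(wide) < 2) return(NULL)
  mat <- as.matrix(wide[, -(1:3)])
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(fit$x))
  scores <- dplyr::bind_cols(wide[, 1:3], tibble::as_tibble(fit$x[, seq_len(k),
                                                                  drop = FALSE]))
  list(scores = scores,
       variance_explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)])
}

#' Write pipeline outputs as TSV files
#'
#' Emits the per-level quantification tables (with a companion long table of
#' per-experiment medians), NSAF, motif, family-percentage and activity
#' tables, the channel scale factors and a YAML run report. Running the
#' pipeline twice on the same inputs produces byte-identical files.
#'
#' @param run A `phosflow_run`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "phosflow_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lv in names(run$quant)) {
    q <- run$quant[[lv]]
    keys <- quant_keys(lv)
    readr::write_tsv(dplyr::select(q, -"by_experiment"),
                     file.path(dir, paste0("quant_", lv, ".tsv")))
    readr::write_tsv(
      tidyr::unnest(q[, c(keys, "sample_label", "by_experiment")],
                    "by_experiment"),
      file.path(dir, paste0("quant_", lv, "_by_experiment.tsv"))
    )
  }
  readr::write_tsv(run$nsaf, file.path(dir, "nsaf.tsv"))
  motifs <- tidy(run$motifs)
  motifs$p_chain <- vapply(motifs$steps, function(s) {
    paste(signif(s$p_value, 6), collapse = ";")
  }, character(1))
  readr::write_tsv(dplyr::select(motifs, -"steps"), file.path(dir, "motifs.tsv"))
  readr::write_tsv(run$families, file.path(dir, "family_percentages.tsv"))
  if (!is.null(run$activity)) {
    readr::write_tsv(run$activity, file.path(dir, "activity_scores.tsv"))
    readr::write_tsv(attr(run$activity, "coverage"),
                     file.path(dir, "activity_coverage.tsv"))
  }
  readr::write_tsv(run$report$scale_factors, file.path(dir, "scale_factors.tsv"))
  readr::write_tsv(run$report$counts, file.path(dir, "counts.tsv"))
  yaml::write_yaml(
    list(contrast = run$report$contrast,
         thresholds = run$report$thresholds,
         n_dropped_psms = run$report$n_dropped_psms,
         n_degenerate_bins = run$report$n_degenerate_bins),
    file.path(dir, "report.yaml")
  )
  invisible(dir)
}

#' @export
print.phosflow_run <- function(x, ...) {
  cat("<phosflow_run>\n")
  cat(sprintf("  contrast: %s vs denominator\n", x$report$contrast))
  print(x$report$counts)
  if (!is.null(x$activity)) {
    cat(sprintf("  kinases scored: %d (of %d annotated)\n",
                nrow(x$activity), nrow(attr(x$activity, "coverage"))))
  }
  cat(sprintf("  motifs: %d\n", nrow(tidy(x$motifs))))
  invisible(x)
}

#' @export
glance.phosflow_run <- function(x, ...) {
  counts <- x$report$counts
  tibble::tibble(
    contrast = x$report$contrast,
    n_phosphosites = counts$n_detected[counts$level == "phosphosite"],
    n_regulated_sites = counts$n_regulated[counts$level == "phosphosite"],
    n_proteins = counts$n_detected[counts$level == "protein"],
    n_regulated_proteins = counts$n_regulated[counts$level == "protein"],
    n_motifs = nrow(tidy(x$motifs)),
    n_kinases_scored = if (is.null(x$activity)) NA_integer_ else nrow(x$activity),
    n_dropped_psms = x$report$n_dropped_psms
  )
}
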
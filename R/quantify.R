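#' Per-channel scale factors by the sum-of-all-intensities approach
#'
#' Within each labelling experiment, channel intensity sums are computed
#' jointly over all phosphorylated and non-phosphorylated PSMs; the scale
#' factor of a channel is the grand mean of the per-channel sums divided by
#' that channel's sum, so that after scaling every channel sums to the same
#' total.
#'
#' @param psms PSM tibble with one intensity column per channel.
#' @param design Design tibble (see [default_design()]).
#' @return A tibble `experiment_id`, `channel`, `total_intensity`,
#'   `scale_factor`.
#' @export
channel_scale_factors <- function(psms, design) {
  validate_design(design)
  channels <- design_channels(psms, design)
  sums <- psms |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(channels), \(x) sum(x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(channels), names_to = "channel",
                        values_to = "total_intensity")
  zero <- sums[sums$total_intensity <= 0, ]
  if (nrow(zero) > 0) {
    phos_abort("channel %s of %s has zero total intensity",
               zero$channel[1], zero$experiment_id[1])
  }
  sums |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::mutate(scale_factor = mean(.data$total_intensity) / .data$total_intensity) |>
    dplyr::ungroup()
}

#' Normalize reporter channels within each experiment
#'
#' Multiplies every intensity by its channel's scale factor (see
#' [channel_scale_factors()]). After normalization all per-channel sums within
#' an experiment agree to 1e-9 relative tolerance. The factor table is
#' attached as attribute `"scale_factors"`.
#'
#' @inheritParams channel_scale_factors
#' @return The PSM tibble with scaled intensity columns.
#' @examples
#' design <- default_design(n_experiments = 1, channels = c("114", "115"),
#'                          n_reference_channels = 1)
#' psms <- tibble::tibble(psm_id = c("a", "b"), experiment_id = "exp1",
#'                        peptide = "PEPTIDE", protein = "P1",
#'                        site_positions = NA_character_,
#'                        population = "nonphospho",
#'                        `114` = c(40, 60), `115` = c(100, 200))
#' normalize_channels(psms, design)
#' @export
normalize_channels <- function(psms, design) {
  factors <- channel_scale_factors(psms, design)
  channels <- design_channels(psms, design)
  wide <- factors |>
    dplyr::select("experiment_id", "channel", "scale_factor") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "scale_factor")
  fac <- as.matrix(wide[match(psms$experiment_id, wide$experiment_id), channels])
  out <- psms
  out[channels] <- as.data.frame(as.matrix(psms[channels]) * fac)
  attr(out, "scale_factors") <- factors
  out
}

#' Per-PSM log2 reporter ratios against the denominator channel
#'
#' Pivots the normalized PSM table to one row per PSM x channel and computes
#' `log2(intensity / denominator intensity)` together with the PSM's total
#' reporter intensity (the binning statistic for z-scoring). PSMs whose
#' denominator intensity is zero are dropped; the drop count is attached as
#' attribute `"n_dropped"` and reported via a message.
#'
#' @inheritParams channel_scale_factors
#' @return A ratio tibble with columns `psm_id`, `experiment_id`, `protein`,
#'   `peptide`, `site_positions`, `population`, `channel`, `sample_label`,
#'   `is_denominator`, `intensity`, `total_intensity`, `log2_ratio`.
#' @export
compute_ratios <- function(psms, design) {
  validate_design(design)
  channels <- design_channels(psms, design)
  long <- psms |>
    tidyr::pivot_longer(dplyr::all_of(channels), names_to = "channel",
                        values_to = "intensity") |>
    dplyr::inner_join(design, by = c("experiment_id", "channel")) |>
    dplyr::group_by(.data$psm_id, .data$experiment_id) |>
    dplyr::mutate(
      total_intensity = sum(.data$intensity),
      .den = .data$intensity[.data$is_denominator]
    ) |>
    dplyr::ungroup()
  dropped <- long |>
    dplyr::filter(.data$.den <= 0) |>
    dplyr::distinct(.data$psm_id)
  if (nrow(dropped) > 0) {
    message(sprintf("compute_ratios: dropped %d PSM(s) with zero denominator intensity",
                    nrow(dropped)))
  }
  out <- long |>
    dplyr::filter(.data$.den > 0) |>
    dplyr::mutate(log2_ratio = log2(.data$intensity / .data$.den)) |>
    dplyr::select(-".den")
  attr(out, "n_dropped") <- nrow(dropped)
  out
}

# bin assignment for one experiment x channel group, records already ordered
# by descending total intensity
rank_bins <- function(n, bin_size) {
  if (n < 2 * bin_size) return(rep(1L, n))
  bins <- ceiling(seq_len(n) / bin_size)
  n_full <- n %/% bin_size
  remainder <- n - n_full * bin_size
  if (remainder > 0 && remainder < bin_size / 2) {
    bins[bins > n_full] <- n_full
  }
  bins
}

#' Intensity-ranked z-scores for PSM log2 ratios
#'
#' Within each experiment x channel, ratio records are sorted by total
#' reporter intensity (descending) and partitioned into consecutive rank bins
#' of `bin_size` records; a trailing remainder smaller than half a bin is
#' absorbed into the last full bin. Each record's z-score is its log2 ratio
#' standardized by the bin's center and scale: median and 1.4826 x MAD when
#' `robust` (the default, which resists contamination of bin statistics by
#' regulated sites), mean and sd otherwise. Groups with fewer than
#' `2 * bin_size` records fall back to a single global bin. Bins whose scale
#' is zero (all ratios identical) get z = 0 with a warning. Denominator-channel
#' records have ratio 0 by construction and get z = 0.
#'
#' @param ratios Ratio tibble from [compute_ratios()].
#' @param bin_size Records per intensity bin.
#' @param robust Use median/MAD (`TRUE`) or mean/sd (`FALSE`) per bin.
#' @return The ratio tibble with columns `bin` and `z` added; per-bin
#'   diagnostics (center, scale, size) attached as attribute
#'   `"bin_diagnostics"`.
#' @export
assign_zscores <- function(ratios, bin_size = 300L, robust = TRUE) {
  stopifnot_cols(ratios, c("experiment_id", "channel", "is_denominator",
                           "total_intensity", "log2_ratio"), "ratios")
  den <- ratios |>
    dplyr::filter(.data$is_denominator) |>
    dplyr::mutate(bin = NA_integer_, z = 0)
  n_degenerate <- 0L
  scored <- ratios |>
    dplyr::filter(!.data$is_denominator) |>
    dplyr::group_by(.data$experiment_id, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      ord <- order(-df$total_intensity, df$psm_id)
      df <- df[ord, ]
      df$bin <- rank_bins(nrow(df), bin_size)
      df |>
        dplyr::group_by(.data$bin) |>
        dplyr::mutate(
          .center = if (robust) median(.data$log2_ratio) else mean(.data$log2_ratio),
          .scale = if (robust) {
            mad(.data$log2_ratio, constant = 1.4826)
          } else {
            sd(.data$log2_ratio)
          }
        ) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
  degenerate <- !is.finite(scored$.scale) | scored$.scale <= 0
  if (any(degenerate)) {
    n_degenerate <- length(unique(paste(scored$experiment_id[degenerate],
                                        scored$channel[degenerate],
                                        scored$bin[degenerate])))
    phos_warn("assign_zscores: %d bin(s) with zero ratio spread; z set to 0",
              n_degenerate)
  }
  scored$z <- ifelse(degenerate, 0,
                     (scored$log2_ratio - scored$.center) / scored$.scale)
  diagnostics <- scored |>
    dplyr::group_by(.data$experiment_id, .data$channel, .data$bin) |>
    dplyr::summarise(n = dplyr::n(), center = .data$.center[1],
                     scale = .data$.scale[1], .groups = "drop")
  out <- dplyr::bind_rows(
    scored |> dplyr::select(-".center", -".scale"),
    den
  ) |>
    dplyr::arrange(.data$psm_id, .data$channel)
  attr(out, "bin_diagnostics") <- diagnostics
  attr(out, "n_degenerate_bins") <- n_degenerate
  out
}

# level-specific key columns
quant_keys <- function(level) {
  switch(level,
         phosphosite = c("protein", "residue", "position"),
         phosphopeptide = c("peptide", "site_positions"),
         protein = "protein")
}

#' Aggregate PSM-level z-scores and ratios to quantification keys
#'
#' For each key (phosphosite, phosphopeptide, or protein), each contrast
#' sample and each experiment, the median PSM z-score and median log2 ratio
#' are taken; experiments are then combined by the PSM-count-weighted average
#' of the per-experiment medians. Phosphosite level assigns every
#' multiply-phosphorylated PSM to each of its localized sites; phosphopeptide
#' level keys on (peptide, site set); protein level uses non-phospho PSMs
#' only. Denominator-channel records are excluded (their ratio is 0 by
#' construction, not a contrast).
#'
#' @param ratios Ratio tibble with z-scores ([assign_zscores()]).
#' @param level `"phosphosite"`, `"phosphopeptide"` or `"protein"`.
#' @return A quantification tibble with the key columns, `sample_label`,
#'   combined `z`, `log2fc`, `signed_fc`, `n_psms`, `n_experiments`,
#'   `single_experiment`, and a nested `by_experiment` tibble of per-
#'   experiment medians and PSM counts.
#' @export
aggregate_quant <- function(ratios, level = c("phosphosite", "phosphopeptide", "protein")) {
  level <- match.arg(level)
  stopifnot_cols(ratios, c("psm_id", "experiment_id", "protein", "peptide",
                           "site_positions", "population", "sample_label",
                           "is_denominator", "log2_ratio", "z"), "ratios")
  df <- dplyr::filter(ratios, !.data$is_denominator)
  if (level == "protein") {
    df <- dplyr::filter(df, .data$population == "nonphospho")
  } else {
    df <- dplyr::filter(df, .data$population != "nonphospho")
  }
  if (level == "phosphosite") {
    parsed <- parse_site_string(df$site_positions)
    df <- df[parsed$.row, ]
    df$residue <- parsed$residue
    df$position <- parsed$position
  }
  keys <- quant_keys(level)

  per_exp <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "sample_label", "experiment_id")))) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$psm_id),
      median_z = median(.data$z),
      median_log2fc = median(.data$log2_ratio),
      .groups = "drop"
    )

  out <- per_exp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "sample_label")))) |>
    dplyr::summarise(
      z = sum(.data$median_z * .data$n) / sum(.data$n),
      log2fc = sum(.data$median_log2fc * .data$n) / sum(.data$n),
      n_psms = sum(.data$n),
      n_experiments = dplyr::n(),
      by_experiment = list(dplyr::pick("experiment_id", "n", "median_z",
                                       "median_log2fc")),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      signed_fc = signed_fold_change(.data$log2fc),
      single_experiment = .data$n_experiments == 1L
    )
  attr(out, "level") <- level
  out
}

#' Significance and regulation calls
#'
#' Applies the tiered thresholds: phosphosites and phosphopeptides are
#' significant at |z| >= 1 (68.3% central coverage), proteins at |z| >= 1.96
#' (95%) with at least five PSMs. At every level, regulated means significant
#' with |signed fold change| >= 1.5. All comparisons are inclusive.
#'
#' @param quant Quantification tibble from [aggregate_quant()].
#' @param level Quantification level; taken from the `quant` attribute when
#'   omitted.
#' @param z_threshold,fc_threshold,min_psms Override the level defaults
#'   ([default_thresholds()]).
#' @return The tibble with logical columns `significant` and `regulated`;
#'   the thresholds used are attached as attribute `"thresholds"`.
#' @export
call_significance <- function(quant, level = NULL, z_threshold = NULL,
                              fc_threshold = NULL, min_psms = NULL) {
  level <- level %||% attr(quant, "level")
  if (is.null(level)) phos_abort("level not given and not recorded on `quant`")
  defaults <- default_thresholds(level)
  th <- list(z = z_threshold %||% defaults$z,
             fc = fc_threshold %||% defaults$fc,
             min_psms = min_psms %||% defaults$min_psms)
  stopifnot(th$z > 0, th$fc > 0, th$min_psms >= 0)
  out <- quant |>
    dplyr::mutate(
      significant = abs(.data$z) >= th$z & .data$n_psms >= th$min_psms,
      regulated = .data$significant & abs(.data$signed_fc) >= th$fc
    )
  attr(out, "level") <- level
  attr(out, "thresholds") <- th
  out
}

#' One-call quantification from PSMs to flagged results
#'
#' Chains [normalize_channels()], [compute_ratios()], [assign_zscores()],
#' [aggregate_quant()] and [call_significance()].
#'
#' @inheritParams channel_scale_factors
#' @inheritParams assign_zscores
#' @inheritParams aggregate_quant
#' @param ... Threshold overrides passed to [call_significance()].
#' @return A flagged quantification tibble.
#' @export
quantify_psms <- function(psms, design,
                          level = c("phosphosite", "phosphopeptide", "protein"),
                          bin_size = 300L, robust = TRUE, ...) {
  level <- match.arg(level)
  psms |>
    normalize_channels(design) |>
    compute_ratios(design) |>
    assign_zscores(bin_size = bin_size, robust = robust) |>
    aggregate_quant(level = level) |>
    call_significance(level = level, ...)
}
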
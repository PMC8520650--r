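# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# the package's reference desk-scale study with planted effects
fixture_study <- function() {
  memo("study", function() simulate_phospho_study(seed = 101))
}

# same scale, nothing planted (null calibration)
fixture_null_study <- function() {
  memo("null_study", function() simulate_phospho_study(seed = 202, n_regulated = 0))
}

fixture_ratios <- function() {
  memo("ratios", function() {
    study <- fixture_study()
    study$psms |>
      normalize_channels(study$design) |>
      compute_ratios(study$design) |>
      assign_zscores()
  })
}

fixture_site_quant <- function() {
  memo("site_quant", function() {
    fixture_ratios() |>
      aggregate_quant("phosphosite") |>
      call_significance() |>
      dplyr::filter(sample_label == "IFN")
  })
}

zero_noise <- function(...) {
  noise_params(ratio_sd_high = 0, ratio_sd_low = 0, ...)
}

unit_loadings <- function(design) {
  design |>
    dplyr::distinct(experiment_id, channel) |>
    dplyr::mutate(loading = 1)
}

tiny_proteome <- function() {
  tibble::tibble(
    accession = c("P1", "P2"),
    sequence = c("MKAASPQKRSTYAAE", "AAAAAAASAAAAAAAPPPGGS")
  )
}

# hand-built ratio records for aggregation tests
make_ratio_records <- function(z, log2_ratio = z, experiment_id = "exp1",
                               protein = "P1", peptide = "PEPK",
                               site_positions = "S5", population = "mono",
                               sample_label = "IFN", channel = "116",
                               psm_id = NULL) {
  n <- max(length(z), length(log2_ratio))
  z <- rep_len(z, n)
  log2_ratio <- rep_len(log2_ratio, n)
  tibble::tibble(
    psm_id = psm_id %||% sprintf("PSM%03d", seq_len(n)),
    experiment_id = rep_len(experiment_id, n),
    protein = rep_len(protein, n),
    peptide = rep_len(peptide, n),
    site_positions = rep_len(site_positions, n),
    population = rep_len(population, n),
    channel = rep_len(channel, n),
    sample_label = rep_len(sample_label, n),
    is_denominator = FALSE,
    intensity = 100,
    total_intensity = 400,
    log2_ratio = log2_ratio,
    z = z
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
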
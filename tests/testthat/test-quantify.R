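make_wide_psms <- function(i114, i115, experiment_id = "exp1") {
  tibble::tibble(
    psm_id = sprintf("PSM%03d", seq_along(i114)),
    experiment_id = experiment_id,
    peptide = "PEPK", protein = "P1",
    site_positions = NA_character_, population = "nonphospho",
    `114` = i114, `115` = i115
  )
}

two_channel_design <- default_design(n_experiments = 1,
                                     channels = c("114", "115"),
                                     n_reference_channels = 1)

test_that("sum-of-intensities scale factors follow the grand-mean convention", {
  psms <- make_wide_psms(c(40, 60), c(30, 70))
  out <- normalize_channels(psms, two_channel_design)
  expect_equal(attr(out, "scale_factors")$scale_factor, c(1, 1))
  expect_equal(out$`114`, psms$`114`)

  psms2 <- make_wide_psms(c(40, 60), c(100, 200))
  out2 <- normalize_channels(psms2, two_channel_design)
  sf <- attr(out2, "scale_factors")
  expect_equal(sf$scale_factor[sf$channel == "114"], 2)
  expect_equal(sf$scale_factor[sf$channel == "115"], 2 / 3)
  expect_equal(sum(out2$`114`), 200)
  expect_equal(sum(out2$`115`), 200)

  expect_error(normalize_channels(make_wide_psms(c(1, 1), c(0, 0)),
                                  two_channel_design),
               "channel 115.*zero total intensity")
})

test_that("planted channel bias is recovered through normalization", {
  design <- default_design()
  loadings <- unit_loadings(design) |>
    dplyr::mutate(loading = ifelse(channel == "116", 1.7, 1))
  study <- simulate_phospho_study(seed = 31, n_regulated = 0,
                                  channel_loadings = loadings,
                                  noise = zero_noise())
  sf <- channel_scale_factors(study$psms, design) |>
    dplyr::inner_join(loadings, by = c("experiment_id", "channel")) |>
    dplyr::group_by(experiment_id) |>
    dplyr::mutate(grand_mean = mean(loading)) |>
    dplyr::ungroup()
  # factor x loading = grand mean of loadings, i.e. factor recovers 1/bias up
  # to the grand-mean convention
  expect_true(all(abs(sf$scale_factor * sf$loading - sf$grand_mean) < 1e-6))
})

test_that("normalization equalizes channel sums and preserves rank order", {
  study <- fixture_study()
  scaled <- normalize_channels(study$psms, study$design)
  chans <- unique(study$design$channel)
  for (e in unique(study$design$experiment_id)) {
    sums <- colSums(scaled[scaled$experiment_id == e, chans])
    expect_lt(max(abs(sums / mean(sums) - 1)), 1e-9)
    for (ch in chans) {
      expect_identical(order(scaled[[ch]][scaled$experiment_id == e]),
                       order(study$psms[[ch]][study$psms$experiment_id == e]))
    }
  }
})

test_that("log2 ratios follow the denominator convention and drop zero denominators", {
  psms <- tibble::tibble(
    psm_id = c("a", "b", "c"), experiment_id = "exp1",
    peptide = "PEPK", protein = "P1",
    site_positions = NA_character_, population = "nonphospho",
    `114` = c(50, 50, 0), `115` = c(100, 50, 80)
  )
  expect_message(r <- compute_ratios(psms, two_channel_design), "dropped 1 PSM")
  expect_equal(attr(r, "n_dropped"), 1)
  expect_false("c" %in% r$psm_id)
  r115 <- dplyr::filter(r, channel == "115")
  expect_equal(r115$log2_ratio[r115$psm_id == "a"], 1)
  expect_equal(r115$log2_ratio[r115$psm_id == "b"], 0)
  expect_equal(r115$total_intensity[r115$psm_id == "a"], 150)
  expect_true(all(r$log2_ratio[r$is_denominator] == 0))
})

test_that("z-scores standardize per bin with the documented conventions", {
  # zero-spread bin
  flat <- make_ratio_records(z = rep(0, 5), log2_ratio = rep(0.4, 5))
  expect_warning(z1 <- assign_zscores(flat, bin_size = 2), "zero ratio spread")
  expect_true(all(z1$z == 0))

  # {-1, 0, 1} with moment statistics standardizes to itself
  r <- make_ratio_records(z = 0, log2_ratio = c(-1, 0, 1)) |>
    dplyr::mutate(total_intensity = c(300, 200, 100))
  z2 <- assign_zscores(r, bin_size = 300, robust = FALSE)
  expect_equal(sort(z2$z), c(-1, 0, 1))

  # single global bin, non-robust == whole-population standardization
  set.seed(8)
  big <- make_ratio_records(z = 0, log2_ratio = rnorm(400)) |>
    dplyr::mutate(total_intensity = runif(400))
  z3 <- assign_zscores(big, bin_size = 1000, robust = FALSE)
  z3 <- z3[match(big$psm_id, z3$psm_id), ]
  expect_equal(z3$z, as.numeric(scale(big$log2_ratio)), tolerance = 1e-12)

  # z is monotone in the ratio within every bin
  ratios <- fixture_ratios() |> dplyr::filter(!is_denominator)
  chk <- ratios |>
    dplyr::group_by(experiment_id, channel, bin) |>
    dplyr::summarise(mono = !is.unsorted(z[order(log2_ratio)]),
                     .groups = "drop")
  expect_true(all(chk$mono))
})

test_that("rank binning honours bin size and remainder absorption", {
  expect_equal(phosflow:::rank_bins(5, 300), rep(1L, 5))
  b <- phosflow:::rank_bins(700, 300)
  expect_equal(as.integer(table(b)), c(300L, 400L))  # remainder 100 < 150 absorbed
  b2 <- phosflow:::rank_bins(900, 300)
  expect_equal(as.integer(table(b2)), c(300L, 300L, 300L))
  b3 <- phosflow:::rank_bins(950, 300)
  expect_equal(as.integer(table(b3)), c(300L, 300L, 350L))
  b4 <- phosflow:::rank_bins(800, 300)
  expect_equal(as.integer(table(b4)), c(300L, 300L, 200L))  # 200 >= 150 kept
})

test_that("null fixture z-scores are standard-normal calibrated across intensities", {
  study <- fixture_null_study()
  ratios <- study$psms |>
    normalize_channels(study$design) |>
    compute_ratios(study$design) |>
    assign_zscores()
  rec <- dplyr::filter(ratios, !is_denominator, population != "nonphospho")
  expect_equal(mean(abs(rec$z) >= 1), 2 * (1 - pnorm(1)), tolerance = 0.03 / 0.317)
  rec$decile <- dplyr::ntile(rec$total_intensity, 10)
  by_decile <- tapply(abs(rec$z) >= 1, rec$decile, mean)
  expect_true(all(abs(by_decile - 0.317) <= 0.03))
  # the raw ratios genuinely are intensity-heteroscedastic (what binning fixes)
  sd_by_decile <- tapply(rec$log2_ratio, rec$decile, sd)
  expect_gt(sd_by_decile[[1]], 1.5 * sd_by_decile[[10]])
})

test_that("aggregation weights per-experiment medians by PSM counts", {
  one <- make_ratio_records(z = 2, log2_ratio = 0.5)
  q1 <- aggregate_quant(one, "phosphosite")
  expect_equal(q1$z, 2)
  expect_equal(q1$n_psms, 1)

  two <- dplyr::bind_rows(
    make_ratio_records(z = c(0.5, 1, 1.5), experiment_id = "expA",
                       psm_id = c("a1", "a2", "a3")),
    make_ratio_records(z = 2, experiment_id = "expB", psm_id = "b1")
  )
  q2 <- aggregate_quant(two, "phosphosite")
  expect_equal(q2$z, (1 * 3 + 2 * 1) / 4)
  expect_equal(q2$n_psms, 4)
  expect_equal(q2$n_experiments, 2)
  expect_false(q2$single_experiment)

  # signed fold-change convention
  expect_equal(signed_fold_change(-1), -2)
  expect_equal(signed_fold_change(c(0, 1, log2(1.5))), c(1, 2, 1.5))

  # a multi-phospho PSM contributes its ratio to every localized site
  multi <- make_ratio_records(z = 1.2, site_positions = "S5;T9",
                              population = "multi")
  q3 <- aggregate_quant(multi, "phosphosite")
  expect_equal(nrow(q3), 2)
  expect_setequal(paste0(q3$residue, q3$position), c("S5", "T9"))
  expect_equal(q3$z, c(1.2, 1.2))
  # ...but stays a single phosphopeptide key
  q4 <- aggregate_quant(multi, "phosphopeptide")
  expect_equal(nrow(q4), 1)
  # and never enters the protein level
  expect_equal(nrow(aggregate_quant(multi, "protein")), 0)
})

test_that("significance and regulation calls apply inclusive tiered thresholds", {
  q <- tibble::tibble(
    protein = "P1", residue = "S", position = 1:4, sample_label = "IFN",
    z = c(1.0, 0.9, 2.5, -1.2), log2fc = log2(c(1.5, 3, 2, 1 / 1.6)),
    n_psms = c(10L, 10L, 4L, 8L), n_experiments = 2L,
    by_experiment = list(NULL), single_experiment = FALSE
  ) |>
    dplyr::mutate(signed_fc = signed_fold_change(log2fc))

  phos <- call_significance(q, "phosphosite")
  expect_equal(phos$significant, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(phos$regulated, c(TRUE, FALSE, TRUE, TRUE))

  prot <- call_significance(q, "protein")
  # z = 2.5 with only 4 PSMs fails the protein PSM filter
  expect_equal(prot$significant, c(FALSE, FALSE, FALSE, FALSE))

  # raising the fold-change threshold never increases the regulated count
  quant <- fixture_site_quant()
  counts <- vapply(c(1.2, 1.5, 2, 3, 4), function(fc) {
    sum(call_significance(quant, "phosphosite", fc_threshold = fc)$regulated)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("combined fold changes recover planted values within the noise bound", {
  study <- fixture_study()
  m <- fixture_site_quant() |>
    dplyr::inner_join(study$truth$detected_sites,
                      by = c("protein", "residue", "position"),
                      suffix = c("", ".true"))
  expect_equal(nrow(m), nrow(study$truth$detected_sites))
  rmse <- sqrt(mean((m$log2fc - m$log2fc.true)^2))
  n_per_site <- mean(m$n_psms)
  expect_lt(rmse, 3 * noise_params()$ratio_sd_high / sqrt(noise_params()$psms_per_site * 2))
  # planted-site z-scores separate cleanly from null sites
  expect_gt(min(abs(m$z[abs(m$log2fc.true) >= 1])), 1)
})
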
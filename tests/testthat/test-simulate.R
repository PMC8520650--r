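test_that("proteome simulation is deterministic and honours the composition", {
  p1 <- simulate_proteome(1, c(15, 15), seed = 7)
  p2 <- simulate_proteome(1, c(15, 15), seed = 7)
  expect_identical(p1, p2)
  expect_equal(nchar(p1$sequence), 15)

  all_s <- simulate_proteome(2, c(20, 20), aa_frequencies = c(S = 1), seed = 1)
  expect_true(all(strsplit(all_s$sequence, "")[[1]] == "S"))

  expect_error(simulate_proteome(1, c(20, 20), aa_frequencies = c(S = 0.5)),
               "sum to 1")
  expect_error(simulate_proteome(1, c(10, 20)), "min >= 15")
})

test_that("uniform-composition residue frequencies match the binomial oracle", {
  prot <- simulate_proteome(1000, c(100, 500), seed = 1)
  chars <- unlist(strsplit(prot$sequence, ""))
  n <- length(chars)
  freq <- table(factor(chars, levels = phosflow:::aa_alphabet())) / n
  tol <- 3 * sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freq - 0.05) < tol))
})

test_that("zero-noise PSMs reproduce planted fold changes exactly", {
  prot <- tiny_proteome()
  design <- default_design(n_experiments = 1)
  sites <- tibble::tibble(protein = "P2", residue = "S", position = 8L,
                          log2fc = 1)
  truth <- ground_truth(prot, design, sites)
  psms <- simulate_psm_table(truth, noise = zero_noise(), seed = 5)
  phospho <- dplyr::filter(psms, population != "nonphospho")
  expect_gt(nrow(phospho), 0)
  # treated channels carry exactly 2x the denominator; reference channel 1x
  expect_true(all(phospho$`116` / phospho$`114` == 2))
  expect_true(all(phospho$`117` / phospho$`114` == 2))
  expect_true(all(phospho$`115` / phospho$`114` == 1))
})

test_that("channel loading factors multiply intensities exactly", {
  prot <- tiny_proteome()
  design <- default_design(n_experiments = 1)
  sites <- tibble::tibble(protein = "P1", residue = "S", position = 5L,
                          log2fc = 0)
  biased <- unit_loadings(design) |>
    dplyr::mutate(loading = ifelse(channel == "114", 2, 1))
  t_plain <- ground_truth(prot, design, sites)
  t_biased <- ground_truth(prot, design, sites, channel_loadings = biased)
  p_plain <- simulate_psm_table(t_plain, noise = noise_params(), seed = 9)
  p_biased <- simulate_psm_table(t_biased, noise = noise_params(), seed = 9)
  expect_identical(p_biased$`114`, 2 * p_plain$`114`)
  expect_identical(p_biased$`115`, p_plain$`115`)
  expect_equal(sum(p_biased$`114`), 2 * sum(p_plain$`114`))
})

test_that("per-site mean raw log2 ratios recover planted values (Monte-Carlo)", {
  study <- simulate_phospho_study(
    seed = 3, channel_loadings = unit_loadings(default_design())
  )
  treated <- unique(study$design$channel[study$design$sample_label == "IFN"])
  reg <- study$truth$regulated_sites |>
    dplyr::mutate(site = paste(protein, paste0(residue, position)))
  ratios <- study$psms |>
    dplyr::filter(population == "mono") |>
    dplyr::mutate(site = paste(protein, site_positions)) |>
    dplyr::filter(site %in% reg$site) |>
    tidyr::pivot_longer(dplyr::all_of(treated), values_to = "i") |>
    dplyr::mutate(r = log2(i / `114`)) |>
    dplyr::group_by(site) |>
    dplyr::summarise(mean_r = mean(r), n = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(reg[, c("site", "log2fc")], by = "site")
  expect_gt(nrow(ratios), 100)
  # noise sd never exceeds its low-intensity ceiling of 0.5
  expect_true(all(abs(ratios$mean_r - ratios$log2fc) <= 3 * 0.5 / sqrt(ratios$n)))
})

test_that("kinase annotations validate against the proteome", {
  prot <- simulate_proteome(20, c(50, 80), seed = 4)
  ann <- simulate_kinase_annotations(prot, n_kinases = 5, sites_per_kinase = 4,
                                     effect_mix = 0.5, seed = 11)
  expect_equal(nrow(ann), 20)
  seqs <- setNames(prot$sequence, prot$accession)
  expect_identical(unname(substr(seqs[ann$kinase], ann$position, ann$position)),
                   unname(ann$residue))
  expect_true(all(ann$effect %in% c("activity, induced", "activity, inhibited")))

  all_ind <- simulate_kinase_annotations(prot, 3, 2, effect_mix = 1, seed = 2)
  expect_true(all(all_ind$effect == "activity, induced"))
  all_inh <- simulate_kinase_annotations(prot, 3, 2, effect_mix = 0, seed = 2)
  expect_true(all(all_inh$effect == "activity, inhibited"))
  expect_error(simulate_kinase_annotations(prot, 3, 2, effect_mix = 1.5),
               "effect_mix")
})

test_that("studies are deterministic and close over their ground truth", {
  study <- fixture_study()
  again <- simulate_phospho_study(seed = 101)
  expect_identical(study$psms, again$psms)
  expect_identical(study$proteome, again$proteome)

  # every planted regulated site appears with at least the configured minimum
  reg <- study$truth$regulated_sites
  counts <- study$psms |>
    dplyr::filter(population != "nonphospho") |>
    tidyr::separate_rows(site_positions, sep = ";") |>
    dplyr::count(protein, site_positions)
  hits <- reg |>
    dplyr::mutate(site_positions = paste0(residue, position)) |>
    dplyr::left_join(counts, by = c("protein", "site_positions"))
  n_exp <- length(unique(study$design$experiment_id))
  expect_true(all(!is.na(hits$n)))
  expect_true(all(hits$n >= noise_params()$min_psms_per_site * n_exp))

  # sites carrying the planted motif really have it in the emitted proteome
  carriers <- dplyr::filter(study$truth$detected_sites, motif_carrier)
  expect_gt(nrow(carriers), 0)
  seqs <- setNames(study$proteome$sequence, study$proteome$accession)
  expect_true(all(substr(seqs[carriers$protein], carriers$position + 1,
                         carriers$position + 1) == "P"))
})

test_that("study fixtures round-trip through their file formats", {
  study <- simulate_phospho_study(
    seed = 12, n_proteins = 30, n_sites = 20, n_regulated = 4,
    n_kinases = 3, sites_per_kinase = 2, n_active_kinases = 2,
    n_detected_proteins = 10
  )
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_identical(read_proteome(file.path(dir, "proteome.fasta")),
                   study$proteome)
  expect_equal(as.data.frame(read_psm_table(file.path(dir, "psms.tsv"))),
               as.data.frame(study$psms))
  expect_identical(as.data.frame(read_design(file.path(dir, "design.tsv"))),
                   as.data.frame(study$design))
  expect_equal(as.data.frame(read_annotations(file.path(dir, "annotations.tsv"))),
               as.data.frame(study$annotations))
})

test_that("ground truth rejects invalid sites", {
  prot <- tiny_proteome()
  design <- default_design(n_experiments = 1)
  expect_error(
    ground_truth(prot, design,
                 tibble::tibble(protein = "P1", residue = "S", position = 99L,
                                log2fc = 1)),
    "beyond protein length"
  )
  expect_error(
    ground_truth(prot, design,
                 tibble::tibble(protein = "P1", residue = "S", position = 2L,
                                log2fc = 1)),
    "residue mismatch"
  )
  expect_error(
    ground_truth(prot, design,
                 tibble::tibble(protein = "P1", residue = "S", position = 5L,
                                log2fc = 1),
                 channel_loadings = unit_loadings(design) |>
                   dplyr::mutate(loading = -1)),
    "strictly positive"
  )
})
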
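#' Noise and sampling parameters for the synthetic PSM generator
#'
#' Total reporter intensity per PSM is log-normal (base-10 parameters
#' `log10_intensity_mean`/`log10_intensity_sd`). The standard deviation of the
#' log2 reporter ratio decreases linearly with log10 total intensity from
#' `ratio_sd_high` at the 1st intensity percentile to `ratio_sd_low` at the
#' 99th (clamped outside), reproducing the intensity-dependent variance that
#' intensity-ranked z-scoring exists to correct. PSM counts per phosphosite
#' and per protein are shifted-Poisson per experiment with a hard minimum so
#' planted sites always reach the configured PSM depth.
#'
#' @param log10_intensity_mean,log10_intensity_sd Base-10 log-normal
#'   parameters of total reporter intensity.
#' @param ratio_sd_high,ratio_sd_low Log2-ratio noise sd at the 1st and 99th
#'   intensity percentile.
#' @param psms_per_site Mean phospho-PSMs per site per experiment.
#' @param min_psms_per_site Minimum phospho-PSMs per site per experiment.
#' @param multi_fraction Probability that a PSM whose peptide covers a second
#'   acceptor residue is emitted as a doubly phosphorylated ("multi") PSM.
#' @param protein_psms Mean non-phospho PSMs per detected protein per
#'   experiment.
#' @param min_protein_psms Minimum non-phospho PSMs per detected protein per
#'   experiment.
#' @return A list of generator parameters.
#' @export
noise_params <- function(log10_intensity_mean = 6,
                         log10_intensity_sd = 0.6,
                         ratio_sd_high = 0.5,
                         ratio_sd_low = 0.15,
                         psms_per_site = 5,
                         min_psms_per_site = 2L,
                         multi_fraction = 0.15,
                         protein_psms = 5,
                         min_protein_psms = 1L) {
  stopifnot(ratio_sd_high >= 0, ratio_sd_low >= 0,
            psms_per_site >= min_psms_per_site,
            multi_fraction >= 0, multi_fraction <= 1)
  list(
    log10_intensity_mean = log10_intensity_mean,
    log10_intensity_sd = log10_intensity_sd,
    ratio_sd_high = ratio_sd_high,
    ratio_sd_low = ratio_sd_low,
    psms_per_site = psms_per_site,
    min_psms_per_site = as.integer(min_psms_per_site),
    multi_fraction = multi_fraction,
    protein_psms = protein_psms,
    min_protein_psms = as.integer(min_protein_psms)
  )
}

#' Motif-planting parameters for the synthetic generator
#'
#' A fixed residue is written into the proteome at a single offset relative to
#' a configurable fraction of the upregulated sites, making motif recovery a
#' quantitative test. The default plants proline at +1 (the proline-directed
#' MAPK/CDK substrate preference) in 60% of upregulated sites.
#'
#' @param residue Residue planted (one-letter code, uppercase).
#' @param offset Offset relative to the phosphosite (nonzero, within -7..+7).
#' @param fraction Fraction of upregulated sites that receive the motif.
#' @export
motif_params <- function(residue = "P", offset = 1L, fraction = 0.6) {
  stopifnot(offset != 0, abs(offset) <= 7, fraction >= 0, fraction <= 1,
            residue %in% aa_alphabet())
  list(residue = residue, offset = as.integer(offset), fraction = fraction)
}

#' Simulate a PhosphoSitePlus-like kinase regulatory-site annotation table
#'
#' Samples kinase accessions from the proteome and, for each, a set of S/T/Y
#' positions on the kinase protein itself, labelled "activity, induced" with
#' probability `effect_mix` and "activity, inhibited" otherwise.
#'
#' @param proteome Proteome tibble (`accession`, `sequence`).
#' @param n_kinases Number of kinases to annotate.
#' @param sites_per_kinase Regulatory sites per kinase (capped by the number
#'   of acceptor residues available).
#' @param effect_mix Fraction of sites annotated as inducing activity, in
#'   `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Tibble with columns `kinase`, `residue`, `position`, `effect`.
#' @export
simulate_kinase_annotations <- function(proteome,
                                        n_kinases = 30L,
                                        sites_per_kinase = 4L,
                                        effect_mix = 0.5,
                                        seed = NULL) {
  if (effect_mix < 0 || effect_mix > 1) {
    phos_abort("effect_mix must be in [0, 1] (got %g)", effect_mix)
  }
  stopifnot(n_kinases <= nrow(proteome))
  with_seed_if(seed, {
    kinases <- sample(proteome$accession, n_kinases)
    sites <- proteome_sites(proteome) |>
      dplyr::filter(.data$protein %in% kinases) |>
      dplyr::group_by(.data$protein) |>
      dplyr::slice_sample(n = sites_per_kinase) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$protein, .data$position)
    sites |>
      dplyr::mutate(
        effect = ifelse(runif(dplyr::n()) < effect_mix,
                        "activity, induced", "activity, inhibited")
      ) |>
      dplyr::rename(kinase = "protein")
  })
}

#' Construct and validate a ground-truth object
#'
#' Bundles everything the synthetic PSM generator needs and downstream tests
#' recover: the (possibly motif-mutated) proteome, the design, the detected
#' sites with their planted log2 fold changes (0 for unregulated sites), the
#' kinase annotation table and planted kinase directions, and per-channel
#' loading (bias) factors. Invariants are checked: every site exists in the
#' proteome with a matching S/T/Y residue, planted fold changes are finite,
#' and loadings are strictly positive.
#'
#' @param proteome,design Proteome and design tibbles.
#' @param detected_sites Tibble `protein`, `residue`, `position`, `log2fc`
#'   (and optionally `origin`, `motif_carrier`).
#' @param annotations Kinase regulatory-site annotation tibble or `NULL`.
#' @param kinase_truth Tibble `kinase`, `direction` (+1/-1) or `NULL`.
#' @param channel_loadings Tibble `experiment_id`, `channel`, `loading`; all
#'   loadings 1 when `NULL`.
#' @param motif Motif-planting record (list) or `NULL`.
#' @param detected_proteins Accessions carrying non-phospho PSMs; defaults to
#'   all proteins with a detected site.
#' @return An object of class `phos_truth`.
#' @export
ground_truth <- function(proteome, design, detected_sites,
                         annotations = NULL, kinase_truth = NULL,
                         channel_loadings = NULL, motif = NULL,
                         detected_proteins = NULL) {
  validate_design(design)
  stopifnot_cols(detected_sites, c("protein", "residue", "position", "log2fc"),
                 "detected_sites")
  seqs <- setNames(proteome$sequence, proteome$accession)
  missing <- setdiff(detected_sites$protein, names(seqs))
  if (length(missing) > 0) {
    phos_abort("detected sites on protein(s) absent from proteome: %s",
               paste(head(missing, 3), collapse = ", "))
  }
  len <- nchar(seqs[detected_sites$protein])
  beyond <- detected_sites$position > len | detected_sites$position < 1
  if (any(beyond)) {
    phos_abort("site position beyond protein length for %s",
               detected_sites$protein[which(beyond)[1]])
  }
  at <- substr(seqs[detected_sites$protein], detected_sites$position,
               detected_sites$position)
  bad <- at != detected_sites$residue | !detected_sites$residue %in% c("S", "T", "Y")
  if (any(bad)) {
    i <- which(bad)[1]
    phos_abort("residue mismatch at %s position %d: proteome has %s, site says %s",
               detected_sites$protein[i], detected_sites$position[i], at[i],
               detected_sites$residue[i])
  }
  if (any(!is.finite(detected_sites$log2fc))) {
    phos_abort("planted log2 fold changes must be finite")
  }
  if (is.null(channel_loadings)) {
    channel_loadings <- design |>
      dplyr::distinct(.data$experiment_id, .data$channel) |>
      dplyr::mutate(loading = 1)
  }
  if (any(channel_loadings$loading <= 0)) {
    phos_abort("channel loadings must be strictly positive")
  }
  if (is.null(detected_proteins)) {
    detected_proteins <- unique(detected_sites$protein)
  }
  structure(
    list(
      proteome = proteome,
      design = design,
      detected_sites = detected_sites,
      regulated_sites = dplyr::filter(detected_sites, .data$log2fc != 0),
      annotations = annotations,
      kinase_truth = kinase_truth,
      channel_loadings = channel_loadings,
      motif = motif,
      detected_proteins = detected_proteins
    ),
    class = "phos_truth"
  )
}

#' Simulate ground truth: detected sites, planted effects, motifs, kinases
#'
#' Chooses the detected phosphosite set from the proteome's acceptor residues
#' (residue-weighted to emulate the S >> T >> Y composition of real
#' phosphoproteomes), plants log2 fold changes at the configured levels (equal
#' numbers per signed level), drives a subset of kinases by regulating their
#' annotated sites coherently with a planted direction, and writes a motif
#' residue next to a fraction of the upregulated sites.
#'
#' All annotated kinase sites are included in the detected set (regulated for
#' active kinases, unregulated for null kinases) so kinase-direction recovery
#' can be scored against truth.
#'
#' @inheritParams ground_truth
#' @param annotations Kinase annotation table (see
#'   [simulate_kinase_annotations()]); may be `NULL` for a kinase-free study.
#' @param n_sites Total detected phosphosites.
#' @param n_regulated Number of regulated (nonzero fold change) sites,
#'   including the kinase-driven ones; 0 gives a null study.
#' @param log2fc_levels Magnitudes of planted log2 fold changes; both signs
#'   are planted in equal numbers.
#' @param residue_weights Sampling weights for acceptor residues.
#' @param motif Motif-planting parameters ([motif_params()]) or `NULL`.
#' @param n_active_kinases Number of kinases planted with an activity shift
#'   (half increased, half decreased).
#' @param kinase_log2fc Magnitudes used for kinase-driven site fold changes.
#' @param n_detected_proteins Proteins carrying non-phospho PSMs.
#' @param channel_loadings Per-channel bias factors; `NULL` draws them
#'   uniformly from `[0.8, 1.25]`.
#' @param seed Optional integer seed.
#' @return A `phos_truth` object (see [ground_truth()]).
#' @export
simulate_ground_truth <- function(proteome, design, annotations = NULL,
                                  n_sites = 500L, n_regulated = 120L,
                                  log2fc_levels = c(0.585, 1, 2),
                                  residue_weights = c(S = 0.86, T = 0.12, Y = 0.02),
                                  motif = motif_params(),
                                  n_active_kinases = 10L,
                                  kinase_log2fc = c(1, 2),
                                  n_detected_proteins = 500L,
                                  channel_loadings = NULL,
                                  seed = NULL) {
  validate_design(design)
  with_seed_if(seed, {
    all_sites <- proteome_sites(proteome)
    used <- tibble::tibble(protein = character(), position = integer())

    # kinase-driven regulation: an "increased" kinase gets +|L| on its induced
    # sites and -|L| on its inhibited sites, so every activity-score term has
    # the planted sign
    kinase_truth <- NULL
    kinase_sites <- NULL
    if (!is.null(annotations) && n_active_kinases > 0 && n_regulated > 0) {
      kin <- sort(unique(annotations$kinase))
      stopifnot(n_active_kinases <= length(kin))
      active <- sample(kin, n_active_kinases)
      kinase_truth <- tibble::tibble(
        kinase = active,
        direction = sample(rep(c(1L, -1L), length.out = n_active_kinases))
      )
      kinase_sites <- annotations |>
        dplyr::inner_join(kinase_truth, by = "kinase") |>
        dplyr::mutate(
          d = ifelse(.data$effect == "activity, induced", 1, -1),
          log2fc = .data$direction * .data$d *
            sample(kinase_log2fc, dplyr::n(), replace = TRUE),
          origin = "kinase"
        ) |>
        dplyr::select(protein = "kinase", "residue", "position", "log2fc", "origin")
    }
    if (!is.null(annotations)) {
      used <- dplyr::bind_rows(used, annotations |>
                                 dplyr::select(protein = "kinase", "position"))
    }

    n_kin <- if (is.null(kinase_sites)) 0L else nrow(kinase_sites)
    n_generic <- n_regulated - n_kin
    if (n_generic < 0) {
      phos_abort("n_regulated (%d) smaller than the %d kinase-driven sites",
                 n_regulated, n_kin)
    }
    pool <- all_sites |>
      dplyr::anti_join(used, by = c("protein", "position")) |>
      dplyr::mutate(w = unname(residue_weights[.data$residue]))

    generic <- pool |>
      dplyr::slice_sample(n = n_generic, weight_by = .data$w) |>
      dplyr::mutate(
        log2fc = sample(rep(as.vector(outer(c(1, -1), log2fc_levels)),
                            length.out = n_generic)),
        origin = "planted"
      ) |>
      dplyr::select(-"w")
    pool <- dplyr::anti_join(pool, generic, by = c("protein", "position"))

    null_annot <- NULL
    if (!is.null(annotations)) {
      null_annot <- annotations |>
        dplyr::anti_join(
          if (is.null(kinase_truth)) tibble::tibble(kinase = character())
          else kinase_truth,
          by = "kinase"
        ) |>
        dplyr::transmute(protein = .data$kinase, residue = .data$residue,
                         position = .data$position, log2fc = 0,
                         origin = "annotation")
    }

    n_bg <- n_sites - n_regulated - (if (is.null(null_annot)) 0L else nrow(null_annot))
    if (n_bg < 0) phos_abort("n_sites too small for the regulated + annotated sites")
    background <- pool |>
      dplyr::slice_sample(n = n_bg, weight_by = .data$w) |>
      dplyr::mutate(log2fc = 0, origin = "background") |>
      dplyr::select(-"w")

    detected <- dplyr::bind_rows(kinase_sites, generic, null_annot, background) |>
      dplyr::distinct(.data$protein, .data$position, .keep_all = TRUE)

    # motif planting mutates the proteome next to upregulated sites; positions
    # that are themselves detected sites are protected from overwriting
    detected$motif_carrier <- FALSE
    if (!is.null(motif) && motif$fraction > 0) {
      seqs <- setNames(proteome$sequence, proteome$accession)
      up <- detected |>
        dplyr::mutate(.idx = dplyr::row_number()) |>
        dplyr::filter(.data$log2fc > 0) |>
        dplyr::mutate(
          target = .data$position + motif$offset,
          len = nchar(seqs[.data$protein])
        ) |>
        dplyr::filter(.data$target >= 1, .data$target <= .data$len) |>
        dplyr::anti_join(detected |>
                           dplyr::select("protein", target = "position"),
                         by = c("protein", "target"))
      n_plant <- min(round(motif$fraction * sum(detected$log2fc > 0)), nrow(up))
      carriers <- dplyr::slice_sample(up, n = n_plant)
      for (p in unique(carriers$protein)) {
        s <- seqs[[p]]
        for (t in carriers$target[carriers$protein == p]) {
          substr(s, t, t) <- motif$residue
        }
        seqs[[p]] <- s
      }
      proteome$sequence <- unname(seqs[proteome$accession])
      detected$motif_carrier[carriers$.idx] <- TRUE
      motif <- c(motif, list(n_planted = n_plant))
    }

    if (is.null(channel_loadings)) {
      channel_loadings <- design |>
        dplyr::distinct(.data$experiment_id, .data$channel) |>
        dplyr::mutate(loading = round(runif(dplyr::n(), 0.8, 1.25), 3))
    }

    detected_proteins <- union(
      if (is.null(annotations)) character() else unique(annotations$kinase),
      sample(proteome$accession, min(n_detected_proteins, nrow(proteome)))
    )

    ground_truth(proteome, design, detected,
                 annotations = annotations, kinase_truth = kinase_truth,
                 channel_loadings = channel_loadings, motif = motif,
                 detected_proteins = detected_proteins)
  })
}

#' Simulate an isobaric-label PSM table from ground truth
#'
#' Emits one row per peptide-spectrum match with per-channel reporter
#' intensities. For each detected site and experiment, a shifted-Poisson
#' number of PSMs is generated on a tryptic-like peptide spanning the site.
#' Reporter intensities are built so that, before channel loadings, the
#' expected log2 ratio of every treated channel against the denominator equals
#' the site's planted fold change (0 for unregulated sites and for all
#' reference channels), with log2-ratio noise whose sd decreases with total
#' reporter intensity. Channel loading factors then multiply every intensity
#' of their channel, making sum-of-intensities normalization recoverable.
#' Peptides covering a second acceptor residue are emitted as doubly
#' phosphorylated ("multi") PSMs with the configured frequency; non-phospho
#' PSMs are generated for the truth's detected proteins.
#'
#' @param truth A `phos_truth` object ([ground_truth()]).
#' @param noise Generator parameters ([noise_params()]).
#' @param proteome,design Override the truth's proteome/design (rarely
#'   needed).
#' @param seed Optional integer seed.
#' @return A PSM tibble with columns `psm_id`, `experiment_id`, `peptide`,
#'   `protein`, `site_positions`, `population`, and one intensity column per
#'   channel.
#' @export
simulate_psm_table <- function(truth, noise = noise_params(),
                               proteome = truth$proteome,
                               design = truth$design,
                               seed = NULL) {
  stopifnot(inherits(truth, "phos_truth"))
  validate_design(design)
  seqs <- setNames(proteome$sequence, proteome$accession)
  channels <- unique(design$channel)

  with_seed_if(seed, {
    sites <- truth$detected_sites |>
      dplyr::mutate(len = nchar(seqs[.data$protein]))
    n_site <- nrow(sites)

    # one peptide per site; flanks drawn once so phosphopeptide keys are stable
    fl <- sample(5:10, n_site, replace = TRUE)
    fr <- sample(5:10, n_site, replace = TRUE)
    pep_start <- pmax(1L, sites$position - fl)
    pep_end <- pmin(sites$len, sites$position + fr)
    peptide <- stringr::str_sub(seqs[sites$protein], pep_start, pep_end)

    # nearest other acceptor residue inside the peptide, if any, is the
    # candidate second site of multi-phospho PSMs
    sec <- purrr::map(seq_len(n_site), function(i) {
      loc <- stringr::str_locate_all(peptide[i], "[STY]")[[1]][, 1L]
      pos <- loc + pep_start[i] - 1L
      pos <- pos[pos != sites$position[i]]
      if (length(pos) == 0) return(NULL)
      p <- pos[which.min(abs(pos - sites$position[i]))]
      list(residue = substr(seqs[[sites$protein[i]]], p, p), position = p)
    })
    has_sec <- !vapply(sec, is.null, logical(1))
    mono_key <- format_site(sites$residue, sites$position)
    multi_key <- vapply(seq_len(n_site), function(i) {
      if (!has_sec[i]) return(NA_character_)
      ord <- order(c(sites$position[i], sec[[i]]$position))
      paste(c(mono_key[i], format_site(sec[[i]]$residue, sec[[i]]$position))[ord],
            collapse = ";")
    }, character(1))

    experiments <- unique(design$experiment_id)
    lambda_site <- max(0, noise$psms_per_site - noise$min_psms_per_site)
    phospho <- purrr::map_dfr(experiments, function(e) {
      n_psm <- noise$min_psms_per_site + rpois(n_site, lambda_site)
      idx <- rep(seq_len(n_site), n_psm)
      multi <- has_sec[idx] & runif(length(idx)) < noise$multi_fraction
      tibble::tibble(
        experiment_id = e,
        peptide = peptide[idx],
        protein = sites$protein[idx],
        site_positions = ifelse(multi, multi_key[idx], mono_key[idx]),
        population = ifelse(multi, "multi", "mono"),
        log2fc = sites$log2fc[idx]
      )
    })

    # non-phospho PSMs for the detected proteins (null protein-level effects)
    prot <- tibble::tibble(protein = truth$detected_proteins) |>
      dplyr::mutate(len = nchar(seqs[.data$protein]))
    lambda_prot <- max(0, noise$protein_psms - noise$min_protein_psms)
    nonphospho <- purrr::map_dfr(experiments, function(e) {
      n_psm <- noise$min_protein_psms + rpois(nrow(prot), lambda_prot)
      idx <- rep(seq_len(nrow(prot)), n_psm)
      plen <- sample(8:20, length(idx), replace = TRUE)
      plen <- pmin(plen, prot$len[idx])
      start <- 1L + floor(runif(length(idx)) * (prot$len[idx] - plen + 1L))
      tibble::tibble(
        experiment_id = e,
        peptide = stringr::str_sub(seqs[prot$protein[idx]], start, start + plen - 1L),
        protein = prot$protein[idx],
        site_positions = NA_character_,
        population = "nonphospho",
        log2fc = 0
      )
    })

    psms <- dplyr::bind_rows(phospho, nonphospho)
    n <- nrow(psms)

    # intensity model: log-normal totals, intensity-dependent ratio noise
    total <- 10^rnorm(n, noise$log10_intensity_mean, noise$log10_intensity_sd)
    q01 <- noise$log10_intensity_mean + qnorm(0.01) * noise$log10_intensity_sd
    q99 <- noise$log10_intensity_mean + qnorm(0.99) * noise$log10_intensity_sd
    frac <- if (q99 > q01) pmin(1, pmax(0, (log10(total) - q01) / (q99 - q01))) else 0.5
    sd_ratio <- noise$ratio_sd_high + frac * (noise$ratio_sd_low - noise$ratio_sd_high)

    loadings <- truth$channel_loadings
    base <- total / length(channels)
    intens <- matrix(NA_real_, nrow = n, ncol = length(channels),
                     dimnames = list(NULL, channels))
    for (e in experiments) {
      rows <- which(psms$experiment_id == e)
      dsg <- design[design$experiment_id == e, ]
      ref_label <- dsg$sample_label[dsg$is_denominator]
      for (ch in channels) {
        lam <- loadings$loading[loadings$experiment_id == e & loadings$channel == ch]
        if (length(lam) != 1) phos_abort("missing channel loading for %s/%s", e, ch)
        drow <- dsg[dsg$channel == ch, ]
        if (drow$is_denominator) {
          intens[rows, ch] <- base[rows] * lam
        } else {
          mu <- if (drow$sample_label == ref_label) 0 else psms$log2fc[rows]
          eps <- rnorm(length(rows), 0, sd_ratio[rows])
          intens[rows, ch] <- base[rows] * 2^(mu + eps) * lam
        }
      }
    }

    psms |>
      dplyr::select(-"log2fc") |>
      dplyr::mutate(psm_id = sprintf("PSM%06d", dplyr::row_number()),
                    .before = 1) |>
      dplyr::bind_cols(tibble::as_tibble(intens))
  })
}

#' Simulate a complete synthetic phosphoproteomics study
#'
#' One call generates a seeded proteome, a 4-plex duplicate-experiment design,
#' kinase regulatory-site annotations, ground truth with planted site fold
#' changes, sequence motifs and kinase activity directions, and the PSM table.
#' Defaults give the package's reference desk-scale study: 1,000 proteins,
#' 500 detected phosphosites with ~10 PSMs each across two experiments
#' (~5,000 phospho and ~5,000 non-phospho PSMs).
#'
#' @inheritParams simulate_ground_truth
#' @inheritParams simulate_proteome
#' @param design Experimental design (defaults to [default_design()]).
#' @param n_kinases,sites_per_kinase,effect_mix Annotation-table parameters
#'   (see [simulate_kinase_annotations()]).
#' @param noise Generator parameters ([noise_params()]).
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `phos_study` with elements `proteome`, `design`,
#'   `psms`, `annotations` and `truth`.
#' @examples
#' study <- simulate_phospho_study(n_proteins = 50, n_sites = 30,
#'                                 n_regulated = 6, n_kinases = 4,
#'                                 n_active_kinases = 2, seed = 1)
#' dplyr::count(study$psms, population)
#' @export
simulate_phospho_study <- function(n_proteins = 1000L,
                                   length_range = c(100L, 500L),
                                   aa_frequencies = NULL,
                                   design = default_design(),
                                   n_sites = 500L,
                                   n_regulated = 120L,
                                   log2fc_levels = c(0.585, 1, 2),
                                   residue_weights = c(S = 0.86, T = 0.12, Y = 0.02),
                                   motif = motif_params(),
                                   n_kinases = 30L,
                                   sites_per_kinase = 4L,
                                   effect_mix = 0.5,
                                   n_active_kinases = 10L,
                                   kinase_log2fc = c(1, 2),
                                   n_detected_proteins = 500L,
                                   channel_loadings = NULL,
                                   noise = noise_params(),
                                   seed = NULL) {
  if (n_regulated == 0) n_active_kinases <- 0L
  with_seed_if(seed, {
    proteome <- simulate_proteome(n_proteins, length_range, aa_frequencies)
    annotations <- if (n_kinases > 0) {
      simulate_kinase_annotations(proteome, n_kinases, sites_per_kinase, effect_mix)
    }
    truth <- simulate_ground_truth(
      proteome, design, annotations,
      n_sites = n_sites, n_regulated = n_regulated,
      log2fc_levels = log2fc_levels, residue_weights = residue_weights,
      motif = motif, n_active_kinases = n_active_kinases,
      kinase_log2fc = kinase_log2fc,
      n_detected_proteins = n_detected_proteins,
      channel_loadings = channel_loadings
    )
    psms <- simulate_psm_table(truth, noise)
    structure(
      list(proteome = truth$proteome, design = design, psms = psms,
           annotations = annotations, truth = truth),
      class = "phos_study"
    )
  })
}
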
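# exact binomial upper-tail by direct summation (independent of pbinom)
binom_tail_exact <- function(k, n, q) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * q^i * (1 - q)^(n - i), numeric(1)))
}

s_window <- function(plus1 = "G", minus3 = "A") {
  paste0(strrep("A", 4), minus3, "AA", "s", plus1, strrep("A", 6))
}

test_that("sequence windows are padded, centered and validated", {
  prot <- tibble::tibble(accession = "W1", sequence = "MKAASPQKRSTYAAE")
  mid <- extract_windows(tibble::tibble(protein = "W1", residue = "K",
                                        position = 8L),
                         prot, flank = 7L)
  expect_equal(mid$window, "MKAASPQkRSTYAAE")
  expect_false(grepl("_", mid$window))

  first <- extract_windows(tibble::tibble(protein = "W1", residue = "M",
                                          position = 1L), prot)
  expect_equal(first$window, "_______mKAASPQK")

  expect_error(extract_windows(tibble::tibble(protein = "W1", residue = "S",
                                              position = 2L), prot),
               "residue mismatch")

  # fixture oracle: window equals the proteome substring with center lowered
  study <- fixture_study()
  site <- study$truth$detected_sites[5, ]
  w <- extract_windows(site[, c("protein", "residue", "position")],
                       study$proteome)$window
  seqr <- study$proteome$sequence[study$proteome$accession == site$protein]
  expected <- substr(paste0(strrep("_", 7), seqr, strrep("_", 7)),
                     site$position, site$position + 14)
  substr(expected, 8, 8) <- tolower(site$residue)
  expect_identical(w, expected)
})

test_that("pattern matching resolves offsets relative to the center anchor", {
  expect_true(match_pattern("AAAAAAAsPKKKKKK", "sP"))
  expect_false(match_pattern("AAAAAAAsAKKKKKK", "sP"))
  # CaMK-style R at -3 matches regardless of other offsets
  expect_true(match_pattern(s_window(minus3 = "R"), "R..s"))
  expect_false(match_pattern(s_window(minus3 = "K"), "R..s"))
  # sP...K fixes P at +1 and K at +5
  expect_true(match_pattern("AAAAAAAsPAAAKAA", "sP...K"))
  expect_false(match_pattern("AAAAAAAsPAAAAAA", "sP...K"))
  # center residue must agree with the anchor unless the anchor is x
  expect_false(match_pattern("AAAAAAAtPAAAAAA", "sP"))
  expect_true(match_pattern("AAAAAAAtPAAAAAA", "xP"))
  expect_error(match_pattern("AAAAAAAsPAAAAAA", "SP"), "center anchor")
  expect_error(match_pattern("AAAAAAAsPAAAAAA", "sP.......K"), "window")
})

test_that("step p-values equal the exact binomial sum", {
  bg <- c(replicate(5, s_window("P")), replicate(95, s_window("G")))
  fg <- c(replicate(5, s_window("P")), replicate(5, s_window("G")))
  res <- motif_enrichment(fg, bg, p_threshold = 0.05, min_occurrences = 5,
                          center = "s")
  motifs <- tidy(res)
  expect_equal(nrow(motifs), 1)
  expect_equal(motifs$pattern, "sP")
  step <- motifs$steps[[1]]
  expect_equal(step$offset, 1)
  expect_equal(step$fg_matches, 5)
  expect_equal(step$p_value, binom_tail_exact(5, 10, 0.05), tolerance = 1e-12)
  expect_equal(motifs$fold_enrichment, (5 / 10) / (5 / 100))

  # foreground identical to background shows no enrichment
  null <- motif_enrichment(bg, bg, p_threshold = 1e-6, min_occurrences = 5)
  expect_equal(nrow(tidy(null)), 0)

  # empty foreground is a logged no-op
  expect_message(e <- motif_enrichment(character(), bg), "empty foreground")
  expect_equal(nrow(tidy(e)), 0)
})

test_that("greedy steps agree with a brute-force oracle on small instances", {
  aa <- c("A", "P", "R", "E", "K")
  rand_windows <- function(n) {
    vapply(seq_len(n), function(i) {
      w <- sample(aa, 15, replace = TRUE)
      w[8] <- "s"
      paste(w, collapse = "")
    }, character(1))
  }
  withr::with_seed(19, {
    for (rep in 1:5) {
      fg <- rand_windows(sample(8:20, 1))
      bg <- rand_windows(200)
      res <- motif_enrichment(fg, bg, p_threshold = 0.5, min_occurrences = 2,
                              center = "s")
      # oracle: evaluate every (offset, residue) pair on the full sets
      fgM <- do.call(rbind, strsplit(fg, ""))
      bgM <- do.call(rbind, strsplit(bg, ""))
      cand <- expand.grid(col = setdiff(1:15, 8), res = aa,
                          stringsAsFactors = FALSE)
      cand$k <- mapply(function(cl, rs) sum(fgM[, cl] == rs),
                       cand$col, cand$res)
      cand$b <- mapply(function(cl, rs) sum(bgM[, cl] == rs),
                       cand$col, cand$res)
      cand$p <- mapply(function(k, b) binom_tail_exact(k, nrow(fgM), b / nrow(bgM)),
                       cand$k, cand$b)
      ok <- cand$k >= 2 & cand$b >= 1 & cand$p <= 0.5
      motifs <- tidy(res)
      if (!any(ok)) {
        expect_equal(nrow(motifs), 0)
      } else {
        ord <- order(cand$p, abs(cand$col - 8), cand$res)
        best <- cand[ord[ok[ord]][1], ]
        # the first-extracted motif's first step is what the oracle predicts
        step1 <- motifs$steps[motifs$round == 1][[1]][1, ]
        expect_equal(step1$offset, best$col - 8)
        expect_equal(step1$residue, best$res)
        expect_equal(step1$p_value, best$p, tolerance = 1e-12)
      }
    }
  })
})

test_that("the planted proline-directed motif is recovered as the top motif", {
  study <- fixture_study()
  quant <- fixture_site_quant()
  up <- dplyr::filter(quant, regulated, log2fc > 0)
  fg <- extract_windows(up[, c("protein", "residue", "position")],
                        study$proteome)$window
  bg <- extract_windows(proteome_sites(study$proteome), study$proteome)$window
  res <- motif_enrichment(fg, bg, min_occurrences = 10L)
  motifs <- tidy(res)
  expect_gt(nrow(motifs), 0)
  expect_equal(motifs$pattern[1], "sP")
  expect_gt(motifs$fold_enrichment[1], 2)
  expect_true(all(vapply(seq_len(nrow(motifs)), function(i) {
    sum(match_pattern(fg, motifs$pattern[i])) >= motifs$fg_matches[i]
  }, logical(1))))
  # first motif's matches are exactly the matching foreground windows
  expect_equal(sum(match_pattern(fg, motifs$pattern[1])), motifs$fg_matches[1])
  # every step's p-value passed the configured threshold
  expect_true(all(vapply(motifs$steps, function(s) all(s$p_value <= 1e-6),
                         logical(1))))
})
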
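# parse a motif pattern like "sP", "s.E", "R..s", "sP...K" into the anchor
# character and a tibble of fixed (offset, residue) pairs
parse_pattern <- function(pattern, flank = 7L) {
  chars <- strsplit(pattern, "")[[1]]
  anchor_idx <- which(chars %in% c("s", "t", "y", "x"))
  if (length(anchor_idx) != 1) {
    phos_abort("pattern '%s' must contain exactly one lowercase center anchor (s/t/y, or x for any)",
               pattern)
  }
  offsets <- seq_along(chars) - anchor_idx
  fixed_idx <- which(chars != "." & offsets != 0)
  bad <- chars[fixed_idx][!chars[fixed_idx] %in% aa_alphabet()]
  if (length(bad) > 0) {
    phos_abort("pattern '%s' has invalid character(s): %s", pattern,
               paste(unique(bad), collapse = ", "))
  }
  if (any(abs(offsets) > flank)) {
    phos_abort("pattern '%s' exceeds the +/-%d window", pattern, flank)
  }
  list(anchor = chars[anchor_idx],
       fixed = tibble::tibble(offset = offsets[fixed_idx],
                              residue = chars[fixed_idx]))
}

#' Match 15-mer windows against a consensus motif pattern
#'
#' Patterns use a lowercase center anchor (`s`, `t` or `y`; `x` matches any
#' center), uppercase residues at fixed offsets and `.` as a wildcard, e.g.
#' `"sP"` (proline-directed), `"s.E"` (acidophilic), `"R..s"` (basophilic) or
#' `"sP...K"`.
#'
#' @param windows Character vector of 15-mer windows ([extract_windows()]).
#' @param pattern A single pattern string.
#' @param flank Flank width of the windows (7 for 15-mers).
#' @return Logical vector: does each window carry every fixed residue at its
#'   offset (and the anchor at its center)?
#' @examples
#' match_pattern(c("AAAAAAAsPAAAAAA", "AAAAAAAsAAAAAAA"), "sP")
#' @export
match_pattern <- function(windows, pattern, flank = 7L) {
  p <- parse_pattern(pattern, flank)
  center <- flank + 1L
  ok <- if (p$anchor == "x") {
    substr(windows, center, center) %in% c("s", "t", "y")
  } else {
    substr(windows, center, center) == p$anchor
  }
  for (i in seq_len(nrow(p$fixed))) {
    at <- center + p$fixed$offset[i]
    ok <- ok & substr(windows, at, at) == p$fixed$residue[i]
  }
  ok
}

# residue counts per window position for a character matrix of windows
position_counts <- function(mat, cols) {
  aa <- aa_alphabet()
  vapply(cols, function(j) {
    tabulate(factor(mat[, j], levels = aa), nbins = length(aa))
  }, integer(length(aa))) |>
    matrix(nrow = length(aa), dimnames = list(aa, NULL))
}

empty_motif_tibble <- function() {
  tibble::tibble(
    pattern = character(), center = character(), round = integer(),
    n_steps = integer(), fg_matches = integer(), fg_size = integer(),
    bg_matches = integer(), bg_size = integer(), fold_enrichment = numeric(),
    score = numeric(), steps = list()
  )
}

format_motif_pattern <- function(anchor, fixed, flank = 7L) {
  offs <- sort(unique(c(0L, fixed$offset)))
  lo <- min(offs)
  hi <- max(offs)
  chars <- rep(".", hi - lo + 1L)
  chars[0L - lo + 1L] <- anchor
  for (i in seq_len(nrow(fixed))) {
    chars[fixed$offset[i] - lo + 1L] <- fixed$residue[i]
  }
  paste(chars, collapse = "")
}

# one greedy motif-x run over a fixed center class; fg/bg are char matrices
motifx_one_center <- function(fgM, bgM, anchor, log_p_threshold,
                              min_occurrences, flank = 7L) {
  center <- flank + 1L
  motifs <- list()
  repeat {
    if (nrow(fgM) < min_occurrences) break
    fg0 <- nrow(fgM)
    bg0 <- nrow(bgM)
    fg <- fgM
    bg <- bgM
    free <- setdiff(seq_len(2L * flank + 1L), center)
    steps <- list()
    repeat {
      n_fg <- nrow(fg)
      n_bg <- nrow(bg)
      if (n_fg < min_occurrences || n_bg == 0 || length(free) == 0) break
      k <- position_counts(fg, free)
      b <- position_counts(bg, free)
      q <- b / n_bg
      lp <- suppressWarnings(
        pbinom(k - 1L, n_fg, q, lower.tail = FALSE, log.p = TRUE)
      )
      valid <- k >= min_occurrences & b >= 1L & lp <= log_p_threshold
      # padding characters never form motif positions
      if (!any(valid)) break
      cand <- which(valid, arr.ind = TRUE)
      offsets <- free[cand[, "col"]] - center
      ord <- order(lp[valid], abs(offsets), rownames(k)[cand[, "row"]])
      pick <- ord[1]
      res <- rownames(k)[cand[pick, "row"]]
      col <- free[cand[pick, "col"]]
      steps[[length(steps) + 1L]] <- tibble::tibble(
        offset = col - center,
        residue = res,
        fg_matches = k[valid][pick],
        fg_size = n_fg,
        bg_frequency = q[valid][pick],
        p_value = exp(lp[valid][pick]),
        log_p = lp[valid][pick]
      )
      keep_fg <- fg[, col] == res
      keep_bg <- bg[, col] == res
      fg <- fg[keep_fg, , drop = FALSE]
      bg <- bg[keep_bg, , drop = FALSE]
      free <- setdiff(free, col)
    }
    if (length(steps) == 0) break
    steps <- dplyr::bind_rows(steps)
    fixed <- steps[, c("offset", "residue")]
    pattern <- format_motif_pattern(anchor, fixed, flank)
    motifs[[length(motifs) + 1L]] <- tibble::tibble(
      pattern = pattern,
      center = anchor,
      round = length(motifs) + 1L,
      n_steps = nrow(steps),
      fg_matches = nrow(fg),
      fg_size = fg0,
      bg_matches = nrow(bg),
      bg_size = bg0,
      fold_enrichment = (nrow(fg) / fg0) / (nrow(bg) / bg0),
      score = -sum(steps$log_p) / log(10),
      steps = list(steps)
    )
    # remove matched foreground windows; background resets for the next round
    matched <- rep(TRUE, nrow(fgM))
    for (i in seq_len(nrow(fixed))) {
      matched <- matched & fgM[, fixed$offset[i] + center] == fixed$residue[i]
    }
    fgM <- fgM[!matched, , drop = FALSE]
  }
  dplyr::bind_rows(empty_motif_tibble(), motifs)
}

#' Motif-x-style iterative binomial motif enrichment
#'
#' Greedy extraction of over-represented (offset, residue) pairs from
#' foreground windows against a background: at each step, every unfixed pair
#' is scored by the one-sided binomial tail probability of its foreground
#' count given the current background frequency; the smallest p-value at or
#' below `p_threshold` (with at least `min_occurrences` foreground matches) is
#' fixed, both sets are restricted to matching windows, and the step repeats.
#' A completed motif's fold enrichment is computed against the foreground and
#' background as they stood at the start of that motif's chain; its matched
#' foreground windows are then removed and the search restarts for further
#' motifs. Ties break by smaller p, then smaller |offset|, then alphabetical
#' residue, making the result deterministic.
#'
#' By default the search runs separately per central residue (s, t, y), as the
#' foreground of each run; `center = "any"` pools all centers.
#'
#' @param foreground Character vector of 15-mer windows (or a tibble with a
#'   `window` column), e.g. windows of upregulated sites.
#' @param background Character vector/tibble of background windows, e.g. all
#'   S/T/Y windows of the proteome or all detected sites.
#' @param p_threshold Per-step binomial significance threshold.
#' @param min_occurrences Minimum foreground matches for a fixable pair.
#' @param center `"each"` (per-residue runs), `"s"`, `"t"`, `"y"` or `"any"`.
#' @param flank Window flank width (7 for 15-mers).
#' @return An object of class `phos_motifs`; `tidy()` gives one row per motif
#'   (pattern, counts, fold enrichment, per-step p-value chain in `steps`),
#'   ordered by decreasing score (summed -log10 step p-values).
#' @export
motif_enrichment <- function(foreground, background,
                             p_threshold = 1e-6, min_occurrences = 20L,
                             center = c("each", "s", "t", "y", "any"),
                             flank = 7L) {
  center <- match.arg(center)
  fg <- if (is.data.frame(foreground)) foreground$window else foreground
  bg <- if (is.data.frame(background)) background$window else background
  if (length(bg) == 0) phos_abort("background window set is empty")
  if (any(nchar(c(fg, bg)) != 2L * flank + 1L)) {
    phos_abort("all windows must be %d characters wide", 2L * flank + 1L)
  }
  params <- list(p_threshold = p_threshold,
                 min_occurrences = as.integer(min_occurrences),
                 center = center, flank = as.integer(flank))
  empty <- empty_motif_tibble()
  if (length(fg) == 0) {
    message("motif_enrichment: empty foreground; no motifs to extract")
    return(structure(list(motifs = empty, params = params,
                          n_foreground = 0L, n_background = length(bg)),
                     class = "phos_motifs"))
  }
  fgM_all <- do.call(rbind, strsplit(fg, ""))
  bgM_all <- do.call(rbind, strsplit(bg, ""))
  centers <- switch(center, each = c("s", "t", "y"), any = "x", center)
  mid <- flank + 1L
  res <- purrr::map_dfr(centers, function(cc) {
    if (cc == "x") {
      fgM <- fgM_all
      bgM <- bgM_all
    } else {
      fgM <- fgM_all[fgM_all[, mid] == cc, , drop = FALSE]
      bgM <- bgM_all[bgM_all[, mid] == cc, , drop = FALSE]
    }
    if (nrow(fgM) == 0 || nrow(bgM) == 0) return(empty)
    motifx_one_center(fgM, bgM, cc, log(p_threshold), min_occurrences, flank)
  })
  if (nrow(res) > 0) res <- dplyr::arrange(res, dplyr::desc(.data$score))
  structure(
    list(motifs = res, params = params,
         n_foreground = length(fg), n_background = length(bg)),
    class = "phos_motifs"
  )
}

#' @export
tidy.phos_motifs <- function(x, ...) x$motifs

#' @export
glance.phos_motifs <- function(x, ...) {
  tibble::tibble(
    n_motifs = nrow(x$motifs),
    n_foreground = x$n_foreground,
    n_background = x$n_background,
    top_pattern = if (nrow(x$motifs) > 0) x$motifs$pattern[1] else NA_character_,
    top_fold_enrichment = if (nrow(x$motifs) > 0) x$motifs$fold_enrichment[1] else NA_real_
  )
}

#' @export
print.phos_motifs <- function(x, ...) {
  cat(sprintf("<phos_motifs> %d motif(s) from %d foreground / %d background windows\n",
              nrow(x$motifs), x$n_foreground, x$n_background))
  if (nrow(x$motifs) > 0) {
    print(dplyr::select(x$motifs, -"steps"))
  }
  invisible(x)
}
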
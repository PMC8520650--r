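# internal helpers shared across modules

phos_abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

phos_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# run `code` under a fixed RNG seed when one is given, otherwise use the
# ambient RNG stream (lets composite generators share a single seed)
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' The twenty standard amino-acid one-letter codes
#' @keywords internal
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# "S727;T730" -> tibble(residue, position); vectorised over site strings
parse_site_string <- function(x) {
  parts <- stringr::str_split(x, ";")
  tibble::tibble(
    .row = rep(seq_along(parts), lengths(parts)),
    site = unlist(parts)
  ) |>
    dplyr::mutate(
      residue = stringr::str_sub(.data$site, 1L, 1L),
      position = as.integer(stringr::str_sub(.data$site, 2L))
    )
}

# residue + position -> "S727"
format_site <- function(residue, position) paste0(residue, position)

# channel columns of a PSM table as named in the design
design_channels <- function(psms, design) {
  chans <- unique(design$channel)
  missing <- setdiff(chans, names(psms))
  if (length(missing) > 0) {
    phos_abort("PSM table lacks intensity columns for channel(s): %s",
               paste(missing, collapse = ", "))
  }
  chans
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    phos_abort("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}
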
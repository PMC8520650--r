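#' Standard-normal helpers behind the significance tiers
#'
#' The pipeline calls a protein significant when its combined z-score exceeds
#' the two-sided critical value at 95% central coverage (1.96) and a
#' phosphosite/phosphopeptide significant at |z| >= 1, the value whose central
#' coverage is 68.3%. These helpers expose both identities so thresholds are
#' derived, not hard-coded, wherever a confidence level is configured.
#'
#' @param conf Central two-sided coverage probability, e.g. `0.95`.
#' @return `critical_z()`: the positive critical value; `z_coverage()`: the
#'   central coverage probability of `|Z| <= z` for a standard normal.
#' @examples
#' critical_z(0.95)   # 1.959964
#' z_coverage(1)      # 0.6826895
#' @export
critical_z <- function(conf = 0.95) {
  stopifnot(conf > 0, conf < 1)
  qnorm(1 - (1 - conf) / 2)
}

#' @rdname critical_z
#' @param z A z-score magnitude.
#' @export
z_coverage <- function(z) 2 * pnorm(abs(z)) - 1

#' Default significance thresholds per quantification level
#'
#' Phospho levels use |z| >= 1 (68.3% central coverage); the protein level uses
#' |z| >= 1.96 (95%) plus a minimum of five PSMs. Regulation additionally
#' requires |signed fold change| >= 1.5 at every level. All comparisons are
#' inclusive.
#'
#' @param level One of `"phosphosite"`, `"phosphopeptide"`, `"protein"`.
#' @return A list with elements `z`, `fc` and `min_psms`.
#' @export
default_thresholds <- function(level = c("phosphosite", "phosphopeptide", "protein")) {
  level <- match.arg(level)
  if (level == "protein") {
    list(z = 1.96, fc = 1.5, min_psms = 5L)
  } else {
    list(z = 1, fc = 1.5, min_psms = 1L)
  }
}

#' Signed linear-scale fold change from a log2 fold change
#'
#' Maps L >= 0 to `2^L` and L < 0 to `-2^(-L)`, so that a halving reads -2
#' and thresholds like "fold change <= -1.5" are meaningful.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Numeric vector of signed fold changes (magnitude always >= 1).
#' @examples
#' signed_fold_change(c(1, 0, -1))  # 2, 1, -2
#' @export
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}
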
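#' Detect splitting of the heterozygote BAF band
#'
#' Markers heterozygous in the matched normal sit at BAF 0.5 in a pure diploid
#' tumor. Any allelic imbalance (mono-allelic gain or loss, copy-neutral LOH)
#' splits this central band symmetrically into mirrored bands at `0.5 - d` and
#' `0.5 + d`. This function folds the BAF values about 0.5
#' (`f = |BAF - 0.5|`) and compares their 10%-trimmed mean with the
#' expectation under pure half-normal noise, `noise_sd * sqrt(2/pi)`. A split
#' is declared when the trimmed mean exceeds that expectation by more than
#' `se_mult` analytic standard errors; the split deviation `d` is then the
#' trimmed mean itself (an estimator unbiased to well under 0.01 for
#' d >= 0.05 at noise_sd <= 0.05).
#'
#' @param het_bafs Numeric vector of tumor BAF values at markers heterozygous
#'   in the matched normal.
#' @param noise_sd Per-marker BAF noise standard deviation (> 0), estimated
#'   from copy-neutral stretches of the same sample or supplied.
#' @param min_het_markers Minimum number of informative markers below which
#'   the profile is flagged indeterminate (default 10).
#' @param trim Trim fraction for the folded mean (default 0.1).
#' @param se_mult Detection threshold in standard errors (default 3).
#' @param t0,t1 Split-magnitude class boundaries, see [split_class_of()].
#' @return A one-row tibble with columns `n_het`, `d` (split deviation, 0 when
#'   no split), `band_lower`, `band_upper`, `split` (logical), `split_class`
#'   (ordered factor `NO_SPLIT < MODERATE < LARGE`) and `indeterminate`.
#' @examples
#' detect_baf_bands(c(rnorm(250, 0.17, 0.03), rnorm(250, 0.83, 0.03)), 0.03)
#' @export
detect_baf_bands <- function(het_bafs, noise_sd, min_het_markers = 10,
                             trim = 0.1, se_mult = 3,
                             t0 = 0.04, t1 = 0.22) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || is.na(noise_sd) ||
      noise_sd <= 0) {
    abort("`noise_sd` must be a single positive number.")
  }
  het_bafs <- het_bafs[!is.na(het_bafs)]
  n <- length(het_bafs)
  if (n < min_het_markers) {
    return(tibble::tibble(
      n_het = n, d = NA_real_, band_lower = NA_real_, band_upper = NA_real_,
      split = NA, split_class = split_factor(NA), indeterminate = TRUE
    ))
  }
  folded <- abs(het_bafs - 0.5)
  m <- mean(folded, trim = trim)
  # under no split, folded values are half-normal(noise_sd)
  null_mean <- noise_sd * sqrt(2 / pi)
  null_se <- noise_sd * sqrt(1 - 2 / pi) / sqrt(n)
  split <- m > null_mean + se_mult * null_se
  d <- if (split) min(m, 0.5) else 0
  tibble::tibble(
    n_het = n,
    d = d,
    band_lower = 0.5 - d,
    band_upper = 0.5 + d,
    split = split,
    split_class = split_class_of(d, t0 = t0, t1 = t1),
    indeterminate = FALSE
  )
}

#' Classify a split deviation as no / moderate / large
#'
#' Qualitative magnitude classes for the heterozygote-band split deviation
#' `d`. The class boundaries are descriptive conventions chosen so that the
#' canonical worked examples land in their expected rows (a 90% mono-allelic
#' gain at d = 0.16 is MODERATE; an 80% mono-allelic deletion at d = 0.33 is
#' LARGE); the quantitative mechanism call from [enumerate_mosaicism()] is
#' authoritative.
#'
#' @param d Numeric vector of split deviations in \[0, 0.5\].
#' @param t0 Below this, `NO_SPLIT` (default 0.04).
#' @param t1 At or above `t0` and below this, `MODERATE`; otherwise `LARGE`
#'   (default 0.22).
#' @return Ordered factor `NO_SPLIT < MODERATE < LARGE`.
#' @export
split_class_of <- function(d, t0 = 0.04, t1 = 0.22) {
  if (any(d < 0 | d > 0.5, na.rm = TRUE)) {
    abort("`d` must lie in [0, 0.5].")
  }
  split_factor(dplyr::case_when(
    is.na(d) ~ NA_character_,
    d < t0 ~ "NO_SPLIT",
    d < t1 ~ "MODERATE",
    .default = "LARGE"
  ))
}
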
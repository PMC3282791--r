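#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mosaicism fit
#'
#' One row per candidate aberrant karyotype at its best-fitting aberrant
#' proportion, ascending by residual (the first row is the reported call).
#'
#' @param x A `cnm_mosaicism` object from [enumerate_mosaicism()].
#' @param ... Unused.
#' @return Tibble: `mechanism`, `b_aberrant`, `n_aberrant`, `p_aberrant`,
#'   `baf_exp`, `cn_exp`, `residual`.
#' @export
tidy.cnm_mosaicism <- function(x, ...) {
  x$candidates
}

#' Summarize a mosaicism fit in one row
#'
#' @param x A `cnm_mosaicism` object.
#' @param ... Unused.
#' @return One-row tibble: `mechanism`, `p_aberrant`, `b_aberrant`,
#'   `n_aberrant`, `fit_residual`, `observed_cn`, `band_upper`.
#' @export
glance.cnm_mosaicism <- function(x, ...) {
  tibble::tibble(
    mechanism = x$mechanism,
    p_aberrant = x$p_aberrant,
    b_aberrant = x$b_aberrant,
    n_aberrant = x$n_aberrant,
    fit_residual = x$fit_residual,
    observed_cn = x$observed$cn,
    band_upper = if (length(x$observed$bands) > 0) {
      max(x$observed$bands, 1 - x$observed$bands)
    } else {
      NA_real_
    }
  )
}

#' Tidy a contingency test: observed counts in long form
#'
#' @param x A `cnm_contingency` object from [chi_square()].
#' @param ... Unused.
#' @return Tibble: `row`, `col`, `observed`, `expected`.
#' @export
tidy.cnm_contingency <- function(x, ...) {
  obs <- x$observed
  rn <- rownames(obs) %||% as.character(seq_len(nrow(obs)))
  cn <- colnames(obs) %||% as.character(seq_len(ncol(obs)))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  tibble::tibble(
    row = rep(rn, times = ncol(obs)),
    col = rep(cn, each = nrow(obs)),
    observed = as.vector(obs),
    expected = as.vector(expected)
  )
}

#' Summarize a contingency test in one row
#'
#' @param x A `cnm_contingency` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `correction`,
#'   `testable`.
#' @export
glance.cnm_contingency <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n = x$n, correction = x$correction, testable = x$testable
  )
}
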
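#' Expected B-allele frequency of a two-population admixture
#'
#' A sample containing a chromosomally aberrant clone mixed with normal cells
#' produces, at a given SNP, a B-allele frequency (BAF) equal to the
#' allele-dosage-weighted mean over the two populations:
#' \deqn{B_{exp} = \frac{b_1 P_1 + b_2 P_2}{n_1 P_1 + n_2 P_2}}
#' where \eqn{b_i} is the integer number of B alleles (a count, not a
#' frequency), \eqn{n_i} the total copy number of the locus in population
#' \eqn{i}, and \eqn{P_1 + P_2 = 1} the mixing proportions. Population 1 is
#' the aberrant clone; population 2 defaults to a normal heterozygous diploid
#' (1 B allele of 2 copies), the only informative configuration for
#' band-splitting analysis.
#'
#' @param b_aberrant Integer count of B alleles in the aberrant population.
#' @param n_aberrant Integer total copy number in the aberrant population.
#' @param p_aberrant Proportion of aberrant cells, in \[0, 1\].
#' @param b_normal,n_normal Allele count and copy number of the normal
#'   population (default heterozygous diploid, 1 of 2).
#' @return Numeric vector of expected BAF values in \[0, 1\].
#' @examples
#' expected_baf(1, 3, 0.9)  # ~0.345: mono-allelic gain in 90% of cells
#' expected_baf(0, 1, 0.8)  # ~0.167: mono-allelic loss in 80% of cells
#' @seealso [expected_cn()], [enumerate_mosaicism()]
#' @export
expected_baf <- function(b_aberrant, n_aberrant, p_aberrant,
                         b_normal = 1, n_normal = 2) {
  check_population(b_aberrant, n_aberrant)
  check_population(b_normal, n_normal)
  if (any(p_aberrant < 0 | p_aberrant > 1)) {
    abort("`p_aberrant` must lie in [0, 1].")
  }
  den <- n_aberrant * p_aberrant + n_normal * (1 - p_aberrant)
  if (any(den <= 0)) {
    abort(paste(
      "BAF is undefined: the admixture carries zero copies of the locus",
      "(both populations nullisomic)."
    ))
  }
  (b_aberrant * p_aberrant + b_normal * (1 - p_aberrant)) / den
}

#' Expected total copy number of a two-population admixture
#'
#' The mixture-mean copy number \eqn{n_1 P_1 + n_2 P_2}, on the scale where a
#' pure normal diploid locus has CN = 2.
#'
#' @inheritParams expected_baf
#' @return Numeric vector of expected copy numbers.
#' @examples
#' expected_cn(4, 0.3)  # 2.6: bi-allelic gain to 4 copies in 30% of cells
#' @export
expected_cn <- function(n_aberrant, p_aberrant, n_normal = 2) {
  if (any(p_aberrant < 0 | p_aberrant > 1)) {
    abort("`p_aberrant` must lie in [0, 1].")
  }
  n_aberrant * p_aberrant + n_normal * (1 - p_aberrant)
}

check_population <- function(b, n) {
  if (any(b < 0) || any(b > n) || any(n < 0)) {
    abort("Allele counts must satisfy 0 <= b <= n with n >= 0.")
  }
  invisible(TRUE)
}

#' Mechanism implied by an aberrant-clone karyotype
#'
#' Maps the aberrant clone's (B-allele count, copy number) pair to the
#' cytogenetic mechanism it represents, relative to a heterozygous diploid
#' normal. A zero aberrant proportion is always `NORMAL` (the admixture is
#' indistinguishable from pure normal). A single-copy clone observed at a
#' near-complete copy deficit (observed CN at or below `monosomy_cn`) is
#' labelled `MOSAIC_MONOSOMY` rather than `MONOALLELIC_DEL`.
#'
#' @param b_aberrant,n_aberrant Aberrant-clone B-allele count and copy number.
#' @param p_aberrant Aberrant proportion (0 collapses to `NORMAL`).
#' @param observed_cn Observed mean CN, used for the monosomy label; `NA`
#'   disables it.
#' @param monosomy_cn CN at or below which a one-copy clone is called mosaic
#'   monosomy (default 1.05, i.e. >= 95% of cells monosomic).
#' @return Character vector of mechanism labels.
#' @export
mechanism_of <- function(b_aberrant, n_aberrant, p_aberrant,
                         observed_cn = NA_real_, monosomy_cn = 1.05) {
  key <- paste(b_aberrant, n_aberrant)
  mech <- dplyr::case_when(
    p_aberrant == 0 ~ "NORMAL",
    key %in% c("1 2") ~ "NORMAL",
    key %in% c("1 3", "2 3") ~ "MONOALLELIC_AMP",
    key %in% c("2 4") ~ "BIALLELIC_AMP",
    key %in% c("0 1", "1 1") ~ "MONOALLELIC_DEL",
    key %in% c("0 2", "2 2") ~ "CNLOH",
    key %in% c("0 3", "3 3") ~ "AMP_ON_CNLOH",
    .default = "INDETERMINATE"
  )
  if (!is.na(observed_cn) && observed_cn <= monosomy_cn) {
    mech[mech == "MONOALLELIC_DEL" & n_aberrant == 1] <- "MOSAIC_MONOSOMY"
  }
  mech
}

#' Back-calculate mosaicism from observed BAF bands and copy number
#'
#' Exhaustive grid inversion of the admixture model: every candidate aberrant
#' karyotype (b, n) with `0 <= b <= n <= max_copies`, mixed with a
#' heterozygous diploid normal at every aberrant proportion P on a grid, is
#' scored against the observed upper heterozygote band position and the
#' observed mean copy number. The reported estimate is the candidate whose
#' forward predictions best match the observations; the aberrant proportion of
#' that candidate is the mosaicism (tumor-fraction) estimate.
#'
#' The residual is `weight_baf * |BAF_exp - band_upper| + |CN_exp - cn|`.
#' Ties are broken by parsimony (smaller `|n - 2|`, then smaller P). Because
#' A/B labels are arbitrary, mirrored karyotypes (b and n - b) fit equally
#' well and carry the same mechanism.
#'
#' @param band_centers Numeric vector of observed heterozygote band centers in
#'   \[0, 1\] (e.g. `c(0.34, 0.66)`, or `0.5` for an unsplit band). A single
#'   folded value below 0.5 is accepted.
#' @param observed_cn Observed mean copy number of the segment (> 0, at most
#'   `max_copies`).
#' @param grid_step Step of the aberrant-proportion grid (default 0.01).
#' @param max_copies Largest aberrant copy number considered (default 4).
#' @param weight_baf Weight of the BAF mismatch relative to the CN mismatch in
#'   the residual (default 2).
#' @param monosomy_cn Passed to [mechanism_of()].
#' @return An object of class `cnm_mosaicism`: a list with elements
#'   `mechanism`, `p_aberrant` (`NA` for `NORMAL`/`INDETERMINATE`),
#'   `b_aberrant`, `n_aberrant`, `fit_residual`, `observed` and `candidates`
#'   (a tibble of ranked alternatives, one row per candidate karyotype at its
#'   best-fitting P, ascending residual). Supports [tidy()] and [glance()].
#' @examples
#' enumerate_mosaicism(c(0.34, 0.66), 2.9)  # mono-allelic gain, P = 0.90
#' enumerate_mosaicism(0.5, 2.6)            # bi-allelic gain,   P = 0.30
#' enumerate_mosaicism(c(0.25, 0.75), 2.0)  # copy-neutral LOH,  P = 0.50
#' @export
enumerate_mosaicism <- function(band_centers, observed_cn,
                                grid_step = 0.01, max_copies = 4,
                                weight_baf = 2, monosomy_cn = 1.05) {
  if (length(band_centers) == 0 || all(is.na(band_centers))) {
    return(new_mosaicism_fit(
      mechanism = "INDETERMINATE", p_aberrant = NA_real_,
      b_aberrant = NA_integer_, n_aberrant = NA_integer_,
      fit_residual = NA_real_, observed = list(bands = band_centers, cn = observed_cn),
      candidates = empty_candidates()
    ))
  }
  if (!is.numeric(observed_cn) || length(observed_cn) != 1 ||
      is.na(observed_cn) || observed_cn <= 0 || observed_cn > max_copies) {
    abort(sprintf(
      "`observed_cn` must be a single value in (0, %d]; got %s.",
      max_copies, format(observed_cn)
    ))
  }
  if (any(band_centers < 0 | band_centers > 1)) {
    abort("`band_centers` must lie in [0, 1].")
  }
  band_upper <- max(band_centers)
  if (band_upper < 0.5) band_upper <- 1 - band_upper  # pre-folded input

  karyo <- tidyr::expand_grid(
    n_aberrant = 0:max_copies,
    b_aberrant = 0:max_copies
  ) |>
    dplyr::filter(.data$b_aberrant <= .data$n_aberrant)
  grid <- tidyr::expand_grid(
    karyo,
    p_aberrant = seq(0, 1, by = grid_step)
  ) |>
    dplyr::mutate(
      cn_exp = .data$n_aberrant * .data$p_aberrant + 2 * (1 - .data$p_aberrant),
      baf_exp = (.data$b_aberrant * .data$p_aberrant + (1 - .data$p_aberrant)) /
        .data$cn_exp,
      baf_exp = pmax(.data$baf_exp, 1 - .data$baf_exp),
      residual = weight_baf * abs(.data$baf_exp - band_upper) +
        abs(.data$cn_exp - observed_cn)
    ) |>
    dplyr::filter(is.finite(.data$residual)) |>
    dplyr::mutate(
      mechanism = mechanism_of(
        .data$b_aberrant, .data$n_aberrant, .data$p_aberrant,
        observed_cn = observed_cn, monosomy_cn = monosomy_cn
      )
    )

  # one row per candidate karyotype at its best-fitting P; mirrored karyotypes
  # predict algebraically identical values, so rank on a rounded residual to
  # keep the parsimony tie-break immune to floating-point noise
  candidates <- grid |>
    dplyr::arrange(
      round(.data$residual, 10), abs(.data$n_aberrant - 2), .data$p_aberrant,
      .data$b_aberrant, .data$n_aberrant
    ) |>
    dplyr::distinct(.data$b_aberrant, .data$n_aberrant, .keep_all = TRUE) |>
    dplyr::select(
      "mechanism", "b_aberrant", "n_aberrant", "p_aberrant",
      "baf_exp", "cn_exp", "residual"
    )

  best <- candidates[1, ]
  p_est <- if (best$mechanism %in% c("NORMAL", "INDETERMINATE")) {
    NA_real_
  } else {
    best$p_aberrant
  }
  new_mosaicism_fit(
    mechanism = best$mechanism,
    p_aberrant = p_est,
    b_aberrant = best$b_aberrant,
    n_aberrant = best$n_aberrant,
    fit_residual = best$residual,
    observed = list(bands = band_centers, cn = observed_cn),
    candidates = candidates
  )
}

empty_candidates <- function() {
  tibble::tibble(
    mechanism = character(), b_aberrant = integer(), n_aberrant = integer(),
    p_aberrant = double(), baf_exp = double(), cn_exp = double(),
    residual = double()
  )
}

new_mosaicism_fit <- function(mechanism, p_aberrant, b_aberrant, n_aberrant,
                              fit_residual, observed, candidates) {
  structure(
    list(
      mechanism = mechanism, p_aberrant = p_aberrant,
      b_aberrant = b_aberrant, n_aberrant = n_aberrant,
      fit_residual = fit_residual, observed = observed,
      candidates = candidates
    ),
    class = "cnm_mosaicism"
  )
}

#' @export
print.cnm_mosaicism <- function(x, ...) {
  cat("<mosaicism fit>\n")
  cat("  mechanism:  ", x$mechanism, "\n", sep = "")
  if (!is.na(x$p_aberrant)) {
    cat(sprintf(
      "  aberrant cells: %.0f%%  (clone %d of %d B alleles)\n",
      100 * x$p_aberrant, x$b_aberrant, x$n_aberrant
    ))
  }
  cat(sprintf(
    "  observed: bands {%s}, CN %.3g; residual %.4g\n",
    paste(format(x$observed$bands), collapse = ", "),
    x$observed$cn, x$fit_residual
  ))
  invisible(x)
}

#' Interpret a copy-number state and heterozygote-band split qualitatively
#'
#' Returns the descriptive mechanism label for a (CN state, split magnitude)
#' pair, the qualitative companion to the quantitative grid fit of
#' [enumerate_mosaicism()]. Unmapped combinations (e.g. a deletion with no
#' split, impossible for an autosomal clone) yield `"Indeterminate"` rather
#' than an error.
#'
#' @param cn_state Character vector over `{"AMPLIFIED", "DELETED",
#'   "UNCHANGED"}`.
#' @param split Character vector over `{"NO_SPLIT", "MODERATE", "LARGE"}`.
#' @return Character vector of interpretation labels.
#' @examples
#' table2_label("AMPLIFIED", "NO_SPLIT")  # bi-allelic amplification
#' table2_label("UNCHANGED", "MODERATE")  # cnLOH
#' @export
table2_label <- function(cn_state, split) {
  key <- paste(cn_state, split, sep = "/")
  labels <- c(
    "UNCHANGED/NO_SPLIT" = "Normal",
    "AMPLIFIED/MODERATE" = "Mono-allelic Amplification",
    "AMPLIFIED/LARGE" = "Mono-allelic amplification superimposed on cnLOH",
    "AMPLIFIED/NO_SPLIT" = "Bi-allelic amplification",
    "DELETED/LARGE" = "Mono-allelic deletion",
    "DELETED/MODERATE" = "Mono-allelic deletion in small proportion of cells",
    "UNCHANGED/MODERATE" = "cnLOH"
  )
  out <- unname(labels[key])
  out[is.na(out)] <- "Indeterminate"
  out
}
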
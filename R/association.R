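#' Per-region, per-sample copy-number state matrix
#'
#' For each recurrent region and each cohort sample, calls the sample
#' `Amplification` or `Deletion` when qualifying (>= 500 kb) segments of that
#' state cover at least `min_cover` of the region, and `Unchanged` otherwise.
#' If segments of both states reach `min_cover` (possible only for
#' `min_cover <= 0.5`), the larger covered fraction wins. Samples listed in
#' `missing_samples` for a region are marked `NA` (unanalyzable) and are
#' excluded from downstream contingency tables.
#'
#' @param regions Region tibble from [recurrent_regions()] (needs `chrom`,
#'   `start`, `end`; a `region_id` column is added if absent as
#'   `chrom:start-end`).
#' @param segments Cohort segment tibble with `sample_id`, `chrom`, `start`,
#'   `end`, `state`; filtered internally with [filter_segments()].
#' @param sample_ids All cohort sample ids (samples without segments are
#'   `Unchanged`).
#' @param min_cover Minimum covered fraction of the region (default 0.5).
#' @param params A [seg_params()] list for the length filter.
#' @param missing_samples Optional tibble (`region_id`, `sample_id`) of
#'   unanalyzable combinations.
#' @return Tibble in long form: `region_id`, `sample_id`, `cn_state` in
#'   `{"Amplification","Deletion","Unchanged"}` or `NA`.
#' @export
region_state_matrix <- function(regions, segments, sample_ids,
                                min_cover = 0.5, params = seg_params(),
                                missing_samples = NULL) {
  if (!"region_id" %in% names(regions)) {
    regions <- dplyr::mutate(
      regions,
      region_id = paste0(.data$chrom, ":", .data$start, "-", .data$end)
    )
  }
  segs <- segments |>
    dplyr::filter(.data$state %in% c("AMPLIFIED", "DELETED")) |>
    filter_segments(params) |>
    dplyr::mutate(chrom = as.character(.data$chrom))

  states <- tidyr::expand_grid(
    regions |>
      dplyr::select("region_id", "chrom", "start", "end") |>
      dplyr::mutate(chrom = as.character(.data$chrom)),
    sample_id = sample_ids
  ) |>
    dplyr::mutate(
      cn_state = purrr::pmap_chr(
        list(.data$chrom, .data$start, .data$end, .data$sample_id),
        \(ch, s, e, id) {
          sub <- segs[segs$sample_id == id & segs$chrom == ch, ]
          if (nrow(sub) == 0) return("Unchanged")
          len <- e - s + 1
          frac <- vapply(c("AMPLIFIED", "DELETED"), \(st) {
            x <- sub[sub$state == st, ]
            if (nrow(x) == 0) return(0)
            ov <- pmax(0, pmin(x$end, e) - pmax(x$start, s) + 1)
            sum(ov) / len
          }, numeric(1))
          if (max(frac) < min_cover) {
            "Unchanged"
          } else if (frac[["AMPLIFIED"]] >= frac[["DELETED"]]) {
            "Amplification"
          } else {
            "Deletion"
          }
        }
      )
    ) |>
    dplyr::select("region_id", "sample_id", "cn_state")

  if (!is.null(missing_samples)) {
    states <- states |>
      dplyr::rows_update(
        dplyr::mutate(missing_samples, cn_state = NA_character_),
        by = c("region_id", "sample_id")
      )
  }
  states
}

#' Pearson chi-square test on a contingency table
#'
#' Computes the Pearson chi-square statistic after dropping all-zero rows and
#' columns (so the degrees of freedom reflect the observable table, required
#' when an event class never occurs). The optional Yates continuity
#' correction applies to 2x2 tables only. Tables that reduce below 2x2 are
#' flagged untestable and carry no p-value.
#'
#' @param table Matrix (or object coercible to one) of nonnegative integer
#'   counts.
#' @param correction `"none"` (default, used for region-by-phenotype tables)
#'   or `"yates"` (used for 2x2 patient-characteristic tables).
#' @return An object of class `cnm_contingency`: a list with the reduced
#'   `observed` matrix, `correction`, `statistic`, `df`, `p_value`, `n` and
#'   `testable`. Supports [tidy()] and [glance()].
#' @examples
#' chi_square(rbind(c(0, 13, 41), c(1, 0, 7)))             # p ~ 0.0123
#' chi_square(rbind(c(13, 54), c(11, 8)), "yates")         # p ~ 0.003
#' @export
chi_square <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    abort("`table` must contain nonnegative integer counts.")
  }
  reduced <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  res <- list(
    observed = reduced, correction = correction,
    statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
    n = sum(reduced), testable = FALSE
  )
  if (nrow(reduced) < 2 || ncol(reduced) < 2) {
    return(structure(res, class = "cnm_contingency"))
  }
  if (correction == "yates" && !all(dim(reduced) == c(2, 2))) {
    abort("Yates continuity correction is defined for 2x2 tables only.")
  }
  ct <- suppressWarnings(
    stats::chisq.test(reduced, correct = correction == "yates")
  )
  res$statistic <- unname(ct$statistic)
  res$df <- unname(ct$parameter)
  res$p_value <- ct$p.value
  res$testable <- TRUE
  structure(res, class = "cnm_contingency")
}

#' @export
print.cnm_contingency <- function(x, ...) {
  cat("<contingency test>", if (x$correction == "yates") "(Yates-corrected)",
      "\n")
  print(x$observed)
  if (x$testable) {
    cat(sprintf(
      "  X-squared = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value
    ))
  } else {
    cat("  untestable: table reduces below 2x2\n")
  }
  invisible(x)
}

#' One-way analysis of variance
#'
#' Equal-variance one-way F test of a continuous variable across groups; with
#' two groups it equals the squared pooled-variance t test. Degenerate inputs
#' (zero within-group variance everywhere) are flagged: p = 0 if any group
#' means differ, p = 1 otherwise.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`.
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `degenerate`.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need >= 2 groups with >= 2 observations each.")
  }
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0)) {
    means <- tapply(values, groups, mean)
    p <- if (diff(range(means)) > 0) 0 else 1
    return(tibble::tibble(
      statistic = if (p == 0) Inf else 0,
      df_between = length(sizes) - 1L,
      df_within = length(values) - length(sizes),
      p_value = p, degenerate = TRUE
    ))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ft$statistic),
    df_between = as.integer(ft$parameter[["num df"]]),
    df_within = as.integer(ft$parameter[["denom df"]]),
    p_value = ft$p.value,
    degenerate = FALSE
  )
}

#' Region-phenotype association scan
#'
#' For every recurrent region and phenotype variable, cross-tabulates the
#' per-sample region state (`Amplification` / `Deletion` / `Unchanged`)
#' against the phenotype within the chosen MSI stratum and applies the
#' Pearson chi-square test without continuity correction (numeric phenotypes
#' use [anova_oneway()] across region states instead). Samples with `NA`
#' region state are dropped per region. Raw p-values are reported, with an
#' optional Benjamini-Hochberg column for convenience; no adjustment is
#' applied to the reported tests.
#'
#' @param region_states Long tibble from [region_state_matrix()].
#' @param phenotypes Phenotype tibble, one row per sample, with `sample_id`
#'   and an `msi` column (`"MSI"`/`"MSS"`) when stratifying.
#' @param phenotype_vars Character vector of phenotype columns to test
#'   (default: all columns except `sample_id` and `msi`).
#' @param stratify_by_msi Test within each MSI stratum (default `TRUE`);
#'   otherwise the whole cohort forms one stratum labelled `"all"`.
#' @param min_fraction A region-stratum result is flagged `reportable` when
#'   the fraction of stratum samples with a CN abnormality in the region is at
#'   least this (default 0.10).
#' @return Tibble: `stratum`, `region_id`, `phenotype`, `test`, `n`,
#'   `n_abnormal`, `frac_abnormal`, `statistic`, `df`, `p_value`, `p_bh`,
#'   `testable`, `reportable`.
#' @export
run_association <- function(region_states, phenotypes, phenotype_vars = NULL,
                            stratify_by_msi = TRUE, min_fraction = 0.10) {
  phenotype_vars <- phenotype_vars %||%
    setdiff(names(phenotypes), c("sample_id", "msi"))
  strata <- if (stratify_by_msi) {
    if (!"msi" %in% names(phenotypes)) {
      abort("`phenotypes` needs an `msi` column to stratify by MSI status.")
    }
    split(phenotypes, phenotypes$msi)
  } else {
    list(all = phenotypes)
  }

  purrr::imap(strata, \(ph, stratum) {
    joined <- dplyr::inner_join(region_states, ph, by = "sample_id")
    joined |>
      dplyr::group_by(.data$region_id) |>
      dplyr::group_map(\(df, key) {
        df <- df[!is.na(df$cn_state), ]
        purrr::map(phenotype_vars, \(v) {
          vals <- df[[v]]
          ok <- !is.na(vals)
          d <- df[ok, ]
          vals <- vals[ok]
          n_ab <- sum(d$cn_state != "Unchanged")
          base <- tibble::tibble(
            stratum = stratum, region_id = key$region_id, phenotype = v,
            n = nrow(d), n_abnormal = n_ab,
            frac_abnormal = if (nrow(d) > 0) n_ab / nrow(d) else NA_real_
          )
          if (is.numeric(vals)) {
            groups <- factor(d$cn_state)
            sizes <- table(groups)
            if (length(sizes) < 2 || any(sizes < 2)) {
              return(dplyr::mutate(base,
                test = "anova", statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, testable = FALSE
              ))
            }
            a <- anova_oneway(vals, groups)
            dplyr::mutate(base,
              test = "anova", statistic = a$statistic, df = a$df_between,
              p_value = a$p_value, testable = !a$degenerate
            )
          } else {
            tab <- table(
              factor(vals),
              factor(d$cn_state,
                levels = c("Amplification", "Deletion", "Unchanged")
              )
            )
            cs <- chi_square(unclass(tab), correction = "none")
            dplyr::mutate(base,
              test = "chi_square", statistic = cs$statistic, df = cs$df,
              p_value = cs$p_value, testable = cs$testable
            )
          }
        }) |>
          dplyr::bind_rows()
      }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      p_bh = stats::p.adjust(.data$p_value, method = "BH"),
      reportable = .data$testable & .data$frac_abnormal >= min_fraction
    ) |>
    dplyr::select(
      "stratum", "region_id", "phenotype", "test", "n", "n_abnormal",
      "frac_abnormal", "statistic", "df", "p_value", "p_bh", "testable",
      "reportable"
    )
}
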
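#' Segmentation parameters
#'
#' Settings for paired copy-number segmentation and state calling. Defaults
#' follow the conventions for ~600k-marker arrays: a split must leave at least
#' 25 markers on each side (use 10 for ~300k-marker maps), be significant at
#' p < 0.001, and a segment is only reported as an event if it spans at least
#' 500 kb. A segment is amplified at geometric-mean CN >= 2.5, deleted at
#' <= 1.5, and copy-neutral only in the conservative band \[1.9, 2.1\]; the
#' gaps (1.5, 1.9) and (2.1, 2.5) are indeterminate.
#'
#' @param min_markers Minimum markers per segment (>= 2).
#' @param p_threshold Two-sided significance level for accepting a split.
#' @param amp_cn,del_cn Amplification / deletion thresholds on geometric-mean
#'   CN.
#' @param neutral_lo,neutral_hi Conservative copy-neutral band.
#' @param min_length_bp Minimum event segment length in bp.
#' @return A list of class `cnm_seg_params`.
#' @export
seg_params <- function(min_markers = 25, p_threshold = 0.001,
                       amp_cn = 2.5, del_cn = 1.5,
                       neutral_lo = 1.9, neutral_hi = 2.1,
                       min_length_bp = 5e5) {
  if (min_markers < 2) abort("`min_markers` must be >= 2.")
  if (!(del_cn < neutral_lo && neutral_lo < neutral_hi && neutral_hi < amp_cn)) {
    abort("Thresholds must satisfy del_cn < neutral_lo < neutral_hi < amp_cn.")
  }
  structure(
    list(
      min_markers = as.integer(min_markers), p_threshold = p_threshold,
      amp_cn = amp_cn, del_cn = del_cn,
      neutral_lo = neutral_lo, neutral_hi = neutral_hi,
      min_length_bp = min_length_bp
    ),
    class = "cnm_seg_params"
  )
}

#' Paired per-marker copy number
#'
#' Copy number of each marker in the tumor relative to its matched normal:
#' `CN = 2 * 2^(LRR_tumor - LRR_normal)`. Using the matched normal as the
#' reference cancels shared array effects; identical signal gives CN = 2.
#'
#' @param tumor,normal Marker tibbles for one sample each, as returned by
#'   [read_marker_table()] or [simulate_pair()]: columns `snp_name`, `chrom`,
#'   `pos`, `baf`, `lrr`. Marker sets and order must be identical.
#' @return The tumor tibble with columns `cn` (paired copy number) and
#'   `normal_het` (normal BAF in \[0.4, 0.6\]) added.
#' @export
paired_cn <- function(tumor, normal) {
  check_marker_cols(tumor)
  check_marker_cols(normal)
  if (nrow(tumor) != nrow(normal)) {
    abort(sprintf(
      "Tumor and normal tracks differ in marker count (%d vs %d).",
      nrow(tumor), nrow(normal)
    ))
  }
  mismatch <- which(
    tumor$snp_name != normal$snp_name |
      tumor$chrom != normal$chrom | tumor$pos != normal$pos
  )
  if (length(mismatch) > 0) {
    abort(sprintf(
      "Tumor and normal tracks disagree at marker %d ('%s' vs '%s').",
      mismatch[1], tumor$snp_name[mismatch[1]], normal$snp_name[mismatch[1]]
    ))
  }
  tumor |>
    dplyr::mutate(
      cn = 2 * 2^(.data$lrr - normal$lrr),
      normal_het = normal$baf >= 0.4 & normal$baf <= 0.6
    )
}

check_marker_cols <- function(df) {
  need <- c("snp_name", "chrom", "pos", "baf", "lrr")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Marker table is missing column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  invisible(df)
}

# Welch two-sample t over every admissible split point of x, vectorized via
# cumulative sums. Returns the best split (max |t|) or NULL if none allowed.
best_split <- function(x, min_markers) {
  n <- length(x)
  if (n < 2 * min_markers) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq.int(min_markers, n - min_markers)
  n1 <- k
  n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (cs[n] - cs[k]) / n2
  v1 <- pmax((cs2[k] - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax((cs2[n] - cs2[k] - n2 * m2^2) / (n2 - 1), 0)
  se2 <- v1 / n1 + v2 / n2
  # zero pooled variance: infinitely significant if the means differ (exact
  # step), no evidence at all if they coincide up to rounding
  tval <- ifelse(
    se2 > 0, (m1 - m2) / sqrt(se2),
    ifelse(abs(m1 - m2) < 1e-12, 0, Inf)
  )
  df <- ifelse(se2 > 0,
    se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1)),
    1
  )
  p <- ifelse(is.infinite(tval), 0, 2 * pt(-abs(tval), df))
  i <- which.max(abs(tval))
  list(split_after = k[i], statistic = tval[i], p_value = p[i])
}

#' Partition one chromosome's copy-number track into segments
#'
#' Recursive binary splitting on log2(CN): at each level the candidate split
#' maximizing the two-sample Welch t statistic between the left and right
#' halves is accepted if both sides retain at least `min_markers` markers and
#' the two-sided p-value is below `p_threshold`, then both sides are
#' partitioned recursively. Deterministic for fixed input; segments tile the
#' chromosome. This is an equivalent-in-contract reimplementation of
#' commercial mean-difference genomic segmentation, not bit-identical to any
#' proprietary tool.
#'
#' @param cn Positive, finite per-marker copy-number values for one
#'   chromosome, in map order.
#' @param params A [seg_params()] list.
#' @return Tibble with one row per segment: `start_idx`, `end_idx` (1-based
#'   marker indices, inclusive), `n_markers`, `geo_mean_cn`.
#' @export
segment_track <- function(cn, params = seg_params()) {
  bad <- which(!is.finite(cn) | cn <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Non-finite or non-positive CN at marker index %d.", bad[1]))
  }
  x <- log2(cn)
  bounds <- list()
  recurse <- function(lo, hi) {
    seg <- x[lo:hi]
    sp <- best_split(seg, params$min_markers)
    if (is.null(sp) || sp$p_value >= params$p_threshold) {
      bounds[[length(bounds) + 1]] <<- c(lo, hi)
      return(invisible(NULL))
    }
    cut <- lo + sp$split_after - 1
    recurse(lo, cut)
    recurse(cut + 1, hi)
  }
  recurse(1, length(cn))
  mat <- do.call(rbind, bounds)
  mat <- mat[order(mat[, 1]), , drop = FALSE]
  tibble::tibble(
    start_idx = mat[, 1],
    end_idx = mat[, 2],
    n_markers = mat[, 2] - mat[, 1] + 1,
    geo_mean_cn = purrr::map2_dbl(
      mat[, 1], mat[, 2],
      \(a, b) exp(mean(log(cn[a:b])))
    )
  )
}

#' Call the copy-number state of segment means
#'
#' `AMPLIFIED` at geometric-mean CN >= `amp_cn`, `DELETED` at <= `del_cn`,
#' `NEUTRAL` inside the conservative copy-neutral band, `INDETERMINATE` in
#' the gaps between.
#'
#' @param geo_mean_cn Numeric vector of segment geometric-mean CN values.
#' @param params A [seg_params()] list.
#' @return Character vector over
#'   `{"AMPLIFIED","DELETED","NEUTRAL","INDETERMINATE"}`.
#' @export
call_state <- function(geo_mean_cn, params = seg_params()) {
  dplyr::case_when(
    geo_mean_cn >= params$amp_cn ~ "AMPLIFIED",
    geo_mean_cn <= params$del_cn ~ "DELETED",
    geo_mean_cn >= params$neutral_lo & geo_mean_cn <= params$neutral_hi ~ "NEUTRAL",
    .default = "INDETERMINATE"
  )
}

#' Drop segments shorter than the minimum event length
#'
#' Only segments spanning at least `min_length_bp` (by genomic coordinates,
#' end - start + 1) qualify as reportable events. Order-preserving.
#'
#' @param segments Segment tibble with `start` and `end` columns (1-based,
#'   inclusive).
#' @param params A [seg_params()] list (uses `min_length_bp`).
#' @return The qualifying subset of `segments`.
#' @export
filter_segments <- function(segments, params = seg_params()) {
  dplyr::filter(segments, .data$end - .data$start + 1 >= params$min_length_bp)
}

#' Segment and classify one tumor/normal pair
#'
#' The per-sample pipeline: paired copy number ([paired_cn()]), per-chromosome
#' segmentation ([segment_track()]), state calls ([call_state()]),
#' heterozygote-band profiling ([detect_baf_bands()]) on markers heterozygous
#' in the matched normal, and admixture-model mechanism classification with
#' mosaic-fraction estimation ([enumerate_mosaicism()]) for every non-normal
#' segment. BAF noise is estimated from the matched normal's heterozygous
#' markers unless supplied.
#'
#' @inheritParams paired_cn
#' @param params A [seg_params()] list.
#' @param noise_sd BAF noise sd; `NULL` (default) estimates it as the standard
#'   deviation of the normal sample's heterozygote BAF about 0.5.
#' @param max_copies,grid_step Passed to [enumerate_mosaicism()].
#' @return Tibble with one row per segment: `sample_id`, `chrom`, `start`,
#'   `end` (positions of first/last marker, 1-based inclusive), `n_markers`,
#'   `geo_mean_cn`, `state`, `n_het`, `band_d`, `band_lower`, `band_upper`,
#'   `split_class`, `mechanism`, `p_aberrant`, `fit_residual`.
#' @export
call_segments <- function(tumor, normal, params = seg_params(),
                          noise_sd = NULL, max_copies = 4, grid_step = 0.01) {
  paired <- paired_cn(tumor, normal)
  if (is.null(noise_sd)) {
    het <- normal$baf[normal$baf >= 0.4 & normal$baf <= 0.6]
    noise_sd <- if (length(het) >= 10) stats::sd(het - 0.5) else 0.03
  }
  sample_id <- if ("sample_id" %in% names(tumor)) tumor$sample_id[1] else NA_character_

  paired |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(\(mk, key) {
      segs <- segment_track(mk$cn, params)
      segs |>
        dplyr::mutate(
          sample_id = sample_id,
          chrom = key$chrom,
          start = mk$pos[.data$start_idx],
          end = mk$pos[.data$end_idx],
          state = call_state(.data$geo_mean_cn, params),
          profile = purrr::map2(.data$start_idx, .data$end_idx, \(a, b) {
            idx <- a:b
            detect_baf_bands(
              mk$baf[idx][mk$normal_het[idx]],
              noise_sd = noise_sd
            )
          })
        ) |>
        tidyr::unnest("profile") |>
        dplyr::rename(band_d = "d") |>
        dplyr::mutate(
          fit = purrr::pmap(
            list(.data$band_lower, .data$band_upper, .data$geo_mean_cn,
                 .data$indeterminate),
            \(lo, hi, cn, ind) {
              cn_cap <- min(cn, max_copies)  # clip extreme means into the grid
              if (ind || cn <= 0) {
                enumerate_mosaicism(numeric(0), cn_cap)
              } else {
                enumerate_mosaicism(
                  unique(c(lo, hi)), cn_cap,
                  grid_step = grid_step, max_copies = max_copies
                )
              }
            }
          ),
          mechanism = purrr::map_chr(.data$fit, "mechanism"),
          p_aberrant = purrr::map_dbl(.data$fit, "p_aberrant"),
          fit_residual = purrr::map_dbl(.data$fit, "fit_residual"),
          # a copy-neutral segment with an unsplit heterozygote band is normal
          # by definition; the grid fit is only interpreted for abnormalities
          quiet = .data$state == "NEUTRAL" &
            !is.na(.data$split_class) & .data$split_class == "NO_SPLIT",
          mechanism = ifelse(.data$quiet, "NORMAL", .data$mechanism),
          p_aberrant = ifelse(.data$quiet, NA_real_, .data$p_aberrant),
          fit_residual = ifelse(.data$quiet, NA_real_, .data$fit_residual)
        ) |>
        dplyr::select(
          "sample_id", "chrom", "start", "end", "n_markers", "geo_mean_cn",
          "state", "n_het", "band_d", "band_lower", "band_upper",
          "split_class", "mechanism", "p_aberrant", "fit_residual"
        )
    }) |>
    dplyr::bind_rows()
}
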
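#' Recurrent amplification / deletion regions across a cohort
#'
#' Stacks qualifying per-sample event segments and returns the maximal
#' genomic intervals where the number of samples carrying the event at every
#' base is at least `ceil(min_fraction * cohort_size)` (e.g. 9 of 86 samples
#' at the default 10%). Within each sample, segments are merged before
#' counting so a sample contributes at most once per base.
#'
#' @param segments Cohort segment tibble (rows from [call_segments()] over all
#'   samples) with columns `sample_id`, `chrom`, `start`, `end`, `state`; the
#'   >= 500 kb event filter ([filter_segments()]) is applied internally using
#'   `params`.
#' @param event `"AMP"` or `"DEL"`.
#' @param cohort_size Number of samples in the cohort (support is measured
#'   against this, not against the samples present in `segments`).
#' @param min_fraction Minimum supporting fraction of the cohort (default
#'   0.10).
#' @param params A [seg_params()] list used for the length filter.
#' @return Tibble with one row per region: `chrom`, `start`, `end` (1-based
#'   inclusive; BED output converts to 0-based half-open), `event`,
#'   `n_support` (minimum pointwise coverage, i.e. every base of the region
#'   is shared by at least this many samples), `cohort_size`, `support_frac`
#'   and `samples` (list column of sample ids whose qualifying segments
#'   overlap the region; at least `n_support` of them). Regions of one event
#'   type are disjoint and sorted.
#' @export
recurrent_regions <- function(segments, event = c("AMP", "DEL"),
                              cohort_size, min_fraction = 0.10,
                              params = seg_params()) {
  event <- match.arg(event)
  state <- c(AMP = "AMPLIFIED", DEL = "DELETED")[[event]]
  segs <- segments |>
    dplyr::filter(.data$state == !!state) |>
    filter_segments(params)
  stack_regions(segs, event, cohort_size, min_fraction)
}

#' Recurrent copy-neutral LOH regions
#'
#' Same cohort stacking as [recurrent_regions()], applied to segments that are
#' copy-neutral under the conservative band (state `NEUTRAL`, geometric-mean
#' CN in \[1.9, 2.1\]) yet show a detected heterozygote-band split of at least
#' `MODERATE` magnitude -- the signature of copy-neutral loss of
#' heterozygosity, invisible to pure copy-number platforms.
#'
#' @inheritParams recurrent_regions
#' @param min_split Minimum split class counted as LOH (default
#'   `"MODERATE"`).
#' @return As [recurrent_regions()], with `event = "CNLOH"`.
#' @export
cnloh_regions <- function(segments, cohort_size, min_fraction = 0.10,
                          params = seg_params(), min_split = "MODERATE") {
  segs <- segments |>
    dplyr::filter(
      .data$state == "NEUTRAL",
      !is.na(.data$split_class),
      .data$split_class >= split_factor(min_split)
    ) |>
    filter_segments(params)
  stack_regions(segs, "CNLOH", cohort_size, min_fraction)
}

# Maximal intervals with pointwise support >= ceil(min_fraction * cohort_size),
# computed per chromosome from an IRanges coverage profile.
stack_regions <- function(segs, event, cohort_size, min_fraction) {
  if (cohort_size < 1) abort("`cohort_size` must be >= 1.")
  threshold <- ceiling(min_fraction * cohort_size)
  empty <- tibble::tibble(
    chrom = character(), start = double(), end = double(),
    event = character(), n_support = integer(), cohort_size = integer(),
    support_frac = double(), samples = list()
  )
  if (nrow(segs) == 0) return(empty)

  segs |>
    dplyr::mutate(chrom = as.character(.data$chrom)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(\(df, key) {
      # one contribution per sample per base
      by_sample <- df |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::group_map(\(s, k) {
          r <- IRanges::reduce(IRanges::IRanges(s$start, s$end))
          tibble::tibble(
            sample_id = k$sample_id,
            start = IRanges::start(r), end = IRanges::end(r)
          )
        }) |>
        dplyr::bind_rows()
      ir <- IRanges::IRanges(by_sample$start, by_sample$end)
      cov <- IRanges::coverage(ir)
      runs <- IRanges::slice(cov, lower = threshold, rangesOnly = TRUE)
      if (length(runs) == 0) return(NULL)
      # support = pointwise coverage at the region's weakest base, so every
      # base of the region is shared by at least n_support samples
      min_cov <- as.integer(
        IRanges::viewMins(IRanges::Views(cov, runs))
      )
      tibble::tibble(
        chrom = key$chrom,
        start = IRanges::start(runs),
        end = IRanges::end(runs),
        event = event,
        samples = purrr::map2(.data$start, .data$end, \(a, b) {
          hit <- by_sample$start <= b & by_sample$end >= a
          sort(unique(by_sample$sample_id[hit]))
        }),
        n_support = min_cov,
        cohort_size = as.integer(cohort_size),
        support_frac = .data$n_support / cohort_size
      )
    }) |>
    dplyr::bind_rows() |>
    (\(x) if (nrow(x) == 0) empty else x)() |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(
      "chrom", "start", "end", "event", "n_support", "cohort_size",
      "support_frac", "samples"
    )
}
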
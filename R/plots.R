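#' Copy-number and BAF panels for one sample
#'
#' The standard two-panel view of a chromosome (or whole genome): per-marker
#' paired copy number on a linear scale with segment means overlaid, above
#' the B-allele frequency cloud in which heterozygote-band splits are read.
#'
#' @param tumor,normal Single-sample marker tibbles (see [paired_cn()]).
#' @param segments Optional segment tibble from [call_segments()] to overlay.
#' @param chrom Optional chromosome label to restrict the view.
#' @return A ggplot object faceted into CN and BAF panels.
#' @export
plot_cn_baf <- function(tumor, normal, segments = NULL, chrom = NULL) {
  df <- paired_cn(tumor, normal)
  if (!is.null(chrom)) {
    keep <- as.character(chrom)
    df <- dplyr::filter(df, as.character(.data$chrom) %in% keep)
    if (!is.null(segments)) {
      segments <- dplyr::filter(
        segments, as.character(.data$chrom) %in% keep
      )
    }
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(
      df, .data$chrom, .data$pos, value = .data$cn, panel = "Copy number"
    ),
    dplyr::transmute(
      df, .data$chrom, .data$pos, value = .data$baf, panel = "BAF"
    )
  ) |>
    dplyr::mutate(panel = factor(.data$panel, c("Copy number", "BAF")))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$pos, .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey30") +
    ggplot2::facet_grid(
      panel ~ chrom, scales = "free", space = "free_x", switch = "y"
    ) +
    ggplot2::labs(x = "Position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    seg_cn <- dplyr::mutate(segments, panel = factor("Copy number",
      c("Copy number", "BAF")
    ))
    gg <- gg + ggplot2::geom_segment(
      data = seg_cn,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$geo_mean_cn, yend = .data$geo_mean_cn,
        colour = .data$state
      ),
      linewidth = 1.2, inherit.aes = FALSE
    ) +
      ggplot2::scale_colour_manual(values = c(
        AMPLIFIED = "#c23b22", DELETED = "#2b5f9e",
        NEUTRAL = "grey55", INDETERMINATE = "#b89b2c"
      ), name = "State")
  }
  gg
}

#' Cohort event-coverage profile per chromosome
#'
#' Step plot of how many samples carry a qualifying event at each position,
#' with the recurrence threshold line; recurrent regions are the stretches at
#' or above the line.
#'
#' @param segments Cohort segment tibble.
#' @param cohort_size Number of samples in the cohort.
#' @param event `"AMP"` or `"DEL"`.
#' @param min_fraction Recurrence threshold fraction (default 0.10).
#' @param params A [seg_params()] list.
#' @return A ggplot object.
#' @export
plot_region_coverage <- function(segments, cohort_size, event = "AMP",
                                 min_fraction = 0.10, params = seg_params()) {
  state <- c(AMP = "AMPLIFIED", DEL = "DELETED", CNLOH = "NEUTRAL")[[event]]
  segs <- segments |>
    dplyr::filter(.data$state == !!state) |>
    filter_segments(params)
  steps <- segs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(\(df, key) {
      bp <- sort(unique(c(df$start, df$end + 1)))
      if (length(bp) == 0) return(NULL)
      tibble::tibble(
        chrom = key$chrom,
        pos = bp,
        n = vapply(
          bp, \(p) sum(df$start <= p & df$end >= p), integer(1)
        )
      )
    }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(steps, ggplot2::aes(.data$pos, .data$n)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = ceiling(min_fraction * cohort_size),
      linetype = "dashed", colour = "#c23b22"
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "Position (bp)", y = sprintf("Samples with %s event", event)
    ) +
    ggplot2::theme_minimal()
}
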
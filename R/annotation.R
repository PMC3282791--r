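#' Fraction of a gene covered by a region
#'
#' Intersection length divided by gene length, with 1-based inclusive
#' coordinates; 0 when chromosomes differ. Vectorized over genes.
#'
#' @param gene_chrom,gene_start,gene_end Gene interval(s).
#' @param region_chrom,region_start,region_end A single region interval.
#' @return Numeric vector of overlap fractions in \[0, 1\].
#' @export
overlap_fraction <- function(gene_chrom, gene_start, gene_end,
                             region_chrom, region_start, region_end) {
  ov <- pmax(0, pmin(gene_end, region_end) - pmax(gene_start, region_start) + 1)
  frac <- ov / (gene_end - gene_start + 1)
  frac[as.character(gene_chrom) != as.character(region_chrom)] <- 0
  frac
}

#' Genes overlapping recurrent regions
#'
#' Returns, per region, the genes whose overlap fraction with the region is at
#' least `min_frac`. The strict default (`min_frac = 1`, fully contained
#' genes) matches the convention for region gene lists; 0.9 is the relaxed
#' threshold used for aneuploidy gene content.
#'
#' @param genes Gene model tibble from [read_gene_bed()]: `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive), optionally `strand`.
#' @param regions Region tibble (`chrom`, `start`, `end`, optionally
#'   `region_id` and `event`).
#' @param min_frac Minimum overlap fraction in (0, 1] (default 1.0).
#' @return Tibble: `region_id`, `event` (if present), `gene`,
#'   `overlap_frac`, one row per (region, gene), deduplicated.
#' @export
genes_in_regions <- function(genes, regions, min_frac = 1.0) {
  if (!(min_frac > 0 && min_frac <= 1)) {
    abort("`min_frac` must lie in (0, 1].")
  }
  if (!"region_id" %in% names(regions)) {
    regions <- dplyr::mutate(
      regions,
      region_id = paste0(.data$chrom, ":", .data$start, "-", .data$end)
    )
  }
  keep_cols <- intersect(c("region_id", "event"), names(regions))
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(
      region_id = character(),
      !!!(if ("event" %in% keep_cols) list(event = character()) else list()),
      gene = character(), overlap_frac = double()
    ))
  }
  regions |>
    dplyr::mutate(chrom = as.character(.data$chrom)) |>
    purrr::pmap(\(chrom, start, end, region_id, ...) {
      dots <- list(...)
      frac <- overlap_fraction(
        genes$chrom, genes$start, genes$end, chrom, start, end
      )
      hit <- frac >= min_frac
      if (!any(hit)) return(NULL)
      out <- tibble::tibble(
        region_id = region_id,
        gene = genes$gene[hit],
        overlap_frac = frac[hit]
      )
      if ("event" %in% keep_cols) out$event <- dots$event
      out
    }) |>
    dplyr::bind_rows() |>
    dplyr::distinct(.data$region_id, .data$gene, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("region_id", "event", "gene", "overlap_frac")))
}

#' Match region genes against a drug-target table
#'
#' Applies the therapeutic-mode rules: genes in amplified regions are matched
#' to drugs that oppose their product (antagonists, antibodies, inhibitors);
#' genes in deleted regions to drugs that enhance it (agonists, activators,
#' inducers). Records with approval status `discontinued` or `unknown` are
#' excluded from the default ("available") report but retained when
#' `include_unavailable = TRUE`.
#'
#' @param region_genes Tibble with `region_id`, `event` (`"AMP"` or `"DEL"`;
#'   `"CNLOH"` rows are ignored) and `gene`, e.g. from [genes_in_regions()].
#' @param drugs Drug table from [read_drug_table()]: `gene`, `drug`, `type`,
#'   `status`, `indication`.
#' @param include_unavailable Keep discontinued/unknown-status records
#'   (flagged by the `available` column) instead of dropping them.
#' @return Tibble: `region_id`, `event`, `gene`, `drug`, `type`, `status`,
#'   `indication`, `available`.
#' @export
match_drugs <- function(region_genes, drugs, include_unavailable = FALSE) {
  modes <- list(
    AMP = c("antagonist", "antibody", "inhibitor"),
    DEL = c("agonist", "activator", "inducer")
  )
  out <- region_genes |>
    dplyr::filter(.data$event %in% names(modes)) |>
    dplyr::inner_join(drugs, by = "gene", relationship = "many-to-many") |>
    dplyr::filter(purrr::map2_lgl(
      .data$event, .data$type, \(ev, ty) ty %in% modes[[ev]]
    )) |>
    dplyr::mutate(
      available = !.data$status %in% c("discontinued", "unknown")
    ) |>
    dplyr::select(
      "region_id", "event", "gene", "drug", "type", "status", "indication",
      "available"
    ) |>
    dplyr::arrange(.data$region_id, .data$gene, .data$drug)
  if (!include_unavailable) out <- dplyr::filter(out, .data$available)
  out
}
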
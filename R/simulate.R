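#' Synthetic cohort configuration
#'
#' Parameters of the paired tumor/normal marker simulator. The default map is
#' a deliberately scaled-down genome -- two 100 Mb autosomes with 2,500 evenly
#' spaced markers each -- so that a full pipeline run takes seconds; noise
#' defaults (BAF sd 0.03, log-R sd 0.15) match the band widths typical of
#' Infinium-class arrays.
#'
#' @param n_samples Number of tumor/normal pairs.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (names are autosome labels `"1"`..`"22"`).
#' @param markers_per_chrom Markers per chromosome (evenly spaced).
#' @param pop_baf Population B-allele frequency of every marker (default 0.5,
#'   maximizing the heterozygote fraction).
#' @param baf_sd BAF noise sd (truncated normal, clipped to \[0, 1\]).
#' @param lrr_sd Log-R-ratio noise sd (normal, log2 scale).
#' @param seed Mandatory RNG seed; every simulation is reproducible from it.
#' @return A list of class `cnm_sim_config`.
#' @export
sim_config <- function(n_samples = 20,
                       chrom_lengths = c("1" = 1e8, "2" = 1e8),
                       markers_per_chrom = 2500,
                       pop_baf = 0.5, baf_sd = 0.03, lrr_sd = 0.15,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory: simulations must be reproducible.")
  }
  if (baf_sd <= 0 || lrr_sd <= 0) abort("Noise sds must be positive.")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  structure(
    list(
      n_samples = n_samples, chrom_lengths = chrom_lengths,
      markers_per_chrom = markers_per_chrom, pop_baf = pop_baf,
      baf_sd = baf_sd, lrr_sd = lrr_sd, seed = as.integer(seed)
    ),
    class = "cnm_sim_config"
  )
}

#' Aberration event roster entry
#'
#' Convenience constructor for the event tibble consumed by
#' [simulate_pair()] / [simulate_cohort()]: one chromosomal aberration in one
#' sample, defined by its genomic interval, the aberrant clone's karyotype at
#' heterozygous loci (B-allele count `b` of `n` copies) and the aberrant cell
#' fraction.
#'
#' @param sample_id Sample identifier.
#' @param chrom Chromosome label.
#' @param start,end Interval in bp (1-based inclusive).
#' @param b_aberrant,n_aberrant Aberrant-clone B-allele count and copy number
#'   at loci heterozygous in the normal (homozygous loci are mapped to the
#'   corresponding 0 or `n_aberrant` B alleles automatically).
#' @param p_aberrant Aberrant cell fraction in (0, 1].
#' @return One-row tibble.
#' @export
sim_event <- function(sample_id, chrom, start, end,
                      b_aberrant, n_aberrant, p_aberrant) {
  check_population(b_aberrant, n_aberrant)
  if (p_aberrant <= 0 || p_aberrant > 1) {
    abort("`p_aberrant` must lie in (0, 1].")
  }
  tibble::tibble(
    sample_id = sample_id, chrom = as.character(chrom),
    start = start, end = end,
    b_aberrant = as.integer(b_aberrant), n_aberrant = as.integer(n_aberrant),
    p_aberrant = p_aberrant
  )
}

empty_events <- function() {
  tibble::tibble(
    sample_id = character(), chrom = character(), start = double(),
    end = double(), b_aberrant = integer(), n_aberrant = integer(),
    p_aberrant = double()
  )
}

marker_map <- function(config) {
  purrr::imap(config$chrom_lengths, \(len, ch) {
    pos <- round(seq(1, len, length.out = config$markers_per_chrom))
    tibble::tibble(
      snp_name = sprintf("SNP_%s_%06d", ch, seq_along(pos)),
      chrom = ch,
      pos = pos
    )
  }) |>
    dplyr::bind_rows()
}

rtrunc_baf <- function(mean, sd) {
  pmin(pmax(mean + rnorm(length(mean), 0, sd), 0), 1)
}

#' Simulate one paired tumor/normal marker track
#'
#' Forward simulation of the admixture model. Normal genotypes are drawn per
#' marker from the population B-allele frequency; normal BAF is the genotype
#' dosage (0 / 0.5 / 1) plus truncated-normal noise, and normal log-R is pure
#' noise around 0. Outside events the tumor mirrors the normal (independent
#' noise). Within an event, the tumor BAF is the admixture-expected BAF
#' ([expected_baf()]) given the marker's normal genotype, and the tumor log-R
#' is the normal log-R plus `log2(expected_cn / 2)`, each plus noise.
#'
#' @param config A [sim_config()].
#' @param events Event tibble (rows from [sim_event()]) for this sample, or
#'   `NULL` for a flat diploid tumor. Intervals must lie on the marker map
#'   and not overlap.
#' @param sample_id Sample identifier stamped on both tracks.
#' @param seed Seed for this pair; defaults to `config$seed`.
#' @return List with tibbles `tumor` and `normal` (columns `sample_id`,
#'   `snp_name`, `chrom`, `pos`, `baf`, `lrr`) and `truth` (the event roster).
#' @export
simulate_pair <- function(config, events = NULL, sample_id = "S1",
                          seed = config$seed) {
  if (!is.null(events) && nrow(events) > 0) {
    bad <- !events$chrom %in% names(config$chrom_lengths) |
      events$start < 1 |
      events$end > config$chrom_lengths[events$chrom]
    if (any(bad)) {
      abort(sprintf(
        "Event %d (%s:%s-%s) lies outside the marker map.",
        which(bad)[1], events$chrom[which(bad)[1]],
        format(events$start[which(bad)[1]], scientific = FALSE),
        format(events$end[which(bad)[1]], scientific = FALSE)
      ))
    }
    overlap <- events |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::filter(dplyr::row_number() > 1 &
                      .data$start <= dplyr::lag(.data$end)) |>
      nrow()
    if (overlap > 0) abort("Events overlap within the sample.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  mk <- marker_map(config)
  m <- nrow(mk)
  geno <- rbinom(m, 2, config$pop_baf) # B-allele count in the germline
  normal <- mk |>
    dplyr::mutate(
      sample_id = sample_id,
      baf = rtrunc_baf(geno / 2, config$baf_sd),
      lrr = rnorm(m, 0, config$lrr_sd)
    ) |>
    dplyr::relocate("sample_id")
  # tumor baseline: same germline, independent noise
  exp_baf <- geno / 2
  exp_cn <- rep(2, m)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      idx <- which(mk$chrom == ev$chrom & mk$pos >= ev$start &
                     mk$pos <= ev$end)
      b1 <- dplyr::case_when(
        geno[idx] == 0 ~ 0L,
        geno[idx] == 2 ~ ev$n_aberrant,
        .default = ev$b_aberrant
      )
      den <- ev$n_aberrant * ev$p_aberrant + 2 * (1 - ev$p_aberrant)
      exp_baf[idx] <- (b1 * ev$p_aberrant + (geno[idx] / 2) * 2 *
                         (1 - ev$p_aberrant)) / den
      exp_cn[idx] <- den
    }
  }
  tumor <- mk |>
    dplyr::mutate(
      sample_id = sample_id,
      baf = rtrunc_baf(exp_baf, config$baf_sd),
      lrr = normal$lrr + log2(exp_cn / 2) + rnorm(m, 0, config$lrr_sd)
    ) |>
    dplyr::relocate("sample_id")
  list(tumor = tumor, normal = normal, truth = events %||% empty_events())
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a cohort of paired samples with phenotypes
#'
#' Simulates `config$n_samples` tumor/normal pairs (each from its own
#' deterministic sub-seed of `config$seed`), together with a phenotype table.
#' When `phenotypes` is not supplied, one is drawn with class frequencies
#' mimicking a colorectal-cancer case series (28% MSI, 78% left-sided, 87%
#' adenocarcinoma, three stages, binary grade and nodal status); pass an
#' explicit table to plant region-phenotype associations.
#'
#' @param config A [sim_config()].
#' @param events Event roster tibble over all samples (see [sim_event()]).
#' @param phenotypes Optional phenotype tibble (one row per `sample_id`);
#'   generated if `NULL`.
#' @return List with `tumor` and `normal` (all samples row-bound),
#'   `phenotypes`, and `truth` (the event roster). Sample ids are
#'   `"S01"`, `"S02"`, ...
#' @export
simulate_cohort <- function(config, events = NULL, phenotypes = NULL) {
  ids <- sprintf("S%02d", seq_len(config$n_samples))
  pairs <- purrr::imap(ids, \(id, i) {
    ev <- if (is.null(events)) NULL else events[events$sample_id == id, ]
    simulate_pair(config, ev, sample_id = id, seed = config$seed + 1000L + i)
  })
  if (is.null(phenotypes)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed + 999L)
    n <- length(ids)
    phenotypes <- tibble::tibble(
      sample_id = ids,
      sex = sample(c("male", "female"), n, TRUE, c(0.58, 0.42)),
      age = round(rnorm(n, 45, 14)),
      bmi = round(rnorm(n, 21.2, 3.3), 1),
      family_history = sample(c("yes", "no"), n, TRUE, c(0.06, 0.94)),
      location = sample(c("left", "right"), n, TRUE, c(0.78, 0.22)),
      diagnosis = sample(
        c("adenocarcinoma", "mucinous"), n, TRUE, c(0.87, 0.13)
      ),
      tumor_cell_pct = round(rnorm(n, 72.1, 6.5), 1),
      lymph_node = sample(c("yes", "no"), n, TRUE, c(0.52, 0.48)),
      stage = sample(c("1", "2", "3"), n, TRUE, c(0.19, 0.29, 0.52)),
      grade = sample(c("low", "high"), n, TRUE, c(0.78, 0.22)),
      msi = sample(c("MSI", "MSS"), n, TRUE, c(0.28, 0.72))
    )
  }
  list(
    tumor = dplyr::bind_rows(purrr::map(pairs, "tumor")),
    normal = dplyr::bind_rows(purrr::map(pairs, "normal")),
    phenotypes = phenotypes,
    truth = events %||% empty_events()
  )
}
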
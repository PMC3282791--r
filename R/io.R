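# Marker tables follow the BeadStudio final-report-like layout: tab separated,
# '.' decimal, header required. Internal column names are snake_case; the
# header names below are used on disk.
.marker_header <- c(
  sample_id = "Sample ID", snp_name = "SNP Name", chrom = "Chr",
  pos = "Position", baf = "B Allele Freq", lrr = "Log R Ratio"
)

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read a per-marker SNP-array table
#'
#' Reads a tab-delimited marker file with header columns `Sample ID`,
#' `SNP Name`, `Chr`, `Position`, `B Allele Freq`, `Log R Ratio` (one or more
#' samples per file). Chromosome labels are accepted with or without a `chr`
#' prefix and normalized; non-autosomal rows (X, Y, MT, 0) are dropped with a
#' message. Validation is strict: missing columns, malformed numbers,
#' out-of-range BAF, duplicated or non-increasing positions within a sample's
#' chromosome are errors naming the offending marker, never silently coerced.
#'
#' @param path File path.
#' @return Tibble with columns `sample_id`, `snp_name`, `chrom` (character
#'   `"1"`..`"22"`), `pos` (1-based), `baf`, `lrr`, sorted by sample,
#'   chromosome, position.
#' @export
read_marker_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(unname(.marker_header), names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "Marker file ", path, " is missing column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  df <- raw[, unname(.marker_header)]
  names(df) <- names(.marker_header)
  for (col in c("pos", "baf", "lrr")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "Malformed number in column '%s' at line %d of %s ('%s').",
        .marker_header[[col]], bad[1] + 1, path, df[[col]][bad[1]]
      ))
    }
    df[[col]] <- num
  }
  df$chrom <- normalize_chrom(df$chrom)
  autosomal <- df$chrom %in% as.character(1:22)
  if (any(!autosomal)) {
    inform(sprintf(
      "Dropped %d non-autosomal marker row(s) from %s.",
      sum(!autosomal), path
    ))
    df <- df[autosomal, ]
  }
  if (any(df$baf < 0 | df$baf > 1, na.rm = TRUE)) {
    abort(sprintf("BAF outside [0, 1] in %s.", path))
  }
  # positions must already be strictly increasing within sample x chromosome:
  # readers reject rather than silently reorder
  bad <- df |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 & .data$pos <= dplyr::lag(.data$pos)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Positions not strictly increasing at %s:%s (sample %s) in %s.",
      bad$chrom[1], format(bad$pos[1], scientific = FALSE),
      bad$sample_id[1], path
    ))
  }
  tibble::as_tibble(df)
}

#' Write a per-marker table in the tab-delimited exchange format
#'
#' @param markers Marker tibble (`sample_id`, `snp_name`, `chrom`, `pos`,
#'   `baf`, `lrr`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  out <- markers[, names(.marker_header)]
  names(out) <- unname(.marker_header)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Comma-separated, one row per sample, header
#' `sample_id, sex, age, bmi, family_history, location, diagnosis,
#' tumor_cell_pct, lymph_node, stage, grade, msi`. Categorical levels are
#' validated against their closed sets.
#'
#' @param path File path.
#' @return Tibble, one row per sample.
#' @export
read_phenotype_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    age = readr::col_double(), bmi = readr::col_double(),
    tumor_cell_pct = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c(
    "sample_id", "sex", "age", "bmi", "family_history", "location",
    "diagnosis", "tumor_cell_pct", "lymph_node", "stage", "grade", "msi"
  )
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Phenotype file is missing column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(df$sample_id)) {
    abort("Phenotype file has duplicated sample ids.")
  }
  levels_ok <- list(
    location = c("left", "right"),
    diagnosis = c("adenocarcinoma", "mucinous"),
    stage = c("1", "2", "3"),
    grade = c("low", "high"),
    msi = c("MSI", "MSS")
  )
  for (v in names(levels_ok)) {
    bad <- setdiff(unique(df[[v]]), c(levels_ok[[v]], NA))
    if (length(bad) > 0) {
      abort(sprintf(
        "Invalid level '%s' in phenotype column '%s'.", bad[1], v
      ))
    }
  }
  df
}

#' Read a gene model from a BED file
#'
#' BED6 (or BED4): `chrom, start, end, name[, score, strand]`, 0-based
#' half-open as BED mandates; coordinates are converted to the package's
#' internal 1-based inclusive convention on read. Gene names must be unique.
#'
#' @param path File path.
#' @return Tibble: `gene`, `chrom`, `start`, `end` (1-based inclusive),
#'   `strand` (`"."` if absent).
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(
    path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand")[1:6],
    fill = TRUE
  )
  if (ncol(df) < 4) abort("Gene BED needs at least 4 columns.")
  if (any(df$end <= df$start)) {
    abort("Gene BED intervals must satisfy end > start (0-based half-open).")
  }
  if (anyDuplicated(df$name)) {
    abort("Gene symbols must be unique within the gene model.")
  }
  tibble::tibble(
    gene = df$name,
    chrom = normalize_chrom(df$chrom),
    start = df$start + 1, # to 1-based inclusive
    end = df$end,
    strand = if ("strand" %in% names(df)) {
      dplyr::coalesce(as.character(df$strand), ".")
    } else {
      "."
    }
  )
}

#' Read a gene-to-drug table
#'
#' Tab-separated with header `gene, drug, type, status, indication`. Drug
#' types and statuses are matched case-insensitively against their closed
#' sets (`antibody/antagonist/inhibitor/agonist/activator/inducer`;
#' `approved/trial_phase/discontinued/unknown`); an unrecognized value is an
#' error naming the line.
#'
#' @param path File path.
#' @return Tibble: `gene`, `drug`, `type`, `status`, `indication` (types and
#'   statuses lower-cased).
#' @export
read_drug_table <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("gene", "drug", "type", "status", "indication")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Drug table is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  df$type <- tolower(df$type)
  df$status <- tolower(df$status)
  bad <- which(!df$type %in% .cnm_drug_types)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown drug type '%s' at line %d of %s.",
      df$type[bad[1]], bad[1] + 1, path
    ))
  }
  bad <- which(!df$status %in% .cnm_drug_statuses)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown drug status '%s' at line %d of %s.",
      df$status[bad[1]], bad[1] + 1, path
    ))
  }
  df[, need]
}

#' Write intervals as a BED file
#'
#' Converts the package's internal 1-based inclusive intervals to BED's
#' 0-based half-open convention on output.
#'
#' @param df Tibble with `chrom`, `start`, `end` and optionally a `name`
#'   column (or `region_id`/`sample_id` used as name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name_col <- intersect(c("name", "region_id", "sample_id"), names(df))
  name <- if (length(name_col) > 0) df[[name_col[1]]] else "."
  if (nrow(df) == 0) name <- character(0)
  bed <- data.frame(
    chrom = df$chrom,
    start = format(df$start - 1, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = name
  )
  utils::write.table(
    bed, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write the full result set of a pipeline run
#'
#' Writes segments (TSV + BED companion), recurrent regions (TSV + BED),
#' association results (TSV), drug-match report (TSV) and a JSON run-metadata
#' file (package version, seed, parameters) into `outdir`. Components absent
#' from `results` produce headers-only files so downstream tooling always
#' finds the full set.
#'
#' @param results Named list with any of `segments`, `regions`,
#'   `associations`, `drug_matches` (tibbles).
#' @param outdir Output directory, created if needed.
#' @param seed,params Recorded in `run_metadata.json`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, outdir, seed = NA_integer_,
                          params = seg_params()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  segs <- results$segments %||% tibble::tibble(
    sample_id = character(), chrom = character(), start = double(),
    end = double(), n_markers = integer(), geo_mean_cn = double(),
    state = character(), n_het = integer(), band_d = double(),
    band_lower = double(), band_upper = double(), split_class = character(),
    mechanism = character(), p_aberrant = double(), fit_residual = double()
  )
  readr::write_tsv(
    dplyr::mutate(segs, split_class = as.character(.data$split_class)),
    p("segments.tsv"), progress = FALSE
  )
  write_bed(segs, p("segments.bed"))
  regions <- results$regions %||% tibble::tibble(
    chrom = character(), start = double(), end = double(),
    event = character(), n_support = integer(), cohort_size = integer(),
    support_frac = double()
  )
  readr::write_tsv(
    dplyr::select(regions, -dplyr::any_of("samples")) |>
      dplyr::mutate(
        region_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
        .before = 1
      ),
    p("regions.tsv"), progress = FALSE
  )
  write_bed(
    dplyr::mutate(regions, name = .data$event), p("regions.bed")
  )
  readr::write_tsv(
    results$associations %||% tibble::tibble(
      stratum = character(), region_id = character(), phenotype = character(),
      test = character(), n = integer(), n_abnormal = integer(),
      frac_abnormal = double(), statistic = double(), df = integer(),
      p_value = double(), p_bh = double(), testable = logical(),
      reportable = logical()
    ),
    p("associations.tsv"), progress = FALSE
  )
  readr::write_tsv(
    results$drug_matches %||% tibble::tibble(
      region_id = character(), event = character(), gene = character(),
      drug = character(), type = character(), status = character(),
      indication = character(), available = logical()
    ),
    p("drug_matches.tsv"), progress = FALSE
  )
  meta <- list(
    package = "cnmosaic",
    version = as.character(utils::packageVersion("cnmosaic")),
    seed = seed,
    params = unclass(params)
  )
  jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE)
  paths <- setNames(
    p(c("segments.tsv", "segments.bed", "regions.tsv", "regions.bed",
        "associations.tsv", "drug_matches.tsv", "run_metadata.json")),
    c("segments_tsv", "segments_bed", "regions_tsv", "regions_bed",
      "associations_tsv", "drug_matches_tsv", "metadata")
  )
  invisible(paths)
}

#' Write a simulated cohort to disk in the pipeline's exchange formats
#'
#' @param cohort List from [simulate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tumor = file.path(dir, "tumor_markers.tsv"),
    normal = file.path(dir, "normal_markers.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "truth_events.tsv")
  )
  write_marker_table(cohort$tumor, paths[["tumor"]])
  write_marker_table(cohort$normal, paths[["normal"]])
  readr::write_csv(cohort$phenotypes, paths[["phenotypes"]], progress = FALSE)
  readr::write_tsv(cohort$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
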
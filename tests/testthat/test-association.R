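test_that("chi-square reproduces the published contingency p-values", {
  # region-by-phenotype tables, no continuity correction
  cases <- list(
    list(tab = rbind(c(0, 13, 41), c(1, 0, 7)), p = 0.012300),   # diagnosis
    list(tab = rbind(c(5, 6), c(0, 16), c(1, 34)), p = 0.000053), # stage
    list(tab = rbind(c(0, 0, 10), c(7, 0, 9), c(1, 0, 34)), p = 0.000128),
    list(tab = rbind(c(9, 0, 18), c(2, 0, 33)), p = 0.004765),   # lymph node
    list(tab = rbind(c(1, 0, 20), c(0, 1, 2)), p = 0.025010)     # MSI stratum
  )
  for (cs in cases) {
    res <- chi_square(cs$tab, correction = "none")
    expect_true(res$testable)
    expect_equal(signif(res$p_value, 2), signif(cs$p, 2))
  }
  # 2x2 patient characteristic, Yates continuity correction
  loc <- chi_square(rbind(c(13, 54), c(11, 8)), correction = "yates")
  expect_equal(round(loc$p_value, 3), 0.003)
})

test_that("all-zero rows and columns are dropped before computing df", {
  res <- chi_square(rbind(c(0, 0, 10), c(7, 0, 9), c(1, 0, 34)))
  expect_equal(dim(res$observed), c(3L, 2L))
  expect_equal(res$df, 2L)
  # identical to testing the reduced table directly
  direct <- chi_square(rbind(c(0, 10), c(7, 9), c(1, 34)))
  expect_equal(res$p_value, direct$p_value)
})

test_that("chi-square p-values are invariant under table permutation", {
  tab <- rbind(c(9, 0, 18), c(2, 0, 33))
  base <- chi_square(tab)$p_value
  expect_equal(chi_square(tab[, c(3, 1, 2)])$p_value, base)
  expect_equal(chi_square(tab[c(2, 1), ])$p_value, base)
})

test_that("degenerate and proportional tables behave as specified", {
  # proportional rows: statistic 0, p 1
  res <- chi_square(rbind(c(10, 20), c(5, 10)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # reduces below 2x2: untestable, no p
  res <- chi_square(rbind(c(0, 0), c(5, 7)))
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
  expect_error(chi_square(rbind(c(1.5, 2), c(3, 4))), "integer")
  expect_error(
    chi_square(rbind(c(1, 2, 3), c(4, 5, 6)), correction = "yates"),
    "2x2"
  )
})

test_that("contingency objects expose tidy and glance views", {
  res <- chi_square(rbind(c(13, 54), c(11, 8)), "yates")
  gl <- glance(res)
  expect_equal(gl$df, 1L)
  expect_equal(gl$correction, "yates")
  td <- tidy(res)
  expect_equal(sum(td$observed), 86)
  expect_equal(sum(td$expected), 86, tolerance = 1e-9)
})

test_that("one-way ANOVA matches the published tumor-cell comparison", {
  # rebuild two groups with the exact summary statistics
  mk <- function(n, mean, sd) mean + sd * as.numeric(scale(seq_len(n)))
  vals <- c(mk(24, 74.6, 6.24), mk(62, 71.2, 6.48))
  groups <- rep(c("MSI", "MSS"), c(24, 62))
  res <- anova_oneway(vals, groups)
  expect_equal(signif(res$p_value, 1), 0.03)
  # two-group F equals the squared pooled t
  tt <- t.test(vals ~ groups, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("ANOVA handles identical, shifted and degenerate groups", {
  same <- rep(c(1, 2, 3), 3)
  res <- anova_oneway(same, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # one group shifted by 10 sd: overwhelming significance, checked against
  # a permutation oracle (p below the oracle's resolution)
  set.seed(51)
  vals <- c(rnorm(10), rnorm(10), rnorm(10, 10))
  groups <- rep(c("a", "b", "c"), each = 10)
  res <- anova_oneway(vals, groups)
  expect_lt(res$p_value, 1e-6)
  expect_equal(oracle_perm_anova(vals, groups, reps = 2000), 1 / 2001,
               tolerance = 1e-9)
  # zero variance everywhere with differing means: flagged degenerate, p = 0
  res <- anova_oneway(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), ">= 2")
})

test_that("the region state matrix reflects planted segment coverage", {
  regions <- tibble::tibble(chrom = "5", start = 1e7, end = 2e7)
  segments <- dplyr::bind_rows(
    # covers the whole region
    tibble::tibble(sample_id = "S1", chrom = "5", start = 9e6, end = 2.1e7,
                   state = "AMPLIFIED"),
    # covers 40% only: below the half-coverage rule
    tibble::tibble(sample_id = "S2", chrom = "5", start = 1e7, end = 1.4e7,
                   state = "AMPLIFIED"),
    # deletion covering 80%
    tibble::tibble(sample_id = "S3", chrom = "5", start = 1.2e7, end = 2.2e7,
                   state = "DELETED"),
    # short segment: dropped by the 500 kb filter
    tibble::tibble(sample_id = "S4", chrom = "5", start = 1e7, end = 1.04e7,
                   state = "AMPLIFIED")
  )
  states <- region_state_matrix(
    regions, segments, sample_ids = paste0("S", 1:5)
  )
  got <- setNames(states$cn_state, states$sample_id)
  expect_equal(unname(got[paste0("S", 1:5)]),
    c("Amplification", "Unchanged", "Deletion", "Unchanged", "Unchanged"))
  # unanalyzable sample excluded via the missing list
  states2 <- region_state_matrix(
    regions, segments, sample_ids = paste0("S", 1:5),
    missing_samples = tibble::tibble(
      region_id = states$region_id[1], sample_id = "S5"
    )
  )
  expect_true(is.na(states2$cn_state[states2$sample_id == "S5"]))
})

test_that("planted cohort-level state frequencies are recovered", {
  # 30% amplified / 70% unchanged planted truth
  regions <- tibble::tibble(chrom = "8", start = 1e6, end = 6e6)
  ids <- sprintf("S%02d", 1:20)
  segments <- dplyr::bind_rows(purrr::map(ids[1:6], \(id) {
    tibble::tibble(sample_id = id, chrom = "8", start = 1e6, end = 6e6,
                   state = "AMPLIFIED")
  }))
  states <- region_state_matrix(regions, segments, sample_ids = ids)
  expect_equal(
    as.vector(table(factor(states$cn_state,
      c("Amplification", "Deletion", "Unchanged")))),
    c(6L, 0L, 14L)
  )
})

test_that("association scan finds a planted location effect and stratifies", {
  set.seed(52)
  ids <- sprintf("S%02d", 1:30)
  phen <- tibble::tibble(
    sample_id = ids,
    location = rep(c("left", "right"), c(18, 12)),
    msi = rep("MSS", 30)
  )
  # amplification in 12 of 18 left, 0 of 12 right
  states <- tibble::tibble(
    region_id = "20:1-2", sample_id = ids,
    cn_state = c(rep("Amplification", 12), rep("Unchanged", 18))
  )
  res <- run_association(states, phen, stratify_by_msi = TRUE)
  expect_equal(unique(res$stratum), "MSS")
  expect_lt(res$p_value[res$phenotype == "location"], 0.01)
  expect_true(res$reportable[res$phenotype == "location"])
  # one-sample stratum is untestable
  tiny <- run_association(states[1, ], phen[1, ], stratify_by_msi = FALSE)
  expect_false(any(tiny$testable))
})

test_that("a planted odds-ratio-8 enrichment is detected in most replicates", {
  # left-sided samples amplified with odds 8:1 relative to right-sided;
  # power estimated by rerunning the association stage on fresh draws
  set.seed(53)
  n <- 80
  p_right <- 0.08
  p_left <- 8 * p_right / (1 + p_right * 7) # odds ratio 8
  hits <- replicate(100, {
    loc <- rep(c("left", "right"), each = n / 2)
    amp <- ifelse(loc == "left", rbinom(n, 1, p_left), rbinom(n, 1, p_right))
    states <- tibble::tibble(
      region_id = "r1", sample_id = as.character(seq_len(n)),
      cn_state = ifelse(amp == 1, "Amplification", "Unchanged")
    )
    phen <- tibble::tibble(
      sample_id = as.character(seq_len(n)), location = loc
    )
    res <- run_association(states, phen, stratify_by_msi = FALSE)
    isTRUE(res$p_value < 0.01)
  })
  expect_gte(mean(hits), 0.80)
})
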
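test_that("expected BAF and CN follow the admixture equation", {
  # 90% mono-allelic gain: 1/2.9
  expect_equal(expected_baf(1, 3, 0.9), 1 / 2.9, tolerance = 1e-12)
  expect_equal(expected_cn(3, 0.9), 2.9)
  # 80% mono-allelic loss: 0.2/1.2
  expect_equal(expected_baf(0, 1, 0.8), 0.2 / 1.2, tolerance = 1e-12)
  # zero admixture reduces to the normal heterozygote
  expect_equal(expected_baf(2, 4, 0), 0.5)
  expect_equal(expected_cn(4, 0), 2)
  # 30% bi-allelic gain
  expect_equal(expected_cn(4, 0.3), 2.6)
})

test_that("undefined BAF and invalid populations are rejected", {
  expect_error(
    expected_baf(0, 0, 1, b_normal = 0, n_normal = 0),
    "nullisomic"
  )
  expect_error(expected_baf(3, 2, 0.5), "0 <= b <= n")
  expect_error(expected_baf(1, 2, 1.2), "\\[0, 1\\]")
})

test_that("mirrored B-allele counts give complementary BAF", {
  for (n1 in 1:4) {
    for (b1 in 0:n1) {
      for (p in c(0.1, 0.45, 0.8)) {
        expect_equal(
          expected_baf(b1, n1, p) + expected_baf(n1 - b1, n1, p), 1,
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("CN and band separation are strictly monotone in the mosaic fraction", {
  p <- seq(0.05, 0.95, by = 0.05)
  del_cn <- expected_cn(1, p)
  del_sep <- abs(expected_baf(0, 1, p) - 0.5) * 2
  expect_true(all(diff(del_cn) < 0))
  expect_true(all(diff(del_sep) > 0))
  amp_cn <- expected_cn(3, p)
  expect_true(all(diff(amp_cn) > 0))
})

test_that("pure aneuploidy reproduces textbook trisomy and monosomy values", {
  expect_equal(expected_cn(3, 1), 3)
  expect_equal(expected_baf(1, 3, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(expected_baf(2, 3, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(expected_cn(1, 1), 1)
  expect_equal(expected_baf(0, 1, 1), 0)
  expect_equal(expected_baf(1, 1, 1), 1)
})

test_that("grid back-calculation recovers the worked mosaicism examples", {
  cases <- list(
    list(bands = c(0.34, 0.66), cn = 2.9, mech = "MONOALLELIC_AMP", p = 0.90),
    list(bands = 0.5, cn = 2.6, mech = "BIALLELIC_AMP", p = 0.30),
    list(bands = c(0.17, 0.83), cn = 1.2, mech = "MONOALLELIC_DEL", p = 0.80),
    list(bands = c(0.38, 0.62), cn = 2.65, mech = "MONOALLELIC_AMP", p = 0.65),
    list(bands = c(0.25, 0.75), cn = 2.0, mech = "CNLOH", p = 0.50)
  )
  for (cs in cases) {
    fit <- enumerate_mosaicism(cs$bands, cs$cn)
    expect_equal(fit$mechanism, cs$mech)
    expect_equal(fit$p_aberrant, cs$p, tolerance = 1e-9)
  }
})

test_that("an unsplit band at normal CN is NORMAL with undefined fraction", {
  fit <- enumerate_mosaicism(0.5, 2.0)
  expect_equal(fit$mechanism, "NORMAL")
  expect_true(is.na(fit$p_aberrant))
})

test_that("degenerate inputs to the grid are handled as specified", {
  expect_equal(enumerate_mosaicism(numeric(0), 2.0)$mechanism, "INDETERMINATE")
  expect_error(enumerate_mosaicism(0.5, 0), "\\(0, 4\\]")
  expect_error(enumerate_mosaicism(0.5, 5), "\\(0, 4\\]")
  # pre-folded single lower band accepted
  expect_equal(enumerate_mosaicism(0.17, 1.2)$p_aberrant, 0.8)
})

test_that("forward predictions invert to the generating karyotype (round trip)", {
  karyos <- list(c(1, 3), c(2, 3), c(2, 4), c(0, 1), c(0, 2), c(0, 3))
  for (k in karyos) {
    for (p in c(0.2, 0.35, 0.6, 0.85)) {
      baf <- expected_baf(k[1], k[2], p)
      cn <- expected_cn(k[2], p)
      truth_mech <- mechanism_of(k[1], k[2], p, observed_cn = cn)
      fit <- enumerate_mosaicism(sort(c(baf, 1 - baf)), cn)
      expect_equal(fit$mechanism, truth_mech,
        info = sprintf("karyotype (%d,%d) at P=%.2f", k[1], k[2], p)
      )
      expect_lte(abs(fit$p_aberrant - p), 0.01)
      # A/B label symmetry: the mirrored karyotype fits equally well
      cand <- tidy(fit)
      mirror <- cand[cand$b_aberrant == k[2] - k[1] & cand$n_aberrant == k[2], ]
      expect_equal(mirror$residual, fit$fit_residual, tolerance = 1e-9)
    }
  }
})

test_that("near-complete one-copy loss is labelled mosaic monosomy", {
  fit <- enumerate_mosaicism(c(0.01, 0.99), 1.02)
  expect_equal(fit$mechanism, "MOSAIC_MONOSOMY")
  # the 80% deletion at CN 1.2 stays a mono-allelic deletion
  expect_equal(enumerate_mosaicism(c(0.17, 0.83), 1.2)$mechanism,
               "MONOALLELIC_DEL")
})

test_that("qualitative CN/split interpretation matches its lookup", {
  expect_equal(table2_label("UNCHANGED", "NO_SPLIT"), "Normal")
  expect_equal(table2_label("AMPLIFIED", "NO_SPLIT"), "Bi-allelic amplification")
  expect_equal(table2_label("UNCHANGED", "MODERATE"), "cnLOH")
  expect_equal(table2_label("AMPLIFIED", "MODERATE"),
               "Mono-allelic Amplification")
  expect_equal(table2_label("DELETED", "LARGE"), "Mono-allelic deletion")
  expect_equal(table2_label("DELETED", "NO_SPLIT"), "Indeterminate")
  # vectorized
  expect_equal(
    table2_label(c("AMPLIFIED", "DELETED"), c("LARGE", "MODERATE")),
    c("Mono-allelic amplification superimposed on cnLOH",
      "Mono-allelic deletion in small proportion of cells")
  )
})

test_that("mosaicism fits expose tidy and glance views", {
  fit <- enumerate_mosaicism(c(0.34, 0.66), 2.9)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(diff(round(td$residual, 10)) >= 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mechanism, "MONOALLELIC_AMP")
  expect_equal(gl$band_upper, 0.66)
})
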
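make_track <- function(n, chrom = "1", sample_id = "S1", lrr = 0, baf = 0.5) {
  tibble::tibble(
    sample_id = sample_id,
    snp_name = sprintf("SNP_%s_%06d", chrom, seq_len(n)),
    chrom = chrom,
    pos = seq_len(n) * 1000,
    baf = rep_len(baf, n),
    lrr = rep_len(lrr, n)
  )
}

test_that("paired copy number is the doubled intensity ratio", {
  tum <- make_track(4, lrr = c(0, log2(1.3), -1, 0.5))
  nor <- make_track(4, lrr = c(0, 0, 0, 0.5))
  cn <- paired_cn(tum, nor)$cn
  expect_equal(cn, c(2, 2.6, 1, 2))
})

test_that("discordant marker maps are rejected with the first offender", {
  tum <- make_track(5)
  nor <- make_track(5)
  nor$snp_name[3] <- "SNP_OTHER"
  expect_error(paired_cn(tum, nor), "marker 3")
  expect_error(paired_cn(tum, make_track(4)), "marker count")
  expect_error(paired_cn(dplyr::select(tum, -"baf"), nor), "missing column")
})

test_that("a constant track is a single segment", {
  expect_equal(nrow(segment_track(rep(2, 300))), 1)
  set.seed(21)
  segs <- segment_track(2 * 2^rnorm(300, 0, 0.15))
  expect_equal(nrow(segs), 1)
})

test_that("a two-level track splits where the exhaustive scan says", {
  set.seed(22)
  cn <- c(2 * 2^rnorm(200, 0, 0.15), 3 * 2^rnorm(200, 0, 0.15))
  segs <- segment_track(cn, seg_params(min_markers = 25))
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$end_idx[1] - 200), 5)
  k_oracle <- oracle_single_split(log2(cn), 25)
  expect_contains(segs$end_idx, k_oracle)
})

test_that("a three-step track is recovered with accurate middle level", {
  set.seed(23)
  cn <- c(
    2.0 * 2^rnorm(150, 0, 0.15),
    1.2 * 2^rnorm(150, 0, 0.15),
    2.0 * 2^rnorm(150, 0, 0.15)
  )
  segs <- segment_track(cn, seg_params(min_markers = 25))
  expect_equal(nrow(segs), 3)
  expect_lte(abs(segs$end_idx[1] - 150), 5)
  expect_lte(abs(segs$end_idx[2] - 300), 5)
  expect_gte(segs$geo_mean_cn[2], 1.1)
  expect_lte(segs$geo_mean_cn[2], 1.3)
  expect_equal(
    call_state(segs$geo_mean_cn, seg_params()),
    c("NEUTRAL", "DELETED", "NEUTRAL")
  )
})

test_that("noise-free piecewise-constant breakpoints are exact", {
  cn <- rep(c(2, 3), each = 100)
  segs <- segment_track(cn, seg_params(min_markers = 10))
  expect_equal(segs$end_idx, c(100, 200))
  expect_equal(segs$geo_mean_cn, c(2, 3))
})

test_that("segments tile the chromosome and every split re-tests significant", {
  set.seed(24)
  cn <- c(2 * 2^rnorm(120, 0, 0.1), 2.8 * 2^rnorm(90, 0, 0.1),
          1.4 * 2^rnorm(150, 0, 0.1))
  params <- seg_params(min_markers = 25)
  segs <- segment_track(cn, params)
  # tiling: no gaps, no overlap
  expect_equal(segs$start_idx[1], 1)
  expect_equal(segs$end_idx[nrow(segs)], length(cn))
  if (nrow(segs) > 1) {
    expect_equal(segs$start_idx[-1], segs$end_idx[-nrow(segs)] + 1)
    # adjacent segments differ significantly on the final segmentation
    for (i in seq_len(nrow(segs) - 1)) {
      tt <- t.test(
        log2(cn[segs$start_idx[i]:segs$end_idx[i]]),
        log2(cn[segs$start_idx[i + 1]:segs$end_idx[i + 1]])
      )
      expect_lt(tt$p.value, params$p_threshold)
    }
  }
})

test_that("segment means are geometric and order-invariant", {
  set.seed(25)
  cn <- 2 * 2^rnorm(80, 0, 0.2)
  seg <- segment_track(cn, seg_params(min_markers = 25))
  expect_equal(seg$geo_mean_cn, exp(mean(log(cn))))
  expect_equal(
    segment_track(sample(cn), seg_params(min_markers = 25))$geo_mean_cn,
    seg$geo_mean_cn
  )
  expect_error(segment_track(c(2, 2, NA, 2)), "index 3")
  expect_error(segment_track(c(2, 2, -1, 2)), "index 3")
})

test_that("state calls honor the thresholds and the conservative neutral band", {
  p <- seg_params()
  expect_equal(call_state(2.9, p), "AMPLIFIED")
  expect_equal(call_state(2.5, p), "AMPLIFIED")
  expect_equal(call_state(1.5, p), "DELETED")
  expect_equal(call_state(2.0, p), "NEUTRAL")
  expect_equal(
    call_state(c(2.3, 1.7), p), c("INDETERMINATE", "INDETERMINATE")
  )
})

test_that("short segments are filtered at the 500 kb boundary", {
  segs <- tibble::tibble(
    chrom = "1",
    start = c(1e6, 1e6, 1e6),
    end = c(1e6 + 499998, 1e6 + 499999, 1e6 + 700000)
  )
  kept <- filter_segments(segs, seg_params())
  expect_equal(kept$end, c(1e6 + 499999, 1e6 + 700000)) # 500,000 bp retained
  expect_equal(nrow(filter_segments(segs[0, ], seg_params())), 0)
})

test_that("the per-sample pipeline classifies a mid-chromosome deletion", {
  cfg <- demo_config(markers = 900, seed = 31)
  ev <- sim_event("S1", "1", 3e7, 7e7, 0, 1, 0.8)
  pr <- simulate_pair(cfg, ev, "S1")
  segs <- call_segments(pr$tumor, pr$normal, seg_params(min_markers = 10))
  del <- segs[segs$state == "DELETED", ]
  expect_equal(nrow(del), 1)
  expect_lte(abs(del$start - 3e7), 5e5)
  expect_lte(abs(del$end - 7e7), 5e5)
  expect_equal(del$mechanism, "MONOALLELIC_DEL")
  expect_gte(del$p_aberrant, 0.75)
  expect_lte(del$p_aberrant, 0.85)
  expect_equal(as.character(del$split_class), "LARGE")
})
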
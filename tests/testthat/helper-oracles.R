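# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive computation (exhaustive scan, per-base counting,
# permutation) kept free of the package's own code paths.

# Maximum-likelihood split deviation of a symmetric two-component normal
# mixture about 0.5, by exhaustive 1-D scan in 0.001 steps.
oracle_scan_d <- function(bafs, sd) {
  ds <- seq(0, 0.5, by = 0.001)
  ll <- vapply(ds, function(d) {
    sum(log(0.5 * dnorm(bafs, 0.5 - d, sd) + 0.5 * dnorm(bafs, 0.5 + d, sd)))
  }, numeric(1))
  ds[which.max(ll)]
}

# Best single split of a numeric track by exhaustive scan, scoring each
# admissible cut with stats::t.test (Welch).
oracle_single_split <- function(x, min_markers) {
  ks <- seq(min_markers, length(x) - min_markers)
  tt <- vapply(ks, function(k) {
    abs(unname(t.test(x[1:k], x[(k + 1):length(x)])$statistic))
  }, numeric(1))
  ks[which.max(tt)]
}

# Recurrent intervals by brute-force per-base counting on a 1 kb grid.
# Returns a data frame of grid runs with support >= threshold.
oracle_region_grid <- function(segs, threshold, step = 1000) {
  out <- lapply(split(segs, segs$chrom), function(df) {
    grid <- seq(min(df$start), max(df$end), by = step)
    n <- vapply(grid, function(p) {
      length(unique(df$sample_id[df$start <= p & df$end >= p]))
    }, integer(1))
    hit <- n >= threshold
    if (!any(hit)) return(NULL)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(
      chrom = df$chrom[1],
      start = grid[starts[r$values]],
      end = grid[ends[r$values]]
    )
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# One-way ANOVA p-value by permutation of group labels.
oracle_perm_anova <- function(values, groups, reps = 1e4, seed = 1) {
  f_of <- function(g) {
    m <- tapply(values, g, mean)
    n <- tapply(values, g, length)
    k <- length(m)
    ssb <- sum(n * (m - mean(values))^2)
    ssw <- sum((values - ave(values, g))^2)
    (ssb / (k - 1)) / (ssw / (length(values) - k))
  }
  obs <- f_of(groups)
  set.seed(seed)
  exceed <- sum(replicate(reps, f_of(sample(groups)) >= obs))
  (exceed + 1) / (reps + 1)
}

# Deterministic small tumor/normal scenario shared across tests.
demo_config <- function(markers = 500, seed = 7, chroms = c("1" = 1e8)) {
  sim_config(
    n_samples = 1, chrom_lengths = chroms,
    markers_per_chrom = markers, seed = seed
  )
}
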
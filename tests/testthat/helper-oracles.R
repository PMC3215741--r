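# Shared fixtures and independent brute-force oracles.

# tiny regular probe map without jitter
tiny_map <- function(chroms = c(chr1 = 1e6), spacing = 1000,
                     snp_fraction = 0.5, seed = 1) {
  build_probe_map(chroms, spacing = spacing, snp_fraction = snp_fraction,
                  jitter = 0, seed = seed)
}

# plain ratio series data.frame from a numeric vector
series_from_values <- function(x, chrom = "chr1", spacing = 1000) {
  data.frame(probe_id = sprintf("p%05d", seq_along(x)), chrom = chrom,
             pos = spacing * seq_along(x), value = x,
             stringsAsFactors = FALSE)
}

# brute-force first split: leftmost argmax of the pooled-variance t
# statistic over all admissible cuts, computed with t.test()
brute_first_split <- function(x, min_markers) {
  n <- length(x)
  cuts <- min_markers:(n - min_markers)
  tt <- vapply(cuts, function(i) {
    a <- x[1:i]; b <- x[(i + 1):n]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) 0 else Inf
    } else {
      abs(unname(stats::t.test(a, b, var.equal = TRUE)$statistic))
    }
  }, numeric(1))
  cuts[which.max(tt)]
}

# per-base brute force: distinct-sample coverage count at every integer
# position of one chromosome (positions 1..limit)
brute_base_counts <- function(start, end, sample_id, limit) {
  vapply(seq_len(limit), function(pos) {
    length(unique(sample_id[start <= pos & pos < end]))
  }, integer(1))
}

# brute-force MAR on one chromosome: per-base counting, maximal
# constant-count runs with count > threshold, ranked by count desc then
# length desc then start
brute_mar <- function(start, end, sample_id, cohort_size,
                      min_fraction = 0.5, limit = max(end)) {
  cnt <- brute_base_counts(start, end, sample_id, limit)
  thr <- cohort_size * min_fraction
  runs <- rle(cnt)
  stops <- cumsum(runs$lengths)
  starts <- c(1, utils::head(stops, -1) + 1)
  keep <- runs$values > thr
  if (!any(keep)) return(NULL)
  df <- data.frame(start = starts[keep], end = stops[keep] + 1,
                   count = runs$values[keep])
  df$length <- df$end - df$start
  df[order(-df$count, -df$length, df$start), , drop = FALSE]
}

# hypergeometric upper-tail P(X >= k) by exhaustive enumeration
brute_hyper <- function(k, n_a, n_b, universe) {
  js <- k:min(n_a, n_b)
  sum(choose(n_a, js) * choose(universe - n_a, n_b - js)) /
    choose(universe, n_b)
}

# zero-noise cohort with explicit per-sample truth (all probes SNP so
# every lesion has ample informative heterozygous SNPs)
zero_noise_cohort <- function(truths, chroms = c(chr1 = 5e6, chr2 = 5e6),
                              seed = 11) {
  map <- build_probe_map(chroms, spacing = 1000, snp_fraction = 1,
                         jitter = 0, seed = seed)
  nm <- noise_model(lrr_sd = 0, baf_sd = 0, het_fraction = 0.3)
  samples <- lapply(seq_along(truths), function(i) {
    set.seed(seed + i)
    simulate_sample(map, truths[[i]], nm)
  })
  names(samples) <- sprintf("Z%02d", seq_along(truths))
  list(map = map, samples = samples, truths = truths)
}
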
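# Cohort recurrence: densities, cytobands, known/novel annotation,
# recurrence profiles, MAR discovery, overlap significance.

test_that("chromosome densities normalize by Mb and the chi-square test behaves", {
  les <- data.frame(sample_id = "S1",
                    chrom = rep(c("chrA", "chrB"), c(10, 5)),
                    start = 1, end = 1000, stringsAsFactors = FALSE)
  d <- chromosome_density(les, c(chrA = 1e8, chrB = 5e7))
  expect_equal(d$table$density, c(0.1, 0.1))
  expect_equal(d$p_value, 1)          # exactly proportional counts
  expect_equal(sum(d$table$count), nrow(les))

  skew <- data.frame(sample_id = "S1", chrom = rep("chrA", 20),
                     start = 1, end = 1000, stringsAsFactors = FALSE)
  ds <- chromosome_density(skew, c(chrA = 1e8, chrB = 1e8))
  expect_equal(ds$statistic, 20)
  expect_equal(ds$df, 1)
  expect_equal(ds$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_lt(ds$p_value, 0.001)

  single <- chromosome_density(skew, c(chrA = 1e8))
  expect_equal(single$df, 0)
  expect_true(is.na(single$p_value))

  expect_error(chromosome_density(les, c(chrA = 1e8)), "coordinate error")
})

test_that("cytoband mapping returns every band with >= 1 bp overlap in order", {
  cb <- synthetic_cytobands(c(chr1 = 4e6), n_bands = 4)  # 1 Mb bands
  expect_equal(map_to_cytobands("chr1", 1.2e6, 1.4e6, cb), "1p11")
  expect_equal(map_to_cytobands("chr1", 9e5, 1.1e6, cb),
               c("1p12", "1p11"))
  expect_error(map_to_cytobands("chr1", 100, 100, cb), "zero or negative")
  expect_error(map_to_cytobands("chr9", 1, 10, cb), "coordinate error")
})

test_that("known/novel annotation uses covered fraction with an exact partition", {
  les <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(1000, 50000, 100000),
                    end = c(2000, 60000, 104000),
                    stringsAsFactors = FALSE)
  db <- data.frame(chrom = "chr1", start = c(500, 102000),
                   end = c(5000, 103000))
  ann <- annotate_known(les, db)
  expect_equal(ann$known, c(TRUE, FALSE, FALSE))
  expect_equal(ann$known_fraction, c(1, 0, 0.25))

  expect_warning(empty <- annotate_known(les, db[0, ]), "empty")
  expect_true(all(!empty$known))

  s <- summarize_known_novel(c(rep(TRUE, 1773), rep(FALSE, 992)))
  expect_equal(s$pct_known, 64)
  expect_equal(s$pct_novel, 36)
  expect_equal(s$pct_known_exact + s$pct_novel_exact, 100)
})

test_that("recurrence profiles count distinct samples per unit", {
  les <- data.frame(sample_id = sprintf("S%02d", 1:10), chrom = "chr1",
                    start = 1000, end = 2000, stringsAsFactors = FALSE)
  rp <- recurrence_profile(les, 10, unit = "interval")
  expect_equal(nrow(rp$profile), 1)
  expect_equal(rp$profile$count, 10)
  expect_equal(rp$profile$freq_pct, 100)
  expect_equal(unname(rp$histogram["10"]), 1L)

  priv <- data.frame(sample_id = sprintf("S%02d", 1:5), chrom = "chr1",
                     start = seq(1000, 9000, 2000),
                     end = seq(2000, 10000, 2000),
                     stringsAsFactors = FALSE)
  rp2 <- recurrence_profile(priv, 5, unit = "interval")
  expect_true(all(rp2$profile$count == 1))
  expect_equal(unname(rp2$histogram["1"]), 5L)

  # a sample with two lesions on one band still counts once
  cb <- synthetic_cytobands(c(chr1 = 4e6), n_bands = 4)
  dup <- data.frame(sample_id = c("S1", "S1", "S2"), chrom = "chr1",
                    start = c(1000, 5000, 2000), end = c(2000, 6000, 3000),
                    stringsAsFactors = FALSE)
  rp3 <- recurrence_profile(dup, 2, unit = "cytoband", cytobands = cb)
  expect_equal(rp3$profile$count[rp3$profile$unit == "1p12"], 2L)
})

test_that("interval-unit coverage equals per-base brute force on the worked example", {
  les <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                    start = c(100, 150, 250), end = c(200, 300, 400),
                    stringsAsFactors = FALSE)
  rp <- recurrence_profile(les, 3, unit = "interval")
  two <- rp$profile[rp$profile$count == 2, ]
  expect_equal(two$start, c(150, 250))
  expect_equal(two$end, c(200, 300))
  base <- brute_base_counts(les$start, les$end, les$sample_id, 500)
  for (i in seq_len(nrow(rp$profile))) {
    r <- rp$profile[i, ]
    expect_true(all(base[r$start:(r$end - 1)] == r$count))
  }
  expect_equal(sum(base > 0),
               sum(rp$profile$end - rp$profile$start))
})

test_that("define_mar reproduces the worked coverage examples", {
  # 11 identical carrier intervals among 20 samples
  printed <- data.frame(sample_id = sprintf("P%02d", 1:11), chrom = "20",
                        start = 1572019, end = 1581930,
                        cn_estimate = 4.1, category = "AMP_NO_LOH",
                        stringsAsFactors = FALSE)
  res <- define_mar(printed, 20)
  expect_equal(res$mar$start, 1572019)
  expect_equal(res$mar$end, 1581930)
  expect_equal(res$mar$length, 9911)
  expect_equal(res$mar$frequency, 0.55)
  expect_equal(res$mar$mean_cn, 4.1)

  # stacked intervals: max count 3 on [80, 100)
  stack <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                      start = c(1, 50, 80), end = c(100, 150, 200),
                      stringsAsFactors = FALSE)
  m <- define_mar(stack, 3, min_fraction = 0.5)
  expect_equal(m$mar$start, 80)
  expect_equal(m$mar$end, 100)
  expect_equal(m$mar$n_affected, 3)

  # single-sample cohort: the lesion is its own MAR
  solo <- data.frame(sample_id = "A", chrom = "chr1", start = 10,
                     end = 110, stringsAsFactors = FALSE)
  ms <- define_mar(solo, 1)
  expect_equal(ms$mar$start, 10)
  expect_equal(ms$mar$end, 110)
  expect_equal(ms$mar$frequency, 1)

  # no majority anywhere: empty result with explanatory status
  spread <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                       start = c(1, 200, 400), end = c(100, 300, 500),
                       stringsAsFactors = FALSE)
  none <- define_mar(spread, 3)
  expect_null(none$mar)
  expect_equal(none$status, "no majority region")
})

test_that("sweep-line MAR equals per-base brute force on random mini-cohorts", {
  set.seed(31)
  for (rep in 1:30) {
    n_samples <- sample(2:10, 1)
    n_les <- sample(3:12, 1)
    sid <- sample(sprintf("S%d", 1:n_samples), n_les, replace = TRUE)
    start <- sample(1:9000, n_les, replace = TRUE)
    len <- sample(1:1000, n_les, replace = TRUE)
    les <- data.frame(sample_id = sid, chrom = "c1", start = start,
                      end = start + len, stringsAsFactors = FALSE)
    got <- define_mar(les, n_samples, min_fraction = 0.5)
    want <- brute_mar(les$start, les$end, les$sample_id, n_samples,
                      0.5, limit = 10001)
    if (is.null(want)) {
      expect_null(got$mar)
    } else {
      expect_equal(got$mar$start, want$start[1])
      expect_equal(got$mar$end, want$end[1])
      expect_equal(got$mar$n_affected, want$count[1])
      # full candidate sets agree too
      expect_equal(nrow(got$candidates), nrow(want))
    }
  }
})

test_that("recurrence and MAR are invariant under sample relabeling", {
  set.seed(37)
  les <- data.frame(sample_id = sample(sprintf("S%d", 1:6), 15,
                                       replace = TRUE),
                    chrom = "chr1", start = sample(1:5000, 15),
                    stringsAsFactors = FALSE)
  les$end <- les$start + sample(100:800, 15)
  perm <- setNames(sample(sprintf("S%d", 1:6)), sprintf("S%d", 1:6))
  les2 <- les
  les2$sample_id <- unname(perm[les$sample_id])
  m1 <- define_mar(les, 6)
  m2 <- define_mar(les2, 6)
  expect_equal(m1$mar, m2$mar)
  r1 <- recurrence_profile(les, 6, unit = "interval")
  r2 <- recurrence_profile(les2, 6, unit = "interval")
  expect_equal(r1$profile, r2$profile)
  expect_equal(r1$histogram, r2$histogram)
})

test_that("hypergeometric overlap test matches enumeration and the edge cases", {
  res <- overlap_significance(sprintf("b%03d", 1:744),
                              sprintf("b%03d", 418:836), 862)
  expect_equal(res$n_overlap, 327)
  expect_equal(res$pct, 44)
  expect_equal(res$pct_exact, 100 * 327 / 744, tolerance = 1e-12)

  disj <- overlap_significance(c("a", "b"), c("c", "d"), 100)
  expect_equal(disj$pct, 0)
  expect_equal(disj$p_value, 1)

  all_bands <- sprintf("u%d", 1:20)
  degen <- overlap_significance(all_bands, all_bands, 20)
  expect_equal(degen$pct, 100)
  expect_equal(degen$p_value, 1)

  small <- overlap_significance(sprintf("x%d", 1:5),
                                c("x1", "x2", "x3", "y1", "y2"), 20)
  expect_equal(small$p_value, brute_hyper(3, 5, 5, 20), tolerance = 1e-12)

  expect_error(overlap_significance(sprintf("a%d", 1:10),
                                    sprintf("b%d", 1:10), 15),
               "invalid universe")
})
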
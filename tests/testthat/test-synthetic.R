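# Synthetic cohort generator: probe maps, signal model, cohort
# bookkeeping, reproducibility.

test_that("probe map respects spacing, per-chromosome counts and SNP fraction", {
  map <- build_probe_map(c(chr1 = 1e7), spacing = 1000, jitter = 0,
                         seed = 1)
  expect_equal(nrow(map$probes), 10000)
  expect_true(all(diff(map$probes$pos) > 0))

  all_snp <- build_probe_map(c(chr1 = 1e6), spacing = 1000,
                             snp_fraction = 1, seed = 1)
  expect_true(all(all_snp$probes$kind == "SNP"))
  no_snp <- build_probe_map(c(chr1 = 1e6), spacing = 1000,
                            snp_fraction = 0, seed = 1)
  expect_true(all(no_snp$probes$kind == "CN"))

  two <- build_probe_map(c(chrA = 5e6, chrB = 5e6), spacing = 1000,
                         jitter = 0, seed = 1)
  expect_equal(unname(table(two$probes$chrom)[c("chrA", "chrB")]),
               c(5000L, 5000L), ignore_attr = TRUE)

  expect_error(build_probe_map(c(chr1 = 1e6), spacing = 0),
               "invalid specification")
  expect_error(build_probe_map(c(chr1 = 500), spacing = 1000),
               "invalid specification")
})

test_that("jittered probe positions stay strictly increasing", {
  map <- build_probe_map(c(chr1 = 2e6), spacing = 1000, jitter = 400,
                         seed = 3)
  expect_true(all(diff(map$probes$pos) > 0))
  expect_true(max(abs(map$probes$pos - (seq_len(2000) - 0.5) * 1000))
              <= 400)
})

test_that("zero-noise samples follow the LRR/BAF signal model", {
  map <- tiny_map(snp_fraction = 1)
  nm <- noise_model(0, 0, 0.3)

  set.seed(5)
  null <- simulate_sample(map, NULL, nm)
  expect_true(all(null$tumor$lrr == 0))
  expect_true(all(null$tumor$baf %in% c(0, 0.5, 1)))
  expect_true(all(null$normal$lrr == 0))

  truth <- data.frame(chrom = "chr1", start = 2e5, end = 3e5, cn = 4,
                      loh = FALSE)
  set.seed(5)
  amp <- simulate_sample(map, truth, nm)
  inles <- amp$tumor$pos >= 2e5 & amp$tumor$pos < 3e5
  expect_true(all(amp$tumor$lrr[inles] == 1))   # log2(4/2)
  expect_true(all(amp$tumor$lrr[!inles] == 0))

  aupd <- data.frame(chrom = "chr1", start = 2e5, end = 3e5, cn = 2,
                     loh = TRUE)
  set.seed(5)
  cnloh <- simulate_sample(map, aupd, nm)
  inles <- cnloh$tumor$pos >= 2e5 & cnloh$tumor$pos < 3e5
  expect_true(all(cnloh$tumor$lrr[inles] == 0))  # copy-neutral
  het <- cnloh$normal$genotype == "AB"
  expect_true(all(cnloh$tumor$baf[inles & het] %in% c(0, 1)))
  expect_true(all(cnloh$tumor$baf[!inles & het] == 0.5))

  hom_del <- data.frame(chrom = "chr1", start = 2e5, end = 3e5, cn = 0,
                        loh = TRUE)
  set.seed(5)
  del0 <- simulate_sample(map, hom_del, nm)
  inles <- del0$tumor$pos >= 2e5 & del0$tumor$pos < 3e5
  expect_true(all(del0$tumor$lrr[inles] == -5))  # CN = 0 floor
})

test_that("purity dilutes the expected LRR as log2((p*CN + (1-p)*2)/2)", {
  map <- tiny_map(snp_fraction = 0)
  truth <- data.frame(chrom = "chr1", start = 2e5, end = 3e5, cn = 4,
                      loh = FALSE)
  set.seed(5)
  s <- simulate_sample(map, truth, noise_model(0, 0, 0.3), purity = 0.5)
  inles <- s$tumor$pos >= 2e5 & s$tumor$pos < 3e5
  expect_equal(unique(s$tumor$lrr[inles]), log2((0.5 * 4 + 0.5 * 2) / 2))
})

test_that("inconsistent or overlapping truth lesions are rejected", {
  map <- tiny_map()
  bad_cn2 <- data.frame(chrom = "chr1", start = 1e5, end = 2e5, cn = 2,
                        loh = FALSE)
  expect_error(simulate_sample(map, bad_cn2), "aUPD")
  bad_cn1 <- data.frame(chrom = "chr1", start = 1e5, end = 2e5, cn = 1,
                        loh = FALSE)
  expect_error(simulate_sample(map, bad_cn1), "implies LOH")
  overlap <- data.frame(chrom = "chr1", start = c(1e5, 1.5e5),
                        end = c(2e5, 2.5e5), cn = c(4, 1),
                        loh = c(FALSE, TRUE))
  expect_error(simulate_sample(map, overlap), "overlapping")
  outside <- data.frame(chrom = "chr9", start = 1e5, end = 2e5, cn = 4,
                        loh = FALSE)
  expect_error(simulate_sample(map, outside), "not in probe map")
})

test_that("in-lesion LRR mean converges to log2(CN/2) under noise", {
  map <- tiny_map(chroms = c(chr1 = 2e6), snp_fraction = 0)
  truth <- data.frame(chrom = "chr1", start = 1, end = 2e6 + 1, cn = 4,
                      loh = FALSE)
  sdv <- 0.2
  set.seed(9)
  s <- simulate_sample(map, truth, noise_model(sdv, 0.03, 0.3),
                       matched_normal = FALSE)
  n <- nrow(s$tumor)
  expect_lt(abs(mean(s$tumor$lrr) - 1), 3 * sdv / sqrt(n))
})

test_that("cohort carrier bookkeeping is exact and seed-reproducible", {
  map <- tiny_map(chroms = c(chr1 = 2e6), spacing = 2000)
  shared <- data.frame(chrom = "chr1", start = 5e5, end = 6e5, cn = 4,
                       loh = FALSE)
  co <- simulate_cohort(map, 20, shared, carrier_fraction = 0.55,
                        private_lesion_rate = 0, seed = 3)
  expect_length(co$carriers, 11)  # round(0.55 * 20)
  tab <- co$truth[co$truth$start == 5e5 & co$truth$end == 6e5, ]
  expect_setequal(tab$sample_id, co$carriers)

  none <- simulate_cohort(map, 10, shared, carrier_fraction = 0,
                          private_lesion_rate = 0, seed = 3)
  expect_length(none$carriers, 0)
  expect_equal(nrow(none$truth), 0)

  # byte-identical regeneration under the same seed
  co2 <- simulate_cohort(map, 20, shared, carrier_fraction = 0.55,
                         private_lesion_rate = 0, seed = 3)
  expect_identical(co, co2)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(co, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("private lesions respect the per-sample count and stay disjoint", {
  map <- tiny_map(chroms = c(chr1 = 5e6, chr2 = 5e6))
  co <- simulate_cohort(map, 5, NULL, private_lesion_rate = 4, seed = 4)
  counts <- table(co$truth$sample_id)
  expect_true(all(counts == 4))
  for (sid in unique(co$truth$sample_id)) {
    tr <- co$truth[co$truth$sample_id == sid, ]
    for (cn in unique(tr$chrom)) {
      tc <- tr[tr$chrom == cn, ]
      tc <- tc[order(tc$start), ]
      if (nrow(tc) > 1) {
        expect_true(all(tc$start[-1] >= tc$end[-nrow(tc)]))
      }
    }
  }
})

test_that("synthetic cytobands tile each chromosome", {
  cb <- synthetic_cytobands(c(chr1 = 1e6, chr2 = 2e6), n_bands = 4)
  for (cn in c("chr1", "chr2")) {
    b <- cb[cb$chrom == cn, ]
    expect_equal(b$start[-1], b$end[-nrow(b)])  # contiguous tiling
    expect_equal(b$start[1], 1)
  }
  expect_true("1p11" %in% cb$full_name)
})
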
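# Copy-number state, LOH calling, five-state classification, filters,
# aUPD detection.

test_that("cn state and estimate follow cn = 2 * 2^mean_lrr", {
  res <- call_cn_state(c(1, 0, -1, 0.585, -0.2, 0.15))
  expect_equal(res$cn_state,
               c("gain", "neutral", "loss", "gain", "loss", "gain"))
  expect_equal(res$cn_estimate, c(4, 2, 1, 3, 1.7, 2.2))
  expect_error(call_cn_state(0, gain_threshold = -0.1), "gain_threshold")
})

test_that("five-state mapping is total over all six (state, loh) pairs", {
  states <- rep(c("gain", "neutral", "loss"), each = 2)
  lohs <- rep(c(TRUE, FALSE), 3)
  expect_equal(classify_five_state(states, lohs),
               c("AMP_LOH", "AMP_NO_LOH", "AUPD", "NEUTRAL",
                 "DEL_LOH", "DEL_NO_LOH"))
  expect_error(classify_five_state("weird", TRUE))
})

make_loh_fixture <- function(n_het, tumor_baf_het, n_hom = 40) {
  n <- n_het + n_hom
  pos <- seq_len(n) * 1000
  geno <- c(rep("AB", n_het), rep(c("AA", "BB"), length.out = n_hom))
  tumor <- data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                      chrom = "chr1", pos = pos, lrr = 0,
                      baf = c(tumor_baf_het,
                              rep(c(0, 1), length.out = n_hom)),
                      genotype = NA_character_, stringsAsFactors = FALSE)
  normal <- tumor
  normal$baf <- c(rep(0.5, n_het), rep(c(0, 1), length.out = n_hom))
  normal$genotype <- geno
  tumor$genotype <- ifelse(tumor$baf <= 0.25, "AA",
                           ifelse(tumor$baf >= 0.75, "BB", "AB"))
  seg <- data.frame(chrom = "chr1", start = 1, end = max(pos) + 1,
                    n_markers = n, mean_lrr = 0)
  list(seg = seg, tumor = tumor, normal = normal)
}

test_that("LOH calls depend on informative-SNP retention", {
  full <- make_loh_fixture(50, rep(c(0, 1), 25))
  res <- call_loh(full$seg, full$tumor, full$normal)
  expect_true(res$loh)
  expect_equal(res$n_informative, 50)
  expect_equal(res$hom_fraction, 1)

  ret <- make_loh_fixture(50, rep(0.5, 50))
  expect_false(call_loh(ret$seg, ret$tumor, ret$normal)$loh)

  few <- make_loh_fixture(9, rep(0, 9))
  r <- call_loh(few$seg, few$tumor, few$normal)
  expect_false(r$loh)
  expect_equal(r$loh_status, "uninformative")

  # just below the homozygous fraction threshold
  mixed <- make_loh_fixture(20, c(rep(0, 17), rep(0.5, 3)))
  expect_false(call_loh(mixed$seg, mixed$tumor, mixed$normal)$loh)
})

test_that("baseline-mode LOH uses panel-heterozygous SNPs as informative", {
  f <- make_loh_fixture(50, rep(c(0, 1), 25))
  panel <- list(f$normal, f$normal, f$normal)
  res <- call_loh(f$seg, f$tumor, panel = panel)
  expect_true(res$loh)
  expect_equal(res$n_informative, 50)
  expect_error(call_loh(f$seg, f$tumor), "matched normal or a reference")
})

test_that("bundled toy table filter attrition: 7 kept, 3 rejected with named rules", {
  toy <- read_lesion_file(system.file("extdata", "toy_lesions.tsv",
                                      package = "marscan"))
  expect_equal(nrow(toy), 10)
  res <- apply_filters(toy, filter_policy())
  expect_equal(nrow(res$kept), 7)
  expect_equal(nrow(res$rejected), 3)
  rej <- res$rejected
  expect_equal(rej$rule[rej$sample_id == "T01"], "min_cnv_length")
  expect_equal(rej$rule[rej$sample_id == "T02"], "min_aupd_length")
  expect_equal(rej$rule[rej$sample_id == "T03"], "excluded_chromosome")
  # the 1.2 Mb aUPD and the 0.9 Mb one land on opposite sides of 1 Mb
  expect_true("T06" %in% res$kept$sample_id)

  # idempotence
  again <- apply_filters(res$kept, filter_policy())
  expect_identical(again$kept, res$kept)
  expect_equal(nrow(again$rejected), 0)
})

test_that("blacklisted cytobands drop overlapping lesions; undefined names never match", {
  cb <- data.frame(chrom = c("chr7", "chr7", "chr14"),
                   start = c(1, 3e7, 1), end = c(3e7, 6e7, 3e7),
                   band = c("p14.1", "q34", "q11.2"),
                   stain = "gneg", stringsAsFactors = FALSE)
  cb$full_name <- paste0(norm_chrom(cb$chrom), cb$band)
  les <- data.frame(sample_id = "S1", chrom = c("chr7", "chr7", "chr14"),
                    start = c(1e6, 4e7, 5e7), end = c(2e6, 4.1e7, 5.1e7),
                    category = "AMP_NO_LOH", stringsAsFactors = FALSE)
  # "7p34" does not exist in this map, so only 7p14.1 can fire;
  # the chr14 lesion lies outside 14q11.2
  res <- apply_filters(les, filter_policy(excluded_chroms = "X"), cb)
  expect_equal(res$rejected$rule, "blacklist_cytoband")
  expect_equal(res$rejected$chrom, "chr7")
  expect_equal(res$rejected$start, 1e6)
  # accepting the 7q34 spelling drops the TRB-locus lesion too
  res2 <- apply_filters(les, filter_policy(
    excluded_chroms = "X",
    blacklist_cytobands = c("7p14.1", "7q34", "14q11.2")), cb)
  expect_equal(nrow(res2$rejected), 2)
  # unknown lesion chromosome is a coordinate error
  bad <- les
  bad$chrom[1] <- "chr99"
  expect_error(apply_filters(bad, filter_policy(excluded_chroms = "X"),
                             cb), "coordinate error")
})

test_that("zero-noise cohort recovers every implanted lesion with exact category and CN", {
  truths <- list(
    data.frame(chrom = c("chr1", "chr1", "chr2"),
               start = c(5e5, 3e6, 1e6), end = c(7e5, 4.5e6, 1.2e6),
               cn = c(4, 2, 1), loh = c(FALSE, TRUE, TRUE)),
    data.frame(chrom = c("chr1", "chr2"),
               start = c(1e6, 2e6), end = c(1.15e6, 2.2e6),
               cn = c(3, 1), loh = c(TRUE, TRUE)),
    data.frame(chrom = "chr2", start = 3e6, end = 4.4e6, cn = 2,
               loh = TRUE))
  co <- zero_noise_cohort(truths)
  for (i in seq_along(truths)) {
    s <- co$samples[[i]]
    res <- call_sample_lesions(s$tumor, s$normal, mode = "paired",
                               sample_id = names(co$samples)[i])
    kept <- apply_filters(res$lesions, filter_policy())$kept
    tr <- truths[[i]]
    for (j in seq_len(nrow(tr))) {
      hit <- kept[kept$chrom == tr$chrom[j] & kept$start < tr$end[j] &
                    kept$end > tr$start[j], ]
      expect_equal(nrow(hit), 1)
      ov <- min(hit$end, tr$end[j]) - max(hit$start, tr$start[j])
      ro <- ov / max(hit$end - hit$start, tr$end[j] - tr$start[j])
      expect_gte(ro, 0.95)
      truth_cat <- classify_five_state(
        ifelse(tr$cn[j] > 2, "gain", ifelse(tr$cn[j] < 2, "loss",
                                            "neutral")), tr$loh[j])
      expect_equal(hit$category, truth_cat)
      expect_equal(hit$cn_estimate, tr$cn[j])
    }
    # and nothing else was called
    expect_equal(nrow(kept), nrow(tr))
  }
})

test_that("aUPD calls are copy-neutral by construction", {
  truths <- list(data.frame(chrom = "chr1", start = 2e6, end = 3.6e6,
                            cn = 2, loh = TRUE))
  co <- zero_noise_cohort(truths)
  s <- co$samples[[1]]
  res <- call_sample_lesions(s$tumor, s$normal, mode = "paired")
  aupd <- res$lesions[res$lesions$category == "AUPD", ]
  expect_equal(nrow(aupd), 1)
  gain_thr <- 0.15
  expect_true(all(abs(aupd$cn_estimate - 2) <= 2 * (2^gain_thr - 1)))
})

test_that("detect_aupd ignores copy-altered LOH and needs informative SNPs", {
  truths <- list(data.frame(chrom = "chr1", start = 2e6, end = 3.6e6,
                            cn = 1, loh = TRUE))
  co <- zero_noise_cohort(truths)
  s <- co$samples[[1]]
  series <- compute_ratio_series(s$tumor, s$normal, mode = "paired")
  aupd <- detect_aupd(s$tumor, s$normal, series = series)
  expect_equal(nrow(aupd), 0)  # the deleted LOH region is not copy-neutral
})
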
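# Synthetic SNP-array cohort generator.
#
# Emulates the statistical structure that the downstream analysis assumes:
# a ~diploid baseline with LRR ~ N(0, sd), lesions shifting mean LRR to
# log2(CN/2), BAF clusters at the allelic ratios implied by genotype and
# allele-specific copy number, aUPD as CN = 2 with loss of heterozygous BAF
# clusters, and matched normals free of somatic lesions.

#' Noise model for the synthetic array signal
#'
#' @param lrr_sd standard deviation of Gaussian LRR noise (log2 units).
#' @param baf_sd standard deviation of BAF noise; BAF is clipped to [0, 1]
#'   after perturbation (truncated Gaussian).
#' @param het_fraction probability that a SNP probe is germline
#'   heterozygous (AB); homozygotes split evenly between AA and BB.
#' @return a `noise_model` list.
#' @export
noise_model <- function(lrr_sd = 0.2, baf_sd = 0.03, het_fraction = 0.3) {
  stopifnot(lrr_sd >= 0, baf_sd >= 0,
            het_fraction >= 0, het_fraction <= 1)
  structure(list(lrr_sd = lrr_sd, baf_sd = baf_sd,
                 het_fraction = het_fraction),
            class = "noise_model")
}

#' Build a reduced-density probe map
#'
#' Places markers at regular `spacing` with optional uniform jitter
#' (strictly less than spacing/2, so positions stay strictly increasing)
#' and marks a fraction of them as SNP probes; the rest are
#' copy-number-only probes that carry LRR but no BAF/genotype.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param spacing target inter-probe spacing in bp (>= 1).
#' @param snp_fraction probability a probe is a SNP probe.
#' @param jitter maximum absolute positional jitter in bp
#'   (must be < spacing/2); 0 gives a perfectly regular grid.
#' @param seed optional integer seed for the jitter and SNP assignment.
#' @return a `probe_map`: list with `probes`
#'   (`probe_id, chrom, pos, kind`) and `chrom_sizes`.
#' @export
build_probe_map <- function(chromosomes, spacing = 1000, snp_fraction = 0.5,
                            jitter = 0, seed = NULL) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    stop("invalid specification: chromosomes must be a named vector",
         call. = FALSE)
  }
  if (!is.numeric(spacing) || spacing < 1) {
    stop("invalid specification: spacing must be >= 1", call. = FALSE)
  }
  if (any(chromosomes < spacing)) {
    stop("invalid specification: chromosome lengths must be >= spacing",
         call. = FALSE)
  }
  stopifnot(snp_fraction >= 0, snp_fraction <= 1,
            jitter >= 0, jitter < spacing / 2)
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- lapply(names(chromosomes), function(cn) {
    len <- chromosomes[[cn]]
    n <- floor(len / spacing)
    base <- round((seq_len(n) - 0.5) * spacing)
    if (jitter > 0) base <- base + round(stats::runif(n, -jitter, jitter))
    kind <- ifelse(stats::runif(n) < snp_fraction, "SNP", "CN")
    data.frame(probe_id = sprintf("%s_p%06d", cn, seq_len(n)),
               chrom = cn, pos = base, kind = kind,
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, per_chrom)
  rownames(probes) <- NULL
  structure(list(probes = probes, chrom_sizes = chromosomes),
            class = "probe_map")
}

# validate a truth-lesion table against a map; lesions must be disjoint
# within a sample and respect the CN/LOH consistency rules
validate_truth <- function(truth, map) {
  if (is.null(truth) || nrow(truth) == 0) return(invisible(NULL))
  need <- c("chrom", "start", "end", "cn", "loh")
  if (!all(need %in% names(truth))) {
    stop("invalid specification: truth table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(truth$end <= truth$start)) {
    stop("invalid specification: lesion end must be > start", call. = FALSE)
  }
  if (any(!truth$chrom %in% names(map$chrom_sizes))) {
    stop("invalid specification: lesion chromosome not in probe map",
         call. = FALSE)
  }
  if (any(truth$end - 1 > map$chrom_sizes[truth$chrom])) {
    stop("invalid specification: lesion exceeds chromosome length",
         call. = FALSE)
  }
  if (any(truth$cn < 0 | truth$cn != floor(truth$cn))) {
    stop("invalid specification: cn must be a non-negative integer",
         call. = FALSE)
  }
  if (any(truth$cn <= 1 & !truth$loh)) {
    stop("invalid specification: CN <= 1 implies LOH", call. = FALSE)
  }
  if (any(truth$cn == 2 & !truth$loh)) {
    stop("invalid specification: a CN = 2 lesion must be aUPD (loh = TRUE)",
         call. = FALSE)
  }
  for (cn in unique(truth$chrom)) {
    tc <- truth[truth$chrom == cn, , drop = FALSE]
    tc <- tc[order(tc$start), , drop = FALSE]
    if (nrow(tc) > 1 && any(tc$start[-1] < tc$end[-nrow(tc)])) {
      stop("invalid specification: overlapping truth lesions on ", cn,
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Simulate one tumor (and optionally matched-normal) sample
#'
#' Germline genotypes are drawn per SNP probe (AB with probability
#' `noise$het_fraction`). Outside lesions the expected LRR is 0 and
#' heterozygous SNPs cluster at BAF 0.5. Inside a lesion of total copy
#' number CN the expected LRR is `log2(CN/2)` (floored at -5 for CN = 0),
#' scaled by `purity` as `log2((purity*CN + (1-purity)*2)/2)`; BAF moves to
#' the allelic ratio implied by the allele-specific copy number: under LOH
#' one parental allele is lost entirely, under a non-LOH gain all extra
#' copies derive from one randomly chosen allele.
#'
#' @param map a `probe_map`.
#' @param truth data.frame of implanted lesions
#'   (`chrom, start, end, cn, loh`), half-open bp coordinates,
#'   non-overlapping; NULL for a lesion-free sample.
#' @param noise a [noise_model()].
#' @param matched_normal also simulate a lesion-free matched normal sharing
#'   the germline genotypes.
#' @param purity tumor cell fraction in (0, 1]; 1 = pure tumor.
#' @return list with `tumor` and `normal` probe-record data.frames
#'   (`probe_id, chrom, pos, lrr, baf, genotype`; `baf`/`genotype` NA for
#'   CN-only probes); `normal` is NULL when `matched_normal = FALSE`.
#' @export
simulate_sample <- function(map, truth = NULL, noise = noise_model(),
                            matched_normal = TRUE, purity = 1) {
  stopifnot(inherits(map, "probe_map"), purity > 0, purity <= 1)
  validate_truth(truth, map)
  pr <- map$probes
  n <- nrow(pr)
  snp <- pr$kind == "SNP"

  # germline B-allele count g in {0,1,2}; AB w.p. het_fraction
  g <- rep(NA_integer_, n)
  u <- stats::runif(n)
  g[snp] <- ifelse(u[snp] < noise$het_fraction, 1L,
                   ifelse(stats::runif(n)[snp] < 0.5, 0L, 2L))
  geno <- rep(NA_character_, n)
  geno[snp] <- c("AA", "AB", "BB")[g[snp] + 1L]

  # per-probe true CN / LOH from covering lesion
  cn_true <- rep(2, n)
  loh <- rep(FALSE, n)
  if (!is.null(truth) && nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      hit <- pr$chrom == truth$chrom[i] &
        pr$pos >= truth$start[i] & pr$pos < truth$end[i]
      cn_true[hit] <- truth$cn[i]
      loh[hit] <- truth$loh[i]
    }
  }

  # tumor B-allele copies; allele-retention draw made for every SNP probe
  # so the RNG stream is independent of the lesion layout
  pick_b <- stats::runif(n) < 0.5
  nb <- rep(NA_real_, n)
  het <- snp & g == 1L
  hom <- snp & g != 1L
  nb[hom] <- ifelse(g[hom] == 2L, cn_true[hom], 0)
  # heterozygous: LOH keeps one allele (B or A at random), a non-LOH gain
  # duplicates one allele; non-lesion het keeps (1,1)
  nb[het] <- ifelse(loh[het],
                    ifelse(pick_b[het], cn_true[het], 0),
                    ifelse(cn_true[het] == 2, 1,
                           ifelse(pick_b[het], cn_true[het] - 1, 1)))

  mix_cn <- purity * cn_true + (1 - purity) * 2
  lrr_exp <- ifelse(mix_cn <= 0, -5, log2(mix_cn / 2))
  baf_exp <- ifelse(mix_cn <= 0, 0.5,
                    (purity * nb + (1 - purity) * g) / mix_cn)

  tumor_lrr <- lrr_exp + stats::rnorm(n, 0, noise$lrr_sd)
  tumor_baf <- rep(NA_real_, n)
  tumor_baf[snp] <- clip(baf_exp[snp] +
                           stats::rnorm(sum(snp), 0, noise$baf_sd), 0, 1)
  tumor_geno <- rep(NA_character_, n)
  tumor_geno[snp] <- ifelse(tumor_baf[snp] <= 0.25, "AA",
                            ifelse(tumor_baf[snp] >= 0.75, "BB", "AB"))

  tumor <- data.frame(probe_id = pr$probe_id, chrom = pr$chrom,
                      pos = pr$pos, lrr = tumor_lrr, baf = tumor_baf,
                      genotype = tumor_geno, stringsAsFactors = FALSE)
  normal <- NULL
  if (matched_normal) {
    norm_lrr <- stats::rnorm(n, 0, noise$lrr_sd)
    norm_baf <- rep(NA_real_, n)
    norm_baf[snp] <- clip(g[snp] / 2 +
                            stats::rnorm(sum(snp), 0, noise$baf_sd), 0, 1)
    normal <- data.frame(probe_id = pr$probe_id, chrom = pr$chrom,
                         pos = pr$pos, lrr = norm_lrr, baf = norm_baf,
                         genotype = geno, stringsAsFactors = FALSE)
  }
  list(tumor = tumor, normal = normal)
}

# draw `n_private` non-overlapping private lesions for one sample,
# avoiding the shared lesion; a fraction are aUPD (CN 2 + LOH, >= 1 Mb)
draw_private_lesions <- function(map, n_private, avoid = NULL,
                                 size_range = c(2e4, 2e5),
                                 cn_pool = c(1, 3, 4),
                                 aupd_fraction = 0.1,
                                 aupd_size_range = c(1.2e6, 2e6),
                                 max_tries = 200) {
  placed <- if (is.null(avoid)) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               cn = numeric(), loh = logical(), stringsAsFactors = FALSE)
  } else {
    avoid
  }
  out <- list()
  sizes <- map$chrom_sizes
  for (k in seq_len(n_private)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      is_aupd <- stats::runif(1) < aupd_fraction
      len <- round(stats::runif(1,
                                if (is_aupd) aupd_size_range[1] else size_range[1],
                                if (is_aupd) aupd_size_range[2] else size_range[2]))
      chrom <- sample(names(sizes), 1)
      if (sizes[[chrom]] <= len + 1) next
      start <- floor(stats::runif(1, 1, sizes[[chrom]] - len))
      end <- start + len
      clash <- placed$chrom == chrom & placed$start < end & placed$end > start
      if (any(clash)) next
      cn <- if (is_aupd) 2 else sample(cn_pool, 1)
      les <- data.frame(chrom = chrom, start = start, end = end, cn = cn,
                        loh = is_aupd || cn <= 1, stringsAsFactors = FALSE)
      placed <- rbind(placed, les)
      out[[length(out) + 1L]] <- les
      ok <- TRUE
      break
    }
    if (!ok) break  # genome too crowded; stop placing
  }
  if (length(out) == 0) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               cn = numeric(), loh = logical(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Simulate a tumor/matched-normal cohort with a shared implanted lesion
#'
#' Exactly `round(carrier_fraction * n_samples)` samples (chosen at random)
#' carry the shared lesion; every sample additionally receives
#' `private_lesion_rate` private lesions drawn independently (mostly CNVs,
#' occasionally aUPD), placed without overlap.
#'
#' @param map a `probe_map`.
#' @param n_samples cohort size (>= 1).
#' @param shared_lesion one-row data.frame (`chrom, start, end, cn, loh`)
#'   or NULL for no shared lesion.
#' @param carrier_fraction fraction of samples carrying the shared lesion.
#' @param private_lesion_rate number of private lesions per sample
#'   (exact integer count).
#' @param noise a [noise_model()].
#' @param seed integer seed; the cohort is byte-reproducible given
#'   (arguments, seed).
#' @param purity tumor purity passed to [simulate_sample()].
#' @param matched_normal simulate matched normals.
#' @return list with `samples` (named list of `simulate_sample()` results),
#'   `truth` (`sample_id, chrom, start, end, cn, loh`), `carriers`
#'   (sample ids carrying the shared lesion), and `map`.
#' @export
simulate_cohort <- function(map, n_samples, shared_lesion = NULL,
                            carrier_fraction = 0.5, private_lesion_rate = 5,
                            noise = noise_model(), seed = 1, purity = 1,
                            matched_normal = TRUE) {
  stopifnot(is_count(n_samples), n_samples >= 1,
            carrier_fraction >= 0, carrier_fraction <= 1,
            is_count(private_lesion_rate))
  if (!is.null(shared_lesion)) validate_truth(shared_lesion, map)
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_samples))
  n_carriers <- round(carrier_fraction * n_samples)
  carriers <- if (is.null(shared_lesion) || n_carriers == 0) {
    character()
  } else {
    sort(sample(ids, n_carriers))
  }
  samples <- vector("list", n_samples)
  names(samples) <- ids
  truth_rows <- list()
  for (i in seq_len(n_samples)) {
    set.seed(seed + i)
    shared <- if (ids[i] %in% carriers) shared_lesion else NULL
    # private lesions avoid the shared locus in every sample (carrier or
    # not) so they stay genuinely private and the implanted carrier count
    # remains the ground truth of recurrence at that locus
    priv <- draw_private_lesions(map, private_lesion_rate,
                                 avoid = shared_lesion)
    truth_i <- rbind(shared, priv)
    samples[[i]] <- simulate_sample(map, truth_i, noise,
                                    matched_normal = matched_normal,
                                    purity = purity)
    if (!is.null(truth_i) && nrow(truth_i) > 0) {
      truth_rows[[i]] <- cbind(sample_id = ids[i], truth_i)
    }
  }
  truth <- if (length(truth_rows)) {
    out <- do.call(rbind, truth_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(), cn = numeric(),
               loh = logical(), stringsAsFactors = FALSE)
  }
  list(samples = samples, truth = truth, carriers = carriers, map = map)
}

#' Simulate a duplex qPCR copy-number plate
#'
#' Each sample gets `n_replicates` wells; the reference (VIC) Ct is drawn
#' around `base_ct`, and the target (FAM) Ct is offset so that the expected
#' ΔCt for a diploid sample is `dct_diploid` and decreases by log2(CN/2)
#' per copy-number doubling. Independent Gaussian noise of sd `ct_sd` is
#' added to each channel of each well.
#'
#' @param truth_cn named numeric vector of true target copy numbers.
#' @param n_replicates wells per sample.
#' @param ct_sd per-channel Ct noise sd (cycles).
#' @param base_ct mean reference Ct (cycles).
#' @param dct_diploid expected ΔCt (target - reference) at CN = 2.
#' @param seed optional integer seed.
#' @return wells data.frame `sample_id, replicate, ct_fam, ct_vic`.
#' @export
simulate_taqman_plate <- function(truth_cn, n_replicates = 4, ct_sd = 0.05,
                                  base_ct = 26, dct_diploid = 0.5,
                                  seed = NULL) {
  stopifnot(!is.null(names(truth_cn)), all(truth_cn > 0),
            n_replicates >= 1, ct_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(truth_cn), function(sid) {
    dct <- dct_diploid - log2(truth_cn[[sid]] / 2)
    vic <- base_ct + stats::rnorm(n_replicates, 0, ct_sd)
    fam <- vic + dct + stats::rnorm(n_replicates, 0, ct_sd)
    data.frame(sample_id = sid, replicate = seq_len(n_replicates),
               ct_fam = fam, ct_vic = vic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic cytoband map for a probe map's genome
#'
#' Splits every chromosome into `n_bands` equal bands named in UCSC style
#' (p-arm bands counting down toward the centromere, then q-arm bands
#' counting up), e.g. p12, p11, q11, q12 for `n_bands = 4`. Useful for
#' exercising cytoband-level recurrence and blacklist filtering on
#' simulated genomes.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_bands bands per chromosome (even, >= 2).
#' @return cytoband data.frame `chrom, start, end, band, stain, full_name`
#'   with 1-based half-open coordinates.
#' @export
synthetic_cytobands <- function(chrom_sizes, n_bands = 4) {
  stopifnot(n_bands >= 2, n_bands %% 2 == 0)
  half <- n_bands / 2
  band_names <- c(sprintf("p1%d", half:1), sprintf("q1%d", 1:half))
  rows <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    cuts <- round(seq(1, len + 1, length.out = n_bands + 1))
    data.frame(chrom = cn, start = cuts[-(n_bands + 1)], end = cuts[-1],
               band = band_names,
               stain = rep(c("gneg", "gpos50"), length.out = n_bands),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$full_name <- paste0(norm_chrom(out$chrom), out$band)
  rownames(out) <- NULL
  out
}
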
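# Lesion classification and filtering.
#
# Segments become lesions with a copy-number state (from mean LRR), an LOH
# flag (from retention of germline-heterozygous BAF clusters), and one of
# five imbalance categories; amplification with/without LOH, copy-neutral
# LOH (aUPD), deletion with/without LOH. Copy-neutral segments without LOH
# are not lesions. The cohort filters then drop sex/mitochondrial
# chromosomes, sub-threshold lengths, and blacklisted cytobands.

LESION_CATEGORIES <- c("AMP_LOH", "AMP_NO_LOH", "AUPD",
                       "DEL_LOH", "DEL_NO_LOH", "NEUTRAL")

#' LOH-calling parameters
#'
#' @param min_informative minimum germline-heterozygous SNPs a segment
#'   needs before an LOH call is attempted (below it the segment is
#'   annotated uninformative and loh = FALSE).
#' @param min_hom_fraction minimum fraction of informative SNPs whose
#'   tumor BAF falls in the homozygosity bands for loh = TRUE.
#' @param hom_band half-width of the homozygosity bands: BAF <= hom_band
#'   or >= 1 - hom_band counts as homozygous.
#' @return an `loh_params` list.
#' @export
loh_params <- function(min_informative = 10, min_hom_fraction = 0.9,
                       hom_band = 0.1) {
  stopifnot(min_informative >= 1,
            min_hom_fraction > 0, min_hom_fraction <= 1,
            hom_band >= 0, hom_band < 0.5)
  structure(list(min_informative = min_informative,
                 min_hom_fraction = min_hom_fraction,
                 hom_band = hom_band),
            class = "loh_params")
}

#' Filtering policy for called lesions
#'
#' Defaults reproduce the study filters: drop chromosomes X/Y/MT, CNV
#' segments shorter than 1 kb, aUPD regions shorter than 1 Mb, and lesions
#' on the T-cell-receptor artifact cytobands.
#'
#' @param excluded_chroms chromosome names to drop ("chr" prefix ignored).
#' @param min_cnv_length minimum CNV (AMP*/DEL*) length in bp.
#' @param min_aupd_length minimum aUPD length in bp.
#' @param blacklist_cytobands full cytoband names (e.g. "7p14.1") whose
#'   overlap disqualifies a lesion; matched verbatim against the supplied
#'   cytoband map, so a name the map does not define never matches.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(excluded_chroms = c("X", "Y", "MT", "M"),
                          min_cnv_length = 1000,
                          min_aupd_length = 1e6,
                          blacklist_cytobands = c("7p34", "7p14.1",
                                                  "14q11.2")) {
  stopifnot(min_cnv_length > 0, min_aupd_length > 0)
  structure(list(excluded_chroms = norm_chrom(excluded_chroms),
                 min_cnv_length = min_cnv_length,
                 min_aupd_length = min_aupd_length,
                 blacklist_cytobands = blacklist_cytobands),
            class = "filter_policy")
}

#' Copy-number state and estimate from mean segment LRR
#'
#' The copy-number estimate follows `cn = 2 * 2^mean_lrr` (so mean LRR 1
#' is 4 copies), reported to one decimal. Thresholds are asymmetric
#' because one-copy changes are asymmetric on the log2 scale.
#'
#' @param mean_lrr numeric vector of segment mean LRRs (log2 units).
#' @param gain_threshold LRR at or above which a segment is a gain.
#' @param loss_threshold LRR at or below which a segment is a loss
#'   (negative).
#' @return data.frame `cn_state` ("gain"/"neutral"/"loss") and
#'   `cn_estimate` (copies, one decimal).
#' @export
call_cn_state <- function(mean_lrr, gain_threshold = 0.15,
                          loss_threshold = -0.2) {
  stopifnot(loss_threshold < 0, gain_threshold > 0)
  state <- ifelse(mean_lrr >= gain_threshold, "gain",
                  ifelse(mean_lrr <= loss_threshold, "loss", "neutral"))
  data.frame(cn_state = state,
             cn_estimate = round(2 * 2^mean_lrr, 1),
             stringsAsFactors = FALSE)
}

# which panel SNPs count as pseudo-informative in baseline mode: probes
# heterozygous in at least half the reference panel
panel_het_fraction <- function(panel) {
  het <- vapply(panel, function(s) s$genotype == "AB" & !is.na(s$genotype),
                logical(nrow(panel[[1]])))
  rowMeans(het)
}

#' LOH call per segment from tumor BAF at informative SNPs
#'
#' Paired mode: informative SNPs are those the matched normal genotyped
#' AB. Baseline mode: SNPs heterozygous in at least half the reference
#' panel serve as pseudo-informative (population proxy; lower confidence).
#' A segment is LOH when at least `min_hom_fraction` of its informative
#' SNPs show tumor BAF inside the homozygosity bands; segments with fewer
#' than `min_informative` such SNPs return loh = FALSE with status
#' "uninformative".
#'
#' @param segments segment data.frame (from [segment_series()]).
#' @param tumor tumor probe records.
#' @param normal matched-normal probe records, or NULL for baseline mode.
#' @param panel reference panel (list of probe records) for baseline mode.
#' @param params an [loh_params()].
#' @return data.frame `loh, n_informative, hom_fraction, loh_status`
#'   aligned with `segments` rows.
#' @export
call_loh <- function(segments, tumor, normal = NULL, panel = NULL,
                     params = loh_params()) {
  if (is.null(normal) && is.null(panel)) {
    stop("call_loh needs a matched normal or a reference panel",
         call. = FALSE)
  }
  informative_all <- if (!is.null(normal)) {
    !is.na(normal$genotype) & normal$genotype == "AB"
  } else {
    panel_het_fraction(panel) >= 0.5
  }
  hb <- params$hom_band
  res <- lapply(seq_len(nrow(segments)), function(i) {
    inseg <- tumor$chrom == segments$chrom[i] &
      tumor$pos >= segments$start[i] & tumor$pos < segments$end[i]
    inf <- which(inseg & informative_all & !is.na(tumor$baf))
    n_inf <- length(inf)
    if (n_inf < params$min_informative) {
      return(data.frame(loh = FALSE, n_informative = n_inf,
                        hom_fraction = NA_real_,
                        loh_status = "uninformative",
                        stringsAsFactors = FALSE))
    }
    baf <- tumor$baf[inf]
    frac <- mean(baf <= hb | baf >= 1 - hb)
    data.frame(loh = frac >= params$min_hom_fraction, n_informative = n_inf,
               hom_fraction = frac, loh_status = "informative",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Map (copy-number state, LOH) to the five imbalance categories
#'
#' Total over all six state pairs; (neutral, FALSE) maps to NEUTRAL, which
#' is not a lesion.
#'
#' @param cn_state "gain", "neutral" or "loss" (vectorized).
#' @param loh logical LOH flag.
#' @return character vector of categories: AMP_LOH, AMP_NO_LOH, AUPD,
#'   DEL_LOH, DEL_NO_LOH or NEUTRAL.
#' @export
classify_five_state <- function(cn_state, loh) {
  stopifnot(all(cn_state %in% c("gain", "neutral", "loss")),
            is.logical(loh), length(cn_state) == length(loh))
  ifelse(cn_state == "gain", ifelse(loh, "AMP_LOH", "AMP_NO_LOH"),
         ifelse(cn_state == "loss", ifelse(loh, "DEL_LOH", "DEL_NO_LOH"),
                ifelse(loh, "AUPD", "NEUTRAL")))
}

#' Classify segments into lesions for one sample
#'
#' Runs [call_cn_state()], [call_loh()] and [classify_five_state()] and
#' drops NEUTRAL segments (copy-neutral, no LOH: not lesions).
#'
#' @param segments segment data.frame.
#' @param tumor,normal,panel probe records, as in [call_loh()].
#' @param sample_id sample identifier recorded with every lesion.
#' @param gain_threshold,loss_threshold LRR calling cut-offs, see
#'   [call_cn_state()].
#' @param loh a [loh_params()].
#' @param keep_neutral retain NEUTRAL segments (for auditing).
#' @return lesion data.frame `sample_id, chrom, start, end, n_markers,
#'   mean_lrr, cn_estimate, cn_state, loh, n_informative, category,
#'   length`.
#' @export
call_lesions <- function(segments, tumor, normal = NULL, panel = NULL,
                         sample_id = "sample", gain_threshold = 0.15,
                         loss_threshold = -0.2, loh = loh_params(),
                         keep_neutral = FALSE) {
  cn <- call_cn_state(segments$mean_lrr, gain_threshold, loss_threshold)
  lo <- call_loh(segments, tumor, normal, panel, loh)
  out <- data.frame(sample_id = sample_id,
                    chrom = segments$chrom,
                    start = segments$start, end = segments$end,
                    n_markers = segments$n_markers,
                    mean_lrr = segments$mean_lrr,
                    cn_estimate = cn$cn_estimate,
                    cn_state = cn$cn_state,
                    loh = lo$loh,
                    n_informative = lo$n_informative,
                    stringsAsFactors = FALSE)
  out$category <- classify_five_state(out$cn_state, out$loh)
  out$length <- out$end - out$start
  if (!keep_neutral) out <- out[out$category != "NEUTRAL", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the study's exclusion filters to a lesion table
#'
#' Drops, in order: lesions on excluded chromosomes; CNVs (AMP*/DEL*)
#' shorter than the CNV minimum; aUPD shorter than the aUPD minimum;
#' lesions overlapping blacklisted cytobands (only when a cytoband map is
#' supplied). Filtering is idempotent and every rejection is logged with
#' the rule that fired.
#'
#' @param lesions lesion data.frame (see [call_lesions()]).
#' @param policy a [filter_policy()].
#' @param cytobands cytoband map (as from [read_cytoband_file()] or
#'   [synthetic_cytobands()]); NULL skips the blacklist rule.
#' @return list with `kept` (surviving lesions) and `rejected` (dropped
#'   lesions with a `rule` column naming the filter).
#' @export
apply_filters <- function(lesions, policy = filter_policy(),
                          cytobands = NULL) {
  rule <- rep(NA_character_, nrow(lesions))
  is_cnv <- lesions$category %in% c("AMP_LOH", "AMP_NO_LOH",
                                    "DEL_LOH", "DEL_NO_LOH")
  is_aupd <- lesions$category == "AUPD"
  len <- lesions$end - lesions$start

  hit <- is.na(rule) & norm_chrom(lesions$chrom) %in% policy$excluded_chroms
  rule[hit] <- "excluded_chromosome"
  hit <- is.na(rule) & is_cnv & len < policy$min_cnv_length
  rule[hit] <- "min_cnv_length"
  hit <- is.na(rule) & is_aupd & len < policy$min_aupd_length
  rule[hit] <- "min_aupd_length"

  if (!is.null(cytobands) && length(policy$blacklist_cytobands)) {
    black <- cytobands[cytobands$full_name %in% policy$blacklist_cytobands, ,
                       drop = FALSE]
    if (nrow(black)) {
      for (i in which(is.na(rule))) {
        if (!any(norm_chrom(cytobands$chrom) ==
                   norm_chrom(lesions$chrom[i]))) {
          coord_error("unknown chromosome in cytoband map: ",
                      lesions$chrom[i])
        }
        ov <- norm_chrom(black$chrom) == norm_chrom(lesions$chrom[i]) &
          black$start < lesions$end[i] & black$end > lesions$start[i]
        if (any(ov)) rule[i] <- "blacklist_cytoband"
      }
    }
  }
  kept <- lesions[is.na(rule), , drop = FALSE]
  rejected <- lesions[!is.na(rule), , drop = FALSE]
  rejected$rule <- rule[!is.na(rule)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Detect copy-neutral LOH (aUPD) from the BAF signal
#'
#' A copy-neutral LOH region leaves the LRR flat and is therefore
#' invisible to LRR segmentation; it does, however, collapse the
#' heterozygous BAF cluster. This routine segments the mirrored BAF
#' (`|BAF - 0.5|`, ~0 at retained heterozygosity, ~0.5 under LOH) of the
#' germline-informative SNPs with the same recursive t-test splitter and
#' reports segments whose mean mirrored BAF reaches
#' `mirror_threshold` and whose mean ratio LRR stays inside the
#' copy-neutral band as aUPD lesions.
#'
#' @param tumor tumor probe records.
#' @param normal matched-normal probe records (or NULL with `panel`).
#' @param panel reference panel for baseline mode (pseudo-informative
#'   SNPs: heterozygous in >= half the panel; lower confidence).
#' @param series ratio series for the same sample (to judge copy
#'   neutrality), as from [compute_ratio_series()].
#' @param params a [seg_params()]; `min_markers` counts informative SNPs.
#' @param mirror_threshold minimum mean mirrored BAF for an LOH call.
#' @param gain_threshold,loss_threshold copy-neutral band bounds on mean
#'   ratio LRR (as in [call_cn_state()]).
#' @param max_gap informative-SNP gap (bp) above which the series is
#'   split, see [mask_low_density()].
#' @param sample_id recorded with the lesions.
#' @return lesion data.frame of AUPD calls (possibly 0 rows) in the
#'   [call_lesions()] schema.
#' @export
detect_aupd <- function(tumor, normal = NULL, panel = NULL, series,
                        params = seg_params(), mirror_threshold = 0.35,
                        gain_threshold = 0.15, loss_threshold = -0.2,
                        max_gap = 1e6, sample_id = "sample") {
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_markers = integer(), mean_lrr = numeric(),
                      cn_estimate = numeric(), cn_state = character(),
                      loh = logical(), n_informative = integer(),
                      category = character(), length = numeric(),
                      stringsAsFactors = FALSE)
  informative_all <- if (!is.null(normal)) {
    !is.na(normal$genotype) & normal$genotype == "AB"
  } else if (!is.null(panel)) {
    panel_het_fraction(panel) >= 0.5
  } else {
    stop("detect_aupd needs a matched normal or a reference panel",
         call. = FALSE)
  }
  inf <- which(informative_all & !is.na(tumor$baf))
  if (length(inf) < params$min_markers) return(empty)
  mirror <- data.frame(probe_id = tumor$probe_id[inf],
                       chrom = tumor$chrom[inf], pos = tumor$pos[inf],
                       value = abs(tumor$baf[inf] - 0.5),
                       stringsAsFactors = FALSE)
  mirror <- mask_low_density(mirror, max_gap, params$min_markers)
  segs <- segment_series(mirror, params)
  loh_segs <- segs[segs$mean_lrr >= mirror_threshold, , drop = FALSE]
  if (nrow(loh_segs) == 0) return(empty)
  out <- lapply(seq_len(nrow(loh_segs)), function(i) {
    inreg <- series$chrom == loh_segs$chrom[i] &
      series$pos >= loh_segs$start[i] & series$pos < loh_segs$end[i]
    mlrr <- mean(series$value[inreg])
    if (mlrr >= gain_threshold || mlrr <= loss_threshold) return(NULL)
    data.frame(sample_id = sample_id, chrom = loh_segs$chrom[i],
               start = loh_segs$start[i], end = loh_segs$end[i],
               n_markers = sum(inreg), mean_lrr = mlrr,
               cn_estimate = round(2 * 2^mlrr, 1), cn_state = "neutral",
               loh = TRUE, n_informative = loh_segs$n_markers[i],
               category = "AUPD",
               length = loh_segs$end[i] - loh_segs$start[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Full per-sample lesion calling (CNV route + aUPD route)
#'
#' Segments the LRR ratio series and classifies the segments
#' ([call_lesions()]), then adds copy-neutral LOH regions found by
#' [detect_aupd()] that do not overlap an already-called lesion.
#'
#' @param tumor,normal,panel probe records (paired or baseline mode).
#' @param mode "paired" or "baseline".
#' @param sample_id sample identifier.
#' @param params a [seg_params()].
#' @param max_gap low-density gap threshold (bp) for the LRR series.
#' @param gain_threshold,loss_threshold LRR calling cut-offs.
#' @param loh an [loh_params()].
#' @param mirror_threshold see [detect_aupd()].
#' @return list with `segments` (LRR segments) and `lesions` (combined
#'   lesion table, genomic order).
#' @export
call_sample_lesions <- function(tumor, normal = NULL, panel = NULL,
                                mode = c("paired", "baseline"),
                                sample_id = "sample",
                                params = seg_params(), max_gap = 1e5,
                                gain_threshold = 0.15,
                                loss_threshold = -0.2,
                                loh = loh_params(),
                                mirror_threshold = 0.35) {
  mode <- match.arg(mode)
  series <- compute_ratio_series(tumor, normal, panel, mode)
  masked <- mask_low_density(series, max_gap, params$min_markers)
  segs <- segment_series(masked, params)
  les <- call_lesions(segs, tumor, normal, panel, sample_id = sample_id,
                      gain_threshold = gain_threshold,
                      loss_threshold = loss_threshold, loh = loh)
  aupd <- detect_aupd(tumor, normal, panel, series, params,
                      mirror_threshold, gain_threshold, loss_threshold,
                      sample_id = sample_id)
  if (nrow(aupd)) {
    clash <- vapply(seq_len(nrow(aupd)), function(i) {
      any(les$chrom == aupd$chrom[i] & les$start < aupd$end[i] &
            les$end > aupd$start[i])
    }, logical(1))
    les <- rbind(les, aupd[!clash, , drop = FALSE])
  }
  les <- les[order(match(les$chrom, unique(tumor$chrom)), les$start), ,
             drop = FALSE]
  rownames(les) <- NULL
  list(segments = segs, lesions = les)
}
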
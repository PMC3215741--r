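# Calibrator-free qPCR relative copy-number quantitation.
#
# Duplex reactions give a target (FAM) and reference (VIC) Ct per well;
# ΔCt = target - reference. With no calibrator sample, the anchor is the
# median mean-ΔCt across QC-passing samples, assumed to represent the
# reference copy number (2 in a diploid genome): each extra ΔCt unit
# below the anchor doubles the estimate.

#' Aggregate qPCR wells to per-sample ΔCt calls
#'
#' @param wells data.frame `sample_id, replicate, ct_fam, ct_vic`; Ct
#'   values must lie in (0, 45) and replicate indices be unique within a
#'   sample.
#' @param qc_sd replicate ΔCt standard-deviation threshold; a sample
#'   passes QC when its sample sd (n-1 denominator) is strictly below it.
#' @return data.frame `sample_id, n_replicates, mean_dct, sd_dct,
#'   qc_pass`.
#' @export
aggregate_wells <- function(wells, qc_sd = 0.15) {
  need <- c("sample_id", "replicate", "ct_fam", "ct_vic")
  if (!all(need %in% names(wells))) {
    stop("wells table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ct <- c(wells$ct_fam, wells$ct_vic)
  if (any(!is.finite(ct)) || any(ct <= 0 | ct >= 45)) {
    stop("Ct values must be finite and in (0, 45)", call. = FALSE)
  }
  for (sid in unique(wells$sample_id)) {
    reps <- wells$replicate[wells$sample_id == sid]
    if (anyDuplicated(reps)) {
      stop("duplicate replicate index for sample ", sid, call. = FALSE)
    }
    if (length(reps) < 2) {
      stop("insufficient replicates for sample ", sid,
           " (need >= 2, got ", length(reps), ")", call. = FALSE)
    }
  }
  dct <- wells$ct_fam - wells$ct_vic
  ids <- unique(wells$sample_id)
  out <- do.call(rbind, lapply(ids, function(sid) {
    d <- dct[wells$sample_id == sid]
    data.frame(sample_id = sid, n_replicates = length(d),
               mean_dct = mean(d), sd_dct = stats::sd(d),
               stringsAsFactors = FALSE)
  }))
  out$qc_pass <- out$sd_dct < qc_sd
  rownames(out) <- NULL
  out
}

#' Copy-number estimates without a calibrator sample
#'
#' Anchors the scale at the median mean-ΔCt of QC-passing samples, which
#' is assumed to correspond to `reference_cn` copies (valid when more
#' than half the plate is copy-neutral at the target):
#' `cn = reference_cn * 2^(anchor - ΔCt)`.
#'
#' @param calls output of [aggregate_wells()].
#' @param reference_cn copy number assigned to the anchor (default 2).
#' @return `calls` with `cn_estimate` and `cn_integer` (rounded) columns;
#'   the anchor is attached as attribute `"anchor_dct"`.
#' @export
copy_number_no_calibrator <- function(calls, reference_cn = 2) {
  if (!any(calls$qc_pass)) {
    stop("no QC-passing sample: cannot anchor the ", "Δ",
         "Ct scale", call. = FALSE)
  }
  anchor <- stats::median(calls$mean_dct[calls$qc_pass])
  calls$cn_estimate <- reference_cn * 2^(anchor - calls$mean_dct)
  calls$cn_integer <- round(calls$cn_estimate)
  attr(calls, "anchor_dct") <- anchor
  calls
}

#' Concordance between array amplification flags and qPCR calls
#'
#' A sample is qPCR-amplified when its integer copy number reaches
#' `amplified_threshold`. Concordant samples are amplified on both
#' platforms or on neither. Reported both over all samples and restricted
#' to QC-passing ones.
#'
#' @param array_amplified named logical vector: per-sample array
#'   amplification status.
#' @param qpcr_calls output of [copy_number_no_calibrator()].
#' @param amplified_threshold integer CN at or above which a qPCR call is
#'   amplified (default 3).
#' @return list `fraction` (all samples), `fraction_qc` (QC-passing
#'   only), `n`, `n_qc`, and the per-sample comparison `table`.
#' @export
concordance <- function(array_amplified, qpcr_calls,
                        amplified_threshold = 3) {
  ids <- qpcr_calls$sample_id
  if (!setequal(ids, names(array_amplified))) {
    stop("array and qPCR sample sets differ", call. = FALSE)
  }
  arr <- array_amplified[ids]
  qp <- qpcr_calls$cn_integer >= amplified_threshold
  conc <- arr == qp
  tab <- data.frame(sample_id = ids, array_amplified = unname(arr),
                    qpcr_amplified = qp, qc_pass = qpcr_calls$qc_pass,
                    concordant = unname(conc), stringsAsFactors = FALSE)
  qc <- qpcr_calls$qc_pass
  list(fraction = mean(conc),
       fraction_qc = if (any(qc)) mean(conc[qc]) else NA_real_,
       n = length(conc), n_qc = sum(qc), table = tab)
}
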
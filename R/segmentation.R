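# Segmentation of per-probe copy-number signal.
#
# Recursive top-down binary splitting: the candidate breakpoint is the cut
# maximizing the pooled-variance two-sample t statistic between left and
# right probe values; a split is accepted iff both sides keep at least
# min_markers probes and the two-sided p-value is <= split_alpha. Accepted
# halves are recursed; adjacent segments whose means do not differ at
# merge_alpha are re-merged. Segments partition the (non-masked) probes.

#' Segmentation parameters
#'
#' @param min_markers minimum probes per segment (>= 2; default 10).
#' @param split_alpha two-sided p-value threshold to accept a split.
#' @param merge_alpha adjacent segments whose means do not differ at this
#'   level are re-merged; defaults equal to `split_alpha`.
#' @return a `seg_params` list.
#' @export
seg_params <- function(min_markers = 10, split_alpha = 0.001,
                       merge_alpha = split_alpha) {
  stopifnot(min_markers >= 2,
            split_alpha > 0, split_alpha < 1,
            merge_alpha > 0, merge_alpha < 1)
  structure(list(min_markers = min_markers, split_alpha = split_alpha,
                 merge_alpha = merge_alpha),
            class = "seg_params")
}

#' Per-probe comparison series (tumor vs reference)
#'
#' Paired mode subtracts the matched normal's LRR probe-by-probe; baseline
#' mode subtracts the per-probe median LRR across a panel of reference
#' samples (the pooled-healthy baseline).
#'
#' @param tumor tumor probe records.
#' @param normal matched-normal probe records (paired mode).
#' @param panel list of reference probe-record data.frames (baseline mode).
#' @param mode "paired" or "baseline".
#' @return data.frame `probe_id, chrom, pos, value` with a `mode`
#'   attribute; one finite value per probe.
#' @export
compute_ratio_series <- function(tumor, normal = NULL, panel = NULL,
                                 mode = c("paired", "baseline")) {
  mode <- match.arg(mode)
  check_alignment <- function(ref, what) {
    if (nrow(ref) != nrow(tumor)) {
      stop("alignment error: ", what, " has ", nrow(ref),
           " probes, tumor has ", nrow(tumor), call. = FALSE)
    }
    bad <- which(ref$probe_id != tumor$probe_id |
                   ref$chrom != tumor$chrom | ref$pos != tumor$pos)
    if (length(bad)) {
      stop("alignment error: first discordant probe at row ", bad[1],
           " (tumor ", tumor$probe_id[bad[1]], " vs ", what, " ",
           ref$probe_id[bad[1]], ")", call. = FALSE)
    }
  }
  if (mode == "paired") {
    if (is.null(normal)) stop("paired mode requires a matched normal",
                              call. = FALSE)
    check_alignment(normal, "normal")
    value <- tumor$lrr - normal$lrr
  } else {
    if (is.null(panel) || length(panel) < 1) {
      stop("baseline mode requires >= 1 reference sample", call. = FALSE)
    }
    for (i in seq_along(panel)) check_alignment(panel[[i]],
                                                paste0("panel[", i, "]"))
    ref <- apply(vapply(panel, function(s) s$lrr,
                        numeric(nrow(tumor))), 1, stats::median)
    value <- tumor$lrr - ref
  }
  if (any(!is.finite(value))) {
    stop("non-finite ratio values", call. = FALSE)
  }
  out <- data.frame(probe_id = tumor$probe_id, chrom = tumor$chrom,
                    pos = tumor$pos, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Split a series at large inter-probe gaps
#'
#' Regions separated by a gap strictly greater than `max_gap` become
#' independent blocks that no segment may span; blocks shorter than
#' `min_markers` are flagged `excluded` (the low-marker-density exclusion).
#'
#' @param series a ratio series from [compute_ratio_series()].
#' @param max_gap maximum tolerated inter-probe gap in bp (> 0); a gap
#'   exactly equal to `max_gap` does not split.
#' @param min_markers blocks with fewer probes are excluded.
#' @return the series with `block` and `excluded` columns added.
#' @export
mask_low_density <- function(series, max_gap = 1e5, min_markers = 10) {
  stopifnot(max_gap > 0)
  blocks <- unlist(lapply(split(seq_len(nrow(series)), series$chrom), function(idx) {
    p <- series$pos[idx]
    cut <- c(FALSE, diff(p) > max_gap)
    paste0(series$chrom[idx][1], "_b", cumsum(cut) + 1L)
  }))
  # split() reorders by chrom factor level; restore row order
  ord <- unlist(split(seq_len(nrow(series)), series$chrom))
  series$block <- NA_character_
  series$block[ord] <- blocks
  tab <- table(series$block)
  series$excluded <- tab[series$block] < min_markers
  series
}

# t statistics for every admissible cut of x (left size m..n-m) via prefix
# sums; returns list(idx = leftmost argmax cut, t, p) or NULL if no cut.
# Zero pooled variance with unequal means gives t = Inf (p = 0).
best_split <- function(x, min_markers) {
  n <- length(x)
  if (n < 2 * min_markers) return(NULL)
  cuts <- min_markers:(n - min_markers)
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  n1 <- cuts
  n2 <- n - cuts
  m1 <- s1[cuts] / n1
  m2 <- (s1[n] - s1[cuts]) / n2
  ss1 <- pmax(s2[cuts] - s1[cuts]^2 / n1, 0)
  ss2 <- pmax((s2[n] - s2[cuts]) - (s1[n] - s1[cuts])^2 / n2, 0)
  sp2 <- (ss1 + ss2) / (n - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
  i <- which.max(abs(t))  # leftmost maximal |t|
  p <- if (is.infinite(t[i])) 0 else 2 * stats::pt(abs(t[i]), df = n - 2,
                                                   lower.tail = FALSE)
  list(idx = cuts[i], t = t[i], p = p)
}

# Local windowed breakpoint scan, used when the global split is rejected:
# a short lesion in the middle of a long region dilutes the global
# two-sample t (its mean shift is averaged into thousands of flanking
# probes), but comparing the w probes on either side of each cut restores
# full contrast. Scales w = m, 2m, 4m; the (scale, cut) with the smallest
# two-sided p wins, leftmost on ties. Spurious local cuts are removed
# later by the merge step.
local_split <- function(x, min_markers) {
  n <- length(x)
  best <- NULL
  s1 <- cumsum(x)
  s2 <- cumsum(x * x)
  for (w in min_markers * c(1L, 2L, 4L)) {
    if (2 * w > n) break
    cuts <- w:(n - w)
    li <- cuts - w  # prefix index before left window
    sum_l <- s1[cuts] - c(0, s1)[li + 1L]
    sum_r <- s1[cuts + w] - s1[cuts]
    sq_l <- s2[cuts] - c(0, s2)[li + 1L]
    sq_r <- s2[cuts + w] - s2[cuts]
    ss_l <- pmax(sq_l - sum_l^2 / w, 0)
    ss_r <- pmax(sq_r - sum_r^2 / w, 0)
    sp2 <- (ss_l + ss_r) / (2 * w - 2)
    se <- sqrt(sp2 * 2 / w)
    d <- (sum_l - sum_r) / w
    t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
    # admissible cuts must leave >= min_markers probes on each side
    adm <- cuts >= min_markers & (n - cuts) >= min_markers
    if (!any(adm)) next
    t[!adm] <- 0
    i <- which.max(abs(t))
    # Bonferroni over the scan's cuts: the scan takes a maximum over ~n
    # dependent t statistics, so its nominal p is anti-conservative by
    # roughly that factor; the global argmax test is left uncorrected
    # (its statistic is diluted, not maximized over short windows)
    p <- if (is.infinite(t[i])) 0 else
      min(1, length(cuts) *
            2 * stats::pt(abs(t[i]), df = 2 * w - 2, lower.tail = FALSE))
    if (is.null(best) || p < best$p) best <- list(idx = cuts[i], t = t[i],
                                                  p = p)
  }
  best
}

# two-sided pooled-t p-value for the difference of two probe-value groups
merge_pvalue <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  d <- mean(a) - mean(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) return(if (d == 0) 1 else 0)
  2 * stats::pt(abs(d / se), df = n1 + n2 - 2, lower.tail = FALSE)
}

# segment one block of values; returns integer vector of segment end
# indices (relative to the block)
segment_block <- function(x, params) {
  ends <- integer(0)
  stack <- list(c(1L, length(x)))
  while (length(stack)) {
    r <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- r[1]; hi <- r[2]
    bs <- best_split(x[lo:hi], params$min_markers)
    if (is.null(bs) || bs$p > params$split_alpha) {
      # global argmax cut not significant; rescue short embedded lesions
      # with the windowed local scan before giving up on this region
      bs <- if (is.null(bs)) NULL else local_split(x[lo:hi],
                                                   params$min_markers)
      if (is.null(bs) || bs$p > params$split_alpha) {
        ends <- c(ends, hi)
        next
      }
    }
    {
      cut <- lo + bs$idx - 1L
      # right pushed first so segments emerge left-to-right
      stack[[length(stack) + 1L]] <- c(cut + 1L, hi)
      stack[[length(stack) + 1L]] <- c(lo, cut)
    }
  }
  ends <- sort(ends)
  # re-merge adjacent segments whose means do not differ at merge_alpha,
  # most-similar pair first
  starts <- c(1L, utils::head(ends, -1) + 1L)
  while (length(ends) > 1) {
    p <- vapply(seq_len(length(ends) - 1), function(i) {
      merge_pvalue(x[starts[i]:ends[i]], x[starts[i + 1]:ends[i + 1]])
    }, numeric(1))
    i <- which.max(p)
    if (p[i] <= params$merge_alpha) break
    ends <- ends[-i]
    starts <- starts[-(i + 1)]
  }
  ends
}

#' Segment a ratio series
#'
#' Applies recursive t-test splitting independently to every chromosome
#' (or low-density block, if [mask_low_density()] was applied; excluded
#' blocks are skipped). Segment coordinates snap to member probes:
#' start = first probe position, end = last probe position + 1 (half-open).
#'
#' @param series ratio series, optionally masked.
#' @param params a [seg_params()].
#' @return data.frame `chrom, start, end, n_markers, mean_lrr,
#'   first_row, last_row` (row indices into `series`), segments disjoint
#'   and ordered within each chromosome, jointly covering all non-excluded
#'   probes.
#' @export
segment_series <- function(series, params = seg_params()) {
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  if (is.null(series$block)) {
    series$block <- series$chrom
    series$excluded <- FALSE
  }
  out <- list()
  for (b in unique(series$block)) {
    idx <- which(series$block == b)
    if (series$excluded[idx[1]]) next
    x <- series$value[idx]
    if (length(x) < params$min_markers) {
      warning("block ", b, " has fewer than min_markers probes; ",
              "returned as a single segment", call. = FALSE)
      ends <- length(x)
    } else {
      ends <- segment_block(x, params)
    }
    starts <- c(1L, utils::head(ends, -1) + 1L)
    out[[b]] <- data.frame(
      chrom = series$chrom[idx[1]],
      start = series$pos[idx[starts]],
      end = series$pos[idx[ends]] + 1,
      n_markers = ends - starts + 1L,
      mean_lrr = vapply(seq_along(ends), function(i) {
        mean(x[starts[i]:ends[i]])
      }, numeric(1)),
      first_row = idx[starts],
      last_row = idx[ends],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, unique(series$chrom)), res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convenience: ratio series -> mask -> segments for one sample
#'
#' @inheritParams compute_ratio_series
#' @param params a [seg_params()].
#' @param max_gap passed to [mask_low_density()].
#' @return segment data.frame (see [segment_series()]).
#' @export
segment_sample <- function(tumor, normal = NULL, panel = NULL,
                           mode = c("paired", "baseline"),
                           params = seg_params(), max_gap = 1e5) {
  series <- compute_ratio_series(tumor, normal, panel, mode)
  series <- mask_low_density(series, max_gap, params$min_markers)
  segment_series(series, params)
}
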
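# Cohort-level recurrence analysis and MAR discovery.
#
# The MAR (minimal affected region) is the minimal DNA fragment affected
# by any imbalance in the majority of cohort samples. Per-position counts
# of distinct affected samples come from a sweep-line over lesion
# endpoints (after per-sample interval union); candidate regions are
# maximal constant-count runs exceeding the majority threshold, and the
# MAR is the candidate with the highest support, ties broken by longest
# length, then genomic order.

#' Per-chromosome lesion density with a chi-square uniformity test
#'
#' Normalizes lesion counts by chromosome length in Mb and tests the raw
#' counts against an expectation proportional to chromosome length
#' (chi-square goodness of fit, df = #chromosomes - 1).
#'
#' @param lesions lesion data.frame (any table with a `chrom` column).
#' @param chrom_sizes named numeric vector of chromosome lengths in bp;
#'   every lesion chromosome must be present, chromosomes without lesions
#'   contribute zero counts.
#' @return list with `table` (`chrom, size_mb, count, density,
#'   above_median`), `statistic`, `df`, `p_value` (NA with df 0 for a
#'   single chromosome).
#' @export
chromosome_density <- function(lesions, chrom_sizes) {
  missing <- setdiff(unique(lesions$chrom), names(chrom_sizes))
  if (length(missing)) {
    coord_error("no chromosome size for: ", paste(missing, collapse = ", "))
  }
  counts <- vapply(names(chrom_sizes),
                   function(cn) sum(lesions$chrom == cn), numeric(1))
  size_mb <- chrom_sizes / 1e6
  density <- counts / size_mb
  tab <- data.frame(chrom = names(chrom_sizes), size_mb = unname(size_mb),
                    count = unname(counts), density = unname(density),
                    above_median = unname(density > stats::median(density)),
                    stringsAsFactors = FALSE)
  if (length(chrom_sizes) < 2 || sum(counts) == 0) {
    return(list(table = tab, statistic = NA_real_, df = 0L,
                p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::chisq.test(counts, p = chrom_sizes / sum(chrom_sizes)))
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}

#' Cytobands overlapped by an interval
#'
#' @param chrom chromosome name.
#' @param start,end 1-based half-open interval (end > start).
#' @param cytobands cytoband map with `chrom, start, end, full_name`.
#' @return character vector of full band names with >= 1 bp overlap, in
#'   genomic order.
#' @export
map_to_cytobands <- function(chrom, start, end, cytobands) {
  if (end <= start) {
    stop("invalid interval: zero or negative length query", call. = FALSE)
  }
  cb <- cytobands[norm_chrom(cytobands$chrom) == norm_chrom(chrom), ,
                  drop = FALSE]
  if (nrow(cb) == 0) coord_error("chromosome not in cytoband map: ", chrom)
  cb <- cb[order(cb$start), , drop = FALSE]
  cb$full_name[cb$start < end & cb$end > start]
}

#' Cytobands per lesion
#'
#' @param lesions lesion data.frame.
#' @param cytobands cytoband map.
#' @return list (one element per lesion row) of overlapped band names.
#' @export
lesion_cytobands <- function(lesions, cytobands) {
  lapply(seq_len(nrow(lesions)), function(i) {
    map_to_cytobands(lesions$chrom[i], lesions$start[i], lesions$end[i],
                     cytobands)
  })
}

#' Flag lesions as known or novel against an interval database
#'
#' A lesion is known when the fraction of its length covered by the union
#' of database intervals on its chromosome reaches
#' `min_overlap_fraction`.
#'
#' @param lesions lesion data.frame.
#' @param known data.frame `chrom, start, end` of known variants
#'   (1-based half-open; see [read_known_bed()]).
#' @param min_overlap_fraction minimum covered fraction (default 0.5).
#' @return `lesions` with `known` (logical) and `known_fraction` columns.
#' @export
annotate_known <- function(lesions, known, min_overlap_fraction = 0.5) {
  if (is.null(known) || nrow(known) == 0) {
    warning("empty known-variant database: all lesions novel",
            call. = FALSE)
    lesions$known_fraction <- 0
    lesions$known <- FALSE
    return(lesions)
  }
  frac <- numeric(nrow(lesions))
  for (cn in unique(lesions$chrom)) {
    li <- which(norm_chrom(lesions$chrom) == norm_chrom(cn))
    kb <- known[norm_chrom(known$chrom) == norm_chrom(cn), , drop = FALSE]
    if (nrow(kb) == 0) next
    red <- IRanges::reduce(IRanges::IRanges(kb$start, kb$end - 1))
    for (i in li) {
      q <- IRanges::IRanges(lesions$start[i], lesions$end[i] - 1)
      cov <- sum(IRanges::width(IRanges::intersect(q, red)))
      frac[i] <- cov / (lesions$end[i] - lesions$start[i])
    }
  }
  lesions$known_fraction <- frac
  lesions$known <- frac >= min_overlap_fraction
  lesions
}

#' Known/novel summary fractions
#'
#' @param known logical vector of per-lesion known flags.
#' @return list with counts and percentages (rounded to the nearest
#'   integer; exact values retained).
#' @export
summarize_known_novel <- function(known) {
  n <- length(known)
  nk <- sum(known)
  list(n_total = n, n_known = nk, n_novel = n - nk,
       pct_known_exact = 100 * nk / n,
       pct_novel_exact = 100 * (n - nk) / n,
       pct_known = round(100 * nk / n),
       pct_novel = round(100 * (n - nk) / n))
}

# union of possibly-overlapping half-open intervals (matrix start,end);
# gaps of at most `bridge` bp are closed (a hole smaller than the probe
# spacing contains no marker and is not evidence of interruption)
merge_intervals <- function(start, end, bridge = 0) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me + bridge) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# sweep-line: per-position count of distinct affected samples on one
# chromosome; returns maximal constant-count runs with count >= 1 as
# data.frame(start, end, count). Intervals are first unioned per sample
# so each sample contributes at most 1 at any position.
sweep_coverage <- function(start, end, sample_id, bridge = 0) {
  pts <- list()
  for (sid in unique(sample_id)) {
    sel <- sample_id == sid
    m <- merge_intervals(start[sel], end[sel], bridge)
    pts[[sid]] <- m
  }
  ev_pos <- unlist(lapply(pts, function(m) c(m[, 1], m[, 2])))
  ev_del <- unlist(lapply(pts, function(m) c(rep(1, nrow(m)),
                                             rep(-1, nrow(m)))))
  o <- order(ev_pos)
  ev_pos <- ev_pos[o]; ev_del <- ev_del[o]
  # collapse coincident breakpoints
  upos <- unique(ev_pos)
  delta <- vapply(split(ev_del, match(ev_pos, upos)), sum, numeric(1))
  cnt <- cumsum(delta)
  runs <- data.frame(start = upos[-length(upos)], end = upos[-1],
                     count = cnt[-length(cnt)])
  runs <- runs[runs$count > 0 & runs$end > runs$start, , drop = FALSE]
  # merge adjacent runs with identical count
  if (nrow(runs) > 1) {
    keep <- c(TRUE, !(runs$count[-1] == runs$count[-nrow(runs)] &
                        runs$start[-1] == runs$end[-nrow(runs)]))
    grp <- cumsum(keep)
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max),
                       count = tapply(runs$count, grp, function(x) x[1]))
  }
  rownames(runs) <- NULL
  runs
}

#' Cohort recurrence profile
#'
#' Counts, per unit, the number of distinct samples carrying at least one
#' overlapping lesion. With `unit = "cytoband"` the units are the bands of
#' the supplied map; with `unit = "interval"` they are the maximal
#' genomic regions of constant distinct-sample coverage obtained by
#' sweep-line.
#'
#' @param lesions cohort lesion data.frame (`sample_id, chrom, start,
#'   end`).
#' @param cohort_size number of samples in the cohort.
#' @param unit "cytoband" or "interval".
#' @param cytobands cytoband map (required for cytoband unit).
#' @param bridge_gap per-sample gaps of at most this many bp are closed
#'   before counting (interval unit): segment bounds snap to probes, so
#'   holes narrower than the marker spacing are not real interruptions.
#' @return list with `profile` (per-unit data.frame with `count` and
#'   `freq_pct` columns), `histogram` (named vector: number of units
#'   recurring in k = 1..cohort_size samples), `cohort_size`, `unit`.
#' @export
recurrence_profile <- function(lesions, cohort_size,
                               unit = c("cytoband", "interval"),
                               cytobands = NULL, bridge_gap = 0) {
  unit <- match.arg(unit)
  stopifnot(cohort_size >= 1)
  if (nrow(lesions) == 0) stop("no lesions", call. = FALSE)
  if (unit == "cytoband") {
    if (is.null(cytobands)) stop("cytoband unit needs a cytoband map",
                                 call. = FALSE)
    bands <- lesion_cytobands(lesions, cytobands)
    pairs <- unique(data.frame(
      sample_id = rep(lesions$sample_id, lengths(bands)),
      band = unlist(bands), stringsAsFactors = FALSE))
    counts <- table(pairs$band)
    ord <- match(names(counts), cytobands$full_name)
    profile <- data.frame(unit = names(counts)[order(ord)],
                          count = as.integer(counts[order(ord)]),
                          stringsAsFactors = FALSE)
  } else {
    profile <- do.call(rbind, lapply(unique(lesions$chrom), function(cn) {
      sel <- lesions$chrom == cn
      runs <- sweep_coverage(lesions$start[sel], lesions$end[sel],
                             lesions$sample_id[sel], bridge_gap)
      cbind(chrom = cn, runs)
    }))
    profile$unit <- sprintf("%s:%d-%d", profile$chrom, profile$start,
                            profile$end)
    rownames(profile) <- NULL
  }
  profile$freq_pct <- 100 * profile$count / cohort_size
  hist <- vapply(seq_len(cohort_size),
                 function(k) sum(profile$count == k), integer(1))
  names(hist) <- seq_len(cohort_size)
  list(profile = profile, histogram = hist, cohort_size = cohort_size,
       unit = unit)
}

#' Minimal affected region (MAR) of a cohort
#'
#' Builds the per-position count of distinct affected samples (any
#' imbalance category counts) by sweep-line and extracts maximal
#' constant-count candidate regions whose support strictly exceeds
#' `cohort_size * min_fraction`. The MAR is the candidate with the
#' highest support; ties break to the longest run, then to genomic order (a sliver from one fragmented call must not displace the consensus region).
#' The mean copy number averages `cn_estimate` over the supporting
#' samples' lesions that overlap the region.
#'
#' @param lesions filtered cohort lesion data.frame.
#' @param cohort_size number of samples in the cohort (>= 1).
#' @param min_fraction majority threshold; support must be strictly
#'   greater than `cohort_size * min_fraction` (default 0.5: strict
#'   majority).
#' @param bridge_gap close per-sample gaps of at most this many bp before
#'   counting (probe-snapped segment bounds leave marker-free holes
#'   between adjacent calls); 0 disables bridging.
#' @return a `mar_result` list: `mar` (one-row data.frame `chrom, start,
#'   end, length, n_affected, cohort_size, frequency, mean_cn,
#'   dominant_category`, or NULL), `candidates` (all qualifying regions,
#'   ranked), `status` ("ok" or "no majority region").
#' @export
define_mar <- function(lesions, cohort_size, min_fraction = 0.5,
                       bridge_gap = 0) {
  stopifnot(cohort_size >= 1, min_fraction >= 0, min_fraction < 1,
            bridge_gap >= 0)
  threshold <- cohort_size * min_fraction
  cands <- list()
  for (cn in unique(lesions$chrom)) {
    sel <- lesions$chrom == cn
    runs <- sweep_coverage(lesions$start[sel], lesions$end[sel],
                           lesions$sample_id[sel], bridge_gap)
    runs <- runs[runs$count > threshold, , drop = FALSE]
    if (nrow(runs)) cands[[cn]] <- cbind(chrom = cn, runs)
  }
  if (length(cands) == 0) {
    return(structure(list(mar = NULL,
                          candidates = data.frame(),
                          cohort_size = cohort_size,
                          status = "no majority region"),
                     class = "mar_result"))
  }
  cands <- do.call(rbind, cands)
  cands$length <- cands$end - cands$start
  # rank: most supporting samples first; among equal support, the longest
  # run (trimming to majority support is what makes the region "minimal";
  # among equally supported runs the one with the widest evidence wins,
  # so a sliver created by one fragmented call cannot displace the
  # consensus region), then genomic order
  cands <- cands[order(-cands$count, -cands$length,
                       match(cands$chrom, unique(lesions$chrom)),
                       cands$start), , drop = FALSE]
  rownames(cands) <- NULL
  describe <- function(r) {
    sup <- lesions$chrom == r$chrom & lesions$start < r$end &
      lesions$end > r$start
    sup_les <- lesions[sup, , drop = FALSE]
    mean_cn <- if ("cn_estimate" %in% names(sup_les)) {
      mean(sup_les$cn_estimate)
    } else {
      NA_real_
    }
    dom <- if ("category" %in% names(sup_les)) {
      names(sort(table(sup_les$category), decreasing = TRUE))[1]
    } else {
      NA_character_
    }
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               length = r$end - r$start, n_affected = r$count,
               cohort_size = cohort_size,
               frequency = r$count / cohort_size,
               mean_cn = mean_cn, dominant_category = dom,
               stringsAsFactors = FALSE)
  }
  mar <- describe(cands[1, ])
  structure(list(mar = mar, candidates = cands, cohort_size = cohort_size,
                 status = "ok"),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  if (is.null(x$mar)) {
    cat("MAR: none (", x$status, ")\n", sep = "")
  } else {
    m <- x$mar
    cat(sprintf("MAR: %s:%d-%d (%d bp) in %d/%d samples (%.0f%%), mean CN %.1f [%s]\n",
                m$chrom, m$start, m$end, m$length, m$n_affected,
                m$cohort_size, 100 * m$frequency, m$mean_cn,
                m$dominant_category))
    cat(nrow(x$candidates), "candidate region(s)\n")
  }
  invisible(x)
}

#' Hypergeometric overlap test between two cytoband sets
#'
#' Tests whether the overlap between two sets of affected cytobands (for
#' example, training and test cohorts) is larger than expected when
#' drawing |B| bands from a universe containing |A| marked bands; p is
#' the upper-tail hypergeometric probability P(X >= |A ∩ B|). The
#' percentage is reported relative to A.
#'
#' @param bands_a,bands_b character vectors of band names (deduplicated).
#' @param universe_size total number of bands in the universe; must be at
#'   least |A ∪ B|.
#' @return list `n_a, n_b, n_overlap, universe_size, pct_exact, pct
#'   (rounded), p_value`.
#' @export
overlap_significance <- function(bands_a, bands_b, universe_size) {
  a <- unique(bands_a); b <- unique(bands_b)
  k <- length(intersect(a, b))
  if (universe_size < length(union(a, b))) {
    stop("invalid universe: smaller than |A union B|", call. = FALSE)
  }
  pct <- 100 * k / length(a)
  p <- stats::phyper(k - 1, length(a), universe_size - length(a),
                     length(b), lower.tail = FALSE)
  list(n_a = length(a), n_b = length(b), n_overlap = k,
       universe_size = universe_size, pct_exact = pct,
       pct = round(pct), p_value = p)
}
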
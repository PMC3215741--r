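# Readers and writers.
#
# All tabular formats are plain TSV/CSV; gzip input is transparent
# (base R connections auto-detect compression) and paths ending in .gz
# are written compressed. Readers validate and reject rather than coerce;
# writers produce files their own readers accept.
#
# Coordinate conventions: internal tables are 1-based half-open, UCSC
# cytoBand.txt and BED are 0-based half-open (converted on read/write by
# adding/subtracting 1 to both bounds, which preserves lengths).

PROBE_COLS <- c("probe_id", "chrom", "pos", "lrr", "baf", "genotype")
GENOTYPES <- c("AA", "AB", "BB", "NoCall")

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

write_tsv <- function(df, path) {
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write probe records to a per-sample TSV
#'
#' Columns `probe_id chrom pos lrr baf genotype`; `baf`/`genotype` are
#' empty for copy-number-only probes. A path ending in `.gz` is written
#' gzip-compressed.
#'
#' @param records probe-record data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_probe_file <- function(records, path) {
  stopifnot(all(PROBE_COLS %in% names(records)))
  write_tsv(records[PROBE_COLS], path)
}

#' Read and validate a probe file
#'
#' Rejects malformed input rather than repairing it: the header must
#' match the schema, records must already be sorted by position within
#' chromosome blocks (no silent re-sort), BAF must lie in [0, 1] and be
#' present exactly for SNP probes (those with a genotype call). Gzip
#' input is read transparently.
#'
#' @param path probe TSV path.
#' @return validated probe-record data.frame (`baf`/`genotype` NA for
#'   CN-only probes).
#' @export
read_probe_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rt")  # transparently decompresses gzip
  header <- strsplit(readLines(con, n = 1), "\t", fixed = TRUE)[[1]]
  close(con)
  if (!identical(header, PROBE_COLS)) {
    stop("probe file header must be: ", paste(PROBE_COLS, collapse = " "),
         call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(probe_id = "character",
                                         chrom = "character",
                                         pos = "numeric", lrr = "numeric",
                                         baf = "numeric",
                                         genotype = "character"),
                          na.strings = "")
  line <- function(i) i + 1L  # header is line 1
  bad <- which(!is.na(df$baf) & (df$baf < 0 | df$baf > 1))
  if (length(bad)) {
    stop("validation error: baf outside [0,1] at line ", line(bad[1]),
         call. = FALSE)
  }
  bad <- which(is.na(df$baf) != is.na(df$genotype))
  if (length(bad)) {
    stop("validation error: baf and genotype must be jointly present ",
         "(SNP probe) or absent (CN probe); line ", line(bad[1]),
         call. = FALSE)
  }
  bad <- which(!is.na(df$genotype) & !df$genotype %in% GENOTYPES)
  if (length(bad)) {
    stop("validation error: unknown genotype at line ", line(bad[1]),
         call. = FALSE)
  }
  if (any(is.na(df$pos)) || any(is.na(df$lrr))) {
    stop("validation error: missing pos/lrr", call. = FALSE)
  }
  # chromosome blocks must be contiguous and positions strictly increasing
  r <- rle(df$chrom)
  if (anyDuplicated(r$values)) {
    stop("sort-order error: chromosome blocks are not contiguous",
         call. = FALSE)
  }
  for (cn in r$values) {
    p <- df$pos[df$chrom == cn]
    if (any(diff(p) <= 0)) {
      i <- which(df$chrom == cn)[which(diff(p) <= 0)[1] + 1L]
      stop("sort-order error: positions not strictly increasing at line ",
           line(i), call. = FALSE)
    }
  }
  df
}

#' Write / read a lesion TSV
#'
#' Schema: `sample_id chrom start end n_markers mean_lrr cn_estimate
#' cn_state loh n_informative category length` (1-based half-open).
#'
#' @param lesions lesion data.frame.
#' @param path file path.
#' @return `write_lesion_file`: the path; `read_lesion_file`: the
#'   data.frame.
#' @export
write_lesion_file <- function(lesions, path) write_tsv(lesions, path)

#' @rdname write_lesion_file
#' @export
read_lesion_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "category")
  if (!all(need %in% names(df))) {
    stop("lesion file needs columns ", paste(need, collapse = " "),
         call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop("validation error: lesion end <= start", call. = FALSE)
  }
  df
}

#' Write a segment TSV
#'
#' Schema `sample_id chrom start end n_markers mean_lrr`.
#'
#' @param segments segment data.frame.
#' @param sample_id sample id recorded in the first column.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_segment_file <- function(segments, sample_id, path) {
  df <- cbind(sample_id = sample_id,
              segments[c("chrom", "start", "end", "n_markers", "mean_lrr")])
  write_tsv(df, path)
}

#' Write / read a truth-lesion table
#'
#' Schema `sample_id chrom start end cn loh`.
#'
#' @param truth truth data.frame.
#' @param path file path.
#' @return `write_truth_file`: the path; `read_truth_file`: the
#'   data.frame.
#' @export
write_truth_file <- function(truth, path) write_tsv(truth, path)

#' @rdname write_truth_file
#' @export
read_truth_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a UCSC chrom.sizes file (two columns, no header)
#'
#' @param chrom_sizes named numeric vector of lengths in bp.
#' @param path file path.
#' @return `write_chrom_sizes`: the path; `read_chrom_sizes`: a named
#'   numeric vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  df <- data.frame(chrom = names(chrom_sizes), size = unname(chrom_sizes))
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(df$size, df$chrom)
}

#' Read a UCSC cytoBand.txt file
#'
#' Five unnamed columns (chrom, start, end, band, gieStain), 0-based
#' half-open; converted to the internal 1-based half-open convention.
#' Full band names combine the stripped chromosome with the band
#' ("20p13").
#'
#' @param path cytoBand.txt path (gzip transparent).
#' @return data.frame `chrom, start, end, band, stain, full_name`.
#' @export
read_cytoband_file <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "band",
                                        "stain"),
                          stringsAsFactors = FALSE)
  df$start <- df$start + 1
  df$end <- df$end + 1
  df$full_name <- paste0(norm_chrom(df$chrom), df$band)
  df
}

#' Read a known-variant BED file
#'
#' First three columns chrom/start/end, 0-based half-open; converted to
#' 1-based half-open.
#'
#' @param path BED path.
#' @return data.frame `chrom, start, end`.
#' @export
read_known_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs >= 3 columns", call. = FALSE)
  out <- df[1:3]
  names(out) <- c("chrom", "start", "end")
  out$start <- out$start + 1
  out$end <- out$end + 1
  if (any(out$end <= out$start)) {
    stop("validation error: BED end <= start", call. = FALSE)
  }
  out
}

# Fig-1 style category colors for browser display
CATEGORY_RGB <- c(AMP_LOH = "173,216,230",   # light blue
                  AMP_NO_LOH = "0,0,139",    # dark blue
                  AUPD = "0,128,0",          # green
                  DEL_LOH = "238,130,238",   # violet
                  DEL_NO_LOH = "230,75,140") # cyclamen

#' Export lesions as BED9
#'
#' Internal 1-based half-open coordinates become BED (0-based half-open)
#' by subtracting 1 from both bounds, preserving lengths; column 9 colors
#' each lesion by category (light blue / dark blue / green / violet /
#' cyclamen for AMP_LOH / AMP_NO_LOH / AUPD / DEL_LOH / DEL_NO_LOH).
#'
#' @param lesions lesion data.frame.
#' @param path optional output path; with `path = NULL` the BED
#'   data.frame is returned.
#' @return the BED data.frame (invisibly when written).
#' @export
convert_lesions_to_bed <- function(lesions, path = NULL) {
  if (nrow(lesions) == 0) {
    bed <- data.frame(chrom = character(), chromStart = numeric(),
                      chromEnd = numeric(), name = character(),
                      score = numeric(), strand = character(),
                      thickStart = numeric(), thickEnd = numeric(),
                      itemRgb = character(), stringsAsFactors = FALSE)
    if (!is.null(path)) {
      con <- open_out(path)
      on.exit(close(con))
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      return(invisible(bed))
    }
    return(bed)
  }
  bed <- data.frame(chrom = lesions$chrom,
                    chromStart = lesions$start - 1,
                    chromEnd = lesions$end - 1,
                    name = paste(lesions$sample_id, lesions$category,
                                 sep = "|"),
                    score = 0, strand = ".",
                    thickStart = lesions$start - 1,
                    thickEnd = lesions$end - 1,
                    itemRgb = unname(CATEGORY_RGB[lesions$category]),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- open_out(path)
    on.exit(close(con))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Read a BED9 lesion export back into a minimal lesion table
#'
#' @param path BED9 path produced by [convert_lesions_to_bed()].
#' @return data.frame `sample_id, chrom, start, end, category` in the
#'   internal 1-based half-open convention.
#' @export
read_lesion_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(df[[4]], "|", fixed = TRUE)
  data.frame(sample_id = vapply(parts, `[`, "", 1),
             chrom = df[[1]], start = df[[2]] + 1, end = df[[3]] + 1,
             category = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Write / read a qPCR wells CSV (`sample_id,replicate,ct_fam,ct_vic`)
#'
#' @param wells wells data.frame.
#' @param path file path.
#' @return `write_wells_csv`: the path; `read_wells_csv`: the data.frame.
#' @export
write_wells_csv <- function(wells, path) {
  con <- open_out(path)
  on.exit(close(con))
  utils::write.csv(wells, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wells_csv
#' @export
read_wells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "ct_fam", "ct_vic")
  if (!all(need %in% names(df))) {
    stop("wells CSV needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df
}

#' Write qPCR copy-number calls to CSV
#'
#' Columns `sample_id,mean_dct,sd_dct,cn_estimate,cn_integer,qc_pass`.
#'
#' @param calls output of [copy_number_no_calibrator()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_calls_csv <- function(calls, path) {
  cols <- c("sample_id", "mean_dct", "sd_dct", "cn_estimate",
            "cn_integer", "qc_pass")
  con <- open_out(path)
  on.exit(close(con))
  utils::write.csv(calls[cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' One probe TSV per tumor (`<id>.tumor.tsv`) and matched normal
#' (`<id>.normal.tsv`), plus `truth.tsv` and `chrom.sizes`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param outdir output directory (created if needed).
#' @param gzip write probe files gzip-compressed.
#' @return the output directory, invisibly.
#' @export
write_cohort <- function(cohort, outdir, gzip = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".tsv.gz" else ".tsv"
  for (sid in names(cohort$samples)) {
    write_probe_file(cohort$samples[[sid]]$tumor,
                     file.path(outdir, paste0(sid, ".tumor", ext)))
    if (!is.null(cohort$samples[[sid]]$normal)) {
      write_probe_file(cohort$samples[[sid]]$normal,
                       file.path(outdir, paste0(sid, ".normal", ext)))
    }
  }
  write_truth_file(cohort$truth, file.path(outdir, "truth.tsv"))
  write_chrom_sizes(cohort$map$chrom_sizes,
                    file.path(outdir, "chrom.sizes"))
  invisible(outdir)
}
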
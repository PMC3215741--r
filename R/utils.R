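# Shared helpers.
#
# Internal genomic coordinates are 1-based half-open [start, end), so
# length = end - start, and UCSC/BED (0-based half-open) coordinates are
# obtained by subtracting 1 from both bounds.

#' Strip a leading "chr" prefix from chromosome names
#'
#' Chromosome naming conventions differ between sources ("20" vs "chr20");
#' comparisons inside the package are always made on the stripped form.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the "chr" prefix.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Length of half-open genomic intervals
#'
#' @param start,end 1-based half-open interval bounds (end exclusive).
#' @return integer-valued lengths, `end - start`.
#' @export
interval_length <- function(start, end) {
  if (any(end <= start)) {
    stop("invalid interval: end must be > start (half-open [start, end))",
         call. = FALSE)
  }
  end - start
}

# clip to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop with a consistent coordinate-error prefix
coord_error <- function(...) stop("coordinate error: ", ..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
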
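#' Genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' `strand`, using 0-based half-open coordinates throughout the package
#' (BED-native; GTF's 1-based closed convention is converted at the I/O
#' boundary).  Strand is one of `"+"`, `"-"` or `"*"` (unknown); unknown is a
#' first-class value and is never coerced.
#'
#' @param chrom Chromosome names (non-empty character).
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return A data frame with one row per interval.
#' @examples
#' gi("chr2L", 0, 100)
#' @export
gi <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop("interval chromosome names must be non-empty")
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("intervals require 0 <= start < end")
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  invisible(x)
}

# Convert 0-based half-open rows to an IRanges (1-based closed).
.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Overlap length of two intervals
#'
#' Number of bases shared by two intervals on the same chromosome; strand is
#' ignored.  Intervals on different chromosomes share 0 bases, as do
#' half-open-adjacent intervals.
#'
#' @param a,b Single intervals: one-row data frames or lists with `chrom`,
#'   `start`, `end`.
#' @return Overlap in bp (non-negative scalar).
#' @examples
#' overlap_length(gi("chr2L", 0, 100), gi("chr2L", 50, 150))  # 50
#' @export
overlap_length <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Total bases covered by a set of intervals
#'
#' @param intervals Data frame of intervals, all on one chromosome.
#' @return Union length in bp; 0 for an empty set.
#' @examples
#' union_length(gi("chr2L", c(0, 200), c(300, 400)))  # 400
#' @export
union_length <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  validate_intervals(intervals)
  if (length(unique(intervals$chrom)) > 1L) {
    stop("union_length() requires all intervals on one chromosome")
  }
  sum(IRanges::width(IRanges::reduce(.as_iranges(intervals))))
}

#' Fraction of a region covered by peaks
#'
#' Coverage of a (possibly multi-interval) region by the union of a peak set,
#' as used for H3K36me3/Pol II occupancy over transcribed regions.  Peaks on
#' other chromosomes are ignored, peak strand is ignored and peaks extending
#' beyond the region are clipped.
#'
#' @param region Non-empty data frame of intervals on one chromosome.
#' @param peaks Data frame of peak intervals (possibly empty).
#' @return Fraction in `[0, 1]`.
#' @examples
#' coverage_fraction(gi("chr2L", 0, 1000), gi("chr2L", c(0, 500), c(300, 700)))
#' @export
coverage_fraction <- function(region, peaks) {
  if (is.null(region) || nrow(region) == 0L) {
    stop("coverage_fraction() requires a non-empty region")
  }
  validate_intervals(region)
  if (length(unique(region$chrom)) > 1L) {
    stop("coverage_fraction() requires the region on one chromosome")
  }
  denom <- union_length(region)
  if (is.null(peaks) || nrow(peaks) == 0L) return(0)
  peaks <- peaks[peaks$chrom == region$chrom[1L] & peaks$end > 0, , drop = FALSE]
  if (nrow(peaks) == 0L) return(0)
  peaks$start <- pmax(peaks$start, 0)
  hit <- IRanges::intersect(IRanges::reduce(.as_iranges(region)),
                            IRanges::reduce(.as_iranges(peaks)))
  sum(IRanges::width(hit)) / denom
}

# Intersection length between two interval sets on one chromosome (strand
# ignored); used by the coordinate-overlap dedup fallback and classification.
.intersection_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  total <- 0
  for (ch in chroms) {
    ia <- IRanges::reduce(.as_iranges(a[a$chrom == ch, , drop = FALSE]))
    ib <- IRanges::reduce(.as_iranges(b[b$chrom == ch, , drop = FALSE]))
    total <- total + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  total
}
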
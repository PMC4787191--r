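#' @name expression
#' @title Read trimming, RPKM quantification and library flags
#'
#' @description
#' Pre-processing and quantification: a fixed-head 5' trim plus quality-based
#' 3' trim with a minimum retained length; deterministic RPKM from read
#' counts, exonic transcript length, and library-wide mapped totals;
#' expressed and poly(A)-minus calls; and per-stage expression profiles by
#' biotype.
NULL

# phred+33 decode/encode
.qual_ints <- function(q) utf8ToInt(q) - 33L
.qual_chr <- function(q) intToUtf8(q + 33L)

#' Trim reads (5' fixed head, 3' quality scan, minimum length)
#'
#' Removes `trim_head` bases from the 5' end, then removes 3'-terminal bases
#' while their quality is at or below `trim_quality`, stopping at the first
#' base (scanning from the 3' end) whose quality exceeds it.  Reads shorter
#' than `trim_min_len` after trimming are discarded (not errors).
#'
#' @param reads Data frame `read_id`, `seq`, `qual` (phred+33), e.g. from
#'   [read_fastq()].
#' @param thresholds A [lnc_thresholds()].
#' @return Data frame `read_id`, `seq`, `qual`, `kept`; for discarded reads
#'   `seq`/`qual` hold the trimmed remnant (possibly empty).
#' @examples
#' r <- data.frame(read_id = "r1", seq = strrep("A", 46),
#'                 qual = strrep("?", 46))  # q30 throughout
#' trim_reads(r)$kept  # TRUE: 36 bp remain, exactly the minimum
#' @export
trim_reads <- function(reads, thresholds = lnc_thresholds()) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  out <- reads
  out$kept <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    q <- .qual_ints(reads$qual[i])
    n <- length(q)
    from <- thresholds$trim_head + 1L
    to <- n
    while (to >= from && q[to] <= thresholds$trim_quality) to <- to - 1L
    if (to < from) {
      out$seq[i] <- ""; out$qual[i] <- ""; out$kept[i] <- FALSE
    } else {
      out$seq[i] <- substr(reads$seq[i], from, to)
      out$qual[i] <- substr(reads$qual[i], from, to)
      out$kept[i] <- (to - from + 1L) >= thresholds$trim_min_len
    }
  }
  out
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = count * 1e9 / (total_mapped * length)`, with the full exonic
#' transcript length and the library-wide mapped total as denominators.
#'
#' @param read_count Read counts (non-negative).
#' @param transcript_length Exonic transcript lengths in bp (positive).
#' @param total_mapped Library-wide mapped-read totals (positive).
#' @return RPKM values (vectorized).
#' @examples
#' compute_rpkm(10, 2000, 5e6)  # 1
#' @export
compute_rpkm <- function(read_count, transcript_length, total_mapped) {
  if (any(transcript_length <= 0)) stop("transcript length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  if (any(read_count < 0)) stop("read counts must be non-negative")
  as.numeric(read_count) * 1e9 /
    (as.numeric(total_mapped) * as.numeric(transcript_length))
}

#' Expressed flag
#'
#' A transcript is expressed when its RPKM strictly exceeds the threshold
#' (RPKM exactly 1 is *not* expressed under the default).
#'
#' @param rpkm RPKM values.
#' @param threshold Expression threshold (default 1).
#' @return Logical vector.
#' @export
flag_expressed <- function(rpkm, threshold = lnc_thresholds()$rpkm_expressed) {
  rpkm > threshold
}

#' Poly(A)-minus call from dual-chemistry libraries
#'
#' A transcript is called poly(A)-minus under a stringent criterion: it must
#' be expressed in the ribo-zero library (RPKM strictly above the threshold)
#' and show *no* signal in the poly(A)-enriched library (RPKM exactly 0; no
#' epsilon).
#'
#' @param rpkm_ribozero,rpkm_polya RPKM in the ribo-zero and poly(A)-enriched
#'   libraries.
#' @param threshold Expression threshold for the ribo-zero side.
#' @return Logical vector.
#' @export
infer_polya_minus <- function(rpkm_ribozero, rpkm_polya,
                              threshold = lnc_thresholds()$rpkm_expressed) {
  rpkm_ribozero > threshold & rpkm_polya == 0
}

#' Per-stage expression profile by biotype
#'
#' For each stage (column) and biotype: the arithmetic mean RPKM over all
#' transcripts of that biotype, and the number with RPKM above the expressed
#' threshold.
#'
#' @param rpkm_matrix Numeric matrix, transcripts x stages, with transcript
#'   ids as row names.
#' @param biotype Named character vector (`"mRNA"`/`"lncRNA"`) covering every
#'   row.
#' @param threshold Expressed threshold.
#' @return Data frame: `stage`, `biotype`, `mean_rpkm`, `n_expressed`.
#' @export
stage_profile <- function(rpkm_matrix, biotype,
                          threshold = lnc_thresholds()$rpkm_expressed) {
  if (is.null(dim(rpkm_matrix)) || nrow(rpkm_matrix) == 0L ||
      ncol(rpkm_matrix) == 0L) {
    stop("stage_profile() requires a non-empty matrix")
  }
  bt <- biotype[rownames(rpkm_matrix)]
  if (any(is.na(bt))) stop("every transcript needs a biotype")
  stages <- colnames(rpkm_matrix)
  if (is.null(stages)) stages <- as.character(seq_len(ncol(rpkm_matrix)))
  rows <- list()
  for (b in unique(bt)) {
    m <- rpkm_matrix[bt == b, , drop = FALSE]
    rows[[b]] <- data.frame(stage = stages, biotype = b,
                            mean_rpkm = colMeans(m),
                            n_expressed = colSums(m > threshold),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
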
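#' @name chromatin
#' @title Chromatin signatures, CAGE completeness and validation groups
#'
#' @description
#' Assignment of active-transcription chromatin signatures to genes from
#' peak intervals: H3K4me3 presence in a promoter window around the TSS,
#' H3K36me3 coverage of the transcribed region, Pol II occupancy over
#' promoter plus transcribed region, the joint K4-K36 call, CAGE-based 5'
#' completeness of transcripts, and the expression-by-signature validation
#' groups G1-G4.  Peak datasets of one mark are pooled (any-stage presence
#' counts) before assignment.
NULL

#' Promoter window around a TSS
#'
#' The window contains the bases at signed transcription-direction distance
#' `d` from the TSS with `-upstream <= d <= +downstream` (TSS at `d = 0`);
#' 601 bp wide under the defaults, clipped at the chromosome start.
#'
#' @param tss 0-based position of the TSS base.
#' @param strand `"+"` or `"-"`; unknown strand is an error (promoters are
#'   only defined for genes with well-defined transcriptional direction).
#' @param thresholds A [lnc_thresholds()].
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @examples
#' promoter_window(10000, "+")  # bases 9500..10100 -> c(9500, 10101)
#' @export
promoter_window <- function(tss, strand, thresholds = lnc_thresholds()) {
  if (!strand %in% c("+", "-")) {
    stop("promoter window requires a known strand")
  }
  if (strand == "+") {
    w <- c(tss - thresholds$promoter_upstream,
           tss + thresholds$promoter_downstream + 1)
  } else {
    w <- c(tss - thresholds$promoter_downstream,
           tss + thresholds$promoter_upstream + 1)
  }
  c(max(0, w[1L]), w[2L])
}

# gene-level TSS (0-based base) and span for each gene of a transcript_set;
# TSS = 5'-most isoform start on the gene's strand
.gene_tss <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1, genes$start)
}

.mark_peaks <- function(peaks, mark) {
  peaks[!is.na(peaks$mark) & peaks$mark == mark, , drop = FALSE]
}

#' Assign chromatin signatures to genes
#'
#' For each gene:
#'
#' * `h3k4me3_present`: any H3K4me3 peak (any dataset) overlaps the promoter
#'   window by at least 1 bp; `NA` (not assessable, distinct from `FALSE`)
#'   when the gene strand is unknown.
#' * `h3k36me3_coverage` / `h3k36me3_present`: coverage of the transcribed
#'   region (gene span TSS to TES, introns included) by pooled H3K36me3
#'   peaks; present when coverage exceeds 0.
#' * `polII_present` / `polII_coverage`: presence is tested over the promoter
#'   window united with the transcribed region (the promoter is omitted when
#'   the strand is unknown); coverage is computed over the transcribed region
#'   only.
#' * `k4k36`: H3K4me3 present *and* H3K36me3 present.
#'
#' @param genes A [transcript_set()] whose genes are to be annotated.
#' @param peaks Peak data frame (`chrom`, `start`, `end`, `mark`, `dataset`),
#'   e.g. rbind of [read_bed()] results.
#' @param thresholds A [lnc_thresholds()].
#' @return Data frame: `gene_id`, `strand`, `h3k4me3_present`,
#'   `h3k36me3_coverage`, `h3k36me3_present`, `polII_present`,
#'   `polII_coverage`, `k4k36`.
#' @export
chromatin_annotate <- function(genes, peaks,
                               thresholds = lnc_thresholds()) {
  gt <- gene_table(genes)
  k4 <- .mark_peaks(peaks, "H3K4me3")
  k36 <- .mark_peaks(peaks, "H3K36me3")
  pol <- .mark_peaks(peaks, "PolII")
  tss <- .gene_tss(gt)
  out <- lapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    span <- gi(g$chrom, g$start, g$end)
    k4_present <- NA
    promoter <- NULL
    if (g$strand %in% c("+", "-")) {
      pw <- promoter_window(tss[i], g$strand, thresholds)
      promoter <- gi(g$chrom, pw[1L], pw[2L])
      k4g <- k4[k4$chrom == g$chrom, , drop = FALSE]
      k4_present <- any(k4g$start < pw[2L] & k4g$end > pw[1L])
    }
    k36_cov <- coverage_fraction(span, k36)
    pol_cov <- coverage_fraction(span, pol)
    pol_region <- if (is.null(promoter)) span else {
      # span and promoter may overlap; presence only needs any contact
      rbind(span, promoter)
    }
    polg <- pol[pol$chrom == g$chrom, , drop = FALSE]
    pol_present <- any(vapply(seq_len(nrow(pol_region)), function(j) {
      any(polg$start < pol_region$end[j] & polg$end > pol_region$start[j])
    }, logical(1)))
    data.frame(gene_id = g$gene_id, strand = g$strand,
               h3k4me3_present = k4_present,
               h3k36me3_coverage = k36_cov,
               h3k36me3_present = k36_cov > 0,
               polII_present = pol_present,
               polII_coverage = pol_cov,
               k4k36 = isTRUE(k4_present) && k36_cov > 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(
    data.frame(gene_id = character(), strand = character(),
               h3k4me3_present = logical(), h3k36me3_coverage = numeric(),
               h3k36me3_present = logical(), polII_present = logical(),
               polII_coverage = numeric(), k4k36 = logical(),
               stringsAsFactors = FALSE))))
  rownames(res) <- NULL
  res
}

#' Joint K4-K36 signature call
#'
#' @param h3k4me3_present,h3k36me3_present Logical vectors.
#' @return Logical vector: both marks present (`NA` H3K4me3 yields `FALSE`,
#'   matching the not-assessable semantics).
#' @export
k4k36_call <- function(h3k4me3_present, h3k36me3_present) {
  !is.na(h3k4me3_present) & h3k4me3_present & h3k36me3_present
}

#' CAGE 5'-completeness of transcripts
#'
#' A transcript is 5'-complete when a CAGE peak intersects the inclusive
#' window of `cage_window` bp on either side of its 5' base.  Transcripts
#' with unknown strand are not assessable (`NA`).
#'
#' @param ts A [transcript_set()].
#' @param cage_peaks Peak data frame (mark `CAGE` or any peak set).
#' @param thresholds A [lnc_thresholds()].
#' @return Named logical vector over transcript ids.
#' @export
cage_complete <- function(ts, cage_peaks, thresholds = lnc_thresholds()) {
  stopifnot(inherits(ts, "transcript_set"))
  tx <- ts$tx
  w <- thresholds$cage_window
  res <- vapply(seq_len(nrow(tx)), function(i) {
    if (tx$strand[i] == "*") return(NA)
    five <- if (tx$strand[i] == "+") tx$start[i] else tx$end[i] - 1
    lo <- max(0, five - w)
    hi <- five + w + 1  # inclusive window [five-w, five+w] as half-open
    p <- cage_peaks[cage_peaks$chrom == tx$chrom[i], , drop = FALSE]
    any(p$start < hi & p$end > lo)
  }, logical(1))
  stats::setNames(res, tx$transcript_id)
}

#' Assign validation groups G1-G4
#'
#' Expressed genes (RPKM strictly above the expressed threshold; anything
#' else is an error, matching the grouping precondition) are grouped by the
#' joint chromatin state and expression extremes:
#' all three signatures and RPKM above the 3rd quartile -> `G1`; all three
#' and RPKM below the 1st quartile -> `G2`; none of the three and RPKM above
#' the 3rd quartile -> `G3`; none and below the 1st quartile -> `G4`;
#' everything else (mixed signatures or mid-range RPKM) -> `none`.
#'
#' @param rpkm RPKM values (all `> rpkm_expressed`).
#' @param h3k4me3,h3k36me3,polII Logical signature flags (vectorized; `NA`
#'   H3K4me3 counts as not-present for "all three" and as present-unknown for
#'   "none", yielding `none`).
#' @param thresholds A [lnc_thresholds()].
#' @return Character vector of `G1`, `G2`, `G3`, `G4` or `none`.
#' @export
assign_validation_group <- function(rpkm, h3k4me3, h3k36me3, polII,
                                    thresholds = lnc_thresholds()) {
  if (any(rpkm <= thresholds$rpkm_expressed)) {
    stop("validation groups are defined for expressed genes only (RPKM > ",
         thresholds$rpkm_expressed, ")")
  }
  all3 <- !is.na(h3k4me3) & h3k4me3 & h3k36me3 & polII
  none3 <- !is.na(h3k4me3) & !h3k4me3 & !h3k36me3 & !polII
  high <- rpkm > thresholds$rpkm_q3
  low <- rpkm < thresholds$rpkm_q1
  out <- rep("none", length(rpkm))
  out[all3 & high] <- "G1"
  out[all3 & low] <- "G2"
  out[none3 & high] <- "G3"
  out[none3 & low] <- "G4"
  out
}
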
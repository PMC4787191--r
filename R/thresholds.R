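#' Pipeline thresholds
#'
#' Bundle of every numeric cutoff used by the curation, discovery, expression
#' and chromatin stages.  All values can be overridden individually; the
#' defaults are the operating points of the published fly lncRNA catalogue
#' this package re-implements.
#'
#' @param min_lnc_length Minimum lncRNA length in bp; shorter transcripts are
#'   removed (default 200).
#' @param rpkm_expressed RPKM above which a transcript counts as expressed
#'   (strictly greater than; default 1).
#' @param dedup_evalue E-value ceiling for alignments considered during
#'   redundancy removal (default 1e-10).
#' @param dedup_overlap_default Overlap fraction at/above which a candidate is
#'   redundant against the primary set (default 0.5).
#' @param dedup_overlap_young_vs_brown Overlap fraction for the 90 % rule used
#'   when comparing intake candidates against intergenic-only sources
#'   (default 0.9).
#' @param rrna_evalue,rrna_identity rRNA-contamination call: alignment to an
#'   rRNA with E-value below `rrna_evalue` and identity strictly above
#'   `rrna_identity` percent removes the transcript (defaults 1e-10, 99).
#' @param coding_prob_cutoff Coding probability at/above which a candidate is
#'   treated as coding (default 0.39).
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS, in bp along the direction of transcription (defaults 500, 100).
#' @param cage_window Half-width in bp of the inclusive window around a
#'   transcript 5' end searched for a CAGE peak (default 50).
#' @param trim_head Bases removed from the 5' end of every read (default 10).
#' @param trim_quality Phred score a 3'-terminal base must strictly exceed to
#'   stop the 3' trim (default 20).
#' @param trim_min_len Minimum read length retained after trimming
#'   (default 36).
#' @param qpcr_cutoff_brain,qpcr_cutoff_body Minus-delta-Ct detection cutoffs
#'   for brain and whole-body RT-qPCR experiments (defaults 1, 2).
#' @param rpkm_q1,rpkm_q3 RPKM quartiles defining low (< q1) and high (> q3)
#'   expression for validation grouping (defaults 2.78, 12.92).
#'
#' @return A named list of class `"lnc_thresholds"`.
#' @examples
#' th <- lnc_thresholds(min_lnc_length = 250)
#' th$min_lnc_length
#' @export
lnc_thresholds <- function(min_lnc_length = 200,
                           rpkm_expressed = 1,
                           dedup_evalue = 1e-10,
                           dedup_overlap_default = 0.5,
                           dedup_overlap_young_vs_brown = 0.9,
                           rrna_evalue = 1e-10,
                           rrna_identity = 99,
                           coding_prob_cutoff = 0.39,
                           promoter_upstream = 500,
                           promoter_downstream = 100,
                           cage_window = 50,
                           trim_head = 10,
                           trim_quality = 20,
                           trim_min_len = 36,
                           qpcr_cutoff_brain = 1,
                           qpcr_cutoff_body = 2,
                           rpkm_q1 = 2.78,
                           rpkm_q3 = 12.92) {
  th <- list(
    min_lnc_length = min_lnc_length,
    rpkm_expressed = rpkm_expressed,
    dedup_evalue = dedup_evalue,
    dedup_overlap_default = dedup_overlap_default,
    dedup_overlap_young_vs_brown = dedup_overlap_young_vs_brown,
    rrna_evalue = rrna_evalue,
    rrna_identity = rrna_identity,
    coding_prob_cutoff = coding_prob_cutoff,
    promoter_upstream = promoter_upstream,
    promoter_downstream = promoter_downstream,
    cage_window = cage_window,
    trim_head = trim_head,
    trim_quality = trim_quality,
    trim_min_len = trim_min_len,
    qpcr_cutoff_brain = qpcr_cutoff_brain,
    qpcr_cutoff_body = qpcr_cutoff_body,
    rpkm_q1 = rpkm_q1,
    rpkm_q3 = rpkm_q3
  )
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  bad <- names(th)[!vapply(th, num1, logical(1))]
  if (length(bad)) {
    stop("thresholds must be finite scalars: ", paste(bad, collapse = ", "))
  }
  pos <- c("min_lnc_length", "promoter_upstream", "promoter_downstream",
           "cage_window", "trim_min_len", "rpkm_q1", "rpkm_q3")
  for (f in pos) {
    if (th[[f]] <= 0) stop("threshold '", f, "' must be positive")
  }
  if (th$dedup_overlap_default <= 0 || th$dedup_overlap_default > 1 ||
      th$dedup_overlap_young_vs_brown <= 0 ||
      th$dedup_overlap_young_vs_brown > 1) {
    stop("overlap thresholds must lie in (0, 1]")
  }
  if (th$coding_prob_cutoff < 0 || th$coding_prob_cutoff > 1) {
    stop("'coding_prob_cutoff' must lie in [0, 1]")
  }
  if (th$rpkm_q1 >= th$rpkm_q3) stop("'rpkm_q1' must be below 'rpkm_q3'")
  structure(th, class = "lnc_thresholds")
}

#' @export
print.lnc_thresholds <- function(x, ...) {
  cat("lncRNA pipeline thresholds:\n")
  for (f in names(x)) cat(sprintf("  %-30s %g\n", f, x[[f]]))
  invisible(x)
}
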